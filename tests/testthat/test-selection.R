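test_that("deleterious consensus applies the three thresholds jointly", {
  scores <- tibble::tibble(
    sift     = c(0.05, 0.06, 0.01, NA,  0.01),
    provean  = c(-2.6, -3.0, -2.5, -9,  -5.0),
    polyphen = c(0.6,  0.9,  0.9,  0.9, 0.5)
  )
  out <- deleterious_consensus(scores)
  expect_equal(out$consensus,
               c("deleterious",  # boundary: 0.05 <=, -2.6 <, 0.6 >
                 "tolerated",    # sift fails
                 "tolerated",    # provean -2.5 exactly fails (strict <)
                 "unscorable",   # missing sift
                 "tolerated"))   # polyphen 0.5 exactly fails (strict >)
  expect_error(deleterious_consensus(tibble::tibble(sift = 1.2, provean = -3,
                                                    polyphen = 0.5)),
               "sift")
  expect_error(deleterious_consensus(tibble::tibble(sift = 0.5, provean = -3,
                                                    polyphen = -0.1)),
               "polyphen")
})

test_that("relaxing any consensus threshold never shrinks the deleterious set", {
  set.seed(5)
  scores <- tibble::tibble(sift = runif(300), provean = rnorm(300, -2, 2),
                           polyphen = runif(300))
  n_del <- function(...) {
    sum(deleterious_consensus(scores, ...)$consensus == "deleterious")
  }
  base <- n_del()
  expect_gte(n_del(sift_max = 0.1), base)
  expect_gte(n_del(provean_lt = -2.0), base)
  expect_gte(n_del(polyphen_gt = 0.4), base)
})

test_that("deleterious pattern report summarises carriers and fraction", {
  calls <- tibble::tibble(
    chrom = "chr1", pos = c(10L, 20L, 30L), ref = "A", alt = "T",
    carriers = list("s1", "s2", c("s1", "s3")),
    n_carriers = c(1L, 1L, 2L),
    carrier_gt = c("0/1", "0/1", "1/1"),
    consensus = "deleterious"
  )
  rep <- deleterious_pattern_report(calls, total_somatic = 3037)
  expect_equal(rep$n_deleterious, 3)
  expect_equal(rep$n_shared, 1)
  expect_equal(rep$n_homozygous_state, 1)
  expect_equal(rep$per_sample$n[rep$per_sample$sample == "s1"], 2)
  # 44 consensus of 3037 total is the printed 1.45%
  rep44 <- deleterious_pattern_report(calls[rep(1, 44), ],
                                      total_somatic = 3037)
  expect_equal(rep44$consensus_percent, 1.45)
  # empty input: zero report
  rep0 <- deleterious_pattern_report(calls[0, ], total_somatic = 100)
  expect_equal(rep0$n_deleterious, 0)
  expect_equal(rep0$consensus_percent, 0)
})

outgroup_pop <- function(n_ref, n_het, n_alt, pos = 100L) {
  gts <- c(rep("0/0", n_ref), rep("0/1", n_het), rep("1/1", n_alt))
  tibble::tibble(chrom = "chr1", pos = pos,
                 sample = sprintf("o%02d", seq_along(gts)), gt = gts)
}

test_that("selection classes follow the strict 95% thresholds", {
  call <- tibble::tibble(chrom = "chr1", pos = 100L, ref = "A", alt = "T",
                         ancestral = "A", derived = "T")
  # derived (alt) at 0.96 in the outgroup: positive
  pos_call <- classify_selection(call, outgroup_pop(2, 0, 48))
  expect_equal(pos_call$post_af, 0.96)
  expect_equal(pos_call$selection_class, "positive")
  # ancestral at 0.96: purifying
  pur_call <- classify_selection(call, outgroup_pop(48, 0, 2))
  expect_equal(pur_call$pre_af, 0.96)
  expect_equal(pur_call$selection_class, "purifying")
  # exactly 0.95 is not strictly above the threshold
  edge <- classify_selection(call, outgroup_pop(1, 0, 19))
  expect_equal(edge$post_af, 0.95)
  expect_equal(edge$selection_class, "unclassified")
  # balanced frequencies: unclassified
  bal <- classify_selection(call, outgroup_pop(5, 0, 5))
  expect_equal(bal$selection_class, "unclassified")
  # absent from the outgroup: unclassified with reason
  gone <- classify_selection(call, outgroup_pop(5, 0, 5, pos = 999L))
  expect_equal(gone$selection_class, "unclassified")
  expect_equal(gone$selection_reason, "absent_from_outgroup")
  # polarity flips when the derived allele is the reference
  flipped <- call
  flipped$ancestral <- "T"; flipped$derived <- "A"
  fl <- classify_selection(flipped, outgroup_pop(48, 0, 2))
  expect_equal(fl$post_af, 0.96)
  expect_equal(fl$selection_class, "positive")
})

test_that("positive and purifying classes are mutually exclusive", {
  set.seed(11)
  calls <- tibble::tibble(chrom = "chr1", pos = 10L * (1:200), ref = "A",
                          alt = "T", ancestral = "A", derived = "T")
  outg <- dplyr::bind_rows(lapply(calls$pos, function(p) {
    n_alt <- rbinom(1, 20, runif(1))
    outgroup_pop(20 - n_alt, 0, n_alt, pos = p)
  }))
  cl <- classify_selection(calls, outg)
  expect_false(any(cl$pre_af > 0.95 & cl$post_af > 0.95, na.rm = TRUE))
  expect_true(all(cl$selection_class %in% c("positive", "purifying",
                                            "unclassified")))
})

test_that("derived allele burden reports het and fixed fractions", {
  gts <- dplyr::bind_rows(
    tidyr::expand_grid(chrom = "chr1", pos = 1:6 * 10L,
                       sample = c("a", "b")) |>
      dplyr::mutate(gt = rep(c("0/1", "0/1"), 6)),
    tidyr::expand_grid(chrom = "chr1", pos = 7:8 * 10L,
                       sample = c("a", "b")) |>
      dplyr::mutate(gt = "1/1")
  )
  burden <- derived_allele_burden(gts, maf_min = 0.1)
  expect_equal(burden$n_sites, 8)
  expect_equal(burden$het_percent, 75.0)
  expect_equal(burden$fixed_percent, 25.0)
})
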