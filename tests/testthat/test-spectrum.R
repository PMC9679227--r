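toy_ref <- function(seq) list(sequences = c(chr1 = seq))

test_that("strand collapse maps purine-rooted changes to pyrimidine classes", {
  ref <- toy_ref("AGGA")
  calls <- tibble::tibble(chrom = "chr1", pos = 2L, ref = "G", alt = "A")
  spec <- classify_spectrum(calls, ref)
  expect_equal(spec$class6$count[spec$class6$class == "C>T"], 1L)
  expect_equal(sum(spec$class6$count), 1L)
  # empty call set: all-zero table
  spec0 <- classify_spectrum(calls[0, ], ref)
  expect_true(all(spec0$class6$count == 0))
  # ref mismatch against the sequence is coordinate drift
  bad <- tibble::tibble(chrom = "chr1", pos = 2L, ref = "C", alt = "A")
  expect_error(classify_spectrum(bad, ref), "coordinate drift")
})

test_that("6-class spectrum is invariant to reverse complement", {
  cfg <- small_config(seed = 31, genome_length = 5e4, snv_rate = 2e-6,
                      indel_rate = 0)
  ref <- simulate_genome(cfg)
  truth <- simulate_mutations(ref, cfg)
  calls <- truth$branch_mutations[truth$branch_mutations$type == "snv", ]
  spec_fwd <- classify_spectrum(calls, ref)

  comp <- c(A = "T", C = "G", G = "C", T = "A")
  rc_sequences <- vapply(ref$sequences, function(s) {
    paste(rev(comp[strsplit(s, "")[[1]]]), collapse = "")
  }, character(1))
  lens <- nchar(ref$sequences)
  rc_calls <- calls
  rc_calls$pos <- as.integer(lens[calls$chrom] + 1L - calls$pos)
  rc_calls$ref <- unname(comp[calls$ref])
  rc_calls$alt <- unname(comp[calls$alt])
  spec_rc <- classify_spectrum(rc_calls, list(sequences = rc_sequences))
  expect_equal(spec_fwd$class6$count, spec_rc$class6$count)
})

test_that("Ti/Tv follows its definition and rejects zero transversions", {
  mk_spec <- function(counts) {
    list(class6 = tibble::tibble(class = c("C>A", "C>G", "C>T",
                                           "T>A", "T>C", "T>G"),
                                 count = counts))
  }
  expect_equal(titv(mk_spec(c(1, 0, 1, 1, 1, 0))), 1.0)
  expect_equal(titv(mk_spec(c(25, 25, 82, 25, 82, 25))), 1.64)
  expect_error(titv(mk_spec(c(0, 0, 5, 0, 3, 0))), "transversions")
})

test_that("AT bias corrects for genomic base content", {
  # 10-base genome at GC fraction 0.4
  ref <- toy_ref("CCGGAATTAT")
  calls <- dplyr::bind_rows(
    tibble::tibble(chrom = "chr1", pos = 1L, ref = "C",
                   alt = rep("T", 20)),                  # 20 GC -> AT
    tibble::tibble(chrom = "chr1", pos = 7L, ref = "T",
                   alt = rep("C", 5))                    # 5 AT -> GC
  )
  spec <- classify_spectrum(calls, ref)
  expect_equal(at_bias(spec), (20 / 4) / (5 / 6))  # 6.0
  # equal per-base rates give 1
  bal <- dplyr::bind_rows(
    tibble::tibble(chrom = "chr1", pos = 1L, ref = "C", alt = rep("T", 4)),
    tibble::tibble(chrom = "chr1", pos = 7L, ref = "T", alt = rep("C", 6))
  )
  expect_equal(at_bias(classify_spectrum(bal, ref)), 1.0)
  only_gc <- tibble::tibble(chrom = "chr1", pos = 1L, ref = "C", alt = "T")
  expect_error(at_bias(classify_spectrum(only_gc, ref)), "undefined")
})

test_that("cytosine contexts follow their definitions", {
  ref <- toy_ref("ACGACTA")
  expect_equal(site_context(ref, "chr1", 2L), "CpG")  # A[C]G
  expect_equal(site_context(ref, "chr1", 5L), "CHH")  # A[C]TA
  expect_equal(site_context(ref, "chr1", 3L), "CpG")  # G after C, minus strand
  expect_equal(site_context(ref, "chr1", 1L), "nonC")
  # C-H-G triplet
  expect_equal(site_context(toy_ref("ACAGA"), "chr1", 2L), "CHG")
})

test_that("dinucleotide context counts conserve two flanks per mutation", {
  cfg <- small_config(seed = 37, genome_length = 5e4, snv_rate = 4e-6,
                      indel_rate = 0)
  ref <- simulate_genome(cfg)
  truth <- simulate_mutations(ref, cfg)
  calls <- truth$branch_mutations[truth$branch_mutations$type == "snv", ]
  spec <- classify_spectrum(calls, ref)
  total_dinuc <- sum(spec$dinucleotide$count)
  expect_lte(total_dinuc, 2 * spec$n)
  interior <- calls[calls$pos > 1 &
                      calls$pos < nchar(ref$sequences)[calls$chrom], ]
  expect_equal(total_dinuc,
               2 * nrow(interior) + (nrow(calls) - nrow(interior)))
})

test_that("context enrichment recovers a CpG rate multiplier", {
  cfg <- small_config(seed = 41, genome_length = 5e5, gc_content = 0.4,
                      snv_rate = 5e-7, indel_rate = 0,
                      context_multipliers = c(CpG = 5, CHG = 1, CHH = 1,
                                              nonC = 1),
                      n_replicate_samples = 0)
  ref <- simulate_genome(cfg)
  truth <- simulate_mutations(ref, cfg)
  calls <- truth$branch_mutations[truth$branch_mutations$type == "snv", ]
  enr <- context_enrichment(calls, ref)
  cpg <- enr[enr$context == "CpG", ]
  expect_lt(abs(cpg$enrichment - 5), 1)
  expect_true(cpg$significant)
  expect_false(enr$significant[enr$context == "CHH"])
})

test_that("uniform mutations show no significant context enrichment", {
  cfg <- small_config(seed = 43, genome_length = 5e5, snv_rate = 4e-7,
                      indel_rate = 0, n_replicate_samples = 0)
  ref <- simulate_genome(cfg)
  truth <- simulate_mutations(ref, cfg)
  calls <- truth$branch_mutations[truth$branch_mutations$type == "snv", ]
  enr <- context_enrichment(calls, ref)
  expect_true(all(abs(enr$enrichment - 1) < 0.75))
  expect_false(any(enr$significant))
  # per-triplet mode: uniform placement stays non-significant after BH
  tri <- context_enrichment(calls, ref, by = "trinucleotide")
  expect_false(any(tri$significant))
  # each mutation contributes one triplet per position, minus edge cases
  expect_lte(sum(tri$n_mutations), 3 * nrow(calls))
  expect_gte(sum(tri$n_mutations), 3 * nrow(calls) - 12)
})

test_that("flanking composition is flat on a uniform genome", {
  cfg <- small_config(seed = 47, genome_length = 2e5, gc_content = 0.5,
                      snv_rate = 2e-6, indel_rate = 0)
  ref <- simulate_genome(cfg)
  truth <- simulate_mutations(ref, cfg)
  calls <- truth$branch_mutations[truth$branch_mutations$type == "snv", ]
  prof <- flanking_composition(calls, ref, max_dist = 20)
  expect_equal(nrow(prof), 20)
  expect_true(all(abs(prof$prop_gc - 0.5) < 0.1))
  expect_equal(attr(prof, "baseline_gc"), ref$gc_observed, tolerance = 1e-6)
  expect_error(flanking_composition(calls, ref, max_dist = 0), "max_dist")
})
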