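one_site <- function(var_type = "snv", ...) {
  info <- passing_info(1)
  dots <- list(...)
  info[names(dots)] <- dots
  dplyr::bind_cols(
    tibble::tibble(chrom = "chr1", pos = 100L, ref = "A", alt = "T",
                   var_type = var_type),
    info
  )
}

test_that("hard filters use strict printed comparisons", {
  samples <- c("s1", "s2")
  # FS = 61 removed, FS = 60 exactly retained
  s_remove <- manual_sites(one_site(FS = 61), samples)
  s_keep <- manual_sites(one_site(FS = 60), samples)
  expect_equal(nrow(apply_hard_filters(s_remove)), 0)
  expect_equal(nrow(apply_hard_filters(s_keep)), 2)
  # indel ReadPosRankSum = -20 exactly retained, below removed
  i_keep <- manual_sites(one_site("indel", ReadPosRankSum = -20.0), samples)
  i_rm <- manual_sites(one_site("indel", ReadPosRankSum = -20.0001), samples)
  expect_equal(nrow(apply_hard_filters(i_keep)), 2)
  expect_equal(nrow(apply_hard_filters(i_rm)), 0)
  # OR semantics: any failing predicate removes
  s2 <- manual_sites(one_site(MQ = 39.9), samples)
  expect_equal(nrow(apply_hard_filters(s2)), 0)
  # missing annotation cannot trigger a rule
  s3 <- manual_sites(one_site(SOR = NA_real_), samples)
  expect_equal(nrow(apply_hard_filters(s3)), 2)
})

test_that("removal ledger accounts for every removed site", {
  set.seed(1)
  n <- 200
  sites <- dplyr::bind_cols(
    tibble::tibble(chrom = "chr1", pos = seq_len(n) * 10L, ref = "A",
                   alt = "T",
                   var_type = sample(c("snv", "indel"), n, TRUE)),
    tibble::tibble(FS = rexp(n, 1 / 40), MQ = rnorm(n, 45, 10),
                   MQRankSum = rnorm(n, 0, 8), QD = rnorm(n, 10, 6),
                   ReadPosRankSum = rnorm(n, 0, 8),
                   SOR = rexp(n, 1 / 2))
  )
  long <- manual_sites(sites, c("s1", "s2"))
  kept <- apply_hard_filters(long)
  ledger <- removal_ledger(kept)
  n_removed <- length(unique(site_key(ledger$chrom, ledger$pos)))
  n_kept <- length(unique(site_key(kept$chrom, kept$pos)))
  expect_equal(n_removed + n_kept, n)
})

test_that("brute-force predicate oracle reproduces keep/drop decisions", {
  set.seed(99)
  n <- 1000
  sites <- dplyr::bind_cols(
    tibble::tibble(chrom = "chr1", pos = seq_len(n) * 7L, ref = "G",
                   alt = "C", var_type = sample(c("snv", "indel"), n, TRUE)),
    tibble::tibble(
      FS = c(rexp(n - 4, 1 / 45), 60, 60.0001, 200, 200.0001),
      MQ = rnorm(n, 45, 8), MQRankSum = rnorm(n, -5, 6),
      QD = rnorm(n, 8, 5), ReadPosRankSum = rnorm(n, -6, 8),
      SOR = rexp(n, 1 / 2)
    )
  )
  # sprinkle missing annotations
  for (cn in c("MQ", "QD", "SOR")) {
    sites[[cn]][sample.int(n, 30)] <- NA_real_
  }
  long <- manual_sites(sites, "s1")
  kept_keys <- unique(site_key(apply_hard_filters(long)$chrom,
                               apply_hard_filters(long)$pos))
  oracle_keep <- vapply(seq_len(n), function(i) {
    brute_force_hard_keep(as.list(sites[i, ]))
  }, logical(1))
  expect_identical(sort(kept_keys),
                   sort(site_key(sites$chrom[oracle_keep],
                                 sites$pos[oracle_keep])))
})

test_that("post-filters mask and remove per the stated rules", {
  samples <- sprintf("s%02d", 1:12)
  base <- manual_sites(
    dplyr::bind_cols(
      tibble::tibble(chrom = "chr1", pos = 100L * (1:100), ref = "A",
                     alt = "T", var_type = "snv"),
      passing_info(100)),
    samples)

  # depth 3.1x the sample mean -> genotype masked, site kept (others intact);
  # 100 sites at dp 30 keep the per-sample mean essentially at 30
  sites <- base
  sites$dp[sites$pos == 100 & sites$sample == "s01"] <- as.integer(3.1 * 30)
  out <- apply_site_postfilters(sites)
  expect_true(is.na(out$gt[out$pos == 100 & out$sample == "s01"]))
  expect_false(anyNA(out$gt[out$pos == 5000]))
  # extremely low coverage (below one third of the mean) is masked too
  sites$dp[sites$pos == 200 & sites$sample == "s02"] <- 9L
  out2 <- apply_site_postfilters(sites)
  expect_true(is.na(out2$gt[out2$pos == 200 & out2$sample == "s02"]))

  # GQ below 10 masks the genotype; missingness uses the masked table:
  # 3 of 12 masked (25%) retained, 4 of 12 (33%) removed
  sites <- base
  sites$gq[sites$pos == 100][1:3] <- 9L
  out <- apply_site_postfilters(sites)
  expect_true(100 %in% out$pos)
  sites$gq[sites$pos == 100][1:4] <- 9L
  out <- apply_site_postfilters(sites)
  expect_false(100 %in% out$pos)
  expect_true("missing" %in% removal_ledger(out)$rule)

  # SNP 5 bp from an indel removed, 6 bp retained
  mk <- function(offset) {
    df <- dplyr::bind_cols(
      tibble::tibble(chrom = "chr1", pos = c(1000L, 1000L + offset),
                     ref = c("ATT", "A"), alt = c("A", "G"),
                     var_type = c("indel", "snv")),
      passing_info(2))
    manual_sites(df, samples)
  }
  # indel span 1000..1002, closed +-5 window is 995..1007
  out5 <- apply_site_postfilters(mk(7L))   # snv at 1007: within
  expect_false(1007 %in% out5$pos[out5$var_type == "snv"])
  out6 <- apply_site_postfilters(mk(8L))   # snv at 1008: outside
  expect_true(1008 %in% out6$pos[out6$var_type == "snv"])
})

test_that("tightening post-filter thresholds never increases retained sites", {
  cfg <- small_config(seed = 11)
  ref <- simulate_genome(cfg)
  truth <- simulate_mutations(ref, cfg)
  sim <- simulate_site_table(truth, ref, cfg)
  n_sites <- function(x) length(unique(site_key(x$chrom, x$pos)))
  base <- apply_site_postfilters(sim$sites, filter_config())
  stricter_gq <- apply_site_postfilters(sim$sites, filter_config(gq_min = 30))
  stricter_miss <- apply_site_postfilters(sim$sites,
                                          filter_config(site_missing_max = 0.05))
  expect_lte(n_sites(stricter_gq), n_sites(base))
  expect_lte(n_sites(stricter_miss), n_sites(base))
})
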