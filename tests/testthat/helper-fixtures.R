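# shared fixtures built in code

# a small fast simulation config; mutation rate inflated so a 100 kb genome
# carries a workable number of events
small_config <- function(seed = 1, ...) {
  args <- list(
    genome_length = 1e5, n_chromosomes = 2, gc_content = 0.5,
    het_density = 1, snv_rate = 5e-7, indel_rate = 5e-8,
    context_multipliers = c(CpG = 1, CHG = 1, CHH = 1, nonC = 1),
    mean_depth = 30, seq_error = 0.001, n_replicate_samples = 2,
    seed = seed
  )
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(sim_config, args)
}

star_newick <- function(n = 4, years = 67) {
  paste0("(", paste(sprintf("L%02d:%d", seq_len(n), years), collapse = ","),
         ");")
}

# a hand-built long site table: one row per site x sample
manual_sites <- function(df_sites, samples, gt = "0/1", dp = 30L, gq = 99L,
                         fwd_alt = 8L, rev_alt = 7L) {
  grid <- tidyr::expand_grid(idx = seq_len(nrow(df_sites)), sample = samples)
  out <- dplyr::bind_cols(df_sites[grid$idx, ], tibble::tibble(
    sample = grid$sample, gt = gt, gq = gq, dp = dp,
    ad_ref = dp - fwd_alt - rev_alt, ad_alt = fwd_alt + rev_alt,
    fwd_ref = 8L, rev_ref = 7L, fwd_alt = fwd_alt, rev_alt = rev_alt,
    pgt = NA_character_, ps = NA_integer_
  ))
  out
}

# site-level tibble with passing INFO values
passing_info <- function(n) {
  tibble::tibble(FS = rep(10, n), MQ = 55, MQRankSum = 0, QD = 20,
                 ReadPosRankSum = 0, SOR = 1)
}

# variant key for set comparisons (mirrors the package-internal convention)
site_key <- function(chrom, pos, ref = NULL, alt = NULL) {
  if (is.null(ref)) paste(chrom, pos, sep = ":")
  else paste(chrom, pos, ref, alt, sep = ":")
}

# round half away from zero at d decimals (mirrors the package convention)
round_to <- function(x, d) sign(x) * floor(abs(x) * 10^d + 0.5) / 10^d

normalize_gt_for_test <- function(gt) {
  out <- chartr("|", "/", gt)
  ifelse(out == "1/0", "0/1", out)
}

site_in <- function(sub, full) {
  site_key(sub$chrom, sub$pos) %in% site_key(full$chrom, full$pos)
}

# independent brute-force re-evaluation of the hard-filter predicates,
# one site at a time (the oracle for the cascade)
brute_force_hard_keep <- function(site_row) {
  v <- function(x) if (is.null(site_row[[x]]) || is.na(site_row[[x]])) NULL
                   else site_row[[x]]
  fails <- c()
  if (site_row$var_type == "indel") {
    if (!is.null(v("QD"))) fails <- c(fails, v("QD") < 2.0)
    if (!is.null(v("FS"))) fails <- c(fails, v("FS") > 200.0)
    if (!is.null(v("ReadPosRankSum")))
      fails <- c(fails, v("ReadPosRankSum") < -20.0)
  } else {
    if (!is.null(v("FS"))) fails <- c(fails, v("FS") > 60)
    if (!is.null(v("MQ"))) fails <- c(fails, v("MQ") < 40)
    if (!is.null(v("MQRankSum"))) fails <- c(fails, v("MQRankSum") < -12.5)
    if (!is.null(v("QD"))) fails <- c(fails, v("QD") < 2)
    if (!is.null(v("ReadPosRankSum")))
      fails <- c(fails, v("ReadPosRankSum") < -8)
    if (!is.null(v("SOR"))) fails <- c(fails, v("SOR") > 3)
  }
  !any(fails)
}
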