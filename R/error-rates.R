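#' False-positive rate from triplicate re-sequencing
#'
#' For each triplicated sample, candidate mutations are the union of the
#' call sets across its replicates; calls present in every replicate are
#' treated as true, and all others as erroneous. The pooled false-positive
#' rate is the total erroneous count over the total candidate count.
#' Invariant to replicate ordering.
#'
#' @param replicate_calls Tibble with columns `sample`, `replicate`,
#'   `chrom`, `pos` (and optionally `ref`, `alt`), one row per call per
#'   replicate; every sample must have at least 3 replicates.
#' @param n_replicates Optional replicate count; when given, replicates
#'   `1..n_replicates` with no rows for a sample count as empty call sets
#'   (a replicate with zero calls is data, not absence of a replicate).
#' @return An `error_rates` list with `per_sample` (tibble
#'   `sample,n_candidates,n_true,n_erroneous,fp_rate`), pooled
#'   `n_candidates`, `n_erroneous` and `fp_rate`.
#' @export
#' @examples
#' fp_from_counts(1898, 44) # 0.0232: the ratio of the printed counts
estimate_fp <- function(replicate_calls, n_replicates = NULL) {
  stop_if_not(all(c("sample", "replicate", "chrom", "pos") %in%
                    names(replicate_calls)),
              "replicate_calls needs columns sample, replicate, chrom, pos")
  has_allele <- all(c("ref", "alt") %in% names(replicate_calls))
  keyify <- function(df) {
    if (has_allele) site_key(df$chrom, df$pos, df$ref, df$alt)
    else site_key(df$chrom, df$pos)
  }
  rep_levels <- if (is.null(n_replicates)) NULL else seq_len(n_replicates)
  per_sample <- lapply(split(replicate_calls, replicate_calls$sample),
                       function(df) {
    reps <- factor(df$replicate,
                   levels = rep_levels %||% sort(unique(df$replicate)))
    sets <- lapply(split(df, reps), keyify)
    if (length(sets) < 3) {
      abort(sprintf("sample %s has %d replicate call set(s); >= 3 required",
                    df$sample[1], length(sets)))
    }
    u <- unique(unlist(sets))
    i <- Reduce(intersect, sets)
    tibble::tibble(sample = df$sample[1],
                   n_candidates = length(u),
                   n_true = length(i),
                   n_erroneous = length(u) - length(i),
                   fp_rate = if (length(u) == 0) NA_real_
                             else (length(u) - length(i)) / length(u))
  })
  per_sample <- dplyr::bind_rows(per_sample)
  n_cand <- sum(per_sample$n_candidates)
  n_err <- sum(per_sample$n_erroneous)
  structure(
    list(per_sample = per_sample,
         n_candidates = n_cand,
         n_erroneous = n_err,
         fp_rate = fp_from_counts(n_cand, n_err)),
    class = "error_rates"
  )
}

#' @describeIn estimate_fp False-positive rate from pre-tallied counts.
#' @param n_candidates,n_erroneous Candidate and erroneous call counts.
#' @export
fp_from_counts <- function(n_candidates, n_erroneous) {
  stop_if_not(all(n_erroneous <= n_candidates),
              "n_erroneous cannot exceed n_candidates")
  ifelse(n_candidates == 0, NA_real_, n_erroneous / n_candidates)
}

#' Detection sensitivity from spike-in mutations
#'
#' Inserts `n` synthetic single-point substitutions at uniformly random
#' unoccupied genome positions into one sample of a simulated cohort, runs
#' the full filtering and somatic-calling pipeline over them, and reports
#' the spike-in statistic
#' `(n_callable - n_filtered_callable) / n` — the fraction of all spiked
#' mutations that are callable (mutant-allele covered reads strictly greater
#' than `min_covered_reads`) and survive the pipeline. Under the original
#' published design this figure was reported as the "false-negative rate";
#' it is exposed under both names.
#'
#' The spiked variant-allele fraction defaults to 1 (homozygous derived
#' sites, the published design). Because the strand-count filter passes
#' homozygous sites substantially more often than heterozygous ones at
#' moderate depth, a `vaf` of 0.5 should be used when the estimate corrects
#' counts of heterozygous (hom-to-het) somatic mutations; see the methods
#' vignette.
#'
#' @param ref A `ref_model`.
#' @param config The matching [sim_config()].
#' @param n Number of spike-ins (default 1000; below 100 the estimate is
#'   unstable and a warning is raised).
#' @param vaf Variant-allele fraction of the spiked truth (1 = homozygous,
#'   0.5 = heterozygous).
#' @param min_covered_reads Callability threshold: a spiked site is callable
#'   iff its mutant-allele covered reads exceed this (default 3, i.e. >= 4).
#' @param pipeline Function mapping a long site table to a `somatic_calls`
#'   tibble; defaults to hard filters + post-filters + [call_somatic()].
#' @param seed Optional seed (defaults to a sub-stream of `config$seed`).
#' @return An `error_rates` list with `sensitivity`, `false_negative_rate`
#'   (the same figure, under the published name), `n_spikein`, `n_callable`,
#'   `n_filtered_callable`, and `recall_callable`.
#' @export
#' @examples
#' sensitivity_from_counts(1000, 604, 8) # 0.596
spike_in_sensitivity <- function(ref, config, n = 1000, vaf = 1,
                                 min_covered_reads = 3,
                                 pipeline = NULL, seed = NULL) {
  if (n < 100) warn("fewer than 100 spike-ins: unstable estimate")
  set.seed(seed %||% derive_seed(config$seed, 4L))
  tree <- ape::read.tree(text = config$pedigree_newick)
  samples <- tree$tip.label
  target <- samples[1]

  # uniform accessible positions, avoiding background heterozygous sites
  L_total <- sum(ref$chrom_lengths)
  offsets <- cumsum(c(0, ref$chrom_lengths))
  occupied <- site_key(ref$het_sites$chrom, ref$het_sites$pos)
  picked <- NULL
  while (is.null(picked) || nrow(picked) < n) {
    gpos <- sample.int(L_total, n * 2L, replace = TRUE)
    idx <- findInterval(gpos - 1, offsets)
    cand <- tibble::tibble(chrom = names(ref$chrom_lengths)[idx],
                           pos = as.integer(gpos - offsets[idx]))
    cand <- cand[!duplicated(site_key(cand$chrom, cand$pos)) &
                   !site_key(cand$chrom, cand$pos) %in% occupied, ]
    picked <- dplyr::bind_rows(picked, cand)
    picked <- picked[!duplicated(site_key(picked$chrom, picked$pos)), ]
  }
  picked <- picked[seq_len(n), ]
  picked$ref <- mapply(function(ch, p) substring(ref$sequences[[ch]], p, p),
                       picked$chrom, picked$pos, USE.NAMES = FALSE)
  picked$alt <- random_other_base(picked$ref)

  # observation model: spiked truth in the target sample, hom-ref elsewhere
  e <- config$seq_error
  grid <- tidyr::expand_grid(sample = samples,
                             idx = seq_len(n))
  grid <- dplyr::bind_cols(grid, picked[grid$idx, ])
  is_target <- grid$sample == target
  p_alt <- ifelse(is_target,
                  vaf * (1 - e) + (1 - vaf) * e / 3,
                  e / 3)
  m <- nrow(grid)
  dp <- rpois(m, config$mean_depth)
  ad_alt <- rbinom(m, dp, p_alt)
  p_fwd <- pmin(pmax(rnorm(m, 0.5, config$strand_imbalance_sd), 0.02), 0.98)
  fwd_alt <- rbinom(m, ad_alt, p_fwd)
  fwd_ref <- rbinom(m, dp - ad_alt, p_fwd)
  gcall <- call_genotypes_from_reads(dp, ad_alt, e)

  tbl <- tibble::tibble(
    chrom = grid$chrom, pos = grid$pos, ref = grid$ref, alt = grid$alt,
    var_type = "snv", origin = "spikein", sample = grid$sample,
    truth_gt = ifelse(is_target, if (vaf >= 1) "1/1" else "0/1", "0/0"),
    gt = gcall$gt, gq = gcall$gq, dp = dp,
    ad_ref = dp - ad_alt, ad_alt = ad_alt,
    fwd_ref = fwd_ref, rev_ref = dp - ad_alt - fwd_ref,
    fwd_alt = fwd_alt, rev_alt = ad_alt - fwd_alt,
    pgt = NA_character_, ps = NA_integer_
  )
  info <- sim_info_annotations(picked)
  tbl <- dplyr::bind_cols(tbl, info[rep(seq_len(n), times = length(samples)), ])

  callable <- tbl$sample == target & tbl$ad_alt > min_covered_reads
  n_callable <- sum(callable)
  callable_keys <- site_key(tbl$chrom[callable], tbl$pos[callable])

  pipeline <- pipeline %||% function(x) {
    call_somatic(apply_site_postfilters(apply_hard_filters(x)))
  }
  calls <- pipeline(tbl)
  detected <- calls[vapply(calls$carriers, function(cs) target %in% cs,
                           logical(1)), , drop = FALSE]
  detected_keys <- site_key(detected$chrom, detected$pos)
  n_filtered_callable <- sum(!callable_keys %in% detected_keys)

  out <- sensitivity_from_counts(n, n_callable, n_filtered_callable)
  structure(
    list(sensitivity = out, false_negative_rate = out,
         n_spikein = n, n_callable = n_callable,
         n_filtered_callable = n_filtered_callable,
         recall_callable = if (n_callable == 0) NA_real_
                           else (n_callable - n_filtered_callable) / n_callable,
         vaf = vaf),
    class = "error_rates"
  )
}

#' @describeIn spike_in_sensitivity The spike-in statistic from pre-tallied
#'   counts: `(n_callable - n_filtered_callable) / n_spikein`.
#' @param n_spikein,n_callable,n_filtered_callable Spike-in tallies.
#' @export
sensitivity_from_counts <- function(n_spikein, n_callable,
                                    n_filtered_callable) {
  stop_if_not(all(n_filtered_callable <= n_callable),
              "n_filtered_callable cannot exceed n_callable")
  stop_if_not(all(n_callable <= n_spikein),
              "n_callable cannot exceed n_spikein")
  (n_callable - n_filtered_callable) / n_spikein
}

#' @export
print.error_rates <- function(x, ...) {
  cat("<error_rates>\n")
  if (!is.null(x$fp_rate)) {
    cat(sprintf("  false-positive rate: %d / %d = %.4f\n",
                x$n_erroneous, x$n_candidates, x$fp_rate))
  }
  if (!is.null(x$sensitivity)) {
    cat(sprintf("  spike-in sensitivity: (%d - %d) / %d = %.4f (vaf %.2f)\n",
                x$n_callable, x$n_filtered_callable, x$n_spikein,
                x$sensitivity, x$vaf))
  }
  invisible(x)
}

#' @importFrom generics tidy
#' @export
tidy.error_rates <- function(x, ...) {
  rows <- list()
  if (!is.null(x$fp_rate)) {
    rows$fp <- tibble::tibble(term = "fp_rate", estimate = x$fp_rate,
                              numerator = x$n_erroneous,
                              denominator = x$n_candidates)
  }
  if (!is.null(x$sensitivity)) {
    rows$fn <- tibble::tibble(term = "sensitivity", estimate = x$sensitivity,
                              numerator = x$n_callable - x$n_filtered_callable,
                              denominator = x$n_spikein)
  }
  dplyr::bind_rows(rows)
}
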