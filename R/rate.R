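#' Corrected somatic mutation rate per base per year
#'
#' The point estimate is
#' `mean_count * (1 - fp_rate) / (years * ploidy_factor * genome_size * sensitivity)`:
#' the mean per-sample mutation count, purged of the false-positive fraction,
#' divided by the elapsed years, the diploid base count and the detection
#' sensitivity estimated from spike-ins.
#'
#' @param mean_count Mean somatic mutation count per sample.
#' @param years Elapsed years between planting and collection.
#' @param genome_size Haploid genome size in bp.
#' @param fp_rate False-positive fraction in `[0, 1)`.
#' @param sensitivity Detection sensitivity in `(0, 1]`; the spike-in
#'   statistic of [spike_in_sensitivity()].
#' @param ploidy_factor Copies of the genome per cell (default 2, diploid).
#' @return Mutation rate per base per year.
#' @export
#' @examples
#' point_rate(312.5, 67, 4.08e8, fp_rate = 0.032, sensitivity = 0.596)
#' # 9.28e-9
point_rate <- function(mean_count, years, genome_size, fp_rate = 0,
                       sensitivity = 1, ploidy_factor = 2) {
  stop_if_not(all(years > 0), "years must be > 0")
  stop_if_not(all(genome_size > 0), "genome_size must be > 0")
  stop_if_not(all(fp_rate >= 0 & fp_rate < 1), "fp_rate must be in [0, 1)")
  stop_if_not(all(sensitivity > 0 & sensitivity <= 1),
              "sensitivity must be in (0, 1]; a zero sensitivity is not invertible")
  stop_if_not(all(mean_count >= 0), "mean_count must be >= 0")
  mean_count * (1 - fp_rate) /
    (years * ploidy_factor * genome_size * sensitivity)
}

#' Bootstrap confidence interval for the mutation rate
#'
#' Nonparametric percentile bootstrap over samples: per-sample mutation
#' counts are resampled with replacement, the mean recomputed, and the
#' corrected rate re-evaluated per replicate; the CI is the 2.5/97.5
#' percentile of the bootstrap rates.
#'
#' @param per_sample_counts Numeric vector of somatic mutation counts, one
#'   per sample (at least 2).
#' @inheritParams point_rate
#' @param reps Bootstrap replicates (default 1000; below 100 warns).
#' @param seed Optional integer seed.
#' @return A `rate_estimate` list: `rate`, `ci_low`, `ci_high`, `method`,
#'   and the inputs. Methods: [tidy()], [glance()], `print`.
#' @export
bootstrap_ci <- function(per_sample_counts, years, genome_size, fp_rate = 0,
                         sensitivity = 1, ploidy_factor = 2, reps = 1000,
                         seed = NULL) {
  stop_if_not(length(per_sample_counts) >= 2,
              "need counts for at least 2 samples to bootstrap")
  if (reps < 100) warn("fewer than 100 bootstrap replicates: unstable CI")
  if (!is.null(seed)) set.seed(seed)
  n <- length(per_sample_counts)
  boot_means <- vapply(seq_len(reps), function(i) {
    mean(sample(per_sample_counts, n, replace = TRUE))
  }, numeric(1))
  boot_rates <- point_rate(boot_means, years, genome_size, fp_rate,
                           sensitivity, ploidy_factor)
  rate <- point_rate(mean(per_sample_counts), years, genome_size, fp_rate,
                     sensitivity, ploidy_factor)
  ci <- unname(quantile(boot_rates, c(0.025, 0.975)))
  structure(
    list(rate = rate, ci_low = ci[1], ci_high = ci[2],
         method = "percentile bootstrap over samples",
         reps = reps,
         inputs = list(per_sample_counts = per_sample_counts, years = years,
                       genome_size = genome_size, fp_rate = fp_rate,
                       sensitivity = sensitivity,
                       ploidy_factor = ploidy_factor)),
    class = "rate_estimate"
  )
}

#' Fold difference between two mutation rates
#'
#' @param rate_a,rate_b Rates on the same scale; `rate_b` must be positive.
#' @return `rate_a / rate_b`.
#' @export
#' @examples
#' rate_ratio(9.24e-9, 1.99e-9) # 4.64
rate_ratio <- function(rate_a, rate_b) {
  stop_if_not(all(rate_b > 0), "rate_b must be > 0")
  rate_a / rate_b
}

#' @export
print.rate_estimate <- function(x, ...) {
  cat("<rate_estimate>\n")
  cat(sprintf("  rate: %.3g per bp per year (95%% CI %.3g to %.3g, %s)\n",
              x$rate, x$ci_low, x$ci_high, x$method))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
tidy.rate_estimate <- function(x, ...) {
  tibble::tibble(term = "mutation_rate", estimate = x$rate,
                 conf.low = x$ci_low, conf.high = x$ci_high)
}

#' @importFrom generics glance
#' @export
glance.rate_estimate <- function(x, ...) {
  tibble::tibble(
    n_samples = length(x$inputs$per_sample_counts),
    mean_count = mean(x$inputs$per_sample_counts),
    years = x$inputs$years,
    genome_size = x$inputs$genome_size,
    fp_rate = x$inputs$fp_rate,
    sensitivity = x$inputs$sensitivity,
    ploidy_factor = x$inputs$ploidy_factor,
    reps = x$reps,
    method = x$method
  )
}
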