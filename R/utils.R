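#' @importFrom rlang %||% abort warn .data
#' @importFrom stats rbinom rpois rnorm rexp rgeom dbinom quantile setNames
#'   lm coef pchisq p.adjust binom.test complete.cases
#' @importFrom utils head tail
NULL

# round half away from zero (base round() is banker's rounding)
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Percentage of a count, rounded half away from zero
#'
#' All printed-percentage outputs in this package share one rounding
#' convention: round half away from zero at a fixed number of decimals, so
#' worked examples are deterministic.
#'
#' @param n Numerator count.
#' @param total Denominator count.
#' @param digits Decimal places to keep (default 1).
#' @return Numeric percentage (e.g. `76.7`), `NA` when `total` is zero.
#' @export
#' @examples
#' percent_of(2328, 3037) # 76.7
percent_of <- function(n, total, digits = 1) {
  ifelse(total == 0, NA_real_, round_half_up(100 * n / total, digits))
}

# complement of DNA bases, vectorized over single characters
dna_complement <- function(base) {
  unname(c(A = "T", C = "G", G = "C", T = "A", N = "N")[base])
}

# reverse complement of character strings
dna_revcomp <- function(x) {
  chartr("ACGT", "TGCA", vapply(x, function(s) {
    paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE))
}

# site key used throughout for set operations on variants
site_key <- function(chrom, pos, ref = NULL, alt = NULL) {
  if (is.null(ref)) paste(chrom, pos, sep = ":")
  else paste(chrom, pos, ref, alt, sep = ":")
}

is_het <- function(gt) !is.na(gt) & gt %in% c("0/1", "0|1", "1|0")
is_hom <- function(gt) !is.na(gt) & gt %in% c("0/0", "1/1", "0|0", "1|1")

gt_zygosity <- function(gt) {
  out <- rep(NA_character_, length(gt))
  out[is_het(gt)] <- "het"
  out[!is.na(gt) & gt %in% c("0/0", "0|0")] <- "hom_ref"
  out[!is.na(gt) & gt %in% c("1/1", "1|1")] <- "hom_alt"
  out
}

# derive a module-local RNG seed from the run seed, staying inside 32-bit range
derive_seed <- function(seed, offset) {
  (as.integer(seed) + as.integer(offset) * 1009L) %% 2147483629L
}

stop_if_not <- function(cond, msg) if (!isTRUE(cond)) abort(msg)
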