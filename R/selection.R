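#' Consensus deleteriousness call from three effect predictors
#'
#' A nonsynonymous mutation is deleterious iff all three predictors agree:
#' SIFT score <= 0.05, PROVEAN score < -2.5 (strict) and PolyPhen
#' probability > 0.5. Any missing score makes the call unscorable.
#'
#' @param scores Tibble with numeric columns `sift` (in `[0,1]`), `provean`
#'   (unbounded, negative = damaging) and `polyphen` (in `[0,1]`).
#' @param sift_max,provean_lt,polyphen_gt Thresholds (defaults as above).
#' @return `scores` with an added `consensus` column in
#'   `{deleterious, tolerated, unscorable}`.
#' @export
#' @examples
#' deleterious_consensus(tibble::tibble(sift = 0.05, provean = -2.6,
#'                                      polyphen = 0.6))
deleterious_consensus <- function(scores, sift_max = 0.05, provean_lt = -2.5,
                                  polyphen_gt = 0.5) {
  stop_if_not(all(c("sift", "provean", "polyphen") %in% names(scores)),
              "scores needs columns sift, provean, polyphen")
  ok_sift <- scores$sift[!is.na(scores$sift)]
  ok_poly <- scores$polyphen[!is.na(scores$polyphen)]
  stop_if_not(all(ok_sift >= 0 & ok_sift <= 1), "sift scores must be in [0, 1]")
  stop_if_not(all(ok_poly >= 0 & ok_poly <= 1),
              "polyphen scores must be in [0, 1]")
  missing_any <- is.na(scores$sift) | is.na(scores$provean) |
    is.na(scores$polyphen)
  hit <- scores$sift <= sift_max & scores$provean < provean_lt &
    scores$polyphen > polyphen_gt
  scores$consensus <- dplyr::case_when(
    missing_any ~ "unscorable",
    hit ~ "deleterious",
    TRUE ~ "tolerated"
  )
  scores
}

#' Summary of deleterious-mutation patterns
#'
#' @param calls A `somatic_calls` tibble restricted to (or flagged with)
#'   consensus-deleterious mutations; if a `consensus` column is present,
#'   only `"deleterious"` rows are summarised.
#' @param total_somatic Total somatic SNV count used for the consensus
#'   fraction (e.g. 3037); `NA` skips the fraction.
#' @return A list: `per_sample` (tibble `sample, n`), `n_deleterious`,
#'   `n_shared`, `n_homozygous_state` (calls whose carrier genotype is
#'   homozygous), `consensus_percent` (2-decimal percentage of
#'   `total_somatic`).
#' @export
deleterious_pattern_report <- function(calls, total_somatic = NA) {
  if ("consensus" %in% names(calls)) {
    calls <- calls[calls$consensus == "deleterious", , drop = FALSE]
  }
  per_sample <- if (nrow(calls) > 0) {
    dplyr::count(tibble::tibble(sample = unlist(calls$carriers)),
                 .data$sample, name = "n")
  } else tibble::tibble(sample = character(), n = integer())
  list(
    per_sample = per_sample,
    n_deleterious = nrow(calls),
    n_shared = if (nrow(calls) > 0) sum(calls$n_carriers >= 2) else 0L,
    n_homozygous_state = if (nrow(calls) > 0) {
      sum(gt_zygosity(calls$carrier_gt) %in% c("hom_ref", "hom_alt"))
    } else 0L,
    consensus_percent = if (is.na(total_somatic)) NA_real_
                        else percent_of(nrow(calls), total_somatic, 2)
  )
}

#' Classify selection on somatic alleles from outgroup frequencies
#'
#' For each polarized somatic call, computes the ancestral (pre-mutation)
#' and derived (post-mutation) allele frequencies in an outgroup population
#' from called genotypes (missing genotypes leave the denominator), and
#' classifies: `positive` iff the post-mutation allele frequency strictly
#' exceeds `af_threshold`, `purifying` iff the pre-mutation allele frequency
#' does, otherwise `unclassified`. Sites absent from the outgroup are
#' unclassified with reason.
#'
#' @param calls Polarized calls (needs `chrom,pos,ref,alt,ancestral,derived`
#'   from [polarize_derived()]).
#' @param outgroup Long outgroup genotype tibble `chrom,pos,sample,gt`.
#' @param af_threshold Classification threshold (default 0.95, strict).
#' @return `calls` plus `pre_af`, `post_af`, `selection_class`,
#'   `selection_reason`.
#' @export
classify_selection <- function(calls, outgroup, af_threshold = 0.95) {
  af <- dplyr::summarise(
    dplyr::group_by(outgroup, .data$chrom, .data$pos),
    alt_af = {
      g <- .data$gt[!is.na(.data$gt)]
      n2 <- 2 * length(g)
      if (n2 == 0) NA_real_
      else (2 * sum(g %in% c("1/1", "1|1")) + sum(is_het(g))) / n2
    },
    .groups = "drop")
  k <- site_key(calls$chrom, calls$pos)
  alt_af <- af$alt_af[match(k, site_key(af$chrom, af$pos))]
  derived_is_alt <- calls$derived == calls$alt
  post_af <- ifelse(derived_is_alt, alt_af, 1 - alt_af)
  pre_af <- 1 - post_af
  cls <- dplyr::case_when(
    is.na(calls$ancestral) ~ "unclassified",
    is.na(post_af) ~ "unclassified",
    post_af > af_threshold ~ "positive",
    pre_af > af_threshold ~ "purifying",
    TRUE ~ "unclassified"
  )
  reason <- dplyr::case_when(
    is.na(calls$ancestral) ~ "unpolarized",
    is.na(post_af) ~ "absent_from_outgroup",
    TRUE ~ NA_character_
  )
  calls$pre_af <- pre_af
  calls$post_af <- post_af
  calls$selection_class <- cls
  calls$selection_reason <- reason
  calls
}

#' Derived-allele burden summary
#'
#' Among ingroup genotypes at polarized derived-allele sites, reports the
#' fraction of derived alleles observed in a heterozygous state and the
#' fraction fixed (derived frequency 1 among the ingroup), after removing
#' sites with ingroup minor allele frequency below `maf_min`.
#'
#' @param genotypes Long ingroup genotype tibble `chrom,pos,sample,gt`
#'   restricted to derived-allele sites, where allele 1 is the derived one.
#' @param maf_min Minor-allele-frequency floor (default 0.1; sites strictly
#'   below are removed).
#' @return Tibble `n_sites, het_percent, fixed_percent` (1-decimal).
#' @export
derived_allele_burden <- function(genotypes, maf_min = 0.1) {
  per_site <- dplyr::summarise(
    dplyr::group_by(genotypes, .data$chrom, .data$pos),
    af = {
      g <- .data$gt[!is.na(.data$gt)]
      n2 <- 2 * length(g)
      if (n2 == 0) NA_real_
      else (2 * sum(g %in% c("1/1", "1|1")) + sum(is_het(g))) / n2
    },
    any_het = any(is_het(.data$gt)),
    .groups = "drop")
  per_site <- per_site[!is.na(per_site$af), ]
  per_site <- per_site[pmin(per_site$af, 1 - per_site$af) >= maf_min |
                         per_site$af == 1, ]
  n <- nrow(per_site)
  tibble::tibble(
    n_sites = n,
    het_percent = percent_of(sum(per_site$any_het), n),
    fixed_percent = percent_of(sum(per_site$af == 1), n)
  )
}
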