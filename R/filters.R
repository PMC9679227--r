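#' Hard-filter and post-filter thresholds
#'
#' Defaults reproduce a standard GATK hard-filter recipe for SNPs
#' (`FS > 60 || MQ < 40 || MQRankSum < -12.5 || QD < 2 ||
#' ReadPosRankSum < -8 || SOR > 3`) and indels
#' (`QD < 2 || FS > 200 || ReadPosRankSum < -20`), plus depth, indel
#' proximity, genotype-quality and missingness post-filters. All
#' comparisons are strict, matching the printed operators.
#'
#' @param snp_hard,indel_hard Named threshold lists; see defaults.
#' @param depth_hi_mult,depth_lo_mult Genotypes with depth above
#'   `depth_hi_mult` x the per-sample mean (or below `depth_lo_mult` x) are
#'   masked.
#' @param indel_prox_bp SNVs at or within this many bp of an indel are
#'   removed (closed interval around the indel span).
#' @param gq_min Genotypes with GQ below this are masked (set missing), not
#'   dropped with the site.
#' @param site_missing_max SNV sites whose post-masking genotype missing
#'   rate strictly exceeds this fraction are removed.
#' @return A `filter_config` list.
#' @export
filter_config <- function(snp_hard = list(FS_gt = 60, MQ_lt = 40,
                                          MQRankSum_lt = -12.5, QD_lt = 2,
                                          ReadPosRankSum_lt = -8, SOR_gt = 3),
                          indel_hard = list(QD_lt = 2.0, FS_gt = 200.0,
                                            ReadPosRankSum_lt = -20.0),
                          depth_hi_mult = 3.0,
                          depth_lo_mult = 1 / 3,
                          indel_prox_bp = 5L,
                          gq_min = 10,
                          site_missing_max = 0.25) {
  stop_if_not(all(is.finite(unlist(snp_hard))) &&
                all(is.finite(unlist(indel_hard))),
              "all hard-filter thresholds must be finite")
  stop_if_not(depth_lo_mult < depth_hi_mult,
              "depth_lo_mult must be below depth_hi_mult")
  structure(list(snp_hard = snp_hard, indel_hard = indel_hard,
                 depth_hi_mult = depth_hi_mult, depth_lo_mult = depth_lo_mult,
                 indel_prox_bp = as.integer(indel_prox_bp), gq_min = gq_min,
                 site_missing_max = site_missing_max),
            class = "filter_config")
}

# coerce an INFO column to numeric, warning (once per column) on values that
# cannot be parsed; unparseable values become NA, which makes the rule
# non-evaluable for that site
info_numeric <- function(x, name) {
  if (is.numeric(x)) return(x)
  out <- suppressWarnings(as.numeric(x))
  bad <- !is.na(x) & is.na(out)
  if (any(bad)) {
    warn(sprintf("%d non-numeric %s value(s); rule skipped at those sites",
                 sum(bad), name))
  }
  out
}

#' Apply the hard-filter cascade to a site table
#'
#' A site is removed iff ANY of the type-appropriate predicates is true
#' (OR semantics). A missing or unparseable annotation makes that rule
#' non-evaluable at that site (it cannot trigger removal). Strict
#' inequalities throughout: `FS = 60` exactly is retained.
#'
#' @param sites Long site table (one row per site x sample) carrying the
#'   site-level columns `FS, MQ, MQRankSum, QD, ReadPosRankSum, SOR` and
#'   `var_type` (`"snv"` or `"indel"`).
#' @param config A [filter_config()].
#' @return The retained rows of `sites`, with attributes
#'   `removal_ledger` (tibble `chrom,pos,ref,alt,rule`, one row per removed
#'   site and triggered rule) and `removal_counts` (per-rule tally).
#'   Retrieve them with [removal_ledger()].
#' @export
apply_hard_filters <- function(sites, config = filter_config()) {
  key_cols <- c("chrom", "pos", "ref", "alt")
  info_cols <- c("FS", "MQ", "MQRankSum", "QD", "ReadPosRankSum", "SOR")
  site_level <- dplyr::distinct(
    sites, dplyr::across(dplyr::all_of(c(key_cols, "var_type",
                                         intersect(info_cols, names(sites)))))
  )
  for (cn in intersect(info_cols, names(site_level))) {
    site_level[[cn]] <- info_numeric(site_level[[cn]], cn)
  }
  gv <- function(cn) {
    if (cn %in% names(site_level)) site_level[[cn]]
    else rep(NA_real_, nrow(site_level))
  }
  isTRUEv <- function(x) !is.na(x) & x
  snp <- site_level$var_type != "indel"
  s <- config$snp_hard
  i <- config$indel_hard
  rules <- list(
    FS = isTRUEv(ifelse(snp, gv("FS") > s$FS_gt, gv("FS") > i$FS_gt)),
    MQ = isTRUEv(snp & gv("MQ") < s$MQ_lt),
    MQRankSum = isTRUEv(snp & gv("MQRankSum") < s$MQRankSum_lt),
    QD = isTRUEv(ifelse(snp, gv("QD") < s$QD_lt, gv("QD") < i$QD_lt)),
    ReadPosRankSum = isTRUEv(ifelse(snp,
                                    gv("ReadPosRankSum") < s$ReadPosRankSum_lt,
                                    gv("ReadPosRankSum") < i$ReadPosRankSum_lt)),
    SOR = isTRUEv(snp & gv("SOR") > s$SOR_gt)
  )
  fail_any <- Reduce(`|`, rules)

  ledger <- dplyr::bind_rows(lapply(names(rules), function(rn) {
    hit <- rules[[rn]]
    if (!any(hit)) return(NULL)
    out <- site_level[hit, key_cols]
    out$rule <- rn
    out
  }))
  if (is.null(ledger) || ncol(ledger) == 0) {
    ledger <- tibble::tibble(chrom = character(), pos = integer(),
                             ref = character(), alt = character(),
                             rule = character())
  }

  removed_keys <- site_key(site_level$chrom[fail_any], site_level$pos[fail_any],
                           site_level$ref[fail_any], site_level$alt[fail_any])
  keep <- !site_key(sites$chrom, sites$pos, sites$ref, sites$alt) %in%
    removed_keys
  out <- sites[keep, , drop = FALSE]
  attr(out, "removal_ledger") <- ledger
  attr(out, "removal_counts") <- dplyr::count(ledger, .data$rule,
                                              name = "n_sites")
  out
}

#' Apply the site-level post-filters
#'
#' In order: (1) genotypes with depth above `depth_hi_mult` x or below
#' `depth_lo_mult` x that sample's mean depth are masked; (2) genotypes with
#' GQ below `gq_min` are masked; (3) SNVs at or within `indel_prox_bp` of an
#' indel in the table are removed (closed interval; the indel span is
#' `pos .. pos + max(nchar(ref), nchar(alt)) - 1`); (4) SNV sites whose
#' genotype missing rate after masking strictly exceeds `site_missing_max`
#' are removed. Masking sets `gt` to `NA`; it does not drop the site.
#'
#' @inheritParams apply_hard_filters
#' @return Retained rows with masked genotypes, plus a `removal_ledger`
#'   attribute as in [apply_hard_filters()].
#' @export
apply_site_postfilters <- function(sites, config = filter_config()) {
  sites <- dplyr::group_by(sites, .data$sample)
  sites <- dplyr::mutate(sites, .mean_dp = mean(.data$dp, na.rm = TRUE))
  sites <- dplyr::ungroup(sites)

  depth_bad <- !is.na(sites$dp) &
    (sites$dp > config$depth_hi_mult * sites$.mean_dp |
       sites$dp < config$depth_lo_mult * sites$.mean_dp)
  gq_bad <- !is.na(sites$gq) & sites$gq < config$gq_min
  sites$gt[depth_bad | gq_bad] <- NA_character_
  sites$.mean_dp <- NULL

  # indel proximity: SNVs within the closed interval [start-5, end+5]
  indels <- dplyr::distinct(sites[sites$var_type == "indel", ],
                            .data$chrom, .data$pos, .data$ref, .data$alt)
  prox_keys <- character(0)
  if (nrow(indels) > 0) {
    span_end <- indels$pos +
      pmax(nchar(indels$ref), nchar(indels$alt)) - 1L
    snv_sites <- dplyr::distinct(sites[sites$var_type != "indel", ],
                                 .data$chrom, .data$pos, .data$ref, .data$alt)
    if (nrow(snv_sites) > 0) {
      hit <- logical(nrow(snv_sites))
      for (ch in unique(indels$chrom)) {
        iv <- indels$chrom == ch
        sv <- snv_sites$chrom == ch
        if (!any(sv)) next
        lo <- indels$pos[iv] - config$indel_prox_bp
        hi <- span_end[iv] + config$indel_prox_bp
        p <- snv_sites$pos[sv]
        hit[sv] <- hit[sv] | vapply(p, function(x) any(x >= lo & x <= hi),
                                    logical(1))
      }
      prox_keys <- site_key(snv_sites$chrom[hit], snv_sites$pos[hit],
                            snv_sites$ref[hit], snv_sites$alt[hit])
    }
  }

  keys <- site_key(sites$chrom, sites$pos, sites$ref, sites$alt)
  ledger <- tibble::tibble(chrom = character(), pos = integer(),
                           ref = character(), alt = character(),
                           rule = character())
  if (length(prox_keys) > 0) {
    hit_rows <- dplyr::distinct(
      sites[keys %in% prox_keys, c("chrom", "pos", "ref", "alt")])
    hit_rows$rule <- "indel_proximity"
    ledger <- dplyr::bind_rows(ledger, hit_rows)
    sites <- sites[!keys %in% prox_keys, , drop = FALSE]
    keys <- keys[!keys %in% prox_keys]
  }

  # missingness after masking (SNVs; indels have their own criteria later)
  miss <- dplyr::summarise(
    dplyr::group_by(sites, .data$chrom, .data$pos, .data$ref, .data$alt,
                    .data$var_type),
    miss_rate = mean(is.na(.data$gt)), .groups = "drop")
  miss_bad <- miss[miss$var_type != "indel" &
                     miss$miss_rate > config$site_missing_max, ]
  if (nrow(miss_bad) > 0) {
    bad_keys <- site_key(miss_bad$chrom, miss_bad$pos, miss_bad$ref,
                         miss_bad$alt)
    hit_rows <- miss_bad[, c("chrom", "pos", "ref", "alt")]
    hit_rows$rule <- "missing"
    ledger <- dplyr::bind_rows(ledger, hit_rows)
    sites <- sites[!keys %in% bad_keys, , drop = FALSE]
  }

  attr(sites, "removal_ledger") <- ledger
  attr(sites, "removal_counts") <- dplyr::count(ledger, .data$rule,
                                                name = "n_sites")
  sites
}

#' Retrieve the removal ledger left by a filter step
#'
#' @param sites A site table returned by [apply_hard_filters()] or
#'   [apply_site_postfilters()].
#' @return Tibble `chrom,pos,ref,alt,rule`.
#' @export
removal_ledger <- function(sites) {
  attr(sites, "removal_ledger") %||%
    tibble::tibble(chrom = character(), pos = integer(), ref = character(),
                   alt = character(), rule = character())
}
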