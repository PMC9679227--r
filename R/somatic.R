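#' Strand-count filter for candidate somatic alleles
#'
#' A candidate passes iff the mutant allele is seen on both strands and the
#' strand bias ratio `max(fwd, rev) / min(fwd, rev)` is strictly below 2.
#' Missing counts fail (reason "no-counts").
#'
#' @param fwd_alt,rev_alt Integer vectors of mutant-allele read counts on the
#'   forward and reverse strand.
#' @return Logical vector (`TRUE` = pass).
#' @export
#' @examples
#' strand_filter(3, 2)  # TRUE: ratio 1.5
#' strand_filter(4, 2)  # FALSE: ratio 2 is not < 2
#' strand_filter(5, 0)  # FALSE: single strand
strand_filter <- function(fwd_alt, rev_alt) {
  ok <- !is.na(fwd_alt) & !is.na(rev_alt) &
    fwd_alt >= 1 & rev_alt >= 1 &
    pmax(fwd_alt, rev_alt) < 2 * pmin(fwd_alt, rev_alt)
  unname(ok)
}

#' Mask calls inside recurrent structural variants
#'
#' Builds a per-base support profile from per-sample SV intervals and masks
#' every base supported by strictly more than half of the samples; calls
#' overlapping a masked base (closed intervals) are removed.
#'
#' @param calls Tibble of calls with `chrom` and `pos`.
#' @param sv_intervals Tibble `chrom,start,end,sample` (1-based closed, as
#'   returned by [read_bed()]); intervals are merged within sample before
#'   support counting.
#' @param n_samples Total number of samples the majority is taken over.
#' @return `calls` minus masked rows; attribute `masked` holds the removed
#'   rows and attribute `mask` the active mask intervals.
#' @export
sv_mask <- function(calls, sv_intervals, n_samples) {
  if (is.null(sv_intervals) || nrow(sv_intervals) == 0) {
    attr(calls, "masked") <- calls[0, , drop = FALSE]
    return(calls)
  }
  masks <- list()
  for (ch in unique(sv_intervals$chrom)) {
    iv <- sv_intervals[sv_intervals$chrom == ch, , drop = FALSE]
    merged <- dplyr::bind_rows(lapply(split(iv, iv$sample), merge_intervals))
    # breakpoint sweep: support = number of samples covering each segment
    events <- rbind(cbind(merged$start, 1L), cbind(merged$end + 1L, -1L))
    events <- events[order(events[, 1]), , drop = FALSE]
    bp <- unique(events[, 1])
    support <- cumsum(vapply(bp, function(b) sum(events[events[, 1] == b, 2]),
                             numeric(1)))
    active <- support > n_samples / 2
    if (!any(active)) next
    seg_start <- bp[active]
    seg_end <- c(bp[-1], max(merged$end) + 1L)[active] - 1L
    masks[[ch]] <- tibble::tibble(chrom = ch, start = seg_start,
                                  end = seg_end)
  }
  mask <- dplyr::bind_rows(masks)
  if (is.null(mask) || nrow(mask) == 0) {
    attr(calls, "masked") <- calls[0, , drop = FALSE]
    return(calls)
  }
  hit <- logical(nrow(calls))
  for (ch in unique(mask$chrom)) {
    mv <- mask[mask$chrom == ch, ]
    cv <- which(calls$chrom == ch)
    if (length(cv) == 0) next
    hit[cv] <- vapply(calls$pos[cv],
                      function(p) any(p >= mv$start & p <= mv$end),
                      logical(1))
  }
  out <- calls[!hit, , drop = FALSE]
  attr(out, "masked") <- calls[hit, , drop = FALSE]
  attr(out, "mask") <- mask
  out
}

merge_intervals <- function(iv) {
  iv <- iv[order(iv$start), , drop = FALSE]
  if (nrow(iv) <= 1) return(iv[, c("chrom", "start", "end")])
  out_start <- iv$start[1]; out_end <- iv$end[1]
  starts <- c(); ends <- c()
  for (i in 2:nrow(iv)) {
    if (iv$start[i] <= out_end + 1L) {
      out_end <- max(out_end, iv$end[i])
    } else {
      starts <- c(starts, out_start); ends <- c(ends, out_end)
      out_start <- iv$start[i]; out_end <- iv$end[i]
    }
  }
  starts <- c(starts, out_start); ends <- c(ends, out_end)
  tibble::tibble(chrom = iv$chrom[1], start = starts, end = ends)
}

#' Call somatic mutations among clonal samples
#'
#' A site is a somatic candidate iff the non-missing genotypes are not
#' identical across the clonemates. The clone-founder genotype is the
#' majority genotype (ties broken toward the homozygous ancestral genotype
#' when outgroup genotypes are supplied, else toward the lexicographically
#' smallest genotype); carriers are the samples deviating from it. For SNVs,
#' carriers whose genotype contains the alternate allele must additionally
#' pass the strand-count filter on their mutant-allele reads; carriers
#' failing it are dropped, and a site with no surviving carrier is not
#' called. Sites with more than two alleles are excluded and counted.
#'
#' @param sites Long filtered site table (post [apply_site_postfilters()]).
#' @param annotation Optional annotation intervals
#'   (tibble `chrom,start,end,class`) used to label each call
#'   `exon`/`intron`/`intergenic`.
#' @param outgroup Optional outgroup genotype tibble `chrom,pos,gt` (or long
#'   with `sample`) used for founder tie-breaking.
#' @param apply_strand Apply the strand filter to carriers (default TRUE).
#' @return A `somatic_calls` tibble: one row per call with
#'   `chrom,pos,ref,alt,var_type,founder_gt,carrier_gt,transition,carriers`
#'   (list column), `n_carriers`, `shared`, `annotation`. Excluded
#'   multi-allelic sites are counted in attribute `n_multiallelic`.
#' @export
call_somatic <- function(sites, annotation = NULL, outgroup = NULL,
                         apply_strand = TRUE) {
  multi <- grepl(",", sites$alt, fixed = TRUE)
  n_multi <- length(unique(site_key(sites$chrom[multi], sites$pos[multi])))
  sites <- sites[!multi, , drop = FALSE]

  anc <- NULL
  if (!is.null(outgroup)) anc <- outgroup_ancestral_gt(outgroup)

  # fast pre-screen: only genotype-heterogeneous sites can be somatic
  het_sites <- dplyr::summarise(
    dplyr::group_by(sites, .data$chrom, .data$pos, .data$ref, .data$alt),
    .hetero = dplyr::n_distinct(.data$gt[!is.na(.data$gt)]) > 1,
    .groups = "drop")
  het_sites <- het_sites[het_sites$.hetero, c("chrom", "pos", "ref", "alt")]
  sites <- dplyr::semi_join(sites, het_sites,
                            by = c("chrom", "pos", "ref", "alt"))

  grp <- dplyr::group_by(sites, .data$chrom, .data$pos, .data$ref, .data$alt,
                         .data$var_type)
  calls <- dplyr::group_modify(grp, function(df, key) {
    gts <- df$gt[!is.na(df$gt)]
    if (length(gts) == 0 || length(unique(gts)) == 1) return(tibble::tibble())
    tab <- sort(table(gts), decreasing = TRUE)
    top <- names(tab)[tab == max(tab)]
    founder <- if (length(top) == 1) {
      top[1]
    } else if (!is.null(anc)) {
      k <- site_key(key$chrom, key$pos)
      anc_gt <- anc$gt[match(k, site_key(anc$chrom, anc$pos))]
      if (!is.na(anc_gt) && anc_gt %in% top) anc_gt else min(top)
    } else {
      min(top)
    }
    carrier_rows <- df[!is.na(df$gt) & df$gt != founder, , drop = FALSE]
    if (apply_strand && key$var_type != "indel") {
      has_alt <- grepl("1", carrier_rows$gt, fixed = TRUE)
      pass <- !has_alt |
        strand_filter(carrier_rows$fwd_alt, carrier_rows$rev_alt)
      carrier_rows <- carrier_rows[pass, , drop = FALSE]
    }
    if (nrow(carrier_rows) == 0) return(tibble::tibble())
    cg <- names(sort(table(carrier_rows$gt), decreasing = TRUE))[1]
    tibble::tibble(
      founder_gt = founder,
      carrier_gt = cg,
      transition = classify_transition(founder, cg),
      carriers = list(sort(carrier_rows$sample)),
      n_carriers = nrow(carrier_rows)
    )
  })
  calls <- dplyr::ungroup(calls)
  if (nrow(calls) > 0) {
    calls$shared <- calls$n_carriers >= 2
    calls$annotation <- if (!is.null(annotation)) {
      annotation_class_at(annotation, calls$chrom, calls$pos)
    } else NA_character_
  } else {
    calls <- tibble::tibble(chrom = character(), pos = integer(),
                            ref = character(), alt = character(),
                            var_type = character(), founder_gt = character(),
                            carrier_gt = character(), transition = character(),
                            carriers = list(), n_carriers = integer(),
                            shared = logical(), annotation = character())
  }
  attr(calls, "n_multiallelic") <- n_multi
  class(calls) <- c("somatic_calls", class(calls))
  calls
}

classify_transition <- function(founder, carrier) {
  fz <- gt_zygosity(founder)
  cz <- gt_zygosity(carrier)
  dplyr::case_when(
    fz %in% c("hom_ref", "hom_alt") & cz == "het" ~ "hom_to_het",
    fz == "het" & cz %in% c("hom_ref", "hom_alt") ~ "het_to_hom",
    fz == "hom_ref" & cz == "hom_alt" ~ "hom_to_hom_alt",
    fz == "hom_alt" & cz == "hom_ref" ~ "hom_to_hom_alt",
    TRUE ~ "other"
  )
}

# consensus homozygous genotype per site across an outgroup table
outgroup_ancestral_gt <- function(outgroup) {
  grp <- dplyr::group_by(outgroup, .data$chrom, .data$pos)
  out <- dplyr::summarise(grp, gt = {
    g <- .data$gt[!is.na(.data$gt)]
    g <- unique(g)
    if (length(g) == 1 && g %in% c("0/0", "1/1")) g else NA_character_
  }, .groups = "drop")
  out
}

#' Somatic retention filter for indel sites
#'
#' Indel sites are retained iff the mean mapped read count across evaluable
#' (non-missing) samples is at least `min_reads` and the genotype missing
#' rate is at most `max_missing` (strictly more than `max_missing` removes
#' the site).
#'
#' @param sites Long site table; only `var_type == "indel"` rows are
#'   considered.
#' @param min_reads Minimum mean read count (default 5; a site at 4 is
#'   removed, at 5 retained).
#' @param max_missing Maximum genotype missing rate (default 0.10; exactly
#'   10 percent exactly is retained).
#' @return The retained indel rows.
#' @export
indel_somatic_filter <- function(sites, min_reads = 5, max_missing = 0.10) {
  ind <- sites[sites$var_type == "indel", , drop = FALSE]
  if (nrow(ind) == 0) return(ind)
  stats_tbl <- dplyr::summarise(
    dplyr::group_by(ind, .data$chrom, .data$pos, .data$ref, .data$alt),
    mean_reads = mean(.data$dp[!is.na(.data$gt)]),
    miss_rate = mean(is.na(.data$gt)),
    .groups = "drop")
  keep <- !is.nan(stats_tbl$mean_reads) &
    stats_tbl$mean_reads >= min_reads &
    stats_tbl$miss_rate <= max_missing
  keep_keys <- site_key(stats_tbl$chrom[keep], stats_tbl$pos[keep],
                        stats_tbl$ref[keep], stats_tbl$alt[keep])
  ind[site_key(ind$chrom, ind$pos, ind$ref, ind$alt) %in% keep_keys, ,
      drop = FALSE]
}
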