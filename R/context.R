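#' Configuration for genomic-context analyses
#'
#' @param flank_bp Flank width around each mutation for the
#'   heterozygosity-versus-distance profile (default 1200 bp).
#' @param n_random_sites Random control positions (default 1000).
#' @param window_bp Recombination window width (default 50 kb,
#'   non-overlapping).
#' @param n_groups Number of somatic-SNP-count classes for the
#'   recombination regression (default 7: counts 0..5 and >= 6 pooled).
#' @param distance_bins Monotone bin edges up to `flank_bp` (default 12
#'   equal bins).
#' @return A `context_config` list.
#' @export
context_config <- function(flank_bp = 1200, n_random_sites = 1000,
                           window_bp = 50000, n_groups = 7,
                           distance_bins = NULL) {
  stop_if_not(flank_bp > 0, "flank_bp must be > 0")
  stop_if_not(n_groups >= 2, "n_groups must be >= 2")
  distance_bins <- distance_bins %||% seq(0, flank_bp, length.out = 13)
  stop_if_not(all(diff(distance_bins) > 0) &&
                max(distance_bins) <= flank_bp,
              "distance_bins must be increasing and bounded by flank_bp")
  structure(list(flank_bp = flank_bp, n_random_sites = n_random_sites,
                 window_bp = window_bp, n_groups = as.integer(n_groups),
                 distance_bins = distance_bins),
            class = "context_config")
}

# per-site heterozygous fraction and nucleotide diversity from a long
# genotype table
site_diversity <- function(genotypes) {
  grp <- dplyr::group_by(genotypes, .data$chrom, .data$pos)
  dplyr::summarise(grp,
    n_called = sum(!is.na(.data$gt)),
    het_fraction = mean(is_het(.data$gt[!is.na(.data$gt)])),
    pi = {
      g <- .data$gt[!is.na(.data$gt)]
      n2 <- 2 * length(g)
      if (n2 < 2) NA_real_ else {
        p <- (2 * sum(g %in% c("1/1", "1|1")) + sum(is_het(g))) / n2
        2 * p * (1 - p) * n2 / (n2 - 1)
      }
    },
    .groups = "drop")
}

#' Heterozygosity versus distance to the nearest somatic mutation
#'
#' Computes, for genotyped sites binned by distance to the nearest somatic
#' call, the mean heterozygous fraction and nucleotide diversity (pi,
#' per-site), stratified by the annotation class of the nearest call, plus
#' the same profile around `n_random_sites` uniformly random control
#' positions. Bins with no sites are reported as missing, not zero.
#'
#' @param calls Somatic calls (`chrom,pos`, optionally `annotation` and a
#'   logical `deleterious` column for extra strata).
#' @param genotypes Long population genotype table `chrom,pos,sample,gt`.
#' @param ref A `ref_model` (for chromosome lengths and random controls).
#' @param config A [context_config()].
#' @param seed Seed for the random control positions.
#' @return A `het_profile` tibble: `set` (`somatic`/`random`), `stratum`,
#'   `bin`, `d_lo`, `d_hi`, `n_sites`, `het_fraction`, `pi`.
#' @export
het_vs_distance <- function(calls, genotypes, ref, config = context_config(),
                            seed = NULL) {
  stop_if_not(nrow(calls) > 0, "no somatic calls supplied")
  div <- site_diversity(genotypes)
  strata <- list(all = calls)
  if ("annotation" %in% names(calls)) {
    for (cl in unique(calls$annotation[!is.na(calls$annotation)])) {
      strata[[cl]] <- calls[!is.na(calls$annotation) &
                              calls$annotation == cl, ]
    }
  }
  if ("deleterious" %in% names(calls) && any(calls$deleterious %in% TRUE)) {
    strata[["deleterious"]] <- calls[calls$deleterious %in% TRUE, ]
  }

  profile_for <- function(anchor, set_name, stratum) {
    d <- rep(NA_real_, nrow(div))
    for (ch in unique(anchor$chrom)) {
      sel <- div$chrom == ch
      if (!any(sel)) next
      ap <- sort(anchor$pos[anchor$chrom == ch])
      # nearest anchor; ties to the left
      idx <- findInterval(div$pos[sel], ap)
      left <- ifelse(idx >= 1, ap[pmax(idx, 1)], NA)
      right <- ifelse(idx < length(ap), ap[pmin(idx + 1, length(ap))], NA)
      dl <- abs(div$pos[sel] - left)
      dr <- abs(div$pos[sel] - right)
      d[sel] <- pmin(dl, dr, na.rm = TRUE)
    }
    keep <- !is.na(d) & d > 0 & d <= config$flank_bp
    edges <- config$distance_bins
    bin <- cut(d[keep], edges, include.lowest = FALSE, right = TRUE)
    sub <- div[keep, ]
    agg <- dplyr::summarise(
      dplyr::group_by(tibble::tibble(bin = bin, het = sub$het_fraction,
                                     pi = sub$pi), .data$bin, .drop = FALSE),
      n_sites = dplyr::n(),
      het_fraction = ifelse(dplyr::n() == 0, NA_real_,
                            mean(.data$het, na.rm = TRUE)),
      pi = ifelse(dplyr::n() == 0, NA_real_, mean(.data$pi, na.rm = TRUE)),
      .groups = "drop")
    agg$set <- set_name
    agg$stratum <- stratum
    agg$d_lo <- head(edges, -1)[as.integer(agg$bin)]
    agg$d_hi <- edges[-1][as.integer(agg$bin)]
    agg
  }

  out <- dplyr::bind_rows(lapply(names(strata), function(s) {
    profile_for(strata[[s]], "somatic", s)
  }))
  if (config$n_random_sites > 0) {
    if (!is.null(seed)) set.seed(seed)
    L_total <- sum(ref$chrom_lengths)
    offsets <- cumsum(c(0, ref$chrom_lengths))
    gpos <- sample.int(L_total, min(config$n_random_sites, L_total))
    idx <- findInterval(gpos - 1, offsets)
    rnd <- tibble::tibble(chrom = names(ref$chrom_lengths)[idx],
                          pos = as.integer(gpos - offsets[idx]))
    out <- dplyr::bind_rows(out, profile_for(rnd, "random", "all"))
  }
  out <- dplyr::select(out, "set", "stratum", "bin", "d_lo", "d_hi",
                       "n_sites", "het_fraction", "pi")
  class(out) <- c("het_profile", class(out))
  out
}

#' Yates-corrected chi-square test of annotation-class mutation burden
#'
#' For each annotation class, compares the observed in-class versus
#' out-of-class mutation counts with the counts expected from the genomic
#' base fractions, using the continuity-corrected statistic
#' `sum((|O - E| - 0.5)^2 / E)` on the two cells, df = 1.
#'
#' @param call_counts Named integer vector: somatic calls per annotation
#'   class.
#' @param genome_fractions Named numeric vector of genomic base fractions
#'   per class (same names; must sum to 1).
#' @return Tibble `class, observed, expected, chisq, p_value`.
#' @export
#' @examples
#' annotation_chisq(c(coding = 30, other = 970),
#'                  c(coding = 0.05, other = 0.95))
annotation_chisq <- function(call_counts, genome_fractions) {
  stop_if_not(sum(call_counts) > 0, "zero total calls")
  stop_if_not(abs(sum(genome_fractions) - 1) < 1e-6,
              "genome_fractions must sum to 1")
  stop_if_not(setequal(names(call_counts), names(genome_fractions)),
              "call_counts and genome_fractions need matching names")
  N <- sum(call_counts)
  rows <- lapply(names(call_counts), function(cl) {
    O <- c(call_counts[[cl]], N - call_counts[[cl]])
    E <- N * c(genome_fractions[[cl]], 1 - genome_fractions[[cl]])
    stop_if_not(all(E > 0), "expected counts must be positive")
    x2 <- sum((abs(O - E) - 0.5)^2 / E)
    tibble::tibble(class = cl, observed = O[1], expected = E[1],
                   chisq = x2, p_value = pchisq(x2, df = 1,
                                                lower.tail = FALSE))
  })
  dplyr::bind_rows(rows)
}

#' Recombination-rate regression over somatic-mutation count classes
#'
#' Counts somatic SNVs per recombination window, classes windows by count
#' (0, 1, ..., with the top class pooled at `n_groups - 1` or more; or
#' quantile classes), averages the population recombination rate per class,
#' and fits an ordinary least-squares regression of the class mean rate on
#' the class index.
#'
#' @param calls Somatic calls (`chrom,pos`; SNVs).
#' @param windows Tibble `chrom,start,end,rho` of non-overlapping windows
#'   (1-based closed).
#' @param config A [context_config()].
#' @param grouping `"count"` (default) or `"quantile"`.
#' @return A `recomb_fit` list: `groups` (tibble `group, group_index,
#'   n_windows, mean_rho`), `model` (the `lm`, or NULL when skipped),
#'   `slope`, `p_value`.
#' @export
recomb_regression <- function(calls, windows, config = context_config(),
                              grouping = c("count", "quantile")) {
  grouping <- match.arg(grouping)
  counts <- integer(nrow(windows))
  for (ch in unique(windows$chrom)) {
    wv <- which(windows$chrom == ch)
    cp <- calls$pos[calls$chrom == ch]
    if (length(cp) == 0) next
    counts[wv] <- vapply(wv, function(i) {
      sum(cp >= windows$start[i] & cp <= windows$end[i])
    }, integer(1))
  }
  k <- config$n_groups
  if (grouping == "count") {
    gidx <- pmin(counts, k - 1L)
    glab <- ifelse(gidx == k - 1L, paste0(">=", k - 1L), as.character(gidx))
  } else {
    qs <- unique(quantile(counts, probs = seq(0, 1, length.out = k + 1)))
    gidx <- as.integer(cut(counts, qs, include.lowest = TRUE)) - 1L
    glab <- as.character(gidx)
  }
  groups <- dplyr::summarise(
    dplyr::group_by(tibble::tibble(group = glab, group_index = gidx,
                                   rho = windows$rho),
                    .data$group, .data$group_index),
    n_windows = dplyr::n(), mean_rho = mean(.data$rho, na.rm = TRUE),
    .groups = "drop")
  groups <- dplyr::arrange(groups, .data$group_index)

  model <- NULL; slope <- NA_real_; p <- NA_real_
  if (nrow(groups) >= 2) {
    model <- lm(mean_rho ~ group_index, data = groups)
    sm <- summary(model)$coefficients
    slope <- sm["group_index", "Estimate"]
    p <- sm["group_index", "Pr(>|t|)"]
  } else {
    warn("fewer than 2 non-empty groups: regression skipped")
  }
  structure(list(groups = groups, model = model, slope = slope,
                 p_value = p, grouping = grouping),
            class = "recomb_fit")
}

#' @export
print.recomb_fit <- function(x, ...) {
  cat("<recomb_fit>\n")
  print(x$groups)
  cat(sprintf("  slope %.4g, p = %.4g\n", x$slope, x$p_value))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
tidy.recomb_fit <- function(x, ...) x$groups

#' @importFrom generics glance
#' @export
glance.recomb_fit <- function(x, ...) {
  tibble::tibble(slope = x$slope, p_value = x$p_value,
                 n_groups = nrow(x$groups), grouping = x$grouping)
}
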