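#' Plot a somatic mutation spectrum
#'
#' Bar chart of the six strand-collapsed substitution classes.
#'
#' @param spectrum A `spectrum_tbl` from [classify_spectrum()].
#' @return A ggplot object.
#' @export
plot_spectrum <- function(spectrum) {
  df <- spectrum$class6
  ggplot2::ggplot(df, ggplot2::aes(x = .data$class, y = .data$count,
                                   fill = .data$class)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::labs(x = "substitution class (pyrimidine-rooted)",
                  y = "somatic SNVs",
                  title = sprintf("Mutation spectrum (n = %d)", spectrum$n)) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.spectrum_tbl <- function(object, ...) plot_spectrum(object)

#' Plot base composition by distance from mutations
#'
#' A/T and C/G proportions against flank distance, with the genome-wide
#' fractions as dashed baselines.
#'
#' @param profile A `flank_profile` from [flanking_composition()].
#' @return A ggplot object.
#' @export
plot_flanking_composition <- function(profile) {
  long <- tidyr::pivot_longer(tibble::as_tibble(profile),
                              c("prop_at", "prop_gc"),
                              names_to = "content", values_to = "proportion")
  long$content <- ifelse(long$content == "prop_at", "A/T", "C/G")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$distance,
                                     y = .data$proportion,
                                     colour = .data$content)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = attr(profile, "baseline_at"),
                        linetype = "dashed", colour = "grey40") +
    ggplot2::geom_hline(yintercept = attr(profile, "baseline_gc"),
                        linetype = "dashed", colour = "grey40") +
    ggplot2::labs(x = "distance from mutation (bp)",
                  y = "proportion of base content", colour = NULL) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.flank_profile <- function(object, ...) {
  plot_flanking_composition(object)
}

#' Plot heterozygosity versus distance to somatic mutations
#'
#' @param profile A `het_profile` from [het_vs_distance()].
#' @param y `"pi"` (nucleotide diversity, default) or `"het_fraction"`.
#' @return A ggplot object.
#' @export
plot_het_distance <- function(profile, y = c("pi", "het_fraction")) {
  y <- match.arg(y)
  df <- tibble::as_tibble(profile)
  df$d_mid <- (df$d_lo + df$d_hi) / 2
  ggplot2::ggplot(df, ggplot2::aes(x = .data$d_mid, y = .data[[y]],
                                   colour = .data$stratum,
                                   linetype = .data$set)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = "distance to nearest somatic mutation (bp)",
                  y = if (y == "pi") "nucleotide diversity (π)"
                      else "heterozygous fraction",
                  colour = "stratum", linetype = NULL) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.het_profile <- function(object, ...) plot_het_distance(object, ...)

#' Plot pre- versus post-mutation outgroup allele frequencies
#'
#' @param calls Output of [classify_selection()].
#' @return A ggplot object.
#' @export
plot_selection_af <- function(calls) {
  df <- calls[!is.na(calls$pre_af), ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$pre_af, y = .data$post_af,
                                   colour = .data$selection_class)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::labs(x = "pre-mutation allele frequency (outgroup)",
                  y = "post-mutation allele frequency (outgroup)",
                  colour = "selection") +
    ggplot2::theme_minimal()
}

#' Plot a reconstructed clonal pedigree
#'
#' Simple rectangular layout; horizontal branch lengths are per-branch
#' mutation counts.
#'
#' @param pedigree A `clone_pedigree` from [build_pedigree()].
#' @return A ggplot object.
#' @export
plot_pedigree <- function(pedigree) {
  br <- pedigree$branches
  leaves <- names(pedigree$leaf_counts)
  y_leaf <- setNames(seq_along(leaves), leaves)
  br <- br[order(-br$n_leaves), ]
  # depth of a clade = sum of mutations from root to (and including) it
  depth <- numeric(nrow(br))
  ymid <- numeric(nrow(br))
  for (i in seq_len(nrow(br))) {
    anc <- which(vapply(seq_len(nrow(br)), function(j) {
      j != i && all(br$leaves[[i]] %in% br$leaves[[j]])
    }, logical(1)))
    depth[i] <- sum(br$n_mutations[anc]) + br$n_mutations[i]
    ymid[i] <- mean(y_leaf[br$leaves[[i]]])
  }
  segs <- tibble::tibble(
    x = depth - br$n_mutations, xend = depth, y = ymid, yend = ymid,
    label = vapply(br$leaves, function(l) if (length(l) == 1) l else "",
                   character(1))
  )
  ggplot2::ggplot(segs) +
    ggplot2::geom_segment(ggplot2::aes(x = .data$x, xend = .data$xend,
                                       y = .data$y, yend = .data$yend)) +
    ggplot2::geom_text(ggplot2::aes(x = .data$xend, y = .data$y,
                                    label = .data$label),
                       hjust = -0.2, size = 3) +
    ggplot2::labs(x = "derived mutations from founder", y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank())
}

#' @export
autoplot.clone_pedigree <- function(object, ...) plot_pedigree(object)

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
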