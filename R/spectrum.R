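SPECTRUM_CLASSES6 <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")

# collapse a ref>alt pair onto the pyrimidine-rooted class
collapse_class <- function(ref, alt) {
  pur <- ref %in% c("A", "G")
  r <- ifelse(pur, dna_complement(ref), ref)
  a <- ifelse(pur, dna_complement(alt), alt)
  paste0(r, ">", a)
}

#' Classify the somatic SNV spectrum
#'
#' Tallies the 12 uncollapsed and 6 strand-collapsed substitution classes
#' (purine-rooted changes are mapped to their pyrimidine complement, so
#' G>A counts as C>T), the cytosine methylation context of each mutated
#' site, its flanking dinucleotides and the trinucleotides with the
#' mutation at triplet positions 1, 2 and 3, together with the genome
#' background composition needed to normalise them.
#'
#' @param calls Tibble of SNV calls with `chrom,pos,ref,alt` (rows with
#'   `var_type == "indel"` are dropped if the column is present).
#' @param ref A `ref_model`, or any list with a `sequences` element of
#'   chromosome strings.
#' @param trinucleotide_background Also count all 64 genome triplets
#'   (slower; needed for per-triplet enrichment). Default FALSE.
#' @return A `spectrum_tbl` list: `class6`, `class12`, `context`
#'   (CpG/CHG/CHH/nonC tallies of the mutated sites), `dinucleotide`,
#'   `trinucleotide` (counts keyed by triplet and mutated position),
#'   `background` (genome base counts, context site counts, optionally
#'   triplet counts), `n` (total SNVs), `n_edge_excluded`.
#' @export
classify_spectrum <- function(calls, ref, trinucleotide_background = FALSE) {
  if ("var_type" %in% names(calls)) {
    calls <- calls[calls$var_type != "indel", , drop = FALSE]
  }
  n <- nrow(calls)
  refbase_obs <- character(n)
  if (n > 0) {
    refbase_obs <- mapply(
      function(ch, p) substring(ref$sequences[[ch]], p, p),
      calls$chrom, calls$pos, USE.NAMES = FALSE)
    if (any(refbase_obs != calls$ref)) {
      abort("call ref allele mismatches the reference sequence: coordinate drift")
    }
  }

  cls12 <- if (n > 0) paste0(calls$ref, ">", calls$alt) else character(0)
  cls6 <- if (n > 0) collapse_class(calls$ref, calls$alt) else character(0)
  class6 <- tibble::tibble(class = SPECTRUM_CLASSES6)
  class6$count <- as.integer(table(factor(cls6, SPECTRUM_CLASSES6)))
  class6$percent <- percent_of(class6$count, n)
  all12 <- as.vector(outer(c("A", "C", "G", "T"), c("A", "C", "G", "T"),
                           function(r, a) paste0(r, ">", a)))
  all12 <- all12[substr(all12, 1, 1) != substr(all12, 3, 3)]
  class12 <- tibble::tibble(class = sort(all12))
  class12$count <- as.integer(table(factor(cls12, sort(all12))))
  class12$percent <- percent_of(class12$count, n)

  ctx <- if (n > 0) site_context(ref, calls$chrom, calls$pos) else character(0)
  context <- tibble::tibble(context = c("CpG", "CHG", "CHH", "nonC"))
  context$count <- as.integer(table(factor(ctx, context$context)))

  tri <- dinuc <- NULL
  n_edge <- 0L
  if (n > 0) {
    flank <- function(off1, off2) {
      lens <- nchar(ref$sequences)[calls$chrom]
      lo <- calls$pos + off1
      hi <- calls$pos + off2
      ok <- lo >= 1 & hi <= lens
      out <- rep(NA_character_, n)
      out[ok] <- mapply(function(ch, a, b) substring(ref$sequences[[ch]], a, b),
                        calls$chrom[ok], lo[ok], hi[ok], USE.NAMES = FALSE)
      out
    }
    t1 <- flank(0, 2); t2 <- flank(-1, 1); t3 <- flank(-2, 0)
    tri <- dplyr::count(
      tibble::tibble(
        triplet = c(t1, t2, t3),
        position = rep(1:3, each = n)
      )[!is.na(c(t1, t2, t3)), ],
      .data$triplet, .data$position, name = "count")
    n_edge <- sum(is.na(t1)) + sum(is.na(t2)) + sum(is.na(t3))
    dleft <- flank(-1, 0); dright <- flank(0, 1)
    dinuc <- dplyr::count(
      tibble::tibble(
        dinucleotide = c(dleft, dright),
        side = rep(c("left", "right"), each = n)
      )[!is.na(c(dleft, dright)), ],
      .data$dinucleotide, .data$side, name = "count")
  }

  structure(
    list(class6 = class6, class12 = class12, context = context,
         dinucleotide = dinuc, trinucleotide = tri,
         background = genome_background(ref, trinucleotide_background),
         n = n, n_edge_excluded = n_edge),
    class = "spectrum_tbl"
  )
}

# genome-wide base counts and strand-symmetric cytosine-context site counts
genome_background <- function(ref, trinucleotide = FALSE) {
  seqs <- ref$sequences
  count_all <- function(pattern) {
    sum(vapply(seqs, function(s) stringr::str_count(s, pattern), numeric(1)))
  }
  bases <- c(A = count_all("A"), C = count_all("C"),
             G = count_all("G"), T = count_all("T"))
  cpg_p <- count_all("C(?=G)"); cpg_m <- count_all("(?<=C)G")
  chg_p <- count_all("C(?=[ACT]G)"); chg_m <- count_all("(?<=C[AGT])G")
  context_sites <- c(
    CpG = cpg_p + cpg_m,
    CHG = chg_p + chg_m,
    # CHH as the cytosine remainder, consistent with site_context() edge
    # handling (a terminal C falls back to CHH)
    CHH = unname(bases["C"] - cpg_p - chg_p + bases["G"] - cpg_m - chg_m),
    nonC = unname(bases["A"] + bases["T"])
  )
  out <- list(bases = bases,
              base_freq = bases / sum(bases),
              context_sites = context_sites,
              context_freq = context_sites / sum(context_sites))
  if (trinucleotide) {
    triplets <- apply(expand.grid(c("A", "C", "G", "T"), c("A", "C", "G", "T"),
                                  c("A", "C", "G", "T")), 1, paste,
                      collapse = "")
    tcounts <- vapply(triplets, function(t) {
      count_all(paste0(substr(t, 1, 1), "(?=", substr(t, 2, 3), ")"))
    }, numeric(1))
    out$triplets <- tcounts
    out$triplet_freq <- tcounts / sum(tcounts)
  }
  out
}

#' Transition/transversion ratio of a spectrum
#'
#' @param spectrum A `spectrum_tbl`.
#' @return `(C>T + T>C) / (C>A + C>G + T>A + T>G)`; errors when there are no
#'   transversions.
#' @export
titv <- function(spectrum) {
  cnt <- setNames(spectrum$class6$count, spectrum$class6$class)
  ti <- sum(cnt[c("C>T", "T>C")])
  tv <- sum(cnt[c("C>A", "C>G", "T>A", "T>G")])
  stop_if_not(tv > 0, "no transversions: Ti/Tv undefined")
  unname(ti / tv)
}

#' Content-corrected AT bias of a spectrum
#'
#' The per-site excess of G/C-to-A/T changes over A/T-to-G/C changes:
#' `(count[GC>AT] / genome GC bases) / (count[AT>GC] / genome AT bases)`.
#'
#' @param spectrum A `spectrum_tbl`.
#' @return Fold bias; errors when no A/T-to-G/C mutations exist.
#' @export
at_bias <- function(spectrum) {
  cnt <- setNames(spectrum$class6$count, spectrum$class6$class)
  gc_to_at <- sum(cnt[c("C>A", "C>T")])
  at_to_gc <- sum(cnt[c("T>C", "T>G")])
  stop_if_not(at_to_gc > 0, "no A/T-to-G/C mutations: AT bias undefined")
  bases <- spectrum$background$bases
  gc_bases <- sum(bases[c("C", "G")])
  at_bases <- sum(bases[c("A", "T")])
  unname((gc_to_at / gc_bases) / (at_to_gc / at_bases))
}

#' Per-context mutation rates and enrichment
#'
#' For each cytosine context (CpG, CHG, CHH; H = A, C or T; plus the
#' non-cytosine remainder) the per-site mutation rate is the number of
#' mutated sites in the context over the number of genomic sites in it.
#' The reported `enrichment` is the relative rate against all sites outside
#' the context — under a generative model with a context rate multiplier m
#' this statistic estimates m directly; `enrichment_vs_mean` relates the
#' context rate to the genome-wide mean rate instead. Significance is a
#' one-sided (enrichment) exact binomial test of the context's mutation
#' share against its genomic site share, Benjamini-Hochberg corrected.
#'
#' @param calls SNV call tibble with `chrom,pos,ref,alt`.
#' @param ref A `ref_model`.
#' @param by `"cytosine"` (CpG/CHG/CHH/nonC, default) or `"trinucleotide"`
#'   (64 triplets x mutated position 1/2/3).
#' @param fdr FDR threshold for the `significant` flag (default 0.05).
#' @return Tibble `context, n_sites, n_mutations, rate, enrichment,
#'   enrichment_vs_mean, p_value, q_value, significant`.
#' @export
context_enrichment <- function(calls, ref, by = c("cytosine", "trinucleotide"),
                               fdr = 0.05) {
  by <- match.arg(by)
  spec <- classify_spectrum(calls, ref,
                            trinucleotide_background = by == "trinucleotide")
  if (by == "cytosine") {
    m <- setNames(spec$context$count, spec$context$context)
    S <- spec$background$context_sites[names(m)]
  } else {
    tri <- spec$trinucleotide
    key <- paste0(tri$triplet, "@", tri$position)
    m_tbl <- setNames(tri$count, key)
    all_keys <- as.vector(outer(names(spec$background$triplets), 1:3,
                                function(t, p) paste0(t, "@", p)))
    m <- setNames(rep(0L, length(all_keys)), all_keys)
    m[names(m_tbl)] <- m_tbl
    S <- spec$background$triplets[sub("@.*", "", names(m))]
  }
  M <- sum(m)
  S_tot <- sum(S)
  stop_if_not(M > 0, "no mutations to test")
  rate <- m / S
  enr <- (m / S) / ((M - m) / (S_tot - S))
  enr_mean <- (m / S) / (M / S_tot)
  p <- vapply(seq_along(m), function(i) {
    binom.test(m[i], M, p = S[i] / S_tot, alternative = "greater")$p.value
  }, numeric(1))
  q <- p.adjust(p, method = "BH")
  tibble::tibble(context = names(m), n_sites = unname(S),
                 n_mutations = unname(m), rate = unname(rate),
                 enrichment = unname(enr), enrichment_vs_mean = unname(enr_mean),
                 p_value = unname(p), q_value = unname(q),
                 significant = unname(q < fdr))
}

#' Base composition by distance from mutations
#'
#' For each distance d in 1..`max_dist`, the A/T and C/G proportions of the
#' bases d positions up- and downstream of each mutation, with genome-wide
#' base fractions as baselines.
#'
#' @param calls SNV call tibble with `chrom,pos`.
#' @param ref A `ref_model`.
#' @param max_dist Maximum flank distance in bp (>= 1).
#' @return A `flank_profile` tibble `distance, n_bases, prop_at, prop_gc`
#'   with attributes `baseline_at`, `baseline_gc`.
#' @export
flanking_composition <- function(calls, ref, max_dist = 100) {
  stop_if_not(max_dist >= 1, "max_dist must be >= 1")
  lens <- nchar(ref$sequences)
  rows <- lapply(seq_len(max_dist), function(d) {
    up <- calls$pos - d
    dn <- calls$pos + d
    ok_up <- up >= 1
    ok_dn <- dn <= lens[calls$chrom]
    bases <- c(
      mapply(function(ch, p) substring(ref$sequences[[ch]], p, p),
             calls$chrom[ok_up], up[ok_up], USE.NAMES = FALSE),
      mapply(function(ch, p) substring(ref$sequences[[ch]], p, p),
             calls$chrom[ok_dn], dn[ok_dn], USE.NAMES = FALSE)
    )
    bases <- unlist(bases)
    tibble::tibble(distance = d, n_bases = length(bases),
                   prop_at = mean(bases %in% c("A", "T")),
                   prop_gc = mean(bases %in% c("G", "C")))
  })
  out <- dplyr::bind_rows(rows)
  bf <- genome_background(ref)$base_freq
  attr(out, "baseline_at") <- unname(bf["A"] + bf["T"])
  attr(out, "baseline_gc") <- unname(bf["C"] + bf["G"])
  class(out) <- c("flank_profile", class(out))
  out
}

#' @export
print.spectrum_tbl <- function(x, ...) {
  cat(sprintf("<spectrum_tbl> %d SNVs\n", x$n))
  print(x$class6)
  invisible(x)
}

#' @importFrom generics tidy
#' @export
tidy.spectrum_tbl <- function(x, ...) x$class6
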