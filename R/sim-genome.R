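#' Simulate a diploid reference genome model
#'
#' Draws per-chromosome sequences at the configured GC content, tiles the
#' genome with non-overlapping exon/intron/intergenic intervals whose total
#' lengths match `annotation_fractions` up to rounding, and places background
#' heterozygous sites uniformly at `het_density` per kb. Background
#' heterozygous sites belong to the clone founder: every descendant cutting
#' inherits them, on a fixed haplotype.
#'
#' @param config A [sim_config()].
#' @return A `ref_model` list with elements `sequences` (named character
#'   vector, one string per chromosome), `chrom_lengths`, `annotation`
#'   (tibble `chrom,start,end,class`, 1-based closed), `het_sites`
#'   (tibble `chrom,pos,ref,alt,hap_alt`), and `gc_observed`.
#' @export
#' @examples
#' ref <- simulate_genome(sim_config(genome_length = 5e4, seed = 7))
simulate_genome <- function(config) {
  validate_sim_config(config)
  set.seed(derive_seed(config$seed, 1L))

  n_chr <- config$n_chromosomes
  base_len <- floor(config$genome_length / n_chr)
  lens <- rep(base_len, n_chr)
  lens[1] <- lens[1] + config$genome_length - sum(lens)
  stop_if_not(all(lens >= 250),
              "chromosomes shorter than 250 bp; use fewer chromosomes")
  chroms <- sprintf("chr%d", seq_len(n_chr))
  names(lens) <- chroms

  gc <- config$gc_content
  base_prob <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  sequences <- vapply(lens, function(L) {
    paste(sample(names(base_prob), L, replace = TRUE, prob = base_prob),
          collapse = "")
  }, character(1))

  annotation <- dplyr::bind_rows(lapply(chroms, function(ch) {
    tile_annotation(ch, lens[[ch]], config$annotation_fractions)
  }))

  het_sites <- dplyr::bind_rows(lapply(chroms, function(ch) {
    L <- lens[[ch]]
    n_het <- rpois(1, L * config$het_density / 1000)
    n_het <- min(n_het, L)
    if (n_het == 0) {
      return(tibble::tibble(chrom = character(), pos = integer(),
                            ref = character(), alt = character(),
                            hap_alt = integer()))
    }
    pos <- sort(sample.int(L, n_het))
    ref <- substring(sequences[[ch]], pos, pos)
    alt <- random_other_base(ref)
    tibble::tibble(chrom = ch, pos = pos, ref = ref, alt = alt,
                   hap_alt = sample(0:1, n_het, replace = TRUE))
  }))

  gc_observed <- {
    counts <- vapply(sequences, function(s) {
      stringr::str_count(s, "[GC]")
    }, numeric(1))
    sum(counts) / sum(lens)
  }

  structure(
    list(sequences = sequences, chrom_lengths = lens,
         annotation = annotation, het_sites = het_sites,
         gc_observed = gc_observed, config = config),
    class = "ref_model"
  )
}

# deterministic annotation tiling: repeated exon/intron/intergenic cycles,
# class totals exact up to per-cycle rounding
tile_annotation <- function(chrom, len, fractions, cycles = NULL) {
  fractions <- fractions[c("exon", "intron", "intergenic")]
  cycles <- cycles %||% max(1L, min(50L, floor(len / 2000)))
  per_cycle <- floor(fractions * len / cycles)
  blocks <- tibble::tibble(
    class = rep(names(per_cycle), cycles),
    width = rep(unname(per_cycle), cycles)
  )
  # absorb the rounding remainder into a final intergenic block
  rem <- len - sum(blocks$width)
  if (rem > 0) {
    blocks <- dplyr::bind_rows(blocks,
                               tibble::tibble(class = "intergenic", width = rem))
  }
  blocks <- dplyr::filter(blocks, .data$width > 0)
  end <- cumsum(blocks$width)
  tibble::tibble(chrom = chrom,
                 start = c(1L, head(end, -1) + 1L),
                 end = as.integer(end),
                 class = blocks$class)
}

random_other_base <- function(ref) {
  bases <- c("A", "C", "G", "T")
  vapply(ref, function(b) sample(setdiff(bases, b), 1), character(1),
         USE.NAMES = FALSE)
}

#' Look up annotation class at genomic positions
#'
#' @param annotation Tibble `chrom,start,end,class` with non-overlapping
#'   1-based closed intervals tiling each chromosome.
#' @param chrom,pos Vectors of positions to classify.
#' @return Character vector of classes (`NA` outside all intervals).
#' @export
annotation_class_at <- function(annotation, chrom, pos) {
  out <- rep(NA_character_, length(pos))
  for (ch in unique(chrom)) {
    ann <- dplyr::arrange(dplyr::filter(annotation, .data$chrom == ch),
                          .data$start)
    sel <- which(chrom == ch)
    if (nrow(ann) == 0 || length(sel) == 0) next
    idx <- findInterval(pos[sel], ann$start)
    ok <- idx >= 1 & idx <= nrow(ann)
    ok[ok] <- pos[sel][ok] <= ann$end[idx[ok]]
    out[sel[ok]] <- ann$class[idx[ok]]
  }
  out
}

#' @export
print.ref_model <- function(x, ...) {
  cat("<ref_model>\n")
  cat(sprintf("  %d chromosomes, %s bp, observed GC %.4f\n",
              length(x$sequences),
              format(sum(x$chrom_lengths), big.mark = ","), x$gc_observed))
  cat(sprintf("  %d background heterozygous sites, %d annotation intervals\n",
              nrow(x$het_sites), nrow(x$annotation)))
  invisible(x)
}
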