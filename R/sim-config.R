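#' Configuration for the synthetic clonal-lineage generator
#'
#' Bundles every knob of the simulator: a diploid genome model with elevated
#' background heterozygosity, a cutting-propagation pedigree with branch
#' lengths in years, Poisson mutation accumulation per branch with
#' methylation-context rate multipliers, and a read-count observation model
#' with sequencing error, strand noise and optional triplicate re-sequencing.
#'
#' Defaults mirror the study system the package targets: a ~67-year cutting
#' lineage of 11 clonal individuals, a per-base per-year SNV rate on the
#' 1e-8 scale, an indel rate roughly 5-fold lower, ~21x sequencing depth,
#' and 5 samples re-sequenced in triplicate. The genome length defaults to
#' 1 Mb — a scaled-down stand-in for a hundreds-of-Mb tree genome chosen so
#' simulations stay interactive; rates are per-base so conclusions scale.
#'
#' @param genome_length Total genome length in bases (>= 1 kb).
#' @param n_chromosomes Number of chromosomes the genome is split into.
#' @param gc_content Genome GC fraction in (0, 1). Default 0.35, a plausible
#'   placeholder for a broadleaf tree genome.
#' @param het_density Expected background heterozygous sites per kb. Clonal
#'   poplar lineages carry elevated heterozygosity; default 2 per kb.
#' @param annotation_fractions Named numeric of genome fractions for
#'   `exon`, `intron`, `intergenic`; must sum to 1.
#' @param pedigree_newick Rooted newick string; branch lengths in years.
#'   Default: an 11-leaf cutting pedigree spanning 67 years with one
#'   4-leaf, one 3-leaf and one 2-leaf cluster, echoing a plantation
#'   propagated from a single founder.
#' @param snv_rate SNV mutations per base per year (diploid base pairs are
#'   counted via a factor 2 at draw time).
#' @param indel_rate Indel mutations per base per year.
#' @param context_multipliers Named numeric relative rate per cytosine
#'   context `CpG`, `CHG`, `CHH`, `nonC`. Default mildly CpG/CHG-elevated,
#'   emulating methylation-associated hypermutability.
#' @param mean_depth Mean sequencing depth (reads) per site per sample.
#' @param seq_error Per-read-base sequencing error probability.
#' @param strand_imbalance_sd SD of the per-site forward-read fraction
#'   around 0.5.
#' @param n_replicate_samples Number of leaves sequenced in triplicate.
#' @param seed Integer seed; fixing it makes all outputs byte-identical.
#' @return A `sim_config` list.
#' @export
#' @examples
#' cfg <- sim_config(genome_length = 1e5, seed = 1)
sim_config <- function(genome_length = 1e6,
                       n_chromosomes = 4,
                       gc_content = 0.35,
                       het_density = 2,
                       annotation_fractions = c(exon = 0.07, intron = 0.13,
                                                intergenic = 0.80),
                       pedigree_newick = default_pedigree_newick(),
                       snv_rate = 1e-8,
                       indel_rate = 1.77e-9,
                       context_multipliers = c(CpG = 2, CHG = 1.5,
                                               CHH = 1, nonC = 1),
                       mean_depth = 21,
                       seq_error = 0.001,
                       strand_imbalance_sd = 0.05,
                       n_replicate_samples = 5,
                       seed = 1L) {
  cfg <- list(
    genome_length = as.numeric(genome_length),
    n_chromosomes = as.integer(n_chromosomes),
    gc_content = gc_content,
    het_density = het_density,
    annotation_fractions = annotation_fractions,
    pedigree_newick = pedigree_newick,
    snv_rate = snv_rate,
    indel_rate = indel_rate,
    context_multipliers = context_multipliers,
    mean_depth = mean_depth,
    seq_error = seq_error,
    strand_imbalance_sd = strand_imbalance_sd,
    n_replicate_samples = as.integer(n_replicate_samples),
    seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  stop_if_not(cfg$genome_length >= 1000,
              "genome_length must be >= 1 kb (sequence contexts are undefined at shorter scales)")
  stop_if_not(cfg$n_chromosomes >= 1, "n_chromosomes must be >= 1")
  stop_if_not(cfg$gc_content > 0 && cfg$gc_content < 1,
              "gc_content must be in (0, 1)")
  stop_if_not(cfg$het_density >= 0, "het_density must be >= 0")
  af <- cfg$annotation_fractions
  stop_if_not(all(c("exon", "intron", "intergenic") %in% names(af)),
              "annotation_fractions needs names exon, intron, intergenic")
  stop_if_not(abs(sum(af) - 1) <= 1e-9, "annotation_fractions must sum to 1")
  stop_if_not(all(af >= 0), "annotation_fractions must be non-negative")
  stop_if_not(cfg$snv_rate >= 0 && is.finite(cfg$snv_rate),
              "snv_rate must be finite and >= 0")
  stop_if_not(cfg$indel_rate >= 0 && is.finite(cfg$indel_rate),
              "indel_rate must be finite and >= 0")
  cm <- cfg$context_multipliers
  stop_if_not(all(c("CpG", "CHG", "CHH", "nonC") %in% names(cm)),
              "context_multipliers needs names CpG, CHG, CHH, nonC")
  stop_if_not(all(cm >= 0), "context_multipliers must be >= 0")
  stop_if_not(cfg$mean_depth >= 0, "mean_depth must be >= 0")
  stop_if_not(cfg$seq_error >= 0 && cfg$seq_error < 1,
              "seq_error must be in [0, 1)")
  stop_if_not(cfg$strand_imbalance_sd >= 0, "strand_imbalance_sd must be >= 0")
  tree <- tryCatch(suppressWarnings(ape::read.tree(text = cfg$pedigree_newick)),
                   error = function(e) NULL)
  stop_if_not(!is.null(tree) && length(tree$tip.label) >= 1,
              "pedigree_newick must parse to a tree with >= 1 leaf")
  stop_if_not(!is.null(tree$edge.length) && all(tree$edge.length >= 0),
              "pedigree_newick must carry non-negative branch lengths (years)")
  stop_if_not(cfg$n_replicate_samples <= length(tree$tip.label),
              "n_replicate_samples exceeds the number of pedigree leaves")
  stop_if_not(cfg$seed >= 0 && cfg$seed < 2^31 - 1, "seed must fit a 32-bit integer")
  invisible(cfg)
}

#' Default 11-leaf cutting pedigree (67 years root to tip)
#'
#' Mirrors the sharing structure seen in a clonal poplar plantation: a
#' 4-leaf cluster, a 3-leaf cluster, a 2-leaf cluster and two singleton
#' cuttings, all descending from one founder.
#'
#' @return A newick string with branch lengths in years.
#' @export
default_pedigree_newick <- function() {
  paste0(
    "((pay01:47,pay08:47,pay09:47,pay10:47):20,",
    "(pay11:52,pay02:52,pay04:52):15,",
    "(pay03:55,pay06:55):12,",
    "pay05:67,pay07:67):0;"
  )
}

#' Read / write a simulation config as YAML
#'
#' @param path YAML file with any subset of [sim_config()] fields;
#'   unspecified fields take their defaults.
#' @return `read_sim_config`: a validated `sim_config`.
#' @export
read_sim_config <- function(path) {
  stop_if_not(file.exists(path), sprintf("no such file: %s", path))
  vals <- yaml::read_yaml(path)
  for (f in c("annotation_fractions", "context_multipliers")) {
    if (!is.null(vals[[f]])) vals[[f]] <- unlist(vals[[f]])
  }
  do.call(sim_config, vals)
}

#' @rdname read_sim_config
#' @param config A `sim_config`.
#' @export
write_sim_config <- function(config, path) {
  out <- unclass(config)
  out$annotation_fractions <- as.list(out$annotation_fractions)
  out$context_multipliers <- as.list(out$context_multipliers)
  yaml::write_yaml(out, path)
  invisible(path)
}

#' @export
print.sim_config <- function(x, ...) {
  tree <- ape::read.tree(text = x$pedigree_newick)
  cat("<sim_config>\n")
  cat(sprintf("  genome: %s bp over %d chromosomes (GC %.2f)\n",
              format(x$genome_length, big.mark = ","), x$n_chromosomes,
              x$gc_content))
  cat(sprintf("  background het: %.3g /kb; pedigree: %d leaves\n",
              x$het_density, length(tree$tip.label)))
  cat(sprintf("  rates: SNV %.3g, indel %.3g per bp per year\n",
              x$snv_rate, x$indel_rate))
  cat(sprintf("  reads: depth %.1f, error %.3g, strand sd %.3g; %d triplicated\n",
              x$mean_depth, x$seq_error, x$strand_imbalance_sd,
              x$n_replicate_samples))
  cat(sprintf("  seed: %d\n", x$seed))
  invisible(x)
}
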