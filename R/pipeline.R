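#' Run the full somatic-mutation pipeline on a simulated lineage
#'
#' Convenience orchestration: simulate (genome, mutations, site table), run
#' the hard-filter cascade and post-filters, call somatic mutations, estimate
#' error rates (false positives from triplicates when simulated; sensitivity
#' from spike-ins), and compute the corrected mutation rate; then the
#' downstream characterisations (spectrum, context enrichment, pedigree,
#' sharing). When `out_dir` is given, all interchange artifacts (FASTA, VCF,
#' strand-count TSV, annotation BED, truth TSV, newick, call TSV, results
#' JSON) are written there together with a provenance log.
#'
#' @param config A [sim_config()]; its `seed` drives every stage.
#' @param out_dir Optional output directory (created if missing).
#' @param spike_in_vaf Variant-allele fraction for the sensitivity spike-ins
#'   (default 0.5, matching the heterozygous somatic events being
#'   corrected; see [spike_in_sensitivity()]).
#' @param fp_mode `"replicates"` (estimate from simulated triplicates when
#'   present) or `"truth"` (measured false-call fraction against simulated
#'   truth; appropriate for recovery experiments, where the triplicate
#'   concordance estimator conflates imperfect per-replicate recall with
#'   false positives).
#' @param n_spikein Number of sensitivity spike-ins.
#' @param stages Character vector of optional downstream stages to run;
#'   subset of `c("spectrum", "pedigree", "context")`.
#' @return A `pipeline_result` list with the intermediate and final objects
#'   (`ref`, `truth`, `sites`, `filtered`, `calls`, `fp`, `sensitivity`,
#'   `rate`, `per_sample_counts`, plus requested stage outputs).
#' @export
run_pipeline <- function(config, out_dir = NULL, spike_in_vaf = 0.5,
                         fp_mode = c("replicates", "truth"),
                         n_spikein = 1000,
                         stages = c("spectrum", "pedigree")) {
  fp_mode <- match.arg(fp_mode)
  t0 <- Sys.time()

  ref <- simulate_genome(config)
  truth <- simulate_mutations(ref, config)
  sim <- simulate_site_table(truth, ref, config)

  fcfg <- filter_config()
  filtered <- apply_site_postfilters(apply_hard_filters(sim$sites, fcfg), fcfg)
  calls <- call_somatic(filtered, annotation = ref$annotation)

  # per-sample somatic SNV counts
  snv_calls <- calls[calls$var_type != "indel", , drop = FALSE]
  samples <- sim$samples
  per_sample_counts <- setNames(vapply(samples, function(s) {
    sum(vapply(snv_calls$carriers, function(cs) s %in% cs, logical(1)))
  }, integer(1)), samples)

  # false positives
  fp <- NULL
  fp_rate <- 0
  if (fp_mode == "replicates" && !is.null(sim$replicates)) {
    rep_calls <- lapply(split(sim$replicates, sim$replicates$replicate),
                        function(tbl) {
      f <- apply_site_postfilters(apply_hard_filters(tbl, fcfg), fcfg)
      cl <- call_somatic(f)
      cl
    })
    rep_tbl <- dplyr::bind_rows(lapply(names(rep_calls), function(r) {
      cl <- rep_calls[[r]]
      if (nrow(cl) == 0) return(NULL)
      long <- tidyr::unnest(dplyr::select(cl, "chrom", "pos", "ref", "alt",
                                          "carriers"),
                            "carriers")
      tibble::tibble(sample = long$carriers, replicate = as.integer(r),
                     chrom = long$chrom, pos = long$pos, ref = long$ref,
                     alt = long$alt)
    }))
    if (!is.null(rep_tbl) && nrow(rep_tbl) > 0) {
      fp <- tryCatch(estimate_fp(rep_tbl, n_replicates = 3),
                     error = function(e) NULL)
      if (!is.null(fp) && !is.na(fp$fp_rate)) fp_rate <- fp$fp_rate
    }
  } else if (fp_mode == "truth") {
    truth_keys <- site_key(truth$branch_mutations$chrom,
                           truth$branch_mutations$pos)
    called_keys <- site_key(snv_calls$chrom, snv_calls$pos)
    n_false <- sum(!called_keys %in% truth_keys)
    fp_rate <- if (length(called_keys) == 0) 0
               else n_false / length(called_keys)
    fp <- list(n_candidates = length(called_keys), n_erroneous = n_false,
               fp_rate = fp_rate)
  }

  sens <- spike_in_sensitivity(ref, config, n = n_spikein, vaf = spike_in_vaf)

  years <- max(ape::node.depth.edgelength(truth$tree))
  rate <- point_rate(mean(per_sample_counts), years,
                     sum(ref$chrom_lengths), fp_rate = fp_rate,
                     sensitivity = max(sens$sensitivity, 1e-6))
  rate_ci <- if (length(per_sample_counts) >= 2) {
    bootstrap_ci(per_sample_counts, years, sum(ref$chrom_lengths),
                 fp_rate = fp_rate,
                 sensitivity = max(sens$sensitivity, 1e-6),
                 seed = derive_seed(config$seed, 9L))
  } else NULL

  out <- list(ref = ref, truth = truth, sites = sim, filtered = filtered,
              calls = calls, per_sample_counts = per_sample_counts,
              fp = fp, fp_rate = fp_rate, sensitivity = sens,
              years = years, rate = rate, rate_ci = rate_ci,
              config = config)

  if ("spectrum" %in% stages && nrow(snv_calls) > 0) {
    out$spectrum <- classify_spectrum(snv_calls, ref)
    out$context_enrichment <- tryCatch(context_enrichment(snv_calls, ref),
                                       error = function(e) NULL)
  }
  if ("pedigree" %in% stages && nrow(snv_calls) > 0 &&
      length(samples) >= 2) {
    out$sharing <- sharing_matrix(snv_calls, samples = samples)
    out$pedigree <- tryCatch(build_pedigree(out$sharing),
                             error = function(e) NULL)
  }
  if ("context" %in% stages && nrow(snv_calls) > 0) {
    gts <- filtered[filtered$origin %in% "background", ]
    if (nrow(gts) > 0) {
      out$het_profile <- het_vs_distance(
        snv_calls, gts, ref, context_config(),
        seed = derive_seed(config$seed, 7L))
    }
  }

  if (!is.null(out_dir)) write_pipeline_outputs(out, out_dir, t0)
  class(out) <- "pipeline_result"
  out
}

write_pipeline_outputs <- function(res, out_dir, t0) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(out_dir, f)
  write_fasta(res$ref, p("genome.fa"))
  write_vcf(res$sites$sites, p("sites.vcf"))
  write_strand_counts(res$sites$sites, p("strand_counts.tsv"))
  write_bed(dplyr::rename(res$ref$annotation, name = "class"),
            p("annotation.bed"))
  readr::write_tsv(res$truth$branch_mutations, p("truth_mutations.tsv"),
                   progress = FALSE)
  write_newick(res$truth$tree, p("pedigree_truth.nwk"))
  write_calls(res$calls, p("somatic_calls.tsv"))
  if (!is.null(res$pedigree)) {
    write_newick(res$pedigree, p("pedigree_inferred.nwk"))
    write_nexus_splits(res$sharing, p("sharing_distances.nex"))
  }
  results <- list(
    seed = res$config$seed,
    n_somatic_snv = sum(res$calls$var_type != "indel"),
    n_somatic_indel = sum(res$calls$var_type == "indel"),
    per_sample_counts = as.list(res$per_sample_counts),
    fp_rate = res$fp_rate,
    sensitivity = res$sensitivity$sensitivity,
    years = res$years,
    genome_size = sum(res$ref$chrom_lengths),
    rate_per_bp_per_year = res$rate,
    rate_ci = if (!is.null(res$rate_ci)) {
      c(res$rate_ci$ci_low, res$rate_ci$ci_high)
    } else NULL
  )
  jsonlite::write_json(results, p("results.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  prov <- c(
    sprintf("run started: %s", format(t0, "%Y-%m-%d %H:%M:%S")),
    sprintf("seed: %d", res$config$seed),
    sprintf("config: genome %.0f bp, %d chrom, depth %.1f, error %.4g",
            res$config$genome_length, res$config$n_chromosomes,
            res$config$mean_depth, res$config$seq_error),
    "input checksums:",
    sprintf("  %s %s", tools::md5sum(list.files(out_dir, "\\.(fa|vcf|tsv|bed|nwk)$",
                                                full.names = TRUE)),
            list.files(out_dir, "\\.(fa|vcf|tsv|bed|nwk)$"))
  )
  writeLines(prov, p("provenance.log"))
  invisible(out_dir)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result>\n")
  cat(sprintf("  %d somatic calls (%d SNV, %d indel) across %d samples\n",
              nrow(x$calls), sum(x$calls$var_type != "indel"),
              sum(x$calls$var_type == "indel"),
              length(x$per_sample_counts)))
  cat(sprintf("  fp %.4g, sensitivity %.3f -> rate %.3g per bp per year\n",
              x$fp_rate, x$sensitivity$sensitivity, x$rate))
  invisible(x)
}
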