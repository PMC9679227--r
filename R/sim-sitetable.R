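# phase blocks used by the simulated phasing (bp); within a block phasing is
# taken as correct, with a random per-sample orientation, emulating
# read-based phasing output
PHASE_BLOCK_BP <- 1e5

# density of error-candidate sites fed to the caller (per bp): hom-ref
# positions where sequencing error can masquerade as a variant
ERROR_SITE_DENSITY <- 2e-4

#' Simulate the per-site, per-sample variant table for a clonal lineage
#'
#' Turns simulated truth into the table a multi-sample variant caller would
#' emit: per sample and site, a Poisson depth, binomial allele-read counts at
#' the truth VAF (0.5 for heterozygous truth, error-driven otherwise), a
#' binomial forward/reverse split of each allele's reads with per-site
#' dispersion of the forward fraction, a likelihood-based genotype call with
#' GQ, simulated phased genotypes in fixed-size phase blocks, and site-level
#' GATK-style INFO annotations. Samples designated for triplicate
#' re-sequencing get three additional independent draws conditional on the
#' same truth.
#'
#' @param truth A `pedigree_truth` from [simulate_mutations()].
#' @param ref The `ref_model` the truth was simulated on.
#' @param config The shared [sim_config()].
#' @return A `sim_sites` list: `sites` (long tibble, one row per site x
#'   sample), `replicates` (same schema plus a `replicate` column, only the
#'   triplicated samples), `samples`, and `truth_gt` columns retained for
#'   evaluation (`origin`, `truth_gt`).
#' @export
simulate_site_table <- function(truth, ref, config) {
  validate_sim_config(config)
  set.seed(derive_seed(config$seed, 3L))
  samples <- truth$tree$tip.label

  catalog <- build_site_catalog(truth, ref, config)
  carriers <- build_carrier_table(truth, ref, catalog)

  sites <- draw_observations(catalog, carriers, samples, config)
  sites <- dplyr::bind_cols(
    sites,
    sim_info_annotations(catalog)[rep(seq_len(nrow(catalog)),
                                      times = length(samples)), ]
  )

  rep_samples <- head(sort(samples), config$n_replicate_samples)
  replicates <- NULL
  if (length(rep_samples) > 0) {
    replicates <- dplyr::bind_rows(lapply(1:3, function(r) {
      tbl <- draw_observations(catalog, carriers, rep_samples, config)
      tbl <- dplyr::bind_cols(
        tbl,
        sim_info_annotations(catalog)[rep(seq_len(nrow(catalog)),
                                          times = length(rep_samples)), ]
      )
      tbl$replicate <- r
      tbl
    }))
  }

  structure(
    list(sites = sites, replicates = replicates, samples = samples,
         config = config),
    class = "sim_sites"
  )
}

build_site_catalog <- function(truth, ref, config) {
  het <- ref$het_sites
  bg <- tibble::tibble(chrom = het$chrom, pos = het$pos, ref = het$ref,
                       alt = het$alt, var_type = "snv",
                       origin = "background", hap_alt = het$hap_alt)
  mut <- dplyr::distinct(truth$branch_mutations, .data$chrom, .data$pos,
                         .keep_all = TRUE)
  mut_tbl <- tibble::tibble(chrom = mut$chrom, pos = mut$pos, ref = mut$ref,
                            alt = mut$alt, var_type = mut$type,
                            origin = "mutation", hap_alt = mut$hap)
  L_total <- sum(ref$chrom_lengths)
  n_err <- rpois(1, L_total * ERROR_SITE_DENSITY)
  err_tbl <- NULL
  if (n_err > 0) {
    offsets <- cumsum(c(0, ref$chrom_lengths))
    gpos <- sample.int(L_total, min(n_err, L_total))
    idx <- findInterval(gpos - 1, offsets)
    chrom <- names(ref$chrom_lengths)[idx]
    pos <- as.integer(gpos - offsets[idx])
    keep <- !site_key(chrom, pos) %in%
      site_key(c(bg$chrom, mut_tbl$chrom), c(bg$pos, mut_tbl$pos))
    chrom <- chrom[keep]; pos <- pos[keep]
    rb <- mapply(function(ch, p) substring(ref$sequences[[ch]], p, p),
                 chrom, pos, USE.NAMES = FALSE)
    err_tbl <- tibble::tibble(chrom = chrom, pos = pos, ref = rb,
                              alt = random_other_base(rb), var_type = "snv",
                              origin = "error", hap_alt = NA_integer_)
  }
  out <- dplyr::bind_rows(bg, mut_tbl, err_tbl)
  out <- dplyr::arrange(out, .data$chrom, .data$pos)
  out$site_id <- seq_len(nrow(out))
  out
}

# long (site_id, sample, truth_gt, hap_alt) for sites/samples whose truth
# genotype carries the alt allele
build_carrier_table <- function(truth, ref, catalog) {
  samples <- truth$tree$tip.label
  bg_ids <- catalog$site_id[catalog$origin == "background"]
  bg <- tidyr::expand_grid(site_id = bg_ids, sample = samples)
  la <- truth$leaf_assignments
  mut <- NULL
  if (nrow(la) > 0) {
    mut <- dplyr::inner_join(
      dplyr::select(catalog[catalog$origin == "mutation", ],
                    "site_id", "chrom", "pos"),
      dplyr::select(la, "chrom", "pos", sample = "leaf"),
      by = c("chrom", "pos")
    )
    mut <- dplyr::select(mut, "site_id", "sample")
  }
  dplyr::bind_rows(bg, mut)
}

# one independent sequencing + calling pass over catalog x samples
draw_observations <- function(catalog, carriers, samples, config) {
  n_site <- nrow(catalog)
  grid <- tidyr::expand_grid(sample = samples,
                             site_id = catalog$site_id)
  grid <- dplyr::left_join(grid, dplyr::select(catalog, -"hap_alt"),
                           by = "site_id")
  carrier_key <- paste(carriers$site_id, carriers$sample)
  grid$truth_gt <- ifelse(paste(grid$site_id, grid$sample) %in% carrier_key,
                          "0/1", "0/0")

  e <- config$seq_error
  p_alt <- dplyr::case_when(
    grid$truth_gt == "0/1" ~ 0.5 * (1 - e) + 0.5 * e / 3,
    TRUE ~ e / 3
  )
  n <- nrow(grid)
  dp <- rpois(n, config$mean_depth)
  ad_alt <- rbinom(n, dp, p_alt)
  ad_ref <- dp - ad_alt
  p_fwd <- pmin(pmax(rnorm(n, 0.5, config$strand_imbalance_sd), 0.02), 0.98)
  fwd_alt <- rbinom(n, ad_alt, p_fwd)
  fwd_ref <- rbinom(n, ad_ref, p_fwd)

  gcall <- call_genotypes_from_reads(dp, ad_alt, e)
  grid$dp <- dp
  grid$ad_ref <- ad_ref
  grid$ad_alt <- ad_alt
  grid$fwd_alt <- fwd_alt
  grid$rev_alt <- ad_alt - fwd_alt
  grid$fwd_ref <- fwd_ref
  grid$rev_ref <- ad_ref - fwd_ref
  grid$gt <- gcall$gt
  grid$gq <- gcall$gq

  phased <- simulate_phasing(grid, catalog, config)
  grid$pgt <- phased$pgt
  grid$ps <- phased$ps

  dplyr::select(grid, "chrom", "pos", "ref", "alt", "var_type", "origin",
                "sample", "truth_gt", "gt", "gq", "dp", "ad_ref", "ad_alt",
                "fwd_ref", "rev_ref", "fwd_alt", "rev_alt", "pgt", "ps")
}

# naive diploid genotype likelihoods from allele depths
call_genotypes_from_reads <- function(dp, ad_alt, seq_error) {
  e_m <- max(seq_error / 3, 1e-4)
  ll <- cbind(
    dbinom(ad_alt, dp, e_m, log = TRUE),
    dbinom(ad_alt, dp, 0.5, log = TRUE),
    dbinom(ad_alt, dp, 1 - e_m, log = TRUE)
  )
  best <- max.col(ll, ties.method = "first")
  sorted_gap <- apply(ll, 1, function(x) {
    s <- sort(x, decreasing = TRUE)
    s[1] - s[2]
  })
  gq <- pmin(99L, as.integer(round(10 * sorted_gap / log(10))))
  gt <- c("0/0", "0/1", "1/1")[best]
  gt[dp == 0] <- NA_character_
  gq[dp == 0] <- NA_integer_
  list(gt = gt, gq = gq)
}

# phased genotypes: truth haplotype of the alt allele, displayed in a random
# per-sample, per-block orientation; only called-het genotypes whose truth is
# heterozygous are phased
simulate_phasing <- function(grid, catalog, config) {
  hap_alt <- catalog$hap_alt[match(grid$site_id, catalog$site_id)]
  block <- (grid$pos - 1) %/% PHASE_BLOCK_BP
  ps <- as.integer(block * PHASE_BLOCK_BP + 1L)
  flip_key <- paste(grid$sample, grid$chrom, block)
  keys <- unique(flip_key)
  flips <- setNames(sample(0:1, length(keys), replace = TRUE), keys)
  o <- flips[flip_key]

  pgt <- rep(NA_character_, nrow(grid))
  hom <- !is.na(grid$gt) & grid$gt %in% c("0/0", "1/1")
  pgt[hom] <- chartr("/", "|", grid$gt[hom])
  phasable <- !is.na(grid$gt) & grid$gt == "0/1" &
    grid$truth_gt == "0/1" & !is.na(hap_alt)
  alt_left <- hap_alt == o  # alt sits on the haplotype displayed left
  pgt[phasable] <- ifelse(alt_left[phasable], "1|0", "0|1")
  ps[is.na(pgt) | !grepl("|", pgt, fixed = TRUE)] <- NA_integer_
  list(pgt = pgt, ps = ps)
}

# site-level GATK-style INFO annotations; distributions put a few percent of
# sites beyond each hard-filter threshold
sim_info_annotations <- function(catalog) {
  n <- nrow(catalog)
  tibble::tibble(
    FS = rexp(n, rate = 1 / 20),
    MQ = rnorm(n, 55, 8),
    MQRankSum = rnorm(n, 0, 5),
    QD = pmax(rnorm(n, 20, 8), 0),
    ReadPosRankSum = rnorm(n, 0, 4),
    SOR = 0.5 + rexp(n, rate = 2)
  )
}

#' @export
print.sim_sites <- function(x, ...) {
  cat("<sim_sites>\n")
  cat(sprintf("  %d sites x %d samples (%d rows); %s\n",
              length(unique(paste(x$sites$chrom, x$sites$pos))),
              length(x$samples), nrow(x$sites),
              if (is.null(x$replicates)) "no replicates"
              else sprintf("%d samples in triplicate",
                           length(unique(x$replicates$sample)))))
  invisible(x)
}
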