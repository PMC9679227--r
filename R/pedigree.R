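#' Polarize somatic calls against two outgroups
#'
#' A call is polarizable iff both outgroup populations are fixed for the
#' same homozygous genotype at the site; that allele is the ancestral state
#' and the other allele the derived one. Calls with a missing or
#' heterozygous or discordant outgroup state are flagged unpolarizable and
#' excluded from derived-mutation analyses.
#'
#' @param calls A `somatic_calls` tibble (needs `chrom,pos,ref,alt`).
#' @param outgroup_a,outgroup_b Long genotype tibbles `chrom,pos,gt`
#'   (optionally with `sample`); within each outgroup all non-missing
#'   genotypes at a site must agree and be homozygous for the site to be
#'   informative.
#' @return `calls` plus columns `ancestral`, `derived`, `polarizable`.
#'   Filter on `polarizable` for derived calls.
#' @export
polarize_derived <- function(calls, outgroup_a, outgroup_b) {
  anc_a <- outgroup_ancestral_gt(outgroup_a)
  anc_b <- outgroup_ancestral_gt(outgroup_b)
  k <- site_key(calls$chrom, calls$pos)
  ga <- anc_a$gt[match(k, site_key(anc_a$chrom, anc_a$pos))]
  gb <- anc_b$gt[match(k, site_key(anc_b$chrom, anc_b$pos))]
  agree <- !is.na(ga) & !is.na(gb) & ga == gb
  ancestral <- rep(NA_character_, nrow(calls))
  ancestral[agree & ga == "0/0"] <- calls$ref[agree & ga == "0/0"]
  ancestral[agree & ga == "1/1"] <- calls$alt[agree & ga == "1/1"]
  derived <- ifelse(is.na(ancestral), NA_character_,
                    ifelse(ancestral == calls$ref, calls$alt, calls$ref))
  calls$ancestral <- ancestral
  calls$derived <- derived
  calls$polarizable <- !is.na(ancestral)
  calls
}

#' Mutation-by-sample sharing matrix
#'
#' @param calls A `somatic_calls` tibble with a `carriers` list column.
#' @param samples Optional character vector fixing the sample universe
#'   (defaults to the union of carriers).
#' @return A `sharing_matrix` list: `matrix` (logical, mutations x samples,
#'   rownames are site keys), `pair_counts` (tibble `sample_a, sample_b,
#'   n_shared`), `calls`.
#' @export
sharing_matrix <- function(calls, samples = NULL) {
  samples <- samples %||% sort(unique(unlist(calls$carriers)))
  m <- matrix(FALSE, nrow = nrow(calls), ncol = length(samples),
              dimnames = list(site_key(calls$chrom, calls$pos, calls$ref,
                                       calls$alt),
                              samples))
  for (i in seq_len(nrow(calls))) m[i, calls$carriers[[i]]] <- TRUE
  pairs <- NULL
  if (length(samples) >= 2) {
    cmb <- utils::combn(samples, 2)
    pairs <- tibble::tibble(
      sample_a = cmb[1, ], sample_b = cmb[2, ],
      n_shared = apply(cmb, 2, function(p) sum(m[, p[1]] & m[, p[2]]))
    )
  }
  structure(list(matrix = m, pair_counts = pairs, calls = calls),
            class = "sharing_matrix")
}

#' Reconstruct the cutting pedigree from derived-mutation sharing
#'
#' Greedy perfect phylogeny: carrier sets are processed from largest to
#' smallest (ties in genomic order of their first mutation); a set is
#' accepted as a clade iff it is compatible (nested or disjoint) with every
#' clade accepted so far, and its mutations are assigned to the branch
#' subtending that clade. Incompatible carrier sets are reported as
#' homoplasy and not placed. Samples sharing no mutations attach directly
#' to the root (star topology in the extreme case).
#'
#' @param x A `sharing_matrix` (or a `somatic_calls` tibble, which is
#'   converted first).
#' @param samples Optional sample universe when `x` is a calls tibble.
#' @return A `clone_pedigree` list: `tree` (ape phylo; branch lengths are
#'   mutation counts), `branches` (tibble `clade, leaves (list), n_leaves,
#'   n_mutations`), `homoplasy` (tibble of unplaced carrier sets),
#'   `newick`, `leaf_counts` (mutations inherited per leaf).
#' @export
build_pedigree <- function(x, samples = NULL) {
  sm <- if (inherits(x, "sharing_matrix")) x else sharing_matrix(x, samples)
  m <- sm$matrix
  samples <- colnames(m)
  stop_if_not(length(samples) >= 2, "need >= 2 samples to build a pedigree")

  set_id <- unname(apply(m, 1, function(r) paste(samples[r], collapse = ",")))
  groups <- tibble::tibble(set_id = set_id, row = seq_len(nrow(m)))
  groups <- dplyr::summarise(dplyr::group_by(groups, .data$set_id),
                             n_mutations = dplyr::n(),
                             first_row = min(.data$row), .groups = "drop")
  groups$size <- lengths(strsplit(groups$set_id, ","))
  groups <- groups[groups$size >= 1, ]
  groups <- groups[order(-groups$size, groups$first_row), ]

  compatible <- function(a, b) {
    i <- length(intersect(a, b))
    i == 0 || i == length(a) || i == length(b)
  }
  clades <- list(samples)  # root
  clade_muts <- c(0L)
  homoplasy <- list()
  for (g in seq_len(nrow(groups))) {
    cs <- strsplit(groups$set_id[g], ",")[[1]]
    if (all(vapply(clades, function(cl) compatible(cs, cl), logical(1)))) {
      hit <- which(vapply(clades, function(cl) setequal(cl, cs), logical(1)))
      if (length(hit) == 1) {
        clade_muts[hit] <- clade_muts[hit] + groups$n_mutations[g]
      } else {
        clades[[length(clades) + 1L]] <- cs
        clade_muts <- c(clade_muts, groups$n_mutations[g])
      }
    } else {
      homoplasy[[length(homoplasy) + 1L]] <-
        tibble::tibble(carriers = groups$set_id[g],
                       n_mutations = groups$n_mutations[g])
    }
  }
  # every leaf is a clade (possibly with 0 private mutations)
  for (s in samples) {
    if (!any(vapply(clades, function(cl) setequal(cl, s), logical(1)))) {
      clades[[length(clades) + 1L]] <- s
      clade_muts <- c(clade_muts, 0L)
    }
  }

  newick <- clades_to_newick(clades, clade_muts, samples)
  tree <- ape::read.tree(text = newick)
  branches <- tibble::tibble(
    clade = vapply(clades, function(cl) paste(sort(cl), collapse = ","),
                   character(1)),
    leaves = lapply(clades, sort),
    n_leaves = lengths(clades),
    n_mutations = clade_muts
  )
  leaf_counts <- setNames(vapply(samples, function(s) {
    sum(branches$n_mutations[vapply(branches$leaves, function(l) s %in% l,
                                    logical(1))])
  }, integer(1)), samples)

  structure(
    list(tree = tree, branches = branches,
         homoplasy = if (length(homoplasy)) dplyr::bind_rows(homoplasy)
                     else tibble::tibble(carriers = character(),
                                         n_mutations = integer()),
         newick = newick, leaf_counts = leaf_counts),
    class = "clone_pedigree"
  )
}

# nest accepted clades into a newick string; branch length = mutation count
clades_to_newick <- function(clades, clade_muts, samples) {
  sizes <- lengths(clades)
  build <- function(idx) {
    cl <- clades[[idx]]
    children <- which(vapply(seq_along(clades), function(j) {
      j != idx && all(clades[[j]] %in% cl) && sizes[j] < sizes[idx] &&
        # direct child: no strictly intermediate clade
        !any(vapply(seq_along(clades), function(k) {
          k != idx && k != j && sizes[k] < sizes[idx] &&
            sizes[k] > sizes[j] && all(clades[[j]] %in% clades[[k]]) &&
            all(clades[[k]] %in% cl)
        }, logical(1)))
    }, logical(1)))
    # same-size duplicate protection: keep only unique sets
    inner <- vapply(children, function(j) {
      if (sizes[j] == 1) {
        sprintf("%s:%d", clades[[j]][1], clade_muts[j])
      } else {
        sprintf("%s:%d", build(j), clade_muts[j])
      }
    }, character(1))
    paste0("(", paste(inner, collapse = ","), ")")
  }
  root_idx <- which(sizes == length(samples))[1]
  paste0(build(root_idx), ";")
}

#' Haplotype identity of shared somatic mutations
#'
#' For every shared call, asks whether the somatic allele sits on the same
#' haplotype in all carriers: each carrier's phased genotype gives the side
#' the somatic allele occupies, and heterozygous neighbour sites phased in
#' the same per-sample phase block anchor the haplotypes across carriers.
#' A call is `same` iff every informative shared neighbour shows the same
#' co-occurring allele in all carriers, `different` if any neighbour
#' disagrees, and `unphased` when the call or the carriers lack an
#' informative phased neighbour.
#'
#' @param shared_calls A `somatic_calls` tibble (only rows with
#'   `n_carriers >= 2` are assessed).
#' @param phased Long phased genotype tibble `chrom,pos,sample,pgt,ps`
#'   (`pgt` like `"0|1"`, `ps` the phase-set identifier; pairs with the same
#'   `chrom` and `ps` within a sample are on one block).
#' @return `shared_calls` plus a `phase_class` column in
#'   `{same, different, unphased}` (NA for non-shared rows).
#' @export
haplotype_identity_test <- function(shared_calls, phased) {
  phased <- phased[!is.na(phased$pgt) & !is.na(phased$ps) &
                     phased$pgt %in% c("0|1", "1|0"), ]
  pkey <- paste(phased$chrom, phased$pos, phased$sample)
  out <- rep(NA_character_, nrow(shared_calls))
  for (i in seq_len(nrow(shared_calls))) {
    if (shared_calls$n_carriers[i] < 2) next
    carriers <- shared_calls$carriers[[i]]
    ch <- shared_calls$chrom[i]
    p <- shared_calls$pos[i]
    rows <- phased[match(paste(ch, p, carriers), pkey), ]
    if (any(is.na(rows$pgt))) { out[i] <- "unphased"; next }
    # side on which the somatic (alt) allele sits, per carrier
    alt_side <- ifelse(rows$pgt == "1|0", 1L, 2L)
    blocks <- rows$ps
    # neighbour candidates: phased het in every carrier, same block per carrier
    nb <- phased[phased$chrom == ch & phased$pos != p &
                   phased$sample %in% carriers, ]
    nb <- nb[!is.na(nb$ps) & nb$ps == blocks[match(nb$sample, carriers)], ]
    if (nrow(nb) == 0) { out[i] <- "unphased"; next }
    counts <- table(nb$pos)
    informative <- as.integer(names(counts)[counts == length(carriers)])
    if (length(informative) == 0) { out[i] <- "unphased"; next }
    verdict <- "same"
    for (q in informative) {
      nrows <- nb[nb$pos == q, ]
      nrows <- nrows[match(carriers, nrows$sample), ]
      side_allele <- vapply(seq_along(carriers), function(j) {
        alleles <- strsplit(nrows$pgt[j], "|", fixed = TRUE)[[1]]
        alleles[alt_side[j]]
      }, character(1))
      if (length(unique(side_allele)) > 1) { verdict <- "different"; break }
    }
    out[i] <- verdict
  }
  shared_calls$phase_class <- out
  shared_calls
}

#' Sharing and phasing summary of somatic calls
#'
#' @param calls A `somatic_calls` tibble (optionally carrying
#'   `phase_class`).
#' @param digits Decimals for printed percentages (half away from zero).
#' @return Tibble of counts and percentages: total, shared (carried by >= 2
#'   samples), sample-specific; when `phase_class` is present also phased
#'   counts overall and among shared calls.
#' @export
sharing_summary <- function(calls, digits = 1) {
  total <- nrow(calls)
  shared <- sum(calls$n_carriers >= 2)
  rows <- tibble::tibble(
    metric = c("total", "shared", "sample_specific"),
    n = c(total, shared, total - shared),
    percent = c(NA_real_, percent_of(shared, total, digits),
                percent_of(total - shared, total, digits))
  )
  if ("phase_class" %in% names(calls)) {
    phased_all <- sum(!is.na(calls$phase_class) &
                        calls$phase_class != "unphased")
    shared_idx <- calls$n_carriers >= 2
    phased_shared <- sum(!is.na(calls$phase_class[shared_idx]) &
                           calls$phase_class[shared_idx] != "unphased")
    same_shared <- sum(calls$phase_class[shared_idx] %in% "same")
    rows <- dplyr::bind_rows(rows, tibble::tibble(
      metric = c("phased", "shared_phased", "shared_same_haplotype"),
      n = c(phased_all, phased_shared, same_shared),
      percent = c(percent_of(phased_all, total, digits),
                  percent_of(phased_shared, shared, digits),
                  percent_of(same_shared, phased_shared, digits))
    ))
  }
  rows
}

#' @export
print.clone_pedigree <- function(x, ...) {
  cat("<clone_pedigree>\n")
  cat(sprintf("  %d leaves, %d placed branches, %d homoplastic carrier sets\n",
              length(x$leaf_counts), nrow(x$branches), nrow(x$homoplasy)))
  cat("  ", x$newick, "\n")
  invisible(x)
}

#' @importFrom generics tidy
#' @export
tidy.clone_pedigree <- function(x, ...) {
  dplyr::select(x$branches, "clade", "n_leaves", "n_mutations")
}
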