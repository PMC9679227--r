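#' Cytosine methylation context of genomic sites
#'
#' Classifies each site as `CpG`, `CHG`, `CHH` (H = A, C or T) or `nonC`.
#' Contexts are evaluated strand-symmetrically: a G on the plus strand is a
#' cytosine on the minus strand and is classified by its leftward plus-strand
#' neighbours. Cytosines too close to a chromosome end for a full triplet
#' fall back to the widest context that is still defined (a terminal C with
#' one G neighbour is CpG; otherwise CHH).
#'
#' @param ref A `ref_model` (or any list with a `sequences` element).
#' @param chrom,pos Vectors of positions.
#' @return Character vector of contexts.
#' @export
#' @examples
#' ref <- list(sequences = c(chr1 = "ACGACTA"))
#' site_context(ref, "chr1", c(2, 5)) # CpG (ACG), CHH (ACT... C at 5? A C T)
site_context <- function(ref, chrom, pos) {
  out <- rep(NA_character_, length(pos))
  for (ch in unique(chrom)) {
    sel <- which(chrom == ch)
    s <- ref$sequences[[ch]]
    L <- nchar(s)
    p <- pos[sel]
    b0 <- substring(s, p, p)
    res <- rep("nonC", length(p))

    isC <- b0 == "C"
    if (any(isC)) {
      p1 <- ifelse(p + 1 <= L, substring(s, p + 1, p + 1), "")
      p2 <- ifelse(p + 2 <= L, substring(s, p + 2, p + 2), "")
      res[isC & p1 == "G"] <- "CpG"
      res[isC & p1 != "G" & p2 == "G"] <- "CHG"
      res[isC & p1 != "G" & (p2 != "G" | p2 == "")] <- "CHH"
      res[isC & p1 == ""] <- "CHH"
    }
    isG <- b0 == "G"
    if (any(isG)) {
      m1 <- ifelse(p - 1 >= 1, substring(s, p - 1, p - 1), "")
      m2 <- ifelse(p - 2 >= 1, substring(s, p - 2, p - 2), "")
      res[isG & m1 == "C"] <- "CpG"
      res[isG & m1 != "C" & m2 == "C"] <- "CHG"
      res[isG & m1 != "C" & (m2 != "C" | m2 == "")] <- "CHH"
      res[isG & m1 == ""] <- "CHH"
    }
    out[sel] <- res
  }
  out
}

#' Expected mutation count on a pedigree branch
#'
#' The per-branch Poisson mean: `rate * years * 2 * genome_length`, the
#' factor 2 counting both copies of the diploid genome.
#'
#' @param rate Mutations per base per year.
#' @param years Branch length in years.
#' @param genome_length Haploid genome length in bases.
#' @return Expected mutation count.
#' @export
#' @examples
#' expected_branch_mutations(1e-8, 67, 4.08e8) # ~546.7
expected_branch_mutations <- function(rate, years, genome_length) {
  rate * years * 2 * genome_length
}

#' Simulate pedigree-structured somatic mutations with known truth
#'
#' Walks every branch of the cutting pedigree and draws SNVs (and indels)
#' as a Poisson process at `snv_rate` per base per year over the diploid
#' genome. SNV placement is uniform followed by acceptance-rejection
#' thinning with the cytosine-context multipliers, so the realised per-site
#' rate in context `c` is `snv_rate * context_multipliers[c]`. Every
#' mutation lands on one haplotype; positions are unique across the whole
#' lineage (collisions with earlier mutations or background heterozygous
#' sites are re-drawn and counted).
#'
#' @param ref A `ref_model` from [simulate_genome()].
#' @param config The same [sim_config()] used for the genome.
#' @return A `pedigree_truth` list: `tree` (ape phylo, branch lengths in
#'   years), `branch_mutations` (tibble with `branch` = child-node label,
#'   `chrom,pos,ref,alt,hap,type,context`), `leaf_assignments` (one row per
#'   leaf x inherited mutation), and `collisions`.
#' @export
simulate_mutations <- function(ref, config) {
  validate_sim_config(config)
  set.seed(derive_seed(config$seed, 2L))

  tree <- ape::read.tree(text = config$pedigree_newick)
  if (is.null(tree$node.label) || any(tree$node.label == "")) {
    tree$node.label <- sprintf("node%d", seq_len(tree$Nnode))
  }
  node_names <- c(tree$tip.label, tree$node.label)
  L_total <- sum(ref$chrom_lengths)
  mult <- config$context_multipliers
  m_max <- max(mult, 1e-12)

  occupied <- new.env(parent = emptyenv())
  for (k in site_key(ref$het_sites$chrom, ref$het_sites$pos)) {
    assign(k, TRUE, envir = occupied)
  }
  collisions <- 0L

  draw_positions <- function(n) {
    # uniform over the concatenated genome
    gpos <- sample.int(L_total, n, replace = TRUE)
    offsets <- cumsum(c(0, ref$chrom_lengths))
    idx <- findInterval(gpos - 1, offsets, rightmost.closed = FALSE)
    tibble::tibble(chrom = names(ref$chrom_lengths)[idx],
                   pos = as.integer(gpos - offsets[idx]))
  }

  # n_events candidate mutations drawn at Poisson(lambda * m_max); each draws
  # a uniform position (re-drawn on collision) and then survives context
  # thinning with probability mult(context)/m_max, so the realised per-site
  # rate in context c is snv_rate * mult[c]
  place_snvs <- function(n_events) {
    placed <- list()
    pending <- n_events
    guard <- 0L
    while (pending > 0 && guard < 500L) {
      guard <- guard + 1L
      cand <- draw_positions(pending)
      keys <- site_key(cand$chrom, cand$pos)
      free <- !duplicated(keys) &
        !vapply(keys, exists, logical(1), envir = occupied)
      collisions <<- collisions + sum(!free)
      cand <- cand[free, , drop = FALSE]
      pending <- pending - nrow(cand)  # occupied positions are re-drawn
      if (nrow(cand) == 0) next
      ctx <- site_context(ref, cand$chrom, cand$pos)
      keep <- stats::runif(nrow(cand)) < mult[ctx] / m_max
      cand <- cand[keep, , drop = FALSE]  # thinning cancels the event
      ctx <- ctx[keep]
      if (nrow(cand) == 0) next
      for (k in site_key(cand$chrom, cand$pos)) assign(k, TRUE, envir = occupied)
      cand$context <- ctx
      placed[[length(placed) + 1L]] <- cand
    }
    if (length(placed) == 0) {
      return(tibble::tibble(chrom = character(), pos = integer(),
                            context = character()))
    }
    dplyr::bind_rows(placed)
  }

  place_indels <- function(n_events) {
    empty <- tibble::tibble(chrom = character(), pos = integer(),
                            ref = character(), alt = character())
    if (n_events == 0) return(empty)
    cand <- NULL
    pending <- n_events
    guard <- 0L
    while (pending > 0 && guard < 500L) {
      guard <- guard + 1L
      batch <- draw_positions(pending)
      keys <- site_key(batch$chrom, batch$pos)
      ok <- !duplicated(keys) &
        !vapply(keys, exists, logical(1), envir = occupied) &
        !site_key(batch$chrom, batch$pos) %in%
          site_key(cand$chrom %||% character(), cand$pos %||% integer())
      collisions <<- collisions + sum(!ok)
      cand <- dplyr::bind_rows(cand, batch[ok, , drop = FALSE])
      pending <- n_events - nrow(cand)
    }
    if (is.null(cand) || nrow(cand) == 0) return(empty)
    lens <- pmin(rgeom(nrow(cand), 0.5) + 1L, 10L)
    is_ins <- sample(c(TRUE, FALSE), nrow(cand), replace = TRUE)
    ref_a <- character(nrow(cand))
    alt_a <- character(nrow(cand))
    for (i in seq_len(nrow(cand))) {
      s <- ref$sequences[[cand$chrom[i]]]
      p <- cand$pos[i]
      anchor <- substring(s, p, p)
      if (is_ins[i]) {
        ref_a[i] <- anchor
        alt_a[i] <- paste0(anchor, paste(sample(c("A", "C", "G", "T"),
                                                lens[i], replace = TRUE),
                                         collapse = ""))
      } else {
        p_end <- min(p + lens[i], nchar(s))
        ref_a[i] <- substring(s, p, p_end)
        alt_a[i] <- anchor
      }
      assign(site_key(cand$chrom[i], cand$pos[i]), TRUE, envir = occupied)
    }
    tibble::tibble(chrom = cand$chrom, pos = cand$pos, ref = ref_a,
                   alt = alt_a)
  }

  branches <- list()
  for (e in seq_len(nrow(tree$edge))) {
    child <- node_names[tree$edge[e, 2]]
    years <- tree$edge.length[e]
    lambda_snv <- expected_branch_mutations(config$snv_rate, years, L_total) *
      m_max
    n_snv <- if (lambda_snv > 0) rpois(1, lambda_snv) else 0L
    snvs <- place_snvs(n_snv)
    if (nrow(snvs) > 0) {
      snvs$ref <- mapply(function(ch, p) substring(ref$sequences[[ch]], p, p),
                         snvs$chrom, snvs$pos, USE.NAMES = FALSE)
      snvs$alt <- random_other_base(snvs$ref)
      snvs$type <- "snv"
    }
    lambda_ind <- expected_branch_mutations(config$indel_rate, years, L_total)
    n_ind <- if (lambda_ind > 0) rpois(1, lambda_ind) else 0L
    indels <- place_indels(n_ind)
    if (nrow(indels) > 0) {
      indels$context <- NA_character_
      indels$type <- "indel"
    }
    branch_tbl <- dplyr::bind_rows(snvs, indels)
    if (nrow(branch_tbl) > 0) {
      branch_tbl$branch <- child
      branch_tbl$hap <- sample(0:1, nrow(branch_tbl), replace = TRUE)
      branches[[length(branches) + 1L]] <- branch_tbl
    }
  }

  empty_mut <- tibble::tibble(branch = character(), chrom = character(),
                              pos = integer(), ref = character(),
                              alt = character(), hap = integer(),
                              type = character(), context = character())
  branch_mutations <- if (length(branches)) {
    dplyr::select(dplyr::bind_rows(branches), "branch", "chrom", "pos",
                  "ref", "alt", "hap", "type", "context")
  } else empty_mut

  leaf_assignments <- assign_leaf_mutations(tree, branch_mutations)

  structure(
    list(tree = tree, branch_mutations = branch_mutations,
         leaf_assignments = leaf_assignments, collisions = collisions,
         config = config),
    class = "pedigree_truth"
  )
}

# per leaf: union of branch mutations along its root path
assign_leaf_mutations <- function(tree, branch_mutations) {
  node_names <- c(tree$tip.label, tree$node.label)
  parent_of <- setNames(tree$edge[, 1], node_names[tree$edge[, 2]])
  out <- lapply(tree$tip.label, function(leaf) {
    path <- character()
    node <- leaf
    repeat {
      path <- c(path, node)
      up <- parent_of[node]
      if (is.na(up)) break
      node <- node_names[up]
    }
    muts <- dplyr::filter(branch_mutations, .data$branch %in% path)
    if (nrow(muts) == 0) return(NULL)
    muts$leaf <- leaf
    muts
  })
  res <- dplyr::bind_rows(out)
  if (nrow(res) == 0) {
    return(tibble::tibble(leaf = character(), branch = character(),
                          chrom = character(), pos = integer(),
                          ref = character(), alt = character(),
                          hap = integer(), type = character(),
                          context = character()))
  }
  dplyr::select(res, "leaf", dplyr::everything())
}

#' @export
print.pedigree_truth <- function(x, ...) {
  cat("<pedigree_truth>\n")
  cat(sprintf("  %d leaves; %d branch mutations (%d SNV, %d indel); %d collisions re-drawn\n",
              length(x$tree$tip.label), nrow(x$branch_mutations),
              sum(x$branch_mutations$type == "snv"),
              sum(x$branch_mutations$type == "indel"), x$collisions))
  invisible(x)
}
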