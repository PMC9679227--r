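# Standard-format I/O. Coordinates: VCF and internal tables are 1-based
# closed; BED files are 0-based half-open on disk and converted on read and
# write.

VCF_INFO_FIELDS <- c("FS", "MQ", "MQRankSum", "QD", "ReadPosRankSum", "SOR")

#' Read a multi-sample VCF into the long site-table schema
#'
#' Parses GT, DP, GQ, AD and PS FORMAT fields and the numeric INFO
#' annotations used by the hard filters (`FS, MQ, MQRankSum, QD,
#' ReadPosRankSum, SOR`), returning one row per site per sample. Phased
#' genotypes are kept in `pgt` (with `ps`), and `gt` holds the unphased
#' form.
#'
#' @param path Path to a VCF (plain or bgzipped).
#' @return A long tibble in the package's site-table schema.
#' @export
read_vcf <- function(path) {
  stop_if_not(file.exists(path), sprintf("no such file: %s", path))
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- tibble::as_tibble(as.data.frame(v@fix, stringsAsFactors = FALSE))
  n_site <- nrow(fix)
  stop_if_not(n_site > 0, sprintf("%s contains no records", path))
  info <- lapply(VCF_INFO_FIELDS, function(f) {
    suppressWarnings(as.numeric(vcfR::extract.info(v, element = f)))
  })
  names(info) <- VCF_INFO_FIELDS

  get_fmt <- function(el) {
    out <- tryCatch(vcfR::extract.gt(v, element = el),
                    error = function(e) NULL)
    if (is.null(out)) matrix(NA_character_, nrow = n_site,
                             ncol = length(colnames(v@gt)) - 1) else out
  }
  gt_m <- get_fmt("GT")
  dp_m <- get_fmt("DP")
  gq_m <- get_fmt("GQ")
  ad_m <- get_fmt("AD")
  ps_m <- get_fmt("PS")
  samples <- colnames(gt_m)

  rows <- lapply(seq_along(samples), function(j) {
    ad <- strsplit(ifelse(is.na(ad_m[, j]), ",", ad_m[, j]), ",", fixed = TRUE)
    tibble::tibble(
      chrom = fix$CHROM,
      pos = as.integer(fix$POS),
      ref = fix$REF,
      alt = fix$ALT,
      var_type = ifelse(nchar(fix$REF) == 1 &
                          nchar(gsub(",.*", "", fix$ALT)) == 1 &
                          !grepl(",", fix$ALT, fixed = TRUE),
                        "snv", "indel"),
      FS = info$FS, MQ = info$MQ, MQRankSum = info$MQRankSum, QD = info$QD,
      ReadPosRankSum = info$ReadPosRankSum, SOR = info$SOR,
      sample = samples[j],
      pgt = ifelse(grepl("|", gt_m[, j], fixed = TRUE), gt_m[, j],
                   NA_character_),
      gt = ifelse(gt_m[, j] %in% c(".", "./.", ".|."), NA_character_,
                  normalize_gt(gt_m[, j])),
      dp = suppressWarnings(as.integer(dp_m[, j])),
      gq = suppressWarnings(as.integer(gq_m[, j])),
      ad_ref = suppressWarnings(as.integer(vapply(ad, `[`, "", 1))),
      ad_alt = suppressWarnings(as.integer(vapply(ad, function(x)
        if (length(x) >= 2) x[2] else NA_character_, ""))),
      ps = suppressWarnings(as.integer(ps_m[, j]))
    )
  })
  dplyr::bind_rows(rows)
}

normalize_gt <- function(gt) {
  out <- chartr("|", "/", gt)
  # canonical allele order for unphased genotypes
  ifelse(out == "1/0", "0/1", out)
}

#' Write a long site table as a multi-sample VCF
#'
#' Emits GT (phased where `pgt` is present), DP, GQ, AD and PS FORMAT
#' fields plus the hard-filter INFO annotations. The written file
#' round-trips through [read_vcf()] losslessly for those fields.
#'
#' @param sites Long site table.
#' @param path Output path (plain text).
#' @return `path`, invisibly.
#' @export
write_vcf <- function(sites, path) {
  samples <- sort(unique(sites$sample))
  site_cols <- c("chrom", "pos", "ref", "alt",
                 intersect(VCF_INFO_FIELDS, names(sites)))
  site_level <- dplyr::distinct(sites,
                                dplyr::across(dplyr::all_of(site_cols)))
  site_level <- dplyr::arrange(site_level, .data$chrom, .data$pos)

  info_str <- apply(site_level, 1, function(r) {
    fields <- intersect(VCF_INFO_FIELDS, names(site_level))
    vals <- r[fields]
    ok <- !is.na(vals) & vals != "NA"
    if (!any(ok)) return(".")
    paste(sprintf("%s=%s", fields[ok], trimws(vals[ok])), collapse = ";")
  })

  skey <- paste(sites$chrom, sites$pos, sites$ref, sites$alt, sites$sample)
  n_site <- nrow(site_level)
  # sample-major cell matrix, vectorized lookup
  cell_m <- matrix("./.:.:.:.,.:.", nrow = n_site, ncol = length(samples))
  for (j in seq_along(samples)) {
    idx <- match(paste(site_level$chrom, site_level$pos, site_level$ref,
                       site_level$alt, samples[j]), skey)
    ok <- !is.na(idx)
    i <- idx[ok]
    gt_out <- ifelse(!is.na(sites$pgt[i]), sites$pgt[i],
                     ifelse(is.na(sites$gt[i]), "./.", sites$gt[i]))
    cell_m[ok, j] <- sprintf("%s:%s:%s:%s,%s:%s", gt_out,
                             na_dot(sites$dp[i]), na_dot(sites$gq[i]),
                             na_dot(sites$ad_ref[i]), na_dot(sites$ad_alt[i]),
                             na_dot(sites$ps[i]))
  }
  body <- paste(site_level$chrom, site_level$pos, ".", site_level$ref,
                site_level$alt, ".", "PASS", info_str, "GT:DP:GQ:AD:PS",
                apply(cell_m, 1, paste, collapse = "\t"), sep = "\t")

  header <- c(
    "##fileformat=VCFv4.2",
    sprintf("##INFO=<ID=%s,Number=1,Type=Float,Description=\"%s\">",
            VCF_INFO_FIELDS, VCF_INFO_FIELDS),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Depth\">",
    "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Genotype quality\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allele depths\">",
    "##FORMAT=<ID=PS,Number=1,Type=Integer,Description=\"Phase set\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t")
  )
  writeLines(c(header, body), path)
  invisible(path)
}

na_dot <- function(x) ifelse(is.na(x), ".", as.character(x))

#' Read a BED file (0-based half-open) to 1-based closed intervals
#'
#' @param path BED path; columns chrom, start, end and optionally a name
#'   column (used for sample or class labels).
#' @return Tibble `chrom, start, end[, name]` in 1-based closed coordinates.
#' @export
read_bed <- function(path) {
  stop_if_not(file.exists(path), sprintf("no such file: %s", path))
  raw <- readr::read_tsv(path, col_names = FALSE, show_col_types = FALSE,
                         progress = FALSE, comment = "#")
  stop_if_not(ncol(raw) >= 3, sprintf("%s: BED needs >= 3 columns", path))
  out <- tibble::tibble(chrom = as.character(raw[[1]]),
                        start = as.integer(raw[[2]]) + 1L,
                        end = as.integer(raw[[3]]))
  stop_if_not(!anyNA(out$start) && !anyNA(out$end),
              sprintf("%s: malformed BED coordinates", path))
  if (ncol(raw) >= 4) out$name <- as.character(raw[[4]])
  out
}

#' Write 1-based closed intervals as BED (0-based half-open)
#'
#' @param intervals Tibble `chrom, start, end[, name]` (1-based closed).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(intervals, path) {
  df <- data.frame(intervals$chrom, intervals$start - 1L, intervals$end)
  if ("name" %in% names(intervals)) df$name <- intervals$name
  else if ("class" %in% names(intervals)) df$name <- intervals$class
  readr::write_tsv(df, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' Read / write FASTA
#'
#' Thin wrappers over Biostrings returning and accepting named character
#' vectors of chromosome sequences.
#'
#' @param path FASTA path.
#' @return `read_fasta`: named character vector.
#' @export
read_fasta <- function(path) {
  stop_if_not(file.exists(path), sprintf("no such file: %s", path))
  s <- Biostrings::readDNAStringSet(path)
  setNames(as.character(s), names(s))
}

#' @rdname read_fasta
#' @param sequences Named character vector (or a `ref_model`).
#' @export
write_fasta <- function(sequences, path) {
  if (inherits(sequences, "ref_model")) sequences <- sequences$sequences
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(sequences), path)
  invisible(path)
}

#' Strand-count TSV I/O
#'
#' Long format `chrom, pos, sample, allele, fwd_reads, rev_reads`, one row
#' per allele per sample per site.
#'
#' @param sites Long site table with `fwd_ref/rev_ref/fwd_alt/rev_alt`.
#' @param path TSV path.
#' @return `read_strand_counts`: the long tibble;
#'   `strand_counts_from_sites`: the same shape built in memory.
#' @export
strand_counts_from_sites <- function(sites) {
  dplyr::bind_rows(
    tibble::tibble(chrom = sites$chrom, pos = sites$pos,
                   sample = sites$sample, allele = sites$ref,
                   which = "ref",
                   fwd_reads = sites$fwd_ref, rev_reads = sites$rev_ref),
    tibble::tibble(chrom = sites$chrom, pos = sites$pos,
                   sample = sites$sample, allele = sites$alt,
                   which = "alt",
                   fwd_reads = sites$fwd_alt, rev_reads = sites$rev_alt)
  )
}

#' @rdname strand_counts_from_sites
#' @export
write_strand_counts <- function(sites, path) {
  readr::write_tsv(strand_counts_from_sites(sites), path, progress = FALSE)
  invisible(path)
}

#' @rdname strand_counts_from_sites
#' @export
read_strand_counts <- function(path) {
  stop_if_not(file.exists(path), sprintf("no such file: %s", path))
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                  col_types = readr::cols(
                    chrom = "c", pos = "i", sample = "c", allele = "c",
                    which = "c", fwd_reads = "i", rev_reads = "i"))
}

#' Read a recombination-window TSV (`chrom, start, end, rho`)
#'
#' @param path TSV path; 1-based closed windows.
#' @return Tibble `chrom, start, end, rho`.
#' @export
read_recomb_windows <- function(path) {
  stop_if_not(file.exists(path), sprintf("no such file: %s", path))
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                  col_types = readr::cols(chrom = "c", start = "i",
                                          end = "i", rho = "d"))
}

#' Read an effect-score TSV (`chrom, pos, ref, alt, sift, provean, polyphen`)
#'
#' @param path TSV path.
#' @return Tibble of scores keyed by variant.
#' @export
read_scores <- function(path) {
  stop_if_not(file.exists(path), sprintf("no such file: %s", path))
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
}

#' Write somatic calls as TSV (carriers collapsed with commas)
#'
#' @param calls A `somatic_calls` tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_calls <- function(calls, path) {
  out <- calls
  out$carriers <- vapply(out$carriers, paste, character(1), collapse = ",")
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_calls
#' @export
read_calls <- function(path) {
  stop_if_not(file.exists(path), sprintf("no such file: %s", path))
  out <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  out$carriers <- strsplit(out$carriers, ",", fixed = TRUE)
  out$n_carriers <- lengths(out$carriers)
  class(out) <- c("somatic_calls", class(out))
  out
}

#' Write a pedigree as newick
#'
#' @param x A `clone_pedigree`, an ape `phylo`, or a newick string.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(x, path) {
  if (inherits(x, "clone_pedigree")) {
    writeLines(x$newick, path)
  } else if (inherits(x, "phylo")) {
    ape::write.tree(x, file = path)
  } else {
    writeLines(as.character(x), path)
  }
  invisible(path)
}

#' Write pairwise derived-mutation distances as a NEXUS distances block
#'
#' The distance between two samples is the Hamming distance on mutation
#' presence: `n_a + n_b - 2 * shared(a, b)`, suitable for NeighborNet-style
#' split network tools.
#'
#' @param sm A `sharing_matrix`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_nexus_splits <- function(sm, path) {
  m <- sm$matrix
  samples <- colnames(m)
  totals <- colSums(m)
  d <- outer(seq_along(samples), seq_along(samples),
             Vectorize(function(i, j) {
               totals[i] + totals[j] - 2 * sum(m[, i] & m[, j])
             }))
  lines <- c(
    "#NEXUS",
    "BEGIN taxa;",
    sprintf("  DIMENSIONS ntax=%d;", length(samples)),
    "  TAXLABELS",
    sprintf("    %s", samples),
    "  ;",
    "END;",
    "BEGIN distances;",
    sprintf("  DIMENSIONS ntax=%d;", length(samples)),
    "  FORMAT triangle=both diagonal labels missing=?;",
    "  MATRIX",
    vapply(seq_along(samples), function(i) {
      sprintf("    %s %s", samples[i], paste(d[i, ], collapse = " "))
    }, character(1)),
    "  ;",
    "END;"
  )
  writeLines(lines, path)
  invisible(path)
}
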