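og <- function(gts, pos = 100L) {
  tibble::tibble(chrom = "chr1", pos = pos,
                 sample = sprintf("o%d", seq_along(gts)), gt = gts)
}

test_that("polarization requires concordant homozygous outgroups", {
  calls <- tibble::tibble(chrom = "chr1", pos = 100L, ref = "A", alt = "T")
  # both outgroups fixed 0/0: ancestral = ref, derived = alt
  out <- polarize_derived(calls, og(c("0/0", "0/0")), og("0/0"))
  expect_true(out$polarizable)
  expect_equal(out$ancestral, "A")
  expect_equal(out$derived, "T")
  # discordant outgroups: unpolarizable
  out2 <- polarize_derived(calls, og("0/0"), og("1/1"))
  expect_false(out2$polarizable)
  # heterozygous outgroup: unpolarizable
  out3 <- polarize_derived(calls, og(c("0/0", "0/1")), og("0/0"))
  expect_false(out3$polarizable)
  # missing outgroup genotype at the site: unpolarizable
  out4 <- polarize_derived(calls, og("0/0", pos = 999L), og("0/0"))
  expect_false(out4$polarizable)
  # both fixed alt: ancestral = alt, derived = ref
  out5 <- polarize_derived(calls, og("1/1"), og("1/1"))
  expect_equal(out5$ancestral, "T")
  expect_equal(out5$derived, "A")
})

mk_calls <- function(carrier_sets, pos0 = 100L) {
  tibble::tibble(
    chrom = "chr1",
    pos = pos0 + seq_along(carrier_sets) * 10L,
    ref = "A", alt = "T", var_type = "snv",
    carriers = lapply(carrier_sets, sort),
    n_carriers = lengths(carrier_sets)
  )
}

test_that("pedigree reconstruction recovers nested clades", {
  sets <- c(rep(list(c("A", "B", "C", "D")), 5),
            rep(list(c("A", "B")), 4),
            list("A", "A", "B", "C", "D", "D"))
  ped <- build_pedigree(mk_calls(sets), samples = c("A", "B", "C", "D", "E"))
  expect_true("A,B,C,D" %in% ped$branches$clade)
  expect_true("A,B" %in% ped$branches$clade)
  expect_equal(ped$branches$n_mutations[ped$branches$clade == "A,B,C,D"], 5L)
  expect_equal(ped$branches$n_mutations[ped$branches$clade == "A,B"], 4L)
  # leaf counts sum branch assignments along the root path
  expect_equal(unname(ped$leaf_counts["A"]), 5L + 4L + 2L)
  expect_equal(unname(ped$leaf_counts["E"]), 0L)
  expect_equal(nrow(ped$homoplasy), 0)
})

test_that("no sharing yields a star and conflicts are homoplasy", {
  star <- build_pedigree(mk_calls(list("A", "B", "C")),
                         samples = c("A", "B", "C"))
  expect_equal(sum(star$branches$n_leaves > 1 &
                     star$branches$n_leaves < 3), 0)
  # overlapping but non-nested carrier sets conflict
  conf <- build_pedigree(mk_calls(c(rep(list(c("A", "B")), 3),
                                    list(c("B", "C")))),
                         samples = c("A", "B", "C"))
  expect_equal(conf$homoplasy$carriers, "B,C")
  expect_true("A,B" %in% conf$branches$clade)
})

test_that("reconstruction is invariant to mutation order", {
  sets <- c(rep(list(c("A", "B")), 3), rep(list(c("C", "D")), 3),
            list("A", "B", "C", "D", "A"))
  calls <- mk_calls(sets)
  ped1 <- build_pedigree(calls, samples = c("A", "B", "C", "D"))
  perm <- calls[sample.int(nrow(calls)), ]
  ped2 <- build_pedigree(perm, samples = c("A", "B", "C", "D"))
  expect_setequal(ped1$branches$clade, ped2$branches$clade)
  o1 <- ped1$branches[order(ped1$branches$clade), c("clade", "n_mutations")]
  o2 <- ped2$branches[order(ped2$branches$clade), c("clade", "n_mutations")]
  expect_equal(o1, o2)
})

test_that("a simulated cutting tree is reconstructed exactly from truth", {
  nwk <- "((A:20,B:20):47,(C:35,D:35):32);"
  cfg <- small_config(seed = 53, genome_length = 2e5, snv_rate = 2e-5,
                      indel_rate = 0, pedigree_newick = nwk,
                      n_replicate_samples = 0)
  ref <- simulate_genome(cfg)
  truth <- simulate_mutations(ref, cfg)
  # build calls directly from truth leaf assignments
  la <- truth$leaf_assignments
  agg <- dplyr::summarise(dplyr::group_by(la, .data$chrom, .data$pos,
                                          .data$ref, .data$alt),
                          carriers = list(sort(.data$leaf)), .groups = "drop")
  agg$n_carriers <- lengths(agg$carriers)
  agg$var_type <- "snv"
  ped <- build_pedigree(agg, samples = truth$tree$tip.label)
  # exact topology: the two internal clades, nothing else
  internal <- ped$branches$clade[ped$branches$n_leaves > 1 &
                                   ped$branches$n_leaves < 4]
  expect_setequal(internal, c("A,B", "C,D"))
  expect_equal(nrow(ped$homoplasy), 0)
  # exact branch mutation counts
  bm_counts <- table(truth$branch_mutations$branch)
  expect_gte(min(bm_counts), 20)
  for (b in c("A", "B", "C", "D")) {
    expect_equal(ped$branches$n_mutations[ped$branches$clade == b],
                 unname(bm_counts[b]))
  }
  clade_of <- c("A,B", "C,D")
  stem_counts <- bm_counts[!names(bm_counts) %in% c("A", "B", "C", "D")]
  expect_setequal(unname(stem_counts),
                  ped$branches$n_mutations[ped$branches$clade %in% clade_of])
})

phased_row <- function(sample, pos, pgt, ps = 1L) {
  tibble::tibble(chrom = "chr1", pos = pos, sample = sample, pgt = pgt,
                 ps = ps)
}

test_that("haplotype identity test reads phased co-occurrence", {
  call <- tibble::tibble(chrom = "chr1", pos = 100L, ref = "A", alt = "T",
                         carriers = list(c("s1", "s2")), n_carriers = 2L)
  # somatic allele phased with the same neighbour allele in both carriers
  same <- dplyr::bind_rows(
    phased_row("s1", 100L, "1|0"), phased_row("s1", 150L, "1|0"),
    phased_row("s2", 100L, "0|1"), phased_row("s2", 150L, "0|1"))
  expect_equal(haplotype_identity_test(call, same)$phase_class, "same")
  # somatic allele on opposite phases of the shared neighbour
  diff <- dplyr::bind_rows(
    phased_row("s1", 100L, "1|0"), phased_row("s1", 150L, "1|0"),
    phased_row("s2", 100L, "0|1"), phased_row("s2", 150L, "1|0"))
  expect_equal(haplotype_identity_test(call, diff)$phase_class, "different")
  # no heterozygous neighbour within the block
  lonely <- dplyr::bind_rows(
    phased_row("s1", 100L, "1|0"), phased_row("s2", 100L, "0|1"),
    phased_row("s2", 150L, "0|1"))
  expect_equal(haplotype_identity_test(call, lonely)$phase_class, "unphased")
  # carriers in different phase blocks with no linking site
  split_blocks <- dplyr::bind_rows(
    phased_row("s1", 100L, "1|0", ps = 1L), phased_row("s1", 150L, "1|0", 1L),
    phased_row("s2", 100L, "0|1", ps = 2L), phased_row("s2", 150L, "0|1", 1L))
  expect_equal(haplotype_identity_test(call, split_blocks)$phase_class,
               "unphased")
})

test_that("clonally shared simulated mutations are never on different haplotypes", {
  cfg <- small_config(seed = 59, genome_length = 2e5, snv_rate = 8e-6,
                      het_density = 3,
                      pedigree_newick = "((A:20,B:20):47,(C:35,D:35):32);",
                      n_replicate_samples = 0)
  ref <- simulate_genome(cfg)
  truth <- simulate_mutations(ref, cfg)
  sim <- simulate_site_table(truth, ref, cfg)
  f <- apply_site_postfilters(apply_hard_filters(sim$sites))
  calls <- call_somatic(f)
  shared <- calls[calls$n_carriers >= 2 & calls$var_type == "snv", ]
  expect_gt(nrow(shared), 3)
  phased <- sim$sites[, c("chrom", "pos", "sample", "pgt", "ps")]
  res <- haplotype_identity_test(shared, phased)
  expect_false(any(res$phase_class == "different"))
  expect_gt(sum(res$phase_class == "same"), 0)
})

test_that("sharing summary reports the printed rounding convention", {
  expect_equal(percent_of(2612, 3037), 86.0)
  expect_equal(percent_of(170, 208), 81.7)
  calls <- mk_calls(c(rep(list(c("A", "B")), 2), list("A", "C")))
  calls$phase_class <- c("same", "unphased", "same", NA)
  s <- sharing_summary(calls)
  expect_equal(s$n[s$metric == "total"], 4)
  expect_equal(s$n[s$metric == "shared"], 2)
  expect_equal(s$percent[s$metric == "shared"], 50.0)
  expect_equal(s$n[s$metric == "shared_phased"], 1)
  # empty input: zero report
  s0 <- sharing_summary(mk_calls(list())[0, ])
  expect_equal(s0$n[s0$metric == "total"], 0)
})
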