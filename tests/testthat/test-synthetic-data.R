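test_that("sim_config validates its invariants", {
  expect_error(sim_config(genome_length = 500), "1 kb")
  expect_error(sim_config(annotation_fractions = c(exon = 0.5, intron = 0.5,
                                                   intergenic = 0.1)),
               "sum to 1")
  expect_error(sim_config(snv_rate = -1), "snv_rate")
  expect_error(sim_config(pedigree_newick = "not a tree"), "newick")
  expect_s3_class(sim_config(genome_length = 1e4), "sim_config")
})

test_that("simulated genome matches its composition targets", {
  cfg <- small_config(seed = 42, genome_length = 1e6, gc_content = 0.5)
  ref <- simulate_genome(cfg)
  # binomial 3-sd band around the requested GC
  sd3 <- 3 * sqrt(0.5 * 0.5 / 1e6)
  expect_lt(abs(ref$gc_observed - 0.5), sd3)
  # annotation tiles the genome without overlap, class totals exact
  ann <- ref$annotation
  by_chrom <- split(ann, ann$chrom)
  for (a in by_chrom) {
    a <- a[order(a$start), ]
    expect_equal(a$start[-1], a$end[-nrow(a)] + 1L)
    expect_equal(a$start[1], 1L)
  }
  widths <- tapply(ann$end - ann$start + 1, ann$class, sum)
  expect_equal(unname(widths["exon"]) / 1e6, 0.07, tolerance = 1e-3)
  expect_equal(unname(widths["intron"]) / 1e6, 0.13, tolerance = 1e-3)
})

test_that("het_density zero yields no background heterozygous sites", {
  ref <- simulate_genome(small_config(het_density = 0, genome_length = 5e4))
  expect_equal(nrow(ref$het_sites), 0L)
})

test_that("annotation fractions are realized up to rounding", {
  cfg <- small_config(genome_length = 1e6, n_chromosomes = 1,
                      annotation_fractions = c(exon = 0.1, intron = 0.3,
                                               intergenic = 0.6))
  ref <- simulate_genome(cfg)
  widths <- tapply(ref$annotation$end - ref$annotation$start + 1,
                   ref$annotation$class, sum)
  expect_equal(unname(widths["exon"]), 1e5, tolerance = 1e-3)
})

test_that("branch mutation counts follow the Poisson mean", {
  # arithmetic of the expectation itself
  expect_equal(expected_branch_mutations(1e-8, 67, 4.08e8), 546.72)
  # one realized draw lies within 3*sqrt(lambda) of the mean (scaled genome)
  cfg <- small_config(seed = 7, genome_length = 1e6, n_chromosomes = 2,
                      snv_rate = 4e-6, indel_rate = 0,
                      pedigree_newick = "(A:67);", n_replicate_samples = 0)
  ref <- simulate_genome(cfg)
  truth <- simulate_mutations(ref, cfg)
  lambda <- expected_branch_mutations(4e-6, 67, 1e6)
  expect_lt(abs(nrow(truth$branch_mutations) - lambda), 3 * sqrt(lambda))
})

test_that("zero mutation rate yields zero mutations", {
  cfg <- small_config(snv_rate = 0, indel_rate = 0)
  ref <- simulate_genome(cfg)
  truth <- simulate_mutations(ref, cfg)
  expect_equal(nrow(truth$branch_mutations), 0L)
})

test_that("stem mutations of a shared branch reach all descendant leaves", {
  cfg <- small_config(seed = 3, snv_rate = 2e-6, indel_rate = 0,
    pedigree_newick = "((A:10,B:10,C:10,D:10):57);")
  ref <- simulate_genome(cfg)
  truth <- simulate_mutations(ref, cfg)
  stem <- truth$branch_mutations[!truth$branch_mutations$branch %in%
                                   c("A", "B", "C", "D"), ]
  expect_gt(nrow(stem), 0)
  for (leaf in c("A", "B", "C", "D")) {
    la <- truth$leaf_assignments[truth$leaf_assignments$leaf == leaf, ]
    expect_true(all(site_in(stem, la)))
  }
  # union property: every leaf set equals the union over its root path
  for (leaf in c("A", "B", "C", "D")) {
    la <- truth$leaf_assignments[truth$leaf_assignments$leaf == leaf, ]
    own <- truth$branch_mutations[truth$branch_mutations$branch == leaf, ]
    expect_equal(nrow(la), nrow(own) + nrow(stem))
  }
})

test_that("shared mutations sit on one haplotype in all carriers", {
  cfg <- small_config(seed = 9, snv_rate = 2e-6,
    pedigree_newick = "((A:10,B:10):57,(C:30,D:30):37);")
  ref <- simulate_genome(cfg)
  truth <- simulate_mutations(ref, cfg)
  la <- truth$leaf_assignments
  per_mut <- split(la$hap, site_key(la$chrom, la$pos))
  shared <- per_mut[lengths(per_mut) >= 2]
  expect_gt(length(shared), 0)
  expect_true(all(vapply(shared, function(h) length(unique(h)) == 1,
                         logical(1))))
})

test_that("neutral context multipliers give a uniform 6-class spectrum", {
  cfg <- small_config(seed = 21, genome_length = 5e5, gc_content = 0.5,
                      snv_rate = 2e-6, indel_rate = 0)
  ref <- simulate_genome(cfg)
  truth <- simulate_mutations(ref, cfg)
  bm <- truth$branch_mutations
  spec <- classify_spectrum(bm, ref)
  counts <- spec$class6$count
  # multinomial chi-square against uniform; generous alpha for a hard gate
  p <- stats::chisq.test(counts, p = rep(1 / 6, 6))$p.value
  expect_gt(p, 0.001)
})

test_that("site tables are deterministic given the seed and respect truth", {
  cfg <- small_config(seed = 5)
  ref <- simulate_genome(cfg)
  truth <- simulate_mutations(ref, cfg)
  s1 <- simulate_site_table(truth, ref, cfg)
  s2 <- simulate_site_table(truth, ref, cfg)
  expect_identical(s1$sites, s2$sites)
  expect_identical(s1$replicates, s2$replicates)

  # no alt reads at hom-ref truth when sequencing error is zero
  cfg0 <- small_config(seed = 6, seq_error = 0, mean_depth = 100)
  ref0 <- simulate_genome(cfg0)
  truth0 <- simulate_mutations(ref0, cfg0)
  s0 <- simulate_site_table(truth0, ref0, cfg0)
  homref <- s0$sites[s0$sites$truth_gt == "0/0", ]
  expect_true(all(homref$ad_alt == 0))

  # heterozygous truth: alt fraction within the binomial 95% band
  het <- s1$sites[s1$sites$truth_gt == "0/1" & s1$sites$dp >= 40, ]
  frac <- het$ad_alt / het$dp
  expect_gt(mean(frac >= 0.30 & frac <= 0.70), 0.95)
})
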