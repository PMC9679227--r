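# clonemut

Somatic mutation analysis for clonally propagated plant lineages.

Trees multiplied by cuttings are near-identical copies of one founder.
The differences — somatic mutations picked up in meristems and inherited
by downstream cuttings — carry a lot of information: how fast the genome
mutates per base per year, which sequence contexts are fragile, how the
cuttings are related, and whether the new alleles are tolerated by
selection. `clonemut` turns multi-sample variant calls for a set of
clonemates into those answers, and ships a synthetic clonal-lineage
generator with known ground truth so the entire pipeline is testable
without raw sequencing data.

Every user-facing function takes a data frame and returns a tibble, so
stages chain with the pipe; results have `tidy()`/`glance()` methods and
`autoplot()`/`plot_*()` figures.

## What it computes

* **Hard-filter cascade and post-filters** for multi-sample VCFs
  (`apply_hard_filters()`, `apply_site_postfilters()`): the GATK-style
  predicates `FS > 60 || MQ < 40 || MQRankSum < -12.5 || QD < 2 ||
  ReadPosRankSum < -8 || SOR > 3` (SNPs) and
  `QD < 2 || FS > 200 || ReadPosRankSum < -20` (indels), then depth-,
  GQ-, indel-proximity- and missingness-based cleanup.
* **Somatic calling among clonemates** (`call_somatic()`,
  `strand_filter()`, `sv_mask()`, `indel_somatic_filter()`): genotype
  heterogeneity against the founder genotype, with both-strand support
  and strand ratio < 2 on the mutant allele, recurrent-SV masking and
  indel read-support rules.
* **Error calibration** (`estimate_fp()`, `spike_in_sensitivity()`):
  false positives from triplicate re-sequencing concordance; detection
  sensitivity from synthetic spike-in mutations pushed through the same
  pipeline.
* **Corrected mutation rate** (`point_rate()`, `bootstrap_ci()`):

      rate = mean_count * (1 - FP) / (years * 2 * genome_size * sensitivity)

  with a percentile bootstrap over samples for the 95% CI.
* **Spectrum and context** (`classify_spectrum()`, `titv()`, `at_bias()`,
  `context_enrichment()`, `flanking_composition()`): 6-class
  strand-collapsed spectrum, Ti/Tv, content-corrected AT bias, CpG/CHG/CHH
  enrichment with exact binomial tests (BH-corrected), flanking base
  composition.
* **Sharing, phasing, pedigree** (`polarize_derived()`,
  `sharing_matrix()`, `build_pedigree()`, `haplotype_identity_test()`):
  outgroup polarization, greedy perfect-phylogeny reconstruction of the
  cutting pedigree, and a phased-haplotype identity test for mutations
  shared by several clonemates.
* **Genomic context** (`het_vs_distance()`, `annotation_chisq()`,
  `recomb_regression()`): heterozygosity/diversity versus distance to the
  nearest mutation with a random-site control, Yates-corrected annotation
  burden tests, and recombination-rate regression over 50 kb windows.
* **Selection and deleteriousness** (`deleterious_consensus()`,
  `classify_selection()`): SIFT/PROVEAN/PolyPhen consensus calls and
  outgroup allele-frequency selection classes (>95% post-mutation
  frequency = positive, >95% pre-mutation = purifying).
* **Synthetic data** (`sim_config()`, `simulate_genome()`,
  `simulate_mutations()`, `simulate_site_table()`, `run_pipeline()`):
  diploid genome, pedigree-structured Poisson mutations with
  methylation-context multipliers, read-count sampling with strand noise,
  triplicates, and standard-format emitters (FASTA/VCF/BED/TSV/newick/
  NEXUS).

## Worked example

Simulate an 11-leaf cutting lineage, call somatic mutations, calibrate the
errors and estimate the rate:

```r
library(clonemut)

cfg <- sim_config(genome_length = 2e5, snv_rate = 2e-7, seed = 5,
                  n_replicate_samples = 2)
res <- run_pipeline(cfg, fp_mode = "truth", n_spikein = 300)
res
#> <pipeline_result>
#>   53 somatic calls (52 SNV, 1 indel) across 11 samples
#>   fp 0.05769, sensitivity 0.517 -> rate 3.53e-07 per bp per year
```

Of the 53 genotype-heterogeneous sites that survive filtering, 52 are
SNVs; at 21x depth the strand and quality filters catch only about half
of the true events (spike-in sensitivity 0.52), and after the FP and
sensitivity corrections the per-sample counts give a rate estimate within
sampling error of the simulated truth (the generator's default context
multipliers make the realised genome-wide rate slightly above the nominal
`snv_rate`). The corrected-rate arithmetic itself:

```r
point_rate(312.5, 67, 4.08e8, fp_rate = 0.032, sensitivity = 0.596)
#> [1] 9.283552e-09
```

That is: a mean of 312.5 somatic SNPs per sample accumulated over 67
years on a 408 Mb diploid genome, corrected for a 3.2% false-positive
rate and 59.6% detection sensitivity, is ~9.3e-9 mutations per base per
year.

Downstream characterisation chains off the same result object:

```r
spec <- classify_spectrum(res$calls, res$ref)
titv(spec)
plot_spectrum(spec)
context_enrichment(res$calls, res$ref)
ped <- build_pedigree(sharing_matrix(res$calls))
plot_pedigree(ped)
```

See `vignettes/clonemut-methods.Rmd` for the models, assumptions,
parameter choices and known limitations.

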