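---
title: "Somatic mutations in clonal plant lineages: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Somatic mutations in clonal plant lineages: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clonemut)
```

## The problem

Trees propagated by cuttings are genetically near-identical copies of a
founder plant, but not perfect copies: somatic mutations arise in meristem
tissue and are inherited by every cutting taken downstream of the mutated
sector. Given whole-genome variant calls for a set of clonemates, one can
ask how fast somatic mutations accumulate per base per year, where in the
genome they fall, whether mutations shared by several individuals really
descend from a common mutated ancestor (and therefore sit on one
haplotype), what the cutting pedigree looked like, and whether the derived
alleles are seen by selection in a sexually reproducing relative.

`clonemut` implements that whole analysis as composable functions over
tidy data frames, together with a synthetic clonal-lineage generator so
every stage can be exercised and validated against known truth without
access to raw sequencing data.

## The observation model the simulator emulates

The generator (`sim_config()`, `simulate_genome()`, `simulate_mutations()`,
`simulate_site_table()`) produces:

* **A diploid genome.** Chromosome sequences drawn i.i.d. at a configured
  GC content (default 0.35, a plausible placeholder for a poplar-like
  genome; the true context composition of any real genome is an input, not
  an estimate). Annotation intervals (exon/intron/intergenic; defaults
  0.07/0.13/0.80) tile each chromosome in repeated cycles so class totals
  are exact up to rounding.
* **Elevated background heterozygosity.** Founder heterozygous sites are
  placed uniformly at `het_density` per kb (default 2/kb — clonally
  propagated lineages descend from an outbred founder and carry more
  heterozygosity than their sexual relatives). Every clonemate inherits
  all of them, each on a fixed founder haplotype.
* **Pedigree-structured mutation accumulation.** On each branch of the
  cutting pedigree (newick, branch lengths in years) SNV events arrive as
  a Poisson process with mean `snv_rate * years * 2 * genome_length`; the
  factor 2 counts both genome copies. Placement is uniform followed by
  acceptance-rejection thinning with the cytosine-context multipliers
  (`CpG`, `CHG`, `CHH`, `nonC`), so the realised per-site rate in context
  *c* is exactly `snv_rate * multiplier[c]`. Each mutation lands on one
  haplotype; positions are unique within the lineage (collisions with
  existing variation are re-drawn and logged). Indels (default rate
  1.77e-9/bp/year) are 1–10 bp, lengths geometric(0.5), insertions and
  deletions equally likely; no length model is claimed beyond plausibility.
* **Read counts.** Per sample and site: depth ~ Poisson(`mean_depth`),
  mutant-allele reads ~ Binomial(depth, VAF) with VAF 0.5 for heterozygous
  truth and error-driven otherwise (`seq_error`/3 toward a specific base),
  and a forward/reverse split ~ Binomial(alt, p) with p ~
  Normal(0.5, `strand_imbalance_sd`). Genotypes are called by a naive
  three-state binomial likelihood; GQ is the phred-scaled gap to the
  second-best genotype. Phased genotypes are emitted in 100 kb phase
  blocks with a random per-sample orientation (phasing within a block is
  taken as correct — real read-based phasing also makes switch errors,
  which this model does not emulate).
* **Triplicates.** Designated samples receive three independent read
  draws conditional on the same truth, mirroring independent library
  preparation and sequencing of one DNA source.

What the simulator deliberately does **not** model: alignment artifacts,
mapping bias, CNV/SV events (masks are consumed as intervals, never
generated), index hopping, or spatially clustered mutations. Passing the
recovery tests therefore shows the statistical machinery is coherent under
the stated model, not that any particular real dataset satisfies it.

## Filtering and somatic calling

`apply_hard_filters()` applies the standard GATK-style site predicates
with OR semantics and strict comparisons (`FS > 60 || MQ < 40 ||
MQRankSum < -12.5 || QD < 2 || ReadPosRankSum < -8 || SOR > 3` for SNPs;
`QD < 2 || FS > 200 || ReadPosRankSum < -20` for indels). A missing
annotation makes a rule non-evaluable rather than a removal.
`apply_site_postfilters()` masks genotypes at depth above 3x (or below
1/3x) the per-sample mean — per-sample means because library depths can
differ several-fold between samples — and at GQ < 10, removes SNVs at or
within 5 bp of an indel (closed interval; the indel span is
`pos .. pos + max(len(ref), len(alt)) - 1`), and then removes SNV sites
whose post-masking genotype missing rate strictly exceeds 25%. GQ masking
(rather than site dropping) was chosen because the depth and missingness
rules are already site-level; masking keeps per-sample information and
lets the missingness rule aggregate it.

`call_somatic()` operationalises "somatic" as genotype heterogeneity
among clonemates. The clone-founder genotype is the majority genotype
(ties break toward the homozygous ancestral state when outgroup genotypes
are supplied, else lexicographically); carriers are the deviating
samples. Carriers whose genotype contains the mutant allele must show it
on both strands with a strand ratio strictly below 2
(`strand_filter()`); multi-allelic sites are excluded and counted rather
than decomposed. Recurrent structural variants mask calls when supported
by a strict majority of samples (`sv_mask()`). Indel sites additionally
need a mean read count of at least 5 and missingness of at most 10%
(`indel_somatic_filter()`).

## Error calibration and the corrected rate

Two error rates calibrate the raw counts (`estimate_fp()`,
`spike_in_sensitivity()`):

* **False positives** from triplicate re-sequencing: candidates are the
  union of a sample's replicate call sets, "true" calls the three-way
  intersection, and the FP rate the erroneous fraction of candidates.
  This estimator is exact only when per-replicate recall is 1: a true
  mutation missed in one replicate of three is counted as erroneous, so
  with per-replicate recall *p* the estimator tends to
  `1 - p^3 / (1 - (1-p)^3)` even with no true false positives. At
  moderate depth this bias dominates. The simulation-based recovery
  analysis therefore corrects with the measured false-call fraction
  against truth (`run_pipeline(fp_mode = "truth")`), while
  `fp_mode = "replicates"` reproduces the concordance method.
* **Sensitivity** from spike-ins: `n` synthetic substitutions are placed
  at uniform unoccupied positions in one sample and pushed through the
  identical filter and calling pipeline. A spike-in is *callable* when
  its mutant-allele covered reads exceed 3; the reported statistic is
  `(callable - filtered_callable) / n`. The spiked VAF defaults to 1
  (homozygous spike-ins, as in reads-modification protocols), but the
  strand-ratio filter passes a homozygous site (~25 mutant reads at 25x)
  far more often than a heterozygous one (~12 reads), ~0.89 versus
  ~0.71 at 25x, so homozygous spike-ins overestimate the sensitivity for
  hom→het somatic events by ~20%. When the statistic is used to correct
  heterozygous somatic counts, `vaf = 0.5` is the consistent choice and
  is the default in `run_pipeline()`; both modes are exposed.

The corrected rate (`point_rate()`) is

```
rate = mean_count * (1 - fp_rate) / (years * 2 * genome_size * sensitivity)
```

with `mean_count` the mean per-sample somatic count, 2 the diploid
factor, and division (not multiplication) by the spike-in sensitivity —
the only reading under which the published worked example (mean count
312.5, 67 years, 408 Mb, FP 3.2%, sensitivity 0.596) reproduces the
printed ~9.2e-9 per bp per year. Confidence intervals are nonparametric
percentile bootstraps over samples (`bootstrap_ci()`, 1000 replicates by
default); the original analysis does not state its CI method, and the
bootstrap makes the fewest assumptions at n = 11 samples.

```{r rate}
point_rate(312.5, 67, 4.08e8, fp_rate = 0.032, sensitivity = 0.596)
```

## Spectrum and context statistics

`classify_spectrum()` collapses the 12 substitution types onto the 6
pyrimidine-rooted classes, checks call/reference consistency, and counts
flanking dinucleotides and the trinucleotides containing the mutation at
positions 1, 2 and 3. `titv()` and `at_bias()` follow their textbook
definitions, the latter normalised by genomic G/C and A/T base counts.

`context_enrichment()` evaluates cytosine methylation contexts
strand-symmetrically (a G is a minus-strand C classified by its left
neighbours). The reported `enrichment` is the relative rate
`rate(c) / rate(not c)`: under the generative model with multiplier *m*
this estimates *m* directly, whereas normalising by the overall mean rate
(also reported, as `enrichment_vs_mean`) deflates the fold for common
contexts because the enriched context inflates the mean. Significance is
a one-sided exact binomial test of the context's mutation share against
its genomic site share, BH-corrected: one-sided because the question is
enrichment, and a two-sided test would flag the mechanical depletion of
bystander contexts whenever one context is elevated. Triplet enrichment
corrects per triplet (each triplet's own genomic count), not per class.

## Sharing, phasing and the pedigree

`polarize_derived()` accepts a call as derived only when two outgroup
populations are fixed for the same homozygous genotype — a deliberately
conservative rule. `build_pedigree()` is a greedy perfect phylogeny on
the mutation-by-sample sharing matrix: carrier sets are placed largest
first (ties in genomic order, which makes the result invariant to row
permutations), a set is accepted iff nested-or-disjoint with every
accepted clade, and conflicting sets are reported as homoplasy rather
than forced into the tree. On clonal truth, where every shared mutation
is genuinely monophyletic, this recovers the cutting topology exactly
once every branch carries at least one private mutation.

`haplotype_identity_test()` asks, for each shared call, whether the
somatic allele co-occurs with the same heterozygous-neighbour allele on
one phase in every carrier (neighbours must be phased heterozygous in
all carriers within each carrier's phase block). Clonally inherited
mutations can only be `same` or `unphased`; a `different` verdict
indicates recurrent mutation or a phasing/calling artifact. The
orientation of each phase block is arbitrary per sample, and the test is
invariant to it.

## Genomic context analyses

`het_vs_distance()` bins genotyped sites by distance to the nearest
somatic call (ties to the left, the call site itself excluded) and
reports both the heterozygous fraction and per-site nucleotide diversity
(pi with the small-sample `2n/(2n-1)` correction) per bin — the two
statistics used interchangeably in this literature — stratified by the
annotation class of the nearest call, plus the same profile around
uniformly random control positions. Empty bins are missing, not zero.
`annotation_chisq()` is the two-cell Yates-corrected goodness-of-fit
statistic `sum((|O - E| - 0.5)^2 / E)` with df = 1.
`recomb_regression()` classes 50 kb windows by somatic-SNP count
(0..5 and >=6 pooled — seven classes; a quantile mode is provided since
the binning rule is not canonical), and regresses class mean recombination
rate on class index by OLS.

## Selection and deleteriousness

`deleterious_consensus()` requires all three predictors to agree
(SIFT <= 0.05, PROVEAN < -2.5 strict, PolyPhen > 0.5 strict); any missing
score is unscorable, never silently tolerated. `classify_selection()`
computes pre- and post-mutation allele frequencies from outgroup called
genotypes (missing genotypes leave the denominator — the simplest
estimator; no correction for small outgroup samples is attempted) and
applies the strict >95% thresholds; positive and purifying classes are
mutually exclusive at a biallelic site. The ingroup minor-allele-frequency
floor (0.1) applies to the derived-allele burden summary
(`derived_allele_burden()`), not to selection classification.

## Numerical conventions and degenerate inputs

* Printed percentages round half away from zero (`percent_of()`), one
  decimal by default, so worked examples are deterministic.
* Coordinates are 1-based closed everywhere in memory (the native R and
  VCF convention); BED I/O converts at the boundary.
* One run seed drives everything; each module derives a sub-stream
  (`seed + k * 1009 mod 2^31`) so partial reruns reproduce.
* Degenerate inputs have defined behaviour: depth 0 is a missing
  genotype; empty call sets yield all-zero tables; zero transversions,
  zero A/T→G/C counts, single samples, and zero-sensitivity corrections
  are errors, not silent NaNs.

## Problem sizes used in the validation suite

The packaged tests validate at scaled-down sizes chosen to keep the suite
interactive while leaving enough events for the statistics to bind:
100 kb–600 kb genomes with inflated mutation rates for unit tests, and
for the end-to-end rate recovery a 10-leaf star pedigree (all cuttings
from one founder — the lowest-variance realistic plantation design) over
67 years on a 10 Mb genome at 25x depth, three seeds per rate with the
seed-averaged estimate compared at ±15%. At 5e-9/bp/year a 10 Mb genome
yields only ~7 true mutations per sample, so the per-seed sampling error
alone is 12–15%; averaging three seeds brings the Monte Carlo error
within the band. The recovery experiment uses neutral context multipliers
because its estimand is the genome-wide mean rate, which multipliers
would redefine.

## Known limitations

* The triplicate-concordance FP estimator conflates imperfect
  per-replicate recall with false positives (see above); its output
  should only be multiplied into the rate when per-replicate recall is
  near 1.
* The generator's error-candidate sites arise at a fixed density rather
  than from an alignment model, so absolute FP rates in simulation are
  not calibrated to any platform.
* `het_vs_distance()` treats the genotype table as the universe of
  assayable sites; ascertainment of that table is the caller's
  responsibility.
* The pedigree reconstruction assumes clonal (tree-like) inheritance;
  under recurrent mutation it reports homoplasy but does not resolve it.
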