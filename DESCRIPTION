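Package: clonemut
Title: Somatic Mutation Calling, Rate Estimation and Mutational Patterns in
    Clonally Propagated Plant Lineages
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidy pipeline for detecting somatic mutations among clonally
    propagated (cutting-derived) plant individuals from multi-sample variant
    calls, calibrating the detection error rates, and characterising the
    resulting mutations. Includes a synthetic clonal-lineage data generator
    with known ground truth (diploid genome, pedigree-structured Poisson
    mutation accumulation with methylation-context rate multipliers,
    read-count sampling with strand noise and triplicate re-sequencing);
    GATK-style hard-filter and post-filter cascades; strand-bias,
    structural-variant and indel somatic filters; false-positive estimation
    from triplicate concordance and sensitivity estimation from spike-in
    mutations; corrected per-base per-year mutation-rate estimation with
    bootstrap confidence intervals; mutation spectrum, Ti/Tv, AT-bias and
    CpG/CHG/CHH context enrichment; derived-mutation polarisation, clonal
    pedigree reconstruction and a phased-haplotype identity test for shared
    mutations; heterozygosity-versus-distance profiles, annotation
    chi-square tests and recombination-window regression; and consensus
    deleteriousness plus outgroup allele-frequency selection classification.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    tools,
    utils,
    vcfR,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
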