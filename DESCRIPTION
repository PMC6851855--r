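Package: triadkit
Title: Homoeolog-Resolved CRISPR Genotyping, Trait Dosage Statistics and
    Domestication Diversity Analysis for Hexaploid Wheat
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for gene-editing experiments targeting
    homoeologous gene triads in allohexaploid wheat. Assigns amplicon
    sequencing reads to the A, B and D subgenome copies using diagnostic
    bases, calls and left-normalizes Cas9-induced indels, tabulates allele
    frequencies and per-plant zygosity with functional-copy counts.
    Summarizes grain morphometric and thousand-grain-weight phenotypes by
    genotype with percent change, pooled-variance t tests, one-way ANOVA
    with Tukey post-hoc comparisons and gene-dosage trend reports. Builds
    focal-gene Pearson co-expression networks from quantile-normalized TPM
    matrices with global and local edge thresholds, and performs Fisher
    exact GO term enrichment with Benjamini-Hochberg correction. Computes
    per-site and windowed nucleotide diversity and Hudson F_ST sweep scans
    from VCF genotypes, genic haplotype frequency tables and
    between-population haplotype tests, and Kimura 2-parameter
    neighbor-joining phylogenies with bootstrap support. Includes synthetic
    generators for all input kinds with ground-truth tables so every stage
    is testable end to end.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    limma,
    ape,
    vcfR,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
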