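Package: scafphase
Title: Dual-Scaffold Competitive Alignment for Genotyping and Phasing
    Complex Variants
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects and phases complex structural variants from short
    paired-end reads by competitive alignment to a pair of customized
    reference scaffolds: a wild-type scaffold and a mutant scaffold that
    carries the insertion allele plus an engineered marker base whose
    predetermined variant call flags insertion-bearing reads.  Includes a
    diploid paired-end read simulator, a seed-and-extend affine-gap
    aligner with soft clipping, pileup-based zygosity calling at
    informative sites with a genotype/phase decision table, a
    single-reference comparison mode demonstrating reference bias, and
    carrier-rate statistics (two-sided Fisher's exact tests) for cohort
    comparisons.  The worked example is the cystathionine beta-synthase
    (CBS) c.833T>C single-nucleotide variant and the 68 bp tandem
    duplication insertion c.844_845ins68, whose cis/trans configuration
    determines clinical significance.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
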