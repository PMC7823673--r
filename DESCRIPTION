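Package: twinhap
Title: Noninvasive Paternity, Zygosity and Fetal Fraction Analysis for
    Twin Pregnancies from Microhaplotype cfDNA Profiles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Interprets maternal plasma cell-free DNA read counts over a
    multiallelic microhaplotype panel for twin pregnancies. Detects
    nonmaternal (assumed paternal) alleles against the maternal genotype,
    classifies locus patterns, calls twin zygosity (monozygotic vs
    dizygotic) from informative loci, estimates per-fetus and combined
    fetal fractions from fetal allele read ratios, and computes likelihood
    ratios for paternity under three competing hypotheses (alleged father
    of both twins, heteropaternal superfecundation, unrelated fathers)
    using a qualitative DNA-mixture model with per-contributor dropout,
    drop-in and mutation. Includes a synthetic-data generator for
    twin cfDNA sequencing experiments with known ground truth.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
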