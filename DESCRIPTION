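Package: cubne
Title: Codon Usage Bias, Selection Tests, and Effective Population Size
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to quantify codon usage bias with the effective number of
    codons (ENC) and its background-corrected variant (ENCp), and to test
    whether that bias is shaped by selection and predicted by effective
    population size. Implements per-gene chi-squared tests of observed versus
    expected codon usage with false-discovery-rate control, a polarized
    McDonald-Kreitman contrast of unpreferred-to-preferred versus
    preferred-to-unpreferred codon changes with an intronic imaginary-codon
    null and CpG mis-polarization filters, likelihood-ratio tests between the
    FMutSel0 and FMutSel mutation-selection codon substitution models on
    pairwise alignments, and phylogenetically controlled comparative
    statistics (generalized least squares with Pagel's lambda, independent
    contrasts, ancestral states, compartment ANCOVA, bootstrap median
    intervals). A mutation-selection-drift simulator generates coding
    sequences, polymorphism/divergence site tables, pairwise codon
    alignments, and trait-bearing phylogenies so every stage of the analysis
    can be exercised end to end without external genome downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    methods,
    Biostrings,
    ape,
    MASS
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    nlme,
    Matrix,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
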