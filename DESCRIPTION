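Package: satzone
Title: Satellitome Landscapes and Hybrid-Zone Cline Analysis for Tandem Repeats
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for satellitome analysis of tandem-repeat (TR) DNA and its
    use as a cytological marker system in hybrid zones. Classifies TR consensus
    monomers into subfamilies, families and superfamilies with rotation- and
    strand-aware identity thresholds; builds repeat landscapes in 0.5 percent
    divergence bins and derives the DIVPEAK degeneration index, relative peak
    size (RPS), tandem structure index (TSI) and amplification-burst dates;
    summarizes and compares chromosome band tables between taxa to find
    differential markers; and turns genotype counts along a transect into
    allele-frequency clines with Gardner-Altman paired bootstrap effect sizes.
    A synthetic-data module generates every input with known ground truth:
    monomer libraries with planted family structure, divergence hits from
    amplification-burst evolution, and Hardy-Weinberg or hemizygous transect
    samples under a planted sigmoid cline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
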