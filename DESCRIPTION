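Package: barcodeval
Title: Evaluation of DNA Barcode Loci by Gap, Tree and Best-Match Criteria
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to evaluate candidate DNA barcode loci for species
    discrimination from per-locus sequence collections with species labels.
    Implements the full evaluation pipeline used in plant barcoding surveys:
    Phred-based sequence quality screens (windowed trimming, mean quality
    value, forward/reverse overlap coverage, 5.8S rDNA motif check),
    progressive multiple alignment and multi-locus concatenation, uncorrected
    p-distances under pairwise deletion with per-locus variability summaries
    (variable and parsimony-informative sites), and three species
    discrimination methods: the barcoding-gap criterion (minimum
    inter-specific versus maximum intra-specific distance), neighbor-joining
    bootstrap monophyly at a 50 percent support cutoff, and leave-one-out
    best-match identification against a self database. Includes
    nonparametric locus comparisons (Kruskal-Wallis with Dunn's post hoc,
    exact Wilcoxon matched-pair tests) and a synthetic multi-locus data
    generator with controlled intra- and inter-specific divergence so the
    whole pipeline can be exercised without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    ape,
    phangorn,
    Rcpp,
    stats,
    graphics,
    utils,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
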