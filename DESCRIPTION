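Package: phagelife
Title: Bacteriophage Lifestyle Classification from Lysogeny-Associated
    Protein Domains
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classifies bacteriophage genomes as temperate or virulent from
    nucleotide sequence alone. Genomes are translated in all six reading
    frames, the resulting protein products are searched for a curated set of
    lysogeny-associated conserved protein domains (via HMMER or a built-in
    motif backend), and the resulting presence/absence feature vector is
    scored by a random-forest classifier. The package also provides the full
    model-development machinery (keyword-based domain selection, prevalence
    filtering, 60:40 train/test splitting, hyperparameter grid evaluation
    over repeated validation resplits with max-min-accuracy selection),
    confusion-matrix performance metrics including adjusted balanced
    accuracy and the Matthews correlation coefficient,
    confidence-stratified error analysis, a k-mer containment estimator for
    building phylogenetically independent test subsets, and a synthetic
    fixture generator so the entire pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    purrr,
    ranger,
    readr,
    rlang,
    stringr,
    tibble,
    tidyr,
    withr
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
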