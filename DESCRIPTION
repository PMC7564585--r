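Package: speccount
Title: High-Stringency Spectral Counting and NSAF Quantitation for
    Shotgun Proteomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Converts low-stringency protein identification tables
    exported by peptide-to-spectrum-matching search engines into
    high-stringency, NSAF-quantified datasets. Implements minimum
    spectral counting (MSC) filtering across replicates, normalised
    spectral abundance factor (NSAF) quantitation, two-state
    differential expression testing on lnNSAF with up/down/unchanged/
    unique classification, and a same-same permutation analysis of six
    control replicates that derives an empirical Benjamini-Hochberg
    significance threshold at a target protein-quantitation false
    discovery rate (PQ-FDR). Includes a seeded synthetic spectral-count
    data generator, all standard visualisations (proportional Venn,
    volcano, heatmap, p-value histograms, PQ-FDR curve, PCA), and a zip
    bundle writer mirroring a search-engine workflow's output layout.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml,
    zip
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
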