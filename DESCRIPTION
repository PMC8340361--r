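Package: metstop
Title: Metabolite Modification of Membrane-Binding Sites in PX Domains
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing how metabolite-based post-translational
    modifications of lysine and arginine residues (acetylation, methylation,
    succinylation and relatives) and phosphorylation of Ser/Thr/Tyr intersect
    with the phosphoinositide-binding sites of PX domains. Implements the
    Lipid Specificity Index (LSI), evidence-weighted MET-stop and PIP-stop
    scores (MSS, PSS) over alignment-defined membrane-binding site windows,
    a Membrane Affinity Index classifier, a regression/correlation/paired
    t-test battery over domain feature tables, packaged transcriptions of the
    published PX-domain feature and modification tables, and a synthetic-data
    generator with known ground truth for calibration and power studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    Biostrings,
    tibble,
    tidyr,
    purrr,
    readr,
    rlang,
    stringr,
    ggplot2,
    yaml,
    stats,
    withr
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
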