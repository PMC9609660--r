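Package: rumenbatch
Title: Analysis of In Vitro Rumen Batch-Culture Fermentation Experiments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end analysis of in vitro rumen batch-culture experiments:
    blank correction, cumulation and per-gram normalisation of total gas and
    methane volumes; metabolic hydrogen balance from volatile fatty acid and
    methane stoichiometry (Demeyer equations); end-point fermentation
    summaries (TVFA, acetate:propionate ratio, dry-matter digestibility,
    colorimetric standard curves, amino-acid panel classification); absolute
    qPCR quantification of microbial groups; OTU-table alpha diversity,
    Bray-Curtis dissimilarity and PERMANOVA; and treatment comparison with
    compact significance letters and starred Spearman correlation matrices.
    A synthetic-experiment generator with known ground truth supports
    verification of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    vegan,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
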