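Package: gras2qtl
Title: Co-Dominant Genotype Calling from Amplicon Read Depths and F2 QTL Mapping
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Converts per-locus amplicon read-depth counts from genotyping by
    random amplicon sequencing (GRAS-Di) into co-dominant F2 genotype calls by
    fitting three-component gamma or normal mixtures with an EM algorithm, then
    carries the calls through marker quality control (duplicate collapsing,
    segregation-distortion filtering), genetic linkage-map construction with the
    Kosambi map function, interval and composite interval mapping with
    permutation-based LOD thresholds, and marker-trait association statistics
    (Tukey-Kramer comparisons from raw data or printed summaries). Includes a
    synthetic F2 population generator (trimodal depth matrices, emulated default
    caller output, censored phenotypes) so the whole pipeline is testable
    without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    mclust,
    jsonlite,
    optparse
Config/testthat/edition: 3
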