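Package: exhet
Title: Excess Ancestry Heterozygosity in Recombinant Hybrid Crosses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for detecting environment-dependent selection against
    hybrid incompatibilities from ancestry heterozygosity in recombinant
    (F2/F3) intercrosses. Implements diagnostic-marker filtering and
    ancestry polarization for pedigreed crosses genotyped with
    microsatellites, SNP arrays, or genotyping-by-sequencing; individual-
    and locus-level observed, expected, and excess ancestry heterozygosity;
    linear mixed-model contrasts of field versus laboratory environments;
    robustness analyses (single-marker resampling, genotyping-error and
    selection-strength simulations, bootstrap correlation tests); a
    synthetic cross-data generator with optional viability selection; and
    Fisher-geometric-model simulations linking ancestry heterozygosity to
    phenotypic mismatch in hybrids.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    readr,
    rlang,
    withr,
    yaml,
    lme4,
    emmeans,
    vcfR,
    ggplot2,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
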