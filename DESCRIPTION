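Package: tuskDNA
Title: Ancient DNA Recovery Analysis for Mammoth Ivory Sequencing Libraries
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Simulates partial-UDG ancient-DNA sequencing libraries from
    mammoth ivory (short fragments, terminal C-to-T deamination, substrate
    effects, X-chromosome dosage, mtDNA capture enrichment) and analyses
    them end to end: terminal trimming, deduplication and pileup of aligned
    reads, per-library DNA-recovery metrics, majority-rule mitogenome
    consensus calling with a completeness filter, ChrX:Chr8 read-ratio
    genetic sexing, and the exact binomial, Fisher, Shapiro-Wilk and paired
    t tests used to compare substrates and sex ratios.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
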