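Package: cardiosplice
Title: From a Cardiac Sodium-Channel Splicing Switch to Conduction Delay
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools to trace the functional consequences of the mutually exclusive
    SCN5A exon 6A/6B splicing switch seen in myotonic dystrophy heart. The package
    generates fully synthetic versions of every input the analysis chain consumes
    (two-electrode voltage-clamp current families, gel-shift binding curves,
    restriction-digest gel band tables, exon cohorts with intronic flanks, qPCR Ct
    tables), fits channel biophysics (Boltzmann steady-state activation and
    inactivation, inactivation time constants, recovery, Hill binding curves),
    scores MBNL-type YGC 4-mer motif enrichment around misregulated exons with an
    exact binomial test against control exons, quantifies exon inclusion (PSI) from
    BstBI-digested band intensities, and simulates the electrophysiological
    consequences: a one-dimensional transmural ventricular wedge with unipolar
    pseudo-ECG and QRS measurement, and an atrium-to-AV-node strand reporting the
    atrium-His interval.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    jsonlite,
    minpack.lm,
    Rcpp,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
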