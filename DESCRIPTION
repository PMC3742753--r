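Package: fusionchip
Title: Fusion Gene Detection from Exon-Junction Probe Microarrays
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Scores and ranks candidate fusion genes from exon-junction
    probe microarray intensities. Chimeric probes spanning every possible
    exon-exon boundary between two fusion partners are assembled into a
    breakpoint heatmap, half-binder striping artifacts are filtered,
    isolated strong chimeric probes are enhanced, and each candidate
    breakpoint is scored by combining the (capped) chimeric evidence with
    the 5'/3' expression discontinuity of both partner genes measured by
    intragenic exon probes. Includes a panel-scale junction-probe design
    module and a synthetic-data simulator for end-to-end rank-recovery
    experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
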