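Package: cas3audit
Title: Guide Design, Off-Target Enumeration, and Large-Deletion Calling
    for CRISPR-Cas3 Editing Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for auditing Type I-E CRISPR-Cas3 genome editing from
    targeted capture sequencing. Implements in-silico crRNA screening
    (AAG PAM, GC and positional filters, genome-uniqueness checks),
    genome-wide potential off-target (POT) site enumeration for Cas3
    (PAM-anchored consecutive-match and mismatch-tolerant rules) and Cas9
    (NGG, mismatch budget), capture-window construction, large-deletion
    calling from split-read and discordant-pair evidence with a
    treated-versus-control cut-point rule, control-subtraction off-target
    scoring, windowed indel quantification, neighboring-gene impact
    annotation, and a fully seeded synthetic-data generator that emulates
    one-sided Cas3 deletion libraries with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    data.table,
    stats,
    utils,
    yaml
Suggests:
    BiocGenerics,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
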