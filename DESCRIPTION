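Package: airrkit
Title: Schema-Driven Tools for AIRR Rearrangement TSV Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Reading, writing, validation, and conversion machinery for
    annotated immune-receptor (IG/TR) rearrangement tables in the AIRR
    Community tab-separated format. Provides the versioned rearrangement
    schema as data, strictly typed and null-aware TSV input/output,
    splittable-file access from arbitrary byte offsets (plain text and
    blocked gzip), rule-based record and dataset validation,
    CIGAR/BTOP alignment-encoding algebra with coordinate-convention
    transforms, mapping-driven conversion from legacy tabular dialects,
    and a synthetic V(D)J recombination simulator that produces fully
    consistent annotated records for testing entire toolchains without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    yaml,
    jsonlite,
    Biostrings,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    Rsamtools
Config/testthat/edition: 3
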