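Package: nereidkey
Title: Descriptive Taxonomy Engine with the Nereididae Genus Dataset
Version: 0.9.0
Authors@R:
    person("Museums", "Collective", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for descriptive taxonomy built around coded
    taxon-by-character matrices: natural-language descriptions, minimal
    diagnoses at a chosen diagnostic level, dichotomous/polytomous key
    generation and routing, and interactive multi-entry identification.
    Reads and writes a documented DELTA-style text dialect, NEXUS
    morphology matrices and a canonical JSON serialisation.  Ships a
    transcription of the genus-level morphological dataset for the
    polychaete family Nereididae (45 genera scored for 186 characters)
    together with the printed dichotomous key to genera and the printed
    minimal and secondary diagnoses, plus a synthetic-matrix generator
    for property-based testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    withr,
    ape,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
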