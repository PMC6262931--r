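Package: copelink
Title: Carbon Flux Budgets for the Metazoan-Copepod Trophic Link
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify the global carbon flux from metazoan prey
    (nauplii, larvae, eggs) to small copepods and to propagate it through a
    steady-state C and N budget of the upper 100 m of the ocean. The pipeline
    filters plankton-abundance databases to calanoid/cyclopoid composition
    profiles, estimates weight-specific ingestion rates from feeding-study
    meta-analyses by log-log allometric regression, scales global adult
    copepod standing stocks through a correction chain, converts stocks and
    rates to annual carbon ingestion scenarios, and closes a stoichiometric
    C:N ledger with physiological rate constants and export splits (higher
    trophic levels, remineralization, DOM, sinking). A sequence module
    clusters copepod gut-content clone libraries into operational taxonomic
    units at a divergence threshold and summarises diet incidence across
    oceanographic conditions. Synthetic-data generators with planted ground
    truth make every stage testable without external databases.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    withr,
    Biostrings
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
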