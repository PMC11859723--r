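Package: caulokit
Title: High-Resolution Phylogenetics with Minimally Monophyletic Groups
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for ancestor-descendant ("caulogram") analysis of
    morphological trait matrices: identification of minimally monophyletic
    groups (microgenera) around a most-generalist, most-outgroup-similar
    ancestral species; extraction of each species' newly evolved trait set
    (novon); Shannon-bit sequential-Bayes support with odds-to-posterior
    conversion and extinction-gap detection; a geometric inscribed-polygon
    model of balanced peripatric speciation with Zipf and exponential
    ("meta-law") rank-law comparison; hollow-curve diagnostics of
    species-per-genus distributions; and a seeded peripatric-radiation
    simulator that generates planted trait matrices and genus-size samples
    for method validation. Includes a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
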