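Package: dendrisorb
Title: United-Atom Simulation and Analysis of Silicon-Containing Dendrimer Adsorption
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds united-atom models of four homologous series of
    silicon-containing dendrimers (two carbosilane series differing in core
    functionality, two siloxane series differing in spacer length), integrates
    their dynamics above an attractive 9-3 Lennard-Jones wall with a collisional
    thermostat, and computes the full adsorption-analysis suite: adsorbed-atom
    counts, layer-resolved contact fractions, perpendicular and parallel density
    profiles, per-atom energy audits across adsorption strengths, and gyration
    shape metrics, with replica and time aggregation.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    bio3d,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
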