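Package: gshbuffer
Title: Oxygen-Linked Glutathione Buffering by Hemoglobin
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Models and analysis tools for the oxygen-dependent buffering of
    reduced glutathione (GSH) by hemoglobin in red blood cells. Provides a
    two-state allosteric linkage model that predicts intraerythrocytic free
    GSH from hemoglobin oxygen saturation (stoichiometric-release and
    equilibrium mass-balance variants), forward simulation and one-site
    fitting of isothermal titration calorimetry experiments with full
    thermodynamic decomposition, GSH/GSSG half-cell redox potentials,
    standard-additions quantification, red-cell composition unit
    conversions, and seeded synthetic-data generators for cohort,
    tonometry, calorimetry and standard-additions experiments, together
    with end-to-end analysis pipelines.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    minpack.lm,
    stats,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
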