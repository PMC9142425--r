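Package: fluoroscreen
Title: Suspect Screening and Isotope-Dilution Quantification of PFAS in
    LC-HRMS Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A workflow for characterizing per- and polyfluoroalkyl
    substances (PFAS) in complex environmental matrices such as biosolids
    from liquid chromatography high-resolution mass spectrometry (LC-HRMS)
    data. Provides exact-mass arithmetic on molecular formulas, suspect-list
    curation against a defined schema, diagnostic-fragment annotation of
    data-dependent MS2 spectra, Kendrick-mass-defect homologous-series
    detection, Schymanski identification-confidence assignment, and targeted
    quantification by isotope dilution with blank- and recovery-adjusted
    detection limits. A deterministic synthetic-data generator emulates the
    full study design (calibration series, sample/blank replicates, suspect
    features with fragmentation spectra, homologous series and matrix
    decoys) so every stage of the pipeline can be exercised without
    instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    mzR,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
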