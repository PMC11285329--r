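Package: speclean
Title: Reproducible Cleaning of Annotated MS/MS Spectral Libraries
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for curating annotated tandem mass spectrometry (MS/MS)
    spectral libraries. Harmonizes metadata fields, derives missing fields
    from other fields (ion mode, adduct, parent mass, structure annotations
    from compound names), repairs common annotation errors (salt counterions
    left in the SMILES, parent masses computed from the molar instead of the
    monoisotopic mass, default adducts never updated by submitters,
    internally inconsistent SMILES/InChI/InChIKey triples), and removes
    spectra that fail quality requirements after all repairs have run.
    Pipelines are assembled from single-spectrum filter functions arranged in
    a canonical global order, produce a per-filter processing report, and are
    serialized to YAML workflow files that make a cleaning run exactly
    rerunnable. Reads and writes MGF, MSP and a JSON record dialect. Includes
    a synthetic dirty-library generator with a ground-truth error ledger for
    validating every filter without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    ChemmineOB,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
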