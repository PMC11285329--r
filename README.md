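# speclean

Reproducible cleaning of annotated MS/MS spectral libraries in R.

Public tandem-mass-spectrometry libraries carry community-contributed
metadata, and much of it is subtly wrong: ion modes spelled a dozen ways,
adducts left at the submission default `[M+H]+`, parent masses computed
from the molar instead of the monoisotopic mass, SMILES strings still
containing salt counterions that were never measured, and
SMILES/InChI/InChIKey triples that describe different molecules. Simply
discarding every inconsistent spectrum throws away large amounts of usable
data. `speclean` instead *repairs* annotations whenever the fix is
corroborated by independent metadata fields, and removes only what cannot
be repaired - and it does so reproducibly: every run is deterministic,
produces a per-filter processing report, and is described by a YAML
workflow file that reruns the pipeline byte-identically.

## The model

Every filter is a function from one spectrum to one spectrum (or to a
removal marker). Filters are arranged in a predefined global order -
harmonize, derive, normalize intensities, repair, require - so that fields
are always derived before they are consumed and requirements apply only
after all repairs. The chemistry underneath is the adduct relation

    precursor m/z = (x·M + Δ) / |z|

for an adduct [xM+A−B]^z± with mass shift Δ (gained minus lost species,
electron-corrected), monoisotopic masses from a built-in isotope table,
and 2D structure identity operationalized as equality of InChIKey
first blocks.

Three preset pipelines nest inside each other: `basic` (metadata
harmonization), `default` (+ derivation of missing fields, precursor-m/z
requirement, intensity normalization) and `library_cleaning` (+ all five
annotation repairs and all quality requirements).

## A worked example

```r
library(speclean)

lib <- generateLibrary(200, mixedErrorProfile(), seed = 7)   # dirty library
out <- runPipeline(lib$spectra, buildPreset("library_cleaning"))
reportTotals(out$report)
#>              spectra_in             spectra_out         spectra_removed
#>                     200                     170                      30
#> spectra_with_any_repair
#>                      95
```

200 synthetic spectra go in; 95 are repaired (wrong default adducts,
molar-mass parent masses, salt SMILES, name-only and inconsistent
annotations) and survive, 30 are genuinely unrepairable (too few peaks,
adduct/ion-mode contradictions, unresolvable annotations) and are removed,
170 come out. Scoring against the generator's ground-truth ledger:

```r
scoreCleaning(lib$ledger, out)$per_class
#>               error_class  n fate_match repaired removed
#> 1      inconsistent_inchi 16          1        1       0
#> 2 ionmode_adduct_conflict 11          1        0       1
#> 3       molar_parent_mass 23          1        1       0
#> 4    name_only_annotation 20          1        1       0
#> 5                    none 75          1        0       0
#> 6         salt_counterion 19          1        1       0
#> 7           too_few_peaks 10          1        0       1
#> 8    unrepairable_garbage  9          1        0       1
#> 9    wrong_default_adduct 17          1        1       0
```

`fate_match = 1` in every row: each spectrum met exactly the fate its
injected error class predicts, and no clean spectrum was falsely repaired.

Real libraries are read and written with `readLibrary()` /
`writeLibrary()` (MGF, MSP, JSON), and a run's configuration round-trips
through `writeWorkflowYaml()` / `readWorkflowYaml()`. A thin command-line
front end ships in `inst/scripts/speclean`:

```sh
Rscript inst/scripts/speclean simulate --n 1000 --seed 7 --output dirty.mgf --ledger truth.tsv
Rscript inst/scripts/speclean clean --input dirty.mgf --preset library_cleaning \
    --output cleaned.mgf --report report.tsv --workflow used_workflow.yaml
Rscript inst/scripts/speclean validate --workflow used_workflow.yaml
```

## Package layout

- `R/` - S4 classes (`Spectrum`, `AdductSpec`, `WorkflowConfig`,
  `ProcessingReport`), mass and adduct algebra, structure backends, the
  filter layers, pipeline engine, IO, and the synthetic generator.
- `inst/extdata/` - packaged compound table and metadata key-alias table
  (both plain TSV, user-editable).
- `vignettes/library-cleaning.Rmd` - the methods vignette: model,
  parameters, design decisions, limitations.
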