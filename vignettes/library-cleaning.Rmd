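---
title: "Cleaning annotated MS/MS spectral libraries with speclean"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cleaning annotated MS/MS spectral libraries with speclean}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(speclean)
```

## The problem

Public MS/MS spectral libraries are the raw material for compound
identification by library matching and for training machine-learning models
on fragmentation spectra. Their metadata, however, is contributed by many
submitters over many years: ion modes are spelled a dozen ways, adducts are
left at the submission default, parent masses are computed from the molar
instead of the monoisotopic mass, SMILES strings still carry salt
counterions that were never measured, and SMILES/InChI/InChIKey triples
sometimes describe different molecules. Discarding every inconsistent
spectrum wastes large amounts of usable data; the alternative is to *repair*
errors whenever several independent metadata fields corroborate the fix, and
to remove only what cannot be repaired.

`speclean` implements that strategy as a deterministic pipeline of
single-spectrum filter functions, with three layers:

1. **Harmonization and derivation** - normalize key spellings and ion-mode
   values, extract adduct tokens embedded in compound names, fill a missing
   ion mode from the adduct's charge sign, fill a missing parent mass from
   precursor m/z and adduct, and normalize intensities to a unit base peak.
   Derivation never overwrites a present value.
2. **Repair** - fix annotations when the fix is supported by at least two
   fields: derive structures from a compound name only when the resolved
   mass matches the stored parent mass; drop salt counterions whose removal
   reconciles SMILES and parent mass; replace a molar-mass parent mass by
   the monoisotopic mass of the SMILES; re-assign a default adduct when a
   different common adduct explains SMILES and precursor m/z; and, for
   internally inconsistent annotations, keep exactly the fields whose mass
   matches the parent mass. Repairs never remove a spectrum.
3. **Requirement** - pure predicates that remove what is still wrong after
   all repairs: incomplete or inconsistent annotations, parent masses that
   do not match the SMILES, adduct/precursor/parent mismatches,
   adduct/ion-mode contradictions, and spectra with too few informative
   fragments.

## The adduct model

An adduct $[xM + A - B]^{z\pm}$ relates the neutral monoisotopic mass $M$ to
the measured precursor $m/z$ by

$$\mathrm{precursor\ } m/z = \frac{x M + \Delta}{|z|},\qquad
\Delta = \sum_{\mathrm{gained}} m_i - \sum_{\mathrm{lost}} m_j - z\,m_e,$$

where $m_e$ is the electron mass. Including the electron term costs nothing
and keeps the algebra exact at the sub-mDa level. A built-in table covers
the twelve adducts a practitioner would call common
(`commonAdducts()`); any other grammatical adduct string is parsed and its
$\Delta$ computed from the gain/loss formulas. The adduct-repair filter
scans only the common table, restricted to the spectrum's ion mode,
because scanning exotic adducts would make almost any precursor
"explainable" and defeat the corroboration principle.

## Tunable parameters

* **Mass tolerance** (`mass_tolerance`, default **0.1 Da**): used wherever
  a mass match is asserted. The value accommodates unit-resolution metadata
  while rejecting wrong molecules. One known edge: below roughly 150 Da
  the molar-monoisotopic gap itself can be smaller than 0.1 Da (glucose:
  0.093 Da), so a molar-mass parent mass on a very small molecule may pass
  unrepaired; tightening the tolerance to 0.05 Da catches it at the cost
  of stricter matching everywhere. The synthetic generator assigns the
  molar-mass error class only to compounds whose gap exceeds 0.12 Da for
  exactly this reason.
* **High-peak requirement** (`n_min = 5` fragments at
  `intensity_fraction = 0.02` of the base peak): permissive enough to keep
  sparse but informative spectra; both are exposed in the workflow YAML.
* **`allow_default_adduct` = FALSE** in `deriveParentMass()`: assuming
  \[M+H\]+ for an unannotated spectrum is precisely the error class the
  adduct repair exists to fix, so the library-cleaning preset never
  introduces it.
* **Salt component cap = 8**: the subset search over counterion components
  is exponential; real salts have few components, and above the cap the
  filter leaves the spectrum for the require layer.

## Ordering and determinism

Filters are arranged in a predefined global order (harmonize, derive,
normalize, repair, require) regardless of declaration order, because many
filters depend on earlier ones - the adduct must be pulled out of the
compound-name field before anything consumes the adduct field, and
requirements are meaningful only after all repairs have run. A removed
spectrum is attributed to the *first* failing requirement and never reaches
later filters, which makes the report's conservation law exact:
`spectra_in = spectra_out + sum(removed)`.

Everything is deterministic: no step draws random numbers, ties in the salt
subset search are broken by closest mass, then by heavy-atom count, then by
enumeration order, and the writers emit metadata in a fixed key order with
fixed float precision. Rerunning a pipeline from its own workflow YAML
reproduces the output library and report byte for byte.

## Structure backends

Structure-dependent steps (SMILES to formula, InChIKey generation, 2D
comparison by InChIKey first block) go through an injectable backend
contract - a named list of five resolver functions
(`smilesFormula`, `smilesInchikey`, `smilesToInchi`, `inchiInchikey`,
`inchiToSmiles`), each mapping a string to a string or `NA`. Two backends
ship with the package: a deterministic table backend over the packaged
compound table, and an Open Babel backend (via `ChemmineOB`) for arbitrary
structures. The default chains the two. InChI formulas are read directly
from the InChI's own formula layer, which needs no toolkit at all. The
tests run against the table backend so every expected value is fixed;
a separate test cross-checks the table against Open Babel.

## The synthetic dirty library

`generateLibrary()` emulates the error classes the filters target, against
a packaged table of 32 reference compounds (135-828 Da) whose name,
formula, masses, SMILES, InChI and InChIKey are mutually consistent. Clean
spectra are built by exact adduct algebra; each error class perturbs only
the fields its repair (or removal) filter targets, one class per spectrum,
so the expected fate of every spectrum follows mechanically from its class
and is recorded in a ground-truth ledger. The class mix of the default
"mixed" profile is arbitrary (real-world frequencies are unknown) but
fixed, and exercises every repair and removal path.

What the generator deliberately does **not** emulate: realistic
fragmentation (peak positions are uniform below the precursor; only counts
and relative intensities matter to the filters), multi-error spectra (a
single error class keeps fate attribution deterministic), free-text
comment grammars, and the long tail of vendor-specific metadata spellings.
Passing the ledger tests therefore shows that the filters implement their
contracts exactly on well-posed inputs; it does not quantify behaviour on
the messier error mixtures of real public libraries.

With the offline table resolver every resolvable name maps to exactly one
structure, so the strip-and-rederive audit
(`auditNameDerivation()`) recovers 100% of annotations with 0% structural
mismatch. That is the synthetic upper bound of the protocol - a live
compound database with its name collisions and isomers can only do worse.

## Problem sizes

The shipped validation runs the full pipeline on a 1000-spectrum mixed
library (and the same library without the repair layer for the contrast),
50 small randomized libraries for the conservation property, and
permutation checks on a 120-spectrum library - sizes chosen to exercise
every code path many times over while keeping a complete run comfortable
on a laptop.

## Known limitations

* Consistency is 2D only (InChIKey first block); stereochemistry is
  neither compared nor repaired.
* No fragment-level plausibility checks: a wrong annotation whose mass
  happens to match the parent mass passes undetected.
* Formula parsing covers Hill-style organic formulas without isotope
  labels, charges or parentheses; the element table covers the 22 elements
  common in small-molecule libraries.
* Libraries are loaded in memory; multi-GB streaming is out of scope.

## A worked example

```{r example}
lib <- generateLibrary(200, mixedErrorProfile(), seed = 7)
out <- runPipeline(lib$spectra, buildPreset("library_cleaning"))
reportTotals(out$report)
scoreCleaning(lib$ledger, out)$per_class
```
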