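test_that("valid-annotation requirement demands complete consistency", {
    adenine <- compound_row("adenine")
    caffeine <- compound_row("caffeine")
    full <- makeSpectrum(list(smiles = adenine$smiles,
                              inchi = adenine$inchi,
                              inchikey = adenine$inchikey))
    expect_identical(requireValidAnnotation(full, table_backend), full)
    partial <- makeSpectrum(list(smiles = adenine$smiles))
    expect_null(requireValidAnnotation(partial, table_backend))
    clash <- makeSpectrum(list(smiles = adenine$smiles,
                               inchi = adenine$inchi,
                               inchikey = caffeine$inchikey))
    expect_null(requireValidAnnotation(clash, table_backend))
    malformed <- makeSpectrum(list(smiles = adenine$smiles,
                                   inchi = adenine$inchi,
                                   inchikey = "BROKEN"))
    expect_null(requireValidAnnotation(malformed, table_backend))
})

test_that("parent mass must match the SMILES monoisotopic mass", {
    glucose <- compound_row("glucose")
    keep <- makeSpectrum(list(smiles = glucose$smiles,
                              parent_mass = 180.0634))
    expect_identical(requireParentMassMatchSmiles(keep,
                                                  backend = table_backend),
                     keep)
    # glucose's molar-monoisotopic gap (~0.093 Da) slips under the default
    # 0.1 Da tolerance but is caught at 0.05
    molar <- makeSpectrum(list(smiles = glucose$smiles,
                               parent_mass = 180.156))
    expect_identical(requireParentMassMatchSmiles(molar,
                                                  backend = table_backend),
                     molar)
    expect_null(requireParentMassMatchSmiles(molar, mass_tolerance = 0.05,
                                             backend = table_backend))
    expect_null(requireParentMassMatchSmiles(
        makeSpectrum(list(smiles = glucose$smiles)),
        backend = table_backend))
})

test_that("adduct, precursor m/z and parent mass must agree", {
    keep <- makeSpectrum(list(precursor_mz = 181.070664,
                              adduct = "[M+H]+",
                              parent_mass = 180.063388))
    expect_identical(requireMatchingAdductPrecursorParent(keep), keep)
    off <- makeSpectrum(list(precursor_mz = 181.070664, adduct = "[M+H]+",
                             parent_mass = 181.0707))
    expect_null(requireMatchingAdductPrecursorParent(off))
    junk <- makeSpectrum(list(precursor_mz = 181.070664, adduct = "???",
                              parent_mass = 180.063388))
    expect_null(requireMatchingAdductPrecursorParent(junk))
})

test_that("adduct/ionmode contradictions are removed, absences kept", {
    ok <- makeSpectrum(list(adduct = "[M-H]-", ionmode = "negative"))
    expect_identical(requireMatchingAdductAndIonmode(ok), ok)
    clash <- makeSpectrum(list(adduct = "[M+H]+", ionmode = "negative"))
    expect_null(requireMatchingAdductAndIonmode(clash))
    missing <- makeSpectrum(list(adduct = "[M+H]+"))
    expect_identical(requireMatchingAdductAndIonmode(missing), missing)
})

test_that("sparse spectra fail the high-peak requirement", {
    rich <- makeSpectrum(list(), 1:10, c(rep(1, 6), rep(0.001, 4)))
    expect_identical(requireMinimumNumberOfHighPeaks(rich), rich)
    sparse <- makeSpectrum(list(), 1:3, c(1, 1, 1))
    expect_null(requireMinimumNumberOfHighPeaks(sparse))
    expect_identical(requireMinimumNumberOfHighPeaks(sparse, n_min = 0),
                     sparse)
    low <- makeSpectrum(list(), 1:10, c(1, rep(0.001, 9)))
    expect_null(requireMinimumNumberOfHighPeaks(low))
})

test_that("require filters are pure predicates: keep untouched or remove", {
    lib <- generateLibrary(60, seed = 13)
    preds <- list(
        function(s) requireValidAnnotation(s, table_backend),
        function(s) requireParentMassMatchSmiles(s,
                                                 backend = table_backend),
        requireMatchingAdductPrecursorParent,
        requireMatchingAdductAndIonmode,
        requireMinimumNumberOfHighPeaks,
        requirePrecursorMz)
    for (s in lib$spectra)
        for (p in preds) {
            out <- p(s)
            expect_true(is.null(out) || identical(out, s))
        }
})

test_that("the surviving set is invariant under require-filter order", {
    lib <- generateLibrary(60, seed = 17)
    preds <- list(
        function(s) requireValidAnnotation(s, table_backend),
        function(s) requireParentMassMatchSmiles(s,
                                                 backend = table_backend),
        requireMatchingAdductPrecursorParent,
        requireMatchingAdductAndIonmode,
        requireMinimumNumberOfHighPeaks,
        requirePrecursorMz)
    survives <- function(order) {
        vapply(lib$spectra, function(s) {
            for (p in preds[order]) {
                s <- p(s)
                if (is.null(s)) return(FALSE)
            }
            TRUE
        }, logical(1))
    }
    base <- survives(seq_along(preds))
    set.seed(1)
    for (i in 1:5)
        expect_identical(survives(sample(seq_along(preds))), base)
})
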