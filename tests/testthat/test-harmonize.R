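test_that("ionmode spellings are harmonized and junk is dropped", {
    s <- makeSpectrum(list(ionmode = "Pos"))
    expect_equal(metadataValue(harmonizeIonmode(s), "ionmode"), "positive")
    s2 <- makeSpectrum(list(ionmode = "negative"))
    expect_identical(harmonizeIonmode(s2), s2)
    s3 <- makeSpectrum(list(compound_name = "x"))
    expect_identical(harmonizeIonmode(s3), s3)
    s4 <- makeSpectrum(list(ionmode = "n/a"))
    expect_null(metadataValue(harmonizeIonmode(s4), "ionmode"))
})

test_that("adduct tokens move from the compound name to the adduct field", {
    s <- makeSpectrum(list(compound_name = "Glucose [M+H]+"))
    out <- deriveAdductFromNameOrComment(s)
    expect_equal(metadataValue(out, "compound_name"), "Glucose")
    expect_equal(metadataValue(out, "adduct"), "[M+H]+")

    s2 <- makeSpectrum(list(compound_name = "Glucose"))
    expect_identical(deriveAdductFromNameOrComment(s2), s2)

    # existing adduct is never overwritten, but the name is still cleaned
    s3 <- makeSpectrum(list(compound_name = "Glucose [M+H]+",
                            adduct = "[M+Na]+"))
    out3 <- deriveAdductFromNameOrComment(s3)
    expect_equal(metadataValue(out3, "compound_name"), "Glucose")
    expect_equal(metadataValue(out3, "adduct"), "[M+Na]+")
})

test_that("ionmode derives from the adduct charge sign, never overwriting", {
    s <- makeSpectrum(list(adduct = "[M-H]-"))
    expect_equal(metadataValue(deriveIonmodeFromAdduct(s), "ionmode"),
                 "negative")
    s2 <- makeSpectrum(list(adduct = "???"))
    expect_identical(deriveIonmodeFromAdduct(s2), s2)
    s3 <- makeSpectrum(list(adduct = "[M-H]-", ionmode = "positive"))
    expect_equal(metadataValue(deriveIonmodeFromAdduct(s3), "ionmode"),
                 "positive")
})

test_that("parent mass derives from precursor m/z and adduct", {
    s <- makeSpectrum(list(precursor_mz = 181.070664, adduct = "[M+H]+"))
    expect_equal(metadataValue(deriveParentMass(s), "parent_mass"),
                 180.063388, tolerance = 1e-5)
    s2 <- makeSpectrum(list(precursor_mz = 181.070664, adduct = "[M+H]+",
                            parent_mass = 123.4))
    expect_equal(metadataValue(deriveParentMass(s2), "parent_mass"), 123.4)
    s3 <- makeSpectrum(list(adduct = "[M+H]+"))
    expect_identical(deriveParentMass(s3), s3)
    # the fallback default adduct is opt-in
    s4 <- makeSpectrum(list(precursor_mz = 181.070664,
                            ionmode = "positive"))
    expect_identical(deriveParentMass(s4), s4)
    expect_equal(metadataValue(
        deriveParentMass(s4, allow_default_adduct = TRUE), "parent_mass"),
        180.063388, tolerance = 1e-5)
})

test_that("intensity normalization rescales to a unit base peak", {
    s <- makeSpectrum(list(), c(1, 2, 3), c(10, 100, 50))
    out <- normalizeIntensities(s)
    expect_equal(peaksIntensity(out), c(0.1, 1.0, 0.5))
    expect_identical(peaksMz(out), peaksMz(s))
    expect_identical(normalizeIntensities(out), out)  # idempotent
    empty <- makeSpectrum(list())
    expect_identical(normalizeIntensities(empty), empty)
    zero <- makeSpectrum(list(), c(1, 2), c(0, 0))
    expect_identical(normalizeIntensities(zero), zero)
})

test_that("precursor m/z requirement removes missing and absurd values", {
    keep <- makeSpectrum(list(precursor_mz = 181.07))
    expect_identical(requirePrecursorMz(keep), keep)
    expect_null(requirePrecursorMz(makeSpectrum(list())))
    expect_null(requirePrecursorMz(makeSpectrum(list(precursor_mz = -1))))
    expect_null(requirePrecursorMz(makeSpectrum(list(precursor_mz = 6000))))
    expect_null(requirePrecursorMz(
        makeSpectrum(list(precursor_mz = "not a number"))))
})

test_that("harmonize and derive filters are idempotent and never overwrite", {
    set.seed(11)
    filters <- list(harmonizeMetadataKeys, harmonizeIonmode,
                    deriveAdductFromNameOrComment, deriveIonmodeFromAdduct,
                    deriveParentMass)
    for (rep in 1:20) {
        md <- list()
        if (runif(1) < 0.7) md$ionmode <- sample(
            c("Pos", "NEG", "positive", "whatever", "+"), 1)
        if (runif(1) < 0.7) md$adduct <- sample(
            c("[M+H]+", "M-H", "junk!!"), 1)
        if (runif(1) < 0.7) md$precursor_mz <- runif(1, 50, 1000)
        if (runif(1) < 0.5) md$parent_mass <- runif(1, 50, 1000)
        if (runif(1) < 0.5) md$compound_name <- sample(
            c("caffeine", "x [M+Na]+", "plain name"), 1)
        s <- makeSpectrum(md, c(60, 70, 80), c(1, 2, 3))
        for (f in filters) {
            once <- f(s)
            twice <- f(once)
            expect_identical(spectrumMetadata(twice),
                             spectrumMetadata(once))
            # no-overwrite: any key present before stays unless it was the
            # field the filter harmonizes/strips by contract
            before <- spectrumMetadata(s)
            after <- spectrumMetadata(once)
            for (k in setdiff(names(before),
                              c("ionmode", "compound_name", "comment"))) {
                expect_true(k %in% names(after), info = k)
            }
            s <- once
        }
    }
})
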