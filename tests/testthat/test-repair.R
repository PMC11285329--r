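resolver <- tableNameResolver()

test_that("annotation derives from a resolvable name only with mass support", {
    adenine <- compound_row("adenine")
    s <- makeSpectrum(list(compound_name = "adenine",
                           parent_mass = 135.0545))
    out <- deriveAnnotationFromCompoundName(s, resolver)
    expect_equal(metadataValue(out, "smiles"), adenine$smiles)
    expect_equal(metadataValue(out, "inchikey"), adenine$inchikey)

    # mass veto: resolved structure does not match the stored parent mass
    s2 <- makeSpectrum(list(compound_name = "adenine",
                            parent_mass = 194.08))
    expect_identical(deriveAnnotationFromCompoundName(s2, resolver), s2)

    # existing structure fields are a precondition, not overwritten
    s3 <- makeSpectrum(list(compound_name = "adenine",
                            parent_mass = 135.0545, smiles = "CCO"))
    expect_identical(deriveAnnotationFromCompoundName(s3, resolver), s3)

    # unresolvable name leaves the spectrum alone
    s4 <- makeSpectrum(list(compound_name = "no such compound",
                            parent_mass = 135.0545))
    expect_identical(deriveAnnotationFromCompoundName(s4, resolver), s4)
})

test_that("name-resolver cache files persist hits and misses across runs", {
    cache <- withr::local_tempfile(fileext = ".tsv")
    r1 <- tableNameResolver(cache_path = cache)
    hit <- resolveName(r1, "Caffeine")
    expect_equal(nrow(hit), 1)
    resolveName(r1, "nonexistent thing")
    expect_true(file.exists(cache))

    # a fresh resolver with an empty lookup still answers from the cache
    r2 <- nameResolver(function(name) stop("backend must not be called"),
                       cache_path = cache)
    hit2 <- resolveName(r2, "caffeine")
    expect_equal(hit2$inchikey, hit$inchikey)
    expect_equal(nrow(resolveName(r2, "nonexistent thing")), 0)
})

test_that("salt SMILES are repaired to the component matching parent mass", {
    adenine <- compound_row("adenine")
    s <- makeSpectrum(list(smiles = "C1=NC2=NC=NC(=C2N1)N.Cl",
                           parent_mass = 135.0545))
    out <- repairSmilesOfSalts(s, backend = table_backend)
    expect_equal(metadataValue(out, "smiles"), "C1=NC2=NC=NC(=C2N1)N")
    expect_equal(metadataValue(out, "inchikey"), adenine$inchikey)

    s2 <- makeSpectrum(list(smiles = "[Na+].[Cl-]", parent_mass = 22.9898))
    expect_equal(metadataValue(repairSmilesOfSalts(s2,
                                                   backend = table_backend),
                               "smiles"), "[Na+]")

    s3 <- makeSpectrum(list(smiles = "CCO", parent_mass = 46.04))
    expect_identical(repairSmilesOfSalts(s3, backend = table_backend), s3)

    # full structure already matching is left alone
    s4 <- makeSpectrum(list(smiles = "C1=NC2=NC=NC(=C2N1)N.Cl",
                            parent_mass = 171.0312))
    expect_identical(repairSmilesOfSalts(s4, backend = table_backend), s4)
})

test_that("salt subset search agrees with a brute-force powerset oracle", {
    ions <- c("Cl", "Br", "O", "[Na+]", "[K+]")
    tab <- compoundTable()
    set.seed(99)
    for (rep in 1:25) {
        k <- sample(2:6, 1)
        cmp <- tab[sample(nrow(tab), 1), ]
        comps <- c(cmp$smiles, sample(ions, k - 1, replace = TRUE))
        masses <- vapply(comps, function(cc)
            monoisotopicMass(table_backend$smilesFormula(cc)), numeric(1))
        target_sel <- sample(c(TRUE, FALSE), k, replace = TRUE)
        if (all(target_sel) || !any(target_sel)) next
        parent <- sum(masses[target_sel]) + runif(1, -0.05, 0.05)

        # brute force over every proper non-empty subset
        best_diff <- Inf
        for (mask in seq_len(2^k - 2)) {
            sel <- as.logical(bitwAnd(mask, 2^(seq_len(k) - 1)))
            d <- abs(sum(masses[sel]) - parent)
            if (d < best_diff) best_diff <- d
        }

        s <- makeSpectrum(list(smiles = paste(comps, collapse = "."),
                               parent_mass = parent))
        out <- repairSmilesOfSalts(s, backend = table_backend)
        full_diff <- abs(sum(masses) - parent)
        if (full_diff <= 0.1) {
            expect_identical(out, s)  # precondition: full structure matches
        } else if (best_diff <= 0.1) {
            got <- structureMonoisotopicMass(
                metadataValue(out, "smiles"), table_backend)
            expect_equal(abs(got - parent), best_diff, tolerance = 1e-9)
        } else {
            expect_identical(out, s)
        }
    }
})

test_that("molar-mass parent masses are replaced by the monoisotopic mass", {
    caffeine <- compound_row("caffeine")
    s <- makeSpectrum(list(smiles = caffeine$smiles, parent_mass = 194.19))
    out <- repairParentMassIsMolarMass(s, backend = table_backend)
    expect_equal(metadataValue(out, "parent_mass"), 194.080376,
                 tolerance = 1e-4)

    s2 <- makeSpectrum(list(smiles = caffeine$smiles,
                            parent_mass = 194.0804))
    expect_identical(repairParentMassIsMolarMass(s2,
                                                 backend = table_backend),
                     s2)
    s3 <- makeSpectrum(list(smiles = caffeine$smiles, parent_mass = 300))
    expect_identical(repairParentMassIsMolarMass(s3,
                                                 backend = table_backend),
                     s3)
})

test_that("default adducts are corrected from SMILES and precursor m/z", {
    glucose <- compound_row("glucose")
    prec_na <- precursorFromParent(glucose$monoisotopic_mass, "[M+Na]+")
    s <- makeSpectrum(list(smiles = glucose$smiles, precursor_mz = prec_na,
                           adduct = "[M+H]+", ionmode = "positive"))
    out <- repairAdductAndParentMassBasedOnSmiles(s, backend = table_backend)
    expect_equal(metadataValue(out, "adduct"), "[M+Na]+")
    expect_equal(metadataValue(out, "parent_mass"), 180.063388,
                 tolerance = 1e-5)

    # already consistent: untouched
    s2 <- makeSpectrum(list(smiles = glucose$smiles,
                            precursor_mz = 181.070664, adduct = "[M+H]+",
                            ionmode = "positive"))
    expect_identical(
        repairAdductAndParentMassBasedOnSmiles(s2, backend = table_backend),
        s2)

    # no common adduct explains the precursor: untouched
    s3 <- makeSpectrum(list(smiles = glucose$smiles, precursor_mz = 500,
                            adduct = "[M+H]+", ionmode = "positive"))
    expect_identical(
        repairAdductAndParentMassBasedOnSmiles(s3, backend = table_backend),
        s3)
})

test_that("mismatching annotations keep only the mass-supported field", {
    adenine <- compound_row("adenine")
    caffeine <- compound_row("caffeine")
    s <- makeSpectrum(list(smiles = adenine$smiles,
                           inchi = caffeine$inchi,
                           parent_mass = 135.0545))
    out <- repairNotMatchingAnnotation(s, backend = table_backend)
    expect_equal(metadataValue(out, "inchi"), adenine$inchi)
    expect_equal(metadataValue(out, "inchikey"), adenine$inchikey)

    s2 <- makeSpectrum(list(smiles = adenine$smiles, inchi = adenine$inchi,
                            parent_mass = 135.0545))
    expect_identical(repairNotMatchingAnnotation(s2,
                                                 backend = table_backend),
                     s2)

    # neither field matches the parent mass: ambiguity, leave alone
    s3 <- makeSpectrum(list(smiles = adenine$smiles,
                            inchi = caffeine$inchi, parent_mass = 500))
    expect_identical(repairNotMatchingAnnotation(s3,
                                                 backend = table_backend),
                     s3)
})

test_that("repair filters never remove and are corroborated by mass", {
    lib <- generateLibrary(80, seed = 3)
    repairs <- list(
        function(s) deriveAnnotationFromCompoundName(s, resolver),
        function(s) repairSmilesOfSalts(s, backend = table_backend),
        function(s) repairParentMassIsMolarMass(s, backend = table_backend),
        function(s) repairAdductAndParentMassBasedOnSmiles(
            s, backend = table_backend),
        function(s) repairNotMatchingAnnotation(s, backend = table_backend))
    for (s in lib$spectra)
        for (f in repairs)
            expect_s4_class(f(s), "Spectrum")
})

test_that("salt repair leaves the annotation mass-consistent", {
    lib <- generateLibrary(40, c(salt_counterion = 1), seed = 5)
    for (s in lib$spectra) {
        out <- repairSmilesOfSalts(s, backend = table_backend)
        expect_lte(abs(structureMonoisotopicMass(
            metadataValue(out, "smiles"), table_backend) -
            metadataValue(out, "parent_mass")), 0.1)
    }
})
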