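test_that("formula parsing follows the grammar and rejects junk", {
    expect_equal(parseFormula("C6H12O6"), c(C = 6L, H = 12L, O = 6L))
    expect_equal(parseFormula("H2O"), c(H = 2L, O = 1L))
    expect_equal(parseFormula("NaCl"), c(Na = 1L, Cl = 1L))
    expect_error(parseFormula("C6H12O6X"), "unknown element")
    expect_error(parseFormula("C6H12)"), "parse")
    expect_error(parseFormula(""), "empty")
})

test_that("monoisotopic and average masses match an independent oracle", {
    formulas <- c("H2O", "C6H12O6", "C5H5N5", "C8H10N4O2", "C10H11N3O3S",
                  "NH3", "C2H4O2", "CH2O2", "C27H46O", "C37H67NO13",
                  "C15H10O7", "C10H17N3O6S", "ClH", "C8H14ClN5",
                  "C23H37N7O5S", "C28H37N5O7", "C12H22O11", "C30H52O26",
                  "NaCl", "KBr", "C2H3N", "C3H8O3", "C6H5I", "C4H9BrO")
    expect_gte(length(formulas), 20)
    for (f in formulas) {
        expect_equal(monoisotopicMass(f),
                     oracle_formula_mass(f, oracle_monoisotopic),
                     tolerance = 1e-4, info = f)
        expect_equal(averageMass(f),
                     oracle_formula_mass(f, oracle_average),
                     tolerance = 1e-2, info = f)
    }
    expect_identical(monoisotopicMass("C"), 12)
})

test_that("adduct parsing resolves surface forms to exact mass shifts", {
    a <- parseAdduct("M+H")
    expect_identical(adductName(a), "[M+H]+")
    expect_identical(adductCharge(a), 1L)
    expect_equal(adductMassShift(a), ORACLE_PROTON, tolerance = 1e-6)

    b <- parseAdduct("[M−H]−")  # unicode minus signs
    expect_identical(adductCharge(b), -1L)
    expect_equal(adductMassShift(b), -ORACLE_PROTON, tolerance = 1e-6)

    c2 <- parseAdduct("[2M+Na]+")
    expect_identical(adductMultiplier(c2), 2L)
    expect_equal(adductMassShift(c2), 22.989218, tolerance = 1e-5)

    d <- parseAdduct("[M+2H]2+")
    expect_identical(adductCharge(d), 2L)
    expect_equal(adductMassShift(d), 2 * ORACLE_PROTON, tolerance = 1e-6)

    # grammatical but not in the common table: computed from formulas
    e <- parseAdduct("M-H2O+H")
    expect_false(e@known)
    expect_equal(adductMassShift(e),
                 ORACLE_PROTON - oracle_formula_mass("H2O",
                                                     oracle_monoisotopic),
                 tolerance = 1e-5)

    expect_error(parseAdduct("rubbish"), "unparseable")
    expect_error(parseAdduct("M+ACN"), "no charge")  # neutral gain only
})

test_that("precursor/parent algebra round-trips over all common adducts", {
    set.seed(42)
    masses <- runif(100, 50, 2000)
    for (a in commonAdducts()) {
        back <- vapply(masses, function(M)
            parentMassFromPrecursor(precursorFromParent(M, a), a),
            numeric(1))
        expect_equal(back, masses, tolerance = 1e-6, info = adductName(a))
        # canonicalization round trip
        expect_identical(adductName(parseAdduct(adductName(a))),
                         adductName(a))
    }
})

test_that("parent mass recovery matches known molecules", {
    expect_equal(parentMassFromPrecursor(181.070664, "[M+H]+"),
                 180.063388, tolerance = 1e-5)
    M <- 178.062887
    prec <- precursorFromParent(M, "[M+2H]2+")
    expect_equal(prec, 90.038970, tolerance = 1e-5)
    expect_equal(parentMassFromPrecursor(prec, "[M+2H]2+"), M,
                 tolerance = 1e-8)
    expect_error(parentMassFromPrecursor(0.5, "[M+H]+"), "non-positive")
})

test_that("structure masses work componentwise and are additive", {
    expect_equal(structureMonoisotopicMass("O"), 18.010565,
                 tolerance = 1e-4)
    expect_equal(structureMonoisotopicMass("C1=NC2=NC=NC(=C2N1)N"),
                 135.054495, tolerance = 1e-4)
    lhs <- structureMonoisotopicMass("C1=NC2=NC=NC(=C2N1)N.Cl")
    rhs <- structureMonoisotopicMass("C1=NC2=NC=NC(=C2N1)N") +
        structureMonoisotopicMass("Cl")
    expect_equal(lhs, rhs, tolerance = 1e-6)
    expect_error(structureMonoisotopicMass("not_a_smiles"), "cannot parse")
})

test_that("splitComponents splits on the top-level separator", {
    expect_identical(splitComponents("C1=NC2=NC=NC(=C2N1)N.Cl"),
                     c("C1=NC2=NC=NC(=C2N1)N", "Cl"))
    expect_identical(splitComponents("CCO"), "CCO")
    expect_identical(splitComponents("[Na+].[Cl-]"), c("[Na+]", "[Cl-]"))
})

test_that("2D consistency compares InChIKey first blocks", {
    adenine <- compound_row("adenine")
    caffeine <- compound_row("caffeine")
    expect_true(consistent2d(smiles = adenine$smiles, inchi = adenine$inchi,
                             backend = table_backend))
    expect_false(consistent2d(smiles = adenine$smiles,
                              inchikey = caffeine$inchikey,
                              backend = table_backend))
    expect_true(consistent2d(smiles = adenine$smiles,
                             backend = table_backend))
    expect_false(consistent2d(smiles = "@@garbage@@",
                              inchi = adenine$inchi,
                              backend = table_backend))
    expect_error(consistent2d(backend = table_backend), "at least one")
})

test_that("InChIKey well-formedness check", {
    expect_true(isValidInchikey("GFFGJBXGBJISGV-UHFFFAOYSA-N"))
    expect_false(isValidInchikey("GFFGJBXGBJISGV-UHFFFAOYSA"))
    expect_false(isValidInchikey("not a key"))
})

test_that("packaged compound table is internally consistent", {
    tab <- compoundTable()
    expect_gte(nrow(tab), 20)
    expect_gte(max(tab$monoisotopic_mass), 800)
    expect_lte(min(tab$monoisotopic_mass), 150)
    for (i in seq_len(nrow(tab))) {
        expect_equal(tab$monoisotopic_mass[i],
                     oracle_formula_mass(tab$formula[i],
                                         oracle_monoisotopic),
                     tolerance = 1e-4, info = tab$name[i])
        expect_true(isValidInchikey(tab$inchikey[i]))
        expect_true(consistent2d(smiles = tab$smiles[i],
                                 inchi = tab$inchi[i],
                                 inchikey = tab$inchikey[i],
                                 backend = table_backend))
    }
})

test_that("the Open Babel backend agrees with the packaged table", {
    ob <- obStructureBackend()
    skip_if(is.null(ob), "ChemmineOB not installed")
    for (nm in c("adenine", "caffeine", "verapamil")) {
        cmp <- compound_row(nm)
        expect_identical(ob$smilesInchikey(cmp$smiles), cmp$inchikey)
        f <- ob$smilesFormula(cmp$smiles)
        expect_equal(monoisotopicMass(f), cmp$monoisotopic_mass,
                     tolerance = 1e-4)
    }
})
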