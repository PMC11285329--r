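# Shared fixtures: small spectrum builders and an independent atomic-mass
# oracle used to cross-check the package's mass arithmetic.

# Independent isotope-mass table (NIST/CODATA values typed directly here, on
# purpose not shared with the package's own table).
oracle_monoisotopic <- c(
    H = 1.00782503207, C = 12.0, N = 14.0030740048, O = 15.9949146196,
    P = 30.97376163, S = 31.97207100, F = 18.99840322, Cl = 34.96885268,
    Br = 78.9183371, I = 126.904473, Na = 22.9897692809, K = 38.96370668,
    Ca = 39.96259098, Mg = 23.985041700, Fe = 55.9349375, Zn = 63.9291422,
    Si = 27.9769265325, Se = 79.9165213, B = 11.0093054, Li = 7.01600455,
    Al = 26.98153863, Cu = 62.9295975)

oracle_average <- c(
    H = 1.008, C = 12.011, N = 14.007, O = 15.999, P = 30.974, S = 32.06,
    F = 18.998, Cl = 35.45, Br = 79.904, I = 126.904, Na = 22.990,
    K = 39.098, Ca = 40.078, Mg = 24.305, Fe = 55.845, Zn = 65.38,
    Si = 28.085, Se = 78.971, B = 10.81, Li = 6.94, Al = 26.982,
    Cu = 63.546)

# Brute-force formula mass: tokenize and sum, independent of parseFormula.
oracle_formula_mass <- function(formula, table) {
    total <- 0
    for (tok in regmatches(formula,
                           gregexpr("[A-Z][a-z]?[0-9]*", formula))[[1]]) {
        sym <- gsub("[0-9]", "", tok)
        n <- sub("^[A-Za-z]+", "", tok)
        n <- if (nzchar(n)) as.integer(n) else 1L
        total <- total + n * table[[sym]]
    }
    total
}

ORACLE_PROTON <- 1.007276466879

# A fully self-consistent spectrum for a compound-table row.
clean_spectrum <- function(cmp, adduct = "[M+H]+", n_peaks = 10) {
    a <- parseAdduct(adduct)
    prec <- precursorFromParent(cmp$monoisotopic_mass, a)
    makeSpectrum(
        list(compound_name = cmp$name, precursor_mz = prec,
             parent_mass = cmp$monoisotopic_mass, adduct = a@name,
             ionmode = a@ionmode, smiles = cmp$smiles, inchi = cmp$inchi,
             inchikey = cmp$inchikey),
        mz = seq(60, by = 11, length.out = n_peaks),
        intensities = seq(0.1, 1, length.out = n_peaks))
}

compound_row <- function(name) {
    tab <- compoundTable()
    tab[tab$name == name, ]
}

table_backend <- tableStructureBackend()
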