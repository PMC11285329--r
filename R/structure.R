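# Structure-annotation chemistry: SMILES/InChI -> formula, InChIKey and
# 2D-skeleton consistency.
#
# Structure parsing goes through an injectable backend contract so the
# pipeline logic is independent of any particular chemistry toolkit. Two
# backends ship with the package: a deterministic table backend built from
# the packaged compound table, and an Open Babel backend (via ChemmineOB)
# for arbitrary structures. The default chains the two.

.INCHIKEY_RE <- "^[A-Z]{14}-[A-Z]{10}-[A-Z]$"

#' Split a structure string into components
#'
#' Splits a SMILES (or the formula layer of an InChI) on the top-level
#' component separator `"."`, preserving order. Salts are written as
#' multi-component structures; the mass spectrometer typically measures only
#' one of the components.
#'
#' @param smiles Structure string.
#' @return Character vector of components.
#' @examples
#' splitComponents("C1=NC2=NC=NC(=C2N1)N.Cl")
#' @export
splitComponents <- function(smiles) {
    if (!is.character(smiles) || length(smiles) != 1L || is.na(smiles))
        return(character(0))
    strsplit(smiles, ".", fixed = TRUE)[[1]]
}

#' Is a string a well-formed InChIKey?
#'
#' @param key Candidate string.
#' @return Logical.
#' @examples
#' isValidInchikey("GFFGJBXGBJISGV-UHFFFAOYSA-N")
#' @export
isValidInchikey <- function(key) {
    is.character(key) && length(key) == 1L && !is.na(key) &&
        grepl(.INCHIKEY_RE, key)
}

# Extract the molecular formula encoded in an InChI string's formula layer.
# Returns a named count vector, or NULL if the string is not an InChI.
.inchi_formula <- function(inchi) {
    if (!is.character(inchi) || length(inchi) != 1L || is.na(inchi))
        return(NULL)
    if (!grepl("^InChI=1S?/", inchi)) return(NULL)
    layers <- strsplit(inchi, "/", fixed = TRUE)[[1]]
    if (length(layers) < 2L) return(NULL)
    total <- integer(0)
    for (comp in strsplit(layers[2], ".", fixed = TRUE)[[1]]) {
        mult <- 1L
        m <- regexpr("^[0-9]+", comp)
        if (m > 0) {
            mult <- as.integer(regmatches(comp, m))
            comp <- sub("^[0-9]+", "", comp)
        }
        f <- tryCatch(parseFormula(comp), error = function(e) NULL)
        if (is.null(f)) return(NULL)
        for (el in names(f))
            total[el] <- (if (el %in% names(total)) total[[el]] else 0L) +
                mult * f[[el]]
    }
    total
}

# --- backend contract --------------------------------------------------------
#
# A structure backend is a list of functions, each returning a single string
# or NA_character_:
#   smilesFormula(smiles)   formula of one SMILES component (or whole string)
#   smilesInchikey(smiles)  InChIKey of a SMILES
#   smilesToInchi(smiles)   InChI of a SMILES
#   inchiInchikey(inchi)    InChIKey of an InChI
#   inchiToSmiles(inchi)    SMILES of an InChI

.memoize1 <- function(fn) {
    cache <- new.env(parent = emptyenv())
    function(x) {
        if (!is.character(x) || length(x) != 1L || is.na(x) || !nzchar(x))
            return(NA_character_)
        key <- x
        if (!exists(key, envir = cache, inherits = FALSE))
            assign(key, fn(x), envir = cache)
        get(key, envir = cache, inherits = FALSE)
    }
}

#' Structure backends
#'
#' `tableStructureBackend()` resolves structures by exact lookup in the
#' packaged compound table (including its salt forms and counterion
#' components) and by componentwise lookup for multi-component SMILES; it is
#' fully deterministic and needs no chemistry toolkit.
#' `obStructureBackend()` resolves arbitrary structures through Open Babel
#' (package \pkg{ChemmineOB}); it returns `NULL` when ChemmineOB is not
#' installed. `defaultStructureBackend()` chains the two, preferring the
#' table.
#'
#' @param compounds Compound table as returned by [compoundTable()].
#' @return A backend: a named list of resolver functions (see the package
#'   vignette for the contract).
#' @examples
#' be <- tableStructureBackend()
#' be$smilesFormula("C1=NC2=NC=NC(=C2N1)N")
#' @export
tableStructureBackend <- function(compounds = compoundTable()) {
    smiles_map <- new.env(parent = emptyenv())
    inchi_map <- new.env(parent = emptyenv())
    put <- function(env, key, val) {
        if (is.character(key) && length(key) == 1L && !is.na(key) &&
            nzchar(key) && !exists(key, envir = env, inherits = FALSE))
            assign(key, val, envir = env)
    }
    add_entry <- function(smiles, inchi, inchikey, formula) {
        rec <- list(smiles = smiles, inchi = inchi, inchikey = inchikey,
                    formula = formula)
        put(smiles_map, smiles, rec)
        put(inchi_map, inchi, rec)
    }
    for (i in seq_len(nrow(compounds))) {
        r <- compounds[i, ]
        add_entry(r$smiles, r$inchi, r$inchikey, r$formula)
        if (!is.na(r$salt_smiles) && nzchar(r$salt_smiles))
            add_entry(r$salt_smiles, r$salt_inchi, r$salt_inchikey,
                      r$salt_formula)
    }
    for (i in seq_len(nrow(.counterion_table)))
        add_entry(.counterion_table$smiles[i], NA_character_,
                  NA_character_, .counterion_table$formula[i])

    lookup_smiles <- function(s) {
        if (exists(s, envir = smiles_map, inherits = FALSE))
            get(s, envir = smiles_map, inherits = FALSE) else NULL
    }
    smiles_formula <- function(s) {
        rec <- lookup_smiles(s)
        if (!is.null(rec)) return(rec$formula)
        comps <- splitComponents(s)
        if (length(comps) < 2L) return(NA_character_)
        fs <- lapply(comps, function(cc) {
            rec <- lookup_smiles(cc)
            if (is.null(rec)) NULL else tryCatch(parseFormula(rec$formula),
                                                 error = function(e) NULL)
        })
        if (any(vapply(fs, is.null, logical(1)))) return(NA_character_)
        total <- integer(0)
        for (f in fs) for (el in names(f))
            total[el] <- (if (el %in% names(total)) total[[el]] else 0L) +
                f[[el]]
        .formula_string(total)
    }
    list(
        name = "table",
        smilesFormula = smiles_formula,
        smilesInchikey = function(s) {
            rec <- lookup_smiles(s)
            if (is.null(rec)) NA_character_ else rec$inchikey
        },
        smilesToInchi = function(s) {
            rec <- lookup_smiles(s)
            if (is.null(rec)) NA_character_ else rec$inchi
        },
        inchiInchikey = function(x) {
            rec <- if (exists(x, envir = inchi_map, inherits = FALSE))
                get(x, envir = inchi_map, inherits = FALSE) else NULL
            if (is.null(rec)) NA_character_ else rec$inchikey
        },
        inchiToSmiles = function(x) {
            rec <- if (exists(x, envir = inchi_map, inherits = FALSE))
                get(x, envir = inchi_map, inherits = FALSE) else NULL
            if (is.null(rec)) NA_character_ else rec$smiles
        }
    )
}

#' @rdname tableStructureBackend
#' @export
obStructureBackend <- function() {
    if (!requireNamespace("ChemmineOB", quietly = TRUE))
        return(NULL)
    conv <- function(from, to) function(x) {
        out <- tryCatch(
            ChemmineOB::convertFormat(from, to, source = paste0(x, "\n")),
            error = function(e) "")
        out <- trimws(out)
        if (nzchar(out)) strsplit(out, "[\t\n]")[[1]][1] else NA_character_
    }
    ob_formula <- function(x) {
        f <- tryCatch({
            mol <- ChemmineOB::forEachMol("SMILES", x, identity)
            ChemmineOB::prop_OB(mol)$formula
        }, error = function(e) NA_character_)
        if (is.na(f) || !nzchar(f)) return(NA_character_)
        f <- gsub("[+-]+[0-9]*$", "", f)  # strip net-charge suffix
        ok <- tryCatch({parseFormula(f); TRUE}, error = function(e) FALSE)
        if (ok) f else NA_character_
    }
    list(
        name = "openbabel",
        smilesFormula = .memoize1(ob_formula),
        smilesInchikey = .memoize1(conv("SMI", "inchikey")),
        smilesToInchi = .memoize1(conv("SMI", "inchi")),
        inchiInchikey = .memoize1(conv("inchi", "inchikey")),
        inchiToSmiles = .memoize1(conv("inchi", "can"))
    )
}

.chain_backends <- function(a, b) {
    if (is.null(b)) return(a)
    chain1 <- function(name) function(x) {
        v <- a[[name]](x)
        if (!is.na(v)) v else b[[name]](x)
    }
    list(name = paste(a$name, b$name, sep = "+"),
         smilesFormula = chain1("smilesFormula"),
         smilesInchikey = chain1("smilesInchikey"),
         smilesToInchi = chain1("smilesToInchi"),
         inchiInchikey = chain1("inchiInchikey"),
         inchiToSmiles = chain1("inchiToSmiles"))
}

#' @rdname tableStructureBackend
#' @export
defaultStructureBackend <- function() {
    if (is.null(.pkg_cache$default_backend))
        .pkg_cache$default_backend <-
            .chain_backends(tableStructureBackend(), obStructureBackend())
    .pkg_cache$default_backend
}

# --- derived quantities ------------------------------------------------------

# Monoisotopic mass of a SMILES, NA on failure. Computed componentwise so
# that mass is additive over components by construction.
.smiles_mono <- function(smiles, backend) {
    comps <- splitComponents(smiles)
    if (!length(comps)) return(NA_real_)
    masses <- vapply(comps, function(cc) {
        f <- backend$smilesFormula(cc)
        if (is.na(f)) return(NA_real_)
        tryCatch(monoisotopicMass(f), error = function(e) NA_real_)
    }, numeric(1))
    if (anyNA(masses)) NA_real_ else sum(masses)
}

.smiles_avg <- function(smiles, backend) {
    comps <- splitComponents(smiles)
    if (!length(comps)) return(NA_real_)
    masses <- vapply(comps, function(cc) {
        f <- backend$smilesFormula(cc)
        if (is.na(f)) return(NA_real_)
        tryCatch(averageMass(f), error = function(e) NA_real_)
    }, numeric(1))
    if (anyNA(masses)) NA_real_ else sum(masses)
}

.inchi_mono <- function(inchi) {
    f <- .inchi_formula(inchi)
    if (is.null(f)) NA_real_ else monoisotopicMass(f)
}

#' Monoisotopic mass of a structure string
#'
#' Computes the monoisotopic mass of a (possibly multi-component) SMILES via
#' the structure backend, or of an InChI via its formula layer. Multi-
#' component masses are componentwise sums, so mass is additive over the
#' `"."` separator.
#'
#' @param structure SMILES or InChI string.
#' @param backend A structure backend; see [defaultStructureBackend()].
#' @return Mass in Da.
#' @examples
#' structureMonoisotopicMass("O")  # water, 18.0106
#' @export
structureMonoisotopicMass <- function(structure,
                                      backend = defaultStructureBackend()) {
    m <- if (grepl("^InChI=", structure %||% "")) .inchi_mono(structure)
         else .smiles_mono(structure, backend)
    if (is.na(m))
        stop("cannot parse structure: '", structure, "'")
    m
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# First 14-character block of the InChIKey implied by a structure field;
# NA if the field cannot be resolved.
.first_block <- function(value, kind, backend) {
    key <- switch(kind,
        smiles = backend$smilesInchikey(value),
        inchi = backend$inchiInchikey(value),
        inchikey = if (isValidInchikey(value)) value else NA_character_)
    if (is.na(key) || nchar(key) < 14L) NA_character_ else substr(key, 1, 14)
}

#' Are the structure fields of an annotation mutually consistent?
#'
#' Compares all present structure fields (SMILES, InChI, InChIKey) by the
#' first 14-character block of their InChIKeys, which encodes the 2D
#' skeleton. A single present, parseable field is vacuously consistent; any
#' unresolvable field makes the annotation inconsistent (`FALSE`, never an
#' error).
#'
#' @param smiles,inchi,inchikey Structure fields (`NULL` when absent).
#' @param backend A structure backend.
#' @return Logical.
#' @examples
#' consistent2d(smiles = "C1=NC2=NC=NC(=C2N1)N")
#' @export
consistent2d <- function(smiles = NULL, inchi = NULL, inchikey = NULL,
                         backend = defaultStructureBackend()) {
    fields <- list(smiles = smiles, inchi = inchi, inchikey = inchikey)
    fields <- fields[!vapply(fields, function(v)
        is.null(v) || is.na(v) || !nzchar(v), logical(1))]
    if (!length(fields))
        stop("at least one structure field must be present")
    blocks <- vapply(names(fields), function(k)
        .first_block(fields[[k]], k, backend), character(1))
    if (anyNA(blocks)) return(FALSE)
    length(unique(blocks)) == 1L
}
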