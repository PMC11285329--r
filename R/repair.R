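# Annotation-repair filters: recover, correct or complete annotations
# instead of discarding spectra. Every repair is corroborated by at least
# one independent metadata field (parent mass or precursor m/z evidence);
# no repair filter ever removes a spectrum.

#' Compound-name resolvers
#'
#' A name resolver maps a compound name to candidate structures
#' (`data.frame` with columns `smiles`, `inchi`, `inchikey`,
#' `monoisotopic_mass`), optionally backed by a persistent file cache so
#' that previously found names are reused across runs.
#'
#' `nameResolver()` wraps an arbitrary lookup function;
#' `tableNameResolver()` resolves offline against the packaged compound
#' table (case-insensitive exact name match). The cache file is
#' tab-separated, one row per candidate, append-only within a run; a miss is
#' cached as a row with empty structure fields.
#'
#' @param lookup Function `name -> data.frame` of candidates (0 rows for a
#'   miss).
#' @param cache_path Optional path of a TSV cache file (created on demand).
#' @param compounds Compound table, see [compoundTable()].
#' @return A resolver object for [resolveName()].
#' @export
nameResolver <- function(lookup, cache_path = NULL) {
    mem <- new.env(parent = emptyenv())
    if (!is.null(cache_path) && file.exists(cache_path)) {
        cached <- utils::read.delim(cache_path, stringsAsFactors = FALSE,
                                    colClasses = "character")
        cached$monoisotopic_mass <- as.numeric(cached$monoisotopic_mass)
        for (nm in unique(cached$name)) {
            rows <- cached[cached$name == nm, -1, drop = FALSE]
            rows <- rows[!is.na(rows$smiles) & nzchar(rows$smiles), ,
                         drop = FALSE]
            assign(nm, rows, envir = mem)
        }
    }
    structure(list(lookup = lookup, cache_path = cache_path, memory = mem),
              class = "NameResolver")
}

#' @rdname nameResolver
#' @export
tableNameResolver <- function(compounds = compoundTable(),
                              cache_path = NULL) {
    nameResolver(function(name) {
        hit <- compounds[tolower(compounds$name) == tolower(trimws(name)), ,
                         drop = FALSE]
        data.frame(smiles = hit$smiles, inchi = hit$inchi,
                   inchikey = hit$inchikey,
                   monoisotopic_mass = hit$monoisotopic_mass,
                   stringsAsFactors = FALSE)
    }, cache_path = cache_path)
}

#' Resolve a compound name to structure candidates
#'
#' Cache hits short-circuit the backend lookup; backend results (including
#' misses) are appended to the resolver's cache file when one is configured.
#'
#' @param resolver A resolver from [nameResolver()].
#' @param name Compound name.
#' @return `data.frame` of candidates (possibly 0 rows).
#' @export
resolveName <- function(resolver, name) {
    stopifnot(inherits(resolver, "NameResolver"))
    key <- tolower(trimws(name))
    if (exists(key, envir = resolver$memory, inherits = FALSE))
        return(get(key, envir = resolver$memory, inherits = FALSE))
    hits <- resolver$lookup(name)
    assign(key, hits, envir = resolver$memory)
    if (!is.null(resolver$cache_path)) {
        rows <- if (nrow(hits)) cbind(name = key, hits)
                else data.frame(name = key, smiles = "", inchi = "",
                                inchikey = "", monoisotopic_mass = NA_real_)
        write_header <- !file.exists(resolver$cache_path)
        suppressWarnings(utils::write.table(
            rows, resolver$cache_path, sep = "\t", quote = FALSE,
            row.names = FALSE, col.names = write_header, append = !write_header))
    }
    hits
}

#' Annotation-repair filters
#'
#' Single-spectrum filters that repair common annotation errors, each
#' corroborated by independent mass evidence. All return a new
#' [Spectrum-class]; none ever removes a spectrum (removal is the domain of
#' the require filters, which run after all repairs).
#'
#' * `deriveAnnotationFromCompoundName()`: when SMILES and InChI are both
#'   missing but a compound name is present, resolves the name and accepts
#'   the first candidate whose monoisotopic mass matches the parent mass
#'   within `mass_tolerance`.
#' * `repairSmilesOfSalts()`: when a multi-component (salt) SMILES does not
#'   match the parent mass, searches all proper non-empty subsets of its
#'   components (up to 8 components) for one that does, keeps the
#'   best-matching subset and rederives InChI/InChIKey from it.
#' * `repairParentMassIsMolarMass()`: when the parent mass matches the
#'   average (molar) mass of the SMILES instead of its monoisotopic mass,
#'   replaces it with the monoisotopic mass.
#' * `repairAdductAndParentMassBasedOnSmiles()`: when adduct + precursor m/z
#'   do not explain the SMILES, scans the common-adduct table (restricted to
#'   the spectrum's ion mode) for an adduct that does, and sets adduct and
#'   parent mass accordingly; ties go to the closest implied mass, then to
#'   table priority (protonated/deprotonated first).
#' * `repairNotMatchingAnnotation()`: when SMILES/InChI/InChIKey disagree on
#'   the 2D structure, keeps exactly the fields whose mass matches the
#'   parent mass and rederives the others from them; ambiguous cases (none
#'   or several conflicting fields match) are left untouched.
#'
#' @param s A [Spectrum-class].
#' @param resolver A [nameResolver()] object.
#' @param mass_tolerance Mass-match tolerance in Da.
#' @param backend A structure backend, see [defaultStructureBackend()].
#' @return A [Spectrum-class].
#' @name repairFilters
NULL

#' @rdname repairFilters
#' @export
deriveAnnotationFromCompoundName <- function(s, resolver,
                                             mass_tolerance = 0.1) {
    if (!is.null(.md_get(s, "smiles")) || !is.null(.md_get(s, "inchi")))
        return(s)
    name <- .md_chr(s, "compound_name")
    parent <- .md_num(s, "parent_mass")
    if (is.null(name) || is.null(parent)) return(s)
    hits <- tryCatch(resolveName(resolver, name), error = function(e) {
        warning("name resolver unavailable: ", conditionMessage(e))
        NULL
    })
    if (is.null(hits) || !nrow(hits)) return(s)
    ok <- which(abs(hits$monoisotopic_mass - parent) <= mass_tolerance)
    if (!length(ok)) return(s)
    hit <- hits[ok[1], ]
    for (field in c("smiles", "inchi", "inchikey")) {
        v <- hit[[field]]
        if (!is.na(v) && nzchar(v)) s <- .md_set(s, field, v)
    }
    s
}

# Rederive inchi/inchikey from a SMILES (or smiles/inchikey from an InChI),
# dropping fields the backend cannot produce.
.rederive_from <- function(s, keep = c("smiles", "inchi"), backend) {
    keep <- match.arg(keep)
    if (keep == "smiles") {
        smi <- .md_chr(s, "smiles")
        inchi <- backend$smilesToInchi(smi)
        key <- backend$smilesInchikey(smi)
        s <- if (!is.na(inchi)) .md_set(s, "inchi", inchi)
             else .md_drop(s, "inchi")
        s <- if (!is.na(key)) .md_set(s, "inchikey", key)
             else .md_drop(s, "inchikey")
    } else {
        inchi <- .md_chr(s, "inchi")
        smi <- backend$inchiToSmiles(inchi)
        key <- backend$inchiInchikey(inchi)
        s <- if (!is.na(smi)) .md_set(s, "smiles", smi)
             else .md_drop(s, "smiles")
        s <- if (!is.na(key)) .md_set(s, "inchikey", key)
             else .md_drop(s, "inchikey")
    }
    s
}

.SALT_COMPONENT_CAP <- 8L

#' @rdname repairFilters
#' @export
repairSmilesOfSalts <- function(s, mass_tolerance = 0.1,
                                backend = defaultStructureBackend()) {
    smiles <- .md_chr(s, "smiles")
    parent <- .md_num(s, "parent_mass")
    if (is.null(smiles) || is.null(parent)) return(s)
    comps <- splitComponents(smiles)
    k <- length(comps)
    if (k < 2L || k > .SALT_COMPONENT_CAP) return(s)
    masses <- vapply(comps, function(cc) {
        f <- backend$smilesFormula(cc)
        if (is.na(f)) NA_real_
        else tryCatch(monoisotopicMass(f), error = function(e) NA_real_)
    }, numeric(1))
    if (anyNA(masses)) return(s)
    if (abs(sum(masses) - parent) <= mass_tolerance) return(s)
    heavies <- vapply(comps, function(cc)
        .heavy_atom_count(backend$smilesFormula(cc)), numeric(1))
    best <- NULL
    for (mask in seq_len(2L^k - 2L)) {
        sel <- as.logical(bitwAnd(mask, bitwShiftL(1L, seq_len(k) - 1L)))
        diff <- abs(sum(masses[sel]) - parent)
        if (diff > mass_tolerance) next
        cand <- list(sel = sel, diff = diff, heavy = sum(heavies[sel]))
        if (is.null(best) || cand$diff < best$diff ||
            (cand$diff == best$diff && cand$heavy > best$heavy))
            best <- cand
    }
    if (is.null(best)) return(s)
    new_smiles <- paste(comps[best$sel], collapse = ".")
    s <- .md_set(s, "smiles", new_smiles)
    .rederive_from(s, "smiles", backend)
}

#' @rdname repairFilters
#' @export
repairParentMassIsMolarMass <- function(s, mass_tolerance = 0.1,
                                        backend = defaultStructureBackend()) {
    smiles <- .md_chr(s, "smiles")
    parent <- .md_num(s, "parent_mass")
    if (is.null(smiles) || is.null(parent)) return(s)
    mono <- .smiles_mono(smiles, backend)
    if (is.na(mono) || abs(parent - mono) <= mass_tolerance) return(s)
    avg <- .smiles_avg(smiles, backend)
    if (is.na(avg) || abs(parent - avg) > mass_tolerance) return(s)
    .md_set(s, "parent_mass", mono)
}

#' @rdname repairFilters
#' @export
repairAdductAndParentMassBasedOnSmiles <- function(
        s, mass_tolerance = 0.1, backend = defaultStructureBackend()) {
    smiles <- .md_chr(s, "smiles")
    prec <- .md_num(s, "precursor_mz")
    if (is.null(smiles) || is.null(prec) || prec <= 0) return(s)
    mono <- .smiles_mono(smiles, backend)
    if (is.na(mono)) return(s)
    current <- .parse_adduct_or_null(.md_chr(s, "adduct"))
    if (!is.null(current)) {
        implied <- tryCatch(parentMassFromPrecursor(prec, current),
                            error = function(e) NA_real_)
        if (!is.na(implied) && abs(implied - mono) <= mass_tolerance)
            return(s)  # already consistent
    }
    mode <- .md_chr(s, "ionmode")
    pool <- if (!is.null(mode) && mode %in% c("positive", "negative"))
        commonAdducts(mode) else commonAdducts()
    best <- NULL
    for (a in pool) {
        implied <- tryCatch(parentMassFromPrecursor(prec, a),
                            error = function(e) NA_real_)
        if (is.na(implied)) next
        diff <- abs(implied - mono)
        if (diff > mass_tolerance) next
        if (is.null(best) || diff < best$diff)  # ties keep table priority
            best <- list(adduct = a, diff = diff)
    }
    if (is.null(best)) return(s)
    s <- .md_set(s, "adduct", best$adduct@name)
    .md_set(s, "parent_mass", mono)
}

#' @rdname repairFilters
#' @export
repairNotMatchingAnnotation <- function(s, mass_tolerance = 0.1,
                                        backend = defaultStructureBackend()) {
    smiles <- .md_chr(s, "smiles")
    inchi <- .md_chr(s, "inchi")
    inchikey <- .md_chr(s, "inchikey")
    present <- c(smiles = !is.null(smiles), inchi = !is.null(inchi),
                 inchikey = !is.null(inchikey))
    if (sum(present) < 2L) return(s)
    consistent <- tryCatch(
        consistent2d(smiles, inchi, inchikey, backend = backend),
        error = function(e) TRUE)
    if (consistent) return(s)
    parent <- .md_num(s, "parent_mass")
    if (is.null(parent)) return(s)
    smiles_ok <- FALSE; inchi_ok <- FALSE
    if (!is.null(smiles)) {
        m <- .smiles_mono(smiles, backend)
        smiles_ok <- !is.na(m) && abs(m - parent) <= mass_tolerance
    }
    if (!is.null(inchi)) {
        m <- .inchi_mono(inchi)
        inchi_ok <- !is.na(m) && abs(m - parent) <= mass_tolerance
    }
    if (!smiles_ok && !inchi_ok) return(s)  # nothing corroborated; leave it
    if (smiles_ok && inchi_ok) {
        bs <- .first_block(smiles, "smiles", backend)
        bi <- .first_block(inchi, "inchi", backend)
        if (is.na(bs) || is.na(bi) || bs != bi)
            return(s)  # two conflicting fields both match the mass
        return(.md_set(.rederive_from(s, "smiles", backend),
                       "inchi", inchi))
    }
    if (smiles_ok) .rederive_from(s, "smiles", backend)
    else .rederive_from(s, "inchi", backend)
}
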