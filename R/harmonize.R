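# Basic harmonization filters: normalize metadata values, derive missing
# fields from other fields, normalize peak intensities. Derivation never
# overwrites a value that is already present; only the repair filters may
# overwrite, and only with multi-field support.

.IONMODE_ALIASES <- list(
    positive = c("positive", "pos", "p", "+", "1", "positive ion mode"),
    negative = c("negative", "neg", "n", "-", "-1", "negative ion mode"))

#' Harmonization and derivation filters
#'
#' Single-spectrum filter functions forming the basic and default layers of
#' the cleaning pipeline. Each takes a [Spectrum-class] and returns a new
#' [Spectrum-class] (never mutating its input); [requirePrecursorMz()]
#' returns `NULL` to signal removal.
#'
#' * `harmonizeMetadataKeys()` re-applies the key-alias table (idempotent).
#' * `harmonizeIonmode()` maps ion-mode spellings ("Pos", "+", "NEGATIVE")
#'   onto `"positive"`/`"negative"`; unrecognized values are dropped.
#' * `deriveAdductFromNameOrComment()` moves a grammatical adduct token out
#'   of the compound name (or comment) into the adduct field, without
#'   overwriting an existing adduct; the token is stripped from the source
#'   field either way.
#' * `deriveIonmodeFromAdduct()` fills a missing ion mode from the adduct's
#'   charge sign.
#' * `deriveParentMass()` fills a missing parent mass from precursor m/z and
#'   adduct via the adduct algebra; with `allow_default_adduct = TRUE` an
#'   absent adduct falls back to \[M+H\]+ / \[M-H\]- by ion mode.
#' * `normalizeIntensities()` scales intensities so the base peak is 1.0.
#' * `requirePrecursorMz()` removes spectra whose precursor m/z is missing,
#'   non-numeric, or outside (0, 5000\] Da.
#'
#' @param s A [Spectrum-class].
#' @param allow_default_adduct Logical; see above. Default `FALSE`: assuming
#'   a protonated adduct is exactly the error class the repair filters
#'   exist to fix.
#' @return A [Spectrum-class], or `NULL` (removal) for `requirePrecursorMz`.
#' @name harmonizeFilters
NULL

#' @rdname harmonizeFilters
#' @export
harmonizeMetadataKeys <- function(s) {
    makeSpectrum(s@metadata, s@mz, s@intensity)
}

#' @rdname harmonizeFilters
#' @export
harmonizeIonmode <- function(s) {
    v <- .md_get(s, "ionmode")
    if (is.null(v)) return(s)
    key <- tolower(trimws(as.character(v)))
    for (mode in names(.IONMODE_ALIASES)) {
        if (key %in% .IONMODE_ALIASES[[mode]]) {
            if (identical(v, mode)) return(s)
            return(.md_set(s, "ionmode", mode))
        }
    }
    .md_drop(s, "ionmode")  # unknown spelling carries no information
}

.ADDUCT_TOKEN_RE <- "\\[[0-9]*M([+-][A-Za-z0-9]+)+\\][0-9]*[+-]?"

#' @rdname harmonizeFilters
#' @export
deriveAdductFromNameOrComment <- function(s) {
    for (field in c("compound_name", "comment")) {
        text <- .md_chr(s, field)
        if (is.null(text)) next
        m <- regexpr(.ADDUCT_TOKEN_RE, text)
        if (m == -1) next
        token <- regmatches(text, m)
        adduct <- .parse_adduct_or_null(token)
        if (is.null(adduct)) next
        stripped <- trimws(gsub("[[:space:];,]+$", "",
                                sub(.ADDUCT_TOKEN_RE, "", text)))
        s <- if (nzchar(stripped)) .md_set(s, field, stripped)
             else .md_drop(s, field)
        if (is.null(.md_get(s, "adduct")))
            s <- .md_set(s, "adduct", adduct@name)
        return(s)
    }
    s
}

#' @rdname harmonizeFilters
#' @export
deriveIonmodeFromAdduct <- function(s) {
    if (!is.null(.md_get(s, "ionmode"))) return(s)
    adduct <- .parse_adduct_or_null(.md_chr(s, "adduct"))
    if (is.null(adduct)) return(s)
    .md_set(s, "ionmode", adduct@ionmode)
}

#' @rdname harmonizeFilters
#' @export
deriveParentMass <- function(s, allow_default_adduct = FALSE) {
    if (!is.null(.md_num(s, "parent_mass"))) return(s)
    prec <- .md_num(s, "precursor_mz")
    if (is.null(prec) || prec <= 0) return(s)
    adduct <- .parse_adduct_or_null(.md_chr(s, "adduct"))
    if (is.null(adduct) && allow_default_adduct) {
        mode <- .md_chr(s, "ionmode")
        if (!is.null(mode) && mode %in% c("positive", "negative"))
            adduct <- parseAdduct(if (mode == "positive") "[M+H]+"
                                  else "[M-H]-")
    }
    if (is.null(adduct)) return(s)
    M <- tryCatch(parentMassFromPrecursor(prec, adduct),
                  error = function(e) NULL)
    if (is.null(M)) return(s)
    .md_set(s, "parent_mass", M)
}

#' @rdname harmonizeFilters
#' @export
normalizeIntensities <- function(s) {
    if (!length(s@intensity)) return(s)
    top <- max(s@intensity)
    if (top <= 0 || top == 1) return(s)
    initialize(s, intensity = s@intensity / top)
}

#' @rdname harmonizeFilters
#' @export
requirePrecursorMz <- function(s) {
    prec <- .md_num(s, "precursor_mz")
    if (is.null(prec) || is.na(prec) || prec <= 0 || prec > 5000)
        return(NULL)
    s
}
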