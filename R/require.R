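# Removal filters: pure predicates that enforce quality requirements after
# all repairs have run. They never modify a spectrum; output is the
# untouched input or NULL (removal), so the surviving set is invariant
# under any permutation of require filters.

#' Requirement (removal) filters
#'
#' Each filter checks one quality requirement and returns the input
#' [Spectrum-class] untouched when it passes, or `NULL` when the spectrum
#' must be removed. They run after all repair filters, so only spectra that
#' could not be repaired are removed.
#'
#' * `requireValidAnnotation()`: SMILES, InChI and InChIKey must all be
#'   present, individually well-formed, and describe the same 2D structure
#'   (equal InChIKey first blocks).
#' * `requireParentMassMatchSmiles()`: the monoisotopic mass of the SMILES
#'   must match the parent mass within `mass_tolerance`.
#' * `requireMatchingAdductPrecursorParent()`: the parent mass calculated
#'   from precursor m/z and adduct must match the stored parent mass; an
#'   unparseable adduct cannot be checked and the spectrum is removed.
#' * `requireMatchingAdductAndIonmode()`: removes only contradictions
#'   between the adduct's charge sign and the ion-mode field; a missing ion
#'   mode is not a contradiction.
#' * `requireMinimumNumberOfHighPeaks()`: at least `n_min` fragments with
#'   intensity at or above `intensity_fraction` of the base peak.
#'
#' @param s A [Spectrum-class].
#' @param mass_tolerance Mass-match tolerance in Da.
#' @param backend A structure backend, see [defaultStructureBackend()].
#' @param n_min Minimum number of qualifying fragments.
#' @param intensity_fraction Relative intensity threshold (fraction of the
#'   base peak).
#' @return The input [Spectrum-class] or `NULL`.
#' @name requireFilters
NULL

#' @rdname requireFilters
#' @export
requireValidAnnotation <- function(s, backend = defaultStructureBackend()) {
    smiles <- .md_chr(s, "smiles")
    inchi <- .md_chr(s, "inchi")
    inchikey <- .md_chr(s, "inchikey")
    if (is.null(smiles) || is.null(inchi) || is.null(inchikey)) return(NULL)
    if (!isValidInchikey(inchikey)) return(NULL)
    ok <- tryCatch(consistent2d(smiles, inchi, inchikey, backend = backend),
                   error = function(e) FALSE)
    if (ok) s else NULL
}

#' @rdname requireFilters
#' @export
requireParentMassMatchSmiles <- function(s, mass_tolerance = 0.1,
                                         backend = defaultStructureBackend()) {
    smiles <- .md_chr(s, "smiles")
    parent <- .md_num(s, "parent_mass")
    if (is.null(smiles) || is.null(parent)) return(NULL)
    mono <- .smiles_mono(smiles, backend)
    if (is.na(mono) || abs(mono - parent) > mass_tolerance) return(NULL)
    s
}

#' @rdname requireFilters
#' @export
requireMatchingAdductPrecursorParent <- function(s, mass_tolerance = 0.1) {
    adduct <- .parse_adduct_or_null(.md_chr(s, "adduct"))
    prec <- .md_num(s, "precursor_mz")
    parent <- .md_num(s, "parent_mass")
    if (is.null(adduct) || is.null(prec) || is.null(parent)) return(NULL)
    calc <- tryCatch(parentMassFromPrecursor(prec, adduct),
                     error = function(e) NA_real_)
    if (is.na(calc) || abs(calc - parent) > mass_tolerance) return(NULL)
    s
}

#' @rdname requireFilters
#' @export
requireMatchingAdductAndIonmode <- function(s) {
    adduct <- .parse_adduct_or_null(.md_chr(s, "adduct"))
    mode <- .md_chr(s, "ionmode")
    if (is.null(adduct) || is.null(mode) ||
        !mode %in% c("positive", "negative"))
        return(s)
    if (adduct@ionmode != mode) return(NULL)
    s
}

#' @rdname requireFilters
#' @export
requireMinimumNumberOfHighPeaks <- function(s, n_min = 5,
                                            intensity_fraction = 0.02) {
    if (n_min <= 0) return(s)
    if (!length(s@intensity)) return(NULL)
    top <- max(s@intensity)
    if (top <= 0) return(NULL)
    if (sum(s@intensity >= intensity_fraction * top) >= n_min) s else NULL
}
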