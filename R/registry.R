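# Filter registry: every registered filter has a stable snake_case id, a
# position in the predefined global order, a kind, and default parameters.
# Pipelines refer to filters by id; the global order guarantees that
# derivation runs before consumption (e.g. the adduct is retrieved from the
# compound name before any filter uses the adduct field) and that require
# filters run only after all repairs.

.filter_registry <- list(
    harmonize_metadata_keys = list(
        order = 10, kind = "harmonize", params = list(),
        fn = function(s, p, ctx) harmonizeMetadataKeys(s)),
    harmonize_ionmode = list(
        order = 20, kind = "harmonize", params = list(),
        fn = function(s, p, ctx) harmonizeIonmode(s)),
    derive_adduct_from_name_or_comment = list(
        order = 30, kind = "derive", params = list(),
        fn = function(s, p, ctx) deriveAdductFromNameOrComment(s)),
    derive_ionmode_from_adduct = list(
        order = 40, kind = "derive", params = list(),
        fn = function(s, p, ctx) deriveIonmodeFromAdduct(s)),
    derive_parent_mass = list(
        order = 50, kind = "derive",
        params = list(allow_default_adduct = FALSE),
        fn = function(s, p, ctx)
            deriveParentMass(s, allow_default_adduct =
                                 isTRUE(p$allow_default_adduct))),
    normalize_intensities = list(
        order = 60, kind = "normalize", params = list(),
        fn = function(s, p, ctx) normalizeIntensities(s)),
    derive_annotation_from_compound_name = list(
        order = 110, kind = "repair", params = list(),
        fn = function(s, p, ctx)
            deriveAnnotationFromCompoundName(s, ctx$resolver,
                                             ctx$mass_tolerance)),
    repair_smiles_of_salts = list(
        order = 120, kind = "repair", params = list(),
        fn = function(s, p, ctx)
            repairSmilesOfSalts(s, ctx$mass_tolerance, ctx$backend)),
    repair_parent_mass_is_molar_mass = list(
        order = 130, kind = "repair", params = list(),
        fn = function(s, p, ctx)
            repairParentMassIsMolarMass(s, ctx$mass_tolerance, ctx$backend)),
    repair_adduct_and_parent_mass_based_on_smiles = list(
        order = 140, kind = "repair", params = list(),
        fn = function(s, p, ctx)
            repairAdductAndParentMassBasedOnSmiles(s, ctx$mass_tolerance,
                                                   ctx$backend)),
    repair_not_matching_annotation = list(
        order = 150, kind = "repair", params = list(),
        fn = function(s, p, ctx)
            repairNotMatchingAnnotation(s, ctx$mass_tolerance, ctx$backend)),
    require_precursor_mz = list(
        order = 210, kind = "require", params = list(),
        fn = function(s, p, ctx) requirePrecursorMz(s)),
    require_matching_adduct_and_ionmode = list(
        order = 220, kind = "require", params = list(),
        fn = function(s, p, ctx) requireMatchingAdductAndIonmode(s)),
    require_valid_annotation = list(
        order = 230, kind = "require", params = list(),
        fn = function(s, p, ctx) requireValidAnnotation(s, ctx$backend)),
    require_parent_mass_match_smiles = list(
        order = 240, kind = "require", params = list(),
        fn = function(s, p, ctx)
            requireParentMassMatchSmiles(s, ctx$mass_tolerance, ctx$backend)),
    require_matching_adduct_precursor_parent = list(
        order = 250, kind = "require", params = list(),
        fn = function(s, p, ctx)
            requireMatchingAdductPrecursorParent(s, ctx$mass_tolerance)),
    require_minimum_number_of_high_peaks = list(
        order = 260, kind = "require",
        params = list(n_min = 5, intensity_fraction = 0.02),
        fn = function(s, p, ctx)
            requireMinimumNumberOfHighPeaks(
                s,
                n_min = p$n_min %||% 5,
                intensity_fraction = p$intensity_fraction %||% 0.02))
)

#' Registered filter ids
#'
#' All filter ids known to the pipeline engine, in the predefined global
#' order.
#'
#' @return Character vector of filter ids.
#' @examples
#' registeredFilters()
#' @export
registeredFilters <- function() {
    ids <- names(.filter_registry)
    ids[order(vapply(.filter_registry, `[[`, numeric(1), "order"))]
}

.filter_kind <- function(id) .filter_registry[[id]]$kind

.repair_filter_ids <- function()
    names(Filter(function(f) f$kind == "repair", .filter_registry))

#' Arrange filters in the predefined global order
#'
#' Stable-sorts a list of filter ids by the packaged global order index
#' (harmonization, derivation, intensity normalization, repairs, then
#' requirements); ties keep declaration order. Duplicates are kept once,
#' with a warning.
#'
#' @param ids Character vector of registered filter ids.
#' @return Reordered character vector.
#' @examples
#' canonicalOrder(c("require_valid_annotation", "harmonize_ionmode"))
#' @export
canonicalOrder <- function(ids) {
    unknown <- setdiff(ids, names(.filter_registry))
    if (length(unknown))
        stop("unknown filter id(s): ", paste(unknown, collapse = ", "))
    if (anyDuplicated(ids)) {
        warning("duplicate filter id(s) kept once: ",
                paste(unique(ids[duplicated(ids)]), collapse = ", "))
        ids <- unique(ids)
    }
    idx <- vapply(ids, function(id) .filter_registry[[id]]$order, numeric(1))
    ids[order(idx)]  # order() is stable
}
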