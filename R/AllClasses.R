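#' @import methods
NULL

#' AdductSpec: a parsed adduct
#'
#' Resolved form of an adduct string: canonical name, ion mode, signed charge
#' `z`, molecular multiplier `x` (the count of M in e.g. \[2M+H\]+) and the
#' mass shift delta in Da (gained minus lost species, electron-corrected),
#' so that `precursor_mz = (x * M + delta) / |z|`.
#'
#' @slot name Canonical adduct string, e.g. `"[M+H]+"`.
#' @slot ionmode `"positive"` or `"negative"`, always matching `sign(charge)`.
#' @slot charge Signed integer charge, never 0.
#' @slot multiplier Positive integer count of M.
#' @slot massShift Mass shift delta in Da.
#' @slot known `TRUE` if the adduct is in the built-in common-adduct table.
#' @seealso [parseAdduct()], [commonAdducts()]
#' @export
setClass("AdductSpec", representation(
    name = "character", ionmode = "character", charge = "integer",
    multiplier = "integer", massShift = "numeric", known = "logical"))

setValidity("AdductSpec", function(object) {
    msg <- character(0)
    if (object@charge == 0L) msg <- c(msg, "charge must be non-zero")
    if (object@multiplier < 1L) msg <- c(msg, "multiplier must be >= 1")
    ok_mode <- (object@charge > 0L) == (object@ionmode == "positive")
    if (!object@ionmode %in% c("positive", "negative") || !ok_mode)
        msg <- c(msg, "ionmode must match the sign of the charge")
    if (length(msg)) msg else TRUE
})

#' Spectrum: an annotated MS/MS spectrum
#'
#' The unit every filter consumes and returns: a harmonized metadata map
#' (lowercase underscore-separated keys, unique after harmonization) plus
#' fragment peak arrays sorted by m/z. Spectra are immutable in practice:
#' filters return a modified copy or `NULL` for removal, never mutate their
#' input.
#'
#' @slot metadata Named list of metadata values (string, number or NULL).
#' @slot mz Numeric vector of fragment m/z in Da, sorted non-decreasing.
#' @slot intensity Numeric vector of fragment intensities, same length as
#'   `mz`, all >= 0.
#' @seealso [makeSpectrum()], [spectrumMetadata()], [peaksMz()]
#' @export
setClass("Spectrum", representation(
    metadata = "list", mz = "numeric", intensity = "numeric"))

setValidity("Spectrum", function(object) {
    msg <- character(0)
    if (length(object@mz) != length(object@intensity))
        msg <- c(msg, "mz and intensity must have the same length")
    if (length(object@mz) && is.unsorted(object@mz))
        msg <- c(msg, "mz must be sorted in ascending order")
    if (length(object@intensity) && any(object@intensity < 0, na.rm = TRUE))
        msg <- c(msg, "intensities must be >= 0")
    nm <- names(object@metadata)
    if (length(object@metadata) &&
        (is.null(nm) || anyDuplicated(nm) || any(!nzchar(nm))))
        msg <- c(msg, "metadata must be uniquely named")
    if (length(msg)) msg else TRUE
})

#' FilterOutcome: per-spectrum change classification
#'
#' Records what a single filter did to a single spectrum, in the vocabulary
#' the processing report aggregates: removal, metadata change, peak change,
#' or nothing. A filter that changes both metadata and peaks records both
#' events.
#'
#' @slot filterName Registered filter id.
#' @slot removed `TRUE` if the filter removed the spectrum.
#' @slot metadataChanged `TRUE` if the metadata map changed.
#' @slot peaksChanged `TRUE` if the peak arrays changed.
#' @slot detail Optional human-readable description of the change.
#' @seealso [diffSpectra()]
#' @export
setClass("FilterOutcome", representation(
    filterName = "character", removed = "logical",
    metadataChanged = "logical", peaksChanged = "logical",
    detail = "character"))

setValidity("FilterOutcome", function(object) {
    if (object@removed && (object@metadataChanged || object@peaksChanged))
        "a removed spectrum records no change events"
    else TRUE
})

#' WorkflowConfig: an ordered, parameterized filter list
#'
#' The serializable description of a cleaning run: which filters, with which
#' parameters, in canonical order, plus the tool version that produced it.
#' Round-trips through YAML so that any run can be rerun exactly.
#'
#' @slot preset One of `"basic"`, `"default"`, `"library_cleaning"`,
#'   `"custom"`.
#' @slot filters List of `list(name = <filter id>, params = <named list>)`,
#'   in canonical global order.
#' @slot toolVersion Version string of the package that created the config.
#' @slot massTolerance Default mass-match tolerance in Da.
#' @seealso [buildPreset()], [writeWorkflowYaml()], [readWorkflowYaml()]
#' @export
setClass("WorkflowConfig", representation(
    preset = "character", filters = "list", toolVersion = "character",
    massTolerance = "numeric"))

setValidity("WorkflowConfig", function(object) {
    msg <- character(0)
    if (!object@preset %in% c("basic", "default", "library_cleaning",
                              "custom"))
        msg <- c(msg, "unknown preset")
    bad <- vapply(object@filters, function(f)
        !is.list(f) || !is.character(f$name) || !is.list(f$params),
        logical(1))
    if (any(bad)) msg <- c(msg, "each filter must be list(name, params)")
    if (object@massTolerance <= 0) msg <- c(msg, "massTolerance must be > 0")
    if (length(msg)) msg else TRUE
})

#' ProcessingReport: per-filter counters for a cleaning run
#'
#' Differentiates, per filter, between completely removing spectra, changing
#' the metadata and changing the peak information, plus run totals. A
#' spectrum is counted once at its removing filter but may be counted under
#' several filters' change counters.
#'
#' @slot counts `data.frame` with columns `filter`, `removed`,
#'   `metadata_changed`, `peaks_changed`, one row per filter in canonical
#'   order.
#' @slot spectraIn Number of input spectra.
#' @slot spectraOut Number of surviving spectra.
#' @slot spectraWithRepair Number of spectra changed by at least one repair
#'   filter.
#' @slot toolVersion Version string.
#' @seealso [runPipeline()], [writeReport()]
#' @export
setClass("ProcessingReport", representation(
    counts = "data.frame", spectraIn = "integer", spectraOut = "integer",
    spectraWithRepair = "integer", toolVersion = "character"))

setValidity("ProcessingReport", function(object) {
    msg <- character(0)
    need <- c("filter", "removed", "metadata_changed", "peaks_changed")
    if (!all(need %in% names(object@counts)))
        msg <- c(msg, "counts must have filter/removed/metadata_changed/peaks_changed")
    removed <- sum(object@counts$removed)
    if (object@spectraIn != object@spectraOut + removed)
        msg <- c(msg, "spectra_in must equal spectra_out + total removed")
    if (length(msg)) msg else TRUE
})
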