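# Pipeline engine: preset workflows, sequential execution with per-filter
# change accounting, YAML workflow serialization and processing reports.

.tool_version <- function() {
    as.character(utils::packageVersion("speclean"))
}

.preset_filter_ids <- function(preset) {
    basic <- c("harmonize_metadata_keys", "harmonize_ionmode")
    derive <- c("derive_adduct_from_name_or_comment",
                "derive_ionmode_from_adduct", "derive_parent_mass")
    default <- c(basic, derive, "normalize_intensities",
                 "require_precursor_mz")
    cleaning <- c(default, .repair_filter_ids(),
                  c("require_matching_adduct_and_ionmode",
                    "require_valid_annotation",
                    "require_parent_mass_match_smiles",
                    "require_matching_adduct_precursor_parent",
                    "require_minimum_number_of_high_peaks"))
    switch(preset, basic = basic, default = default,
           library_cleaning = cleaning,
           stop("unknown preset '", preset, "'"))
}

#' Build a preset workflow
#'
#' The three shipped pipelines: `"basic"` runs basic metadata harmonization;
#' `"default"` additionally derives missing metadata from other fields,
#' requires a precursor m/z and normalizes intensities; `"library_cleaning"`
#' runs all default filters plus every annotation repair, and requires
#' complete, consistent annotations after all repairs have run. The presets
#' nest: basic < default < library_cleaning.
#'
#' @param preset `"basic"`, `"default"` or `"library_cleaning"`.
#' @param mass_tolerance Mass-match tolerance in Da used by every filter
#'   that asserts a mass match.
#' @return A [WorkflowConfig-class].
#' @examples
#' buildPreset("basic")
#' @export
buildPreset <- function(preset = c("library_cleaning", "basic", "default"),
                        mass_tolerance = 0.1) {
    preset <- match.arg(preset)
    ids <- canonicalOrder(.preset_filter_ids(preset))
    filters <- lapply(ids, function(id)
        list(name = id, params = .filter_registry[[id]]$params))
    new("WorkflowConfig", preset = preset, filters = filters,
        toolVersion = .tool_version(), massTolerance = mass_tolerance)
}

#' Build a custom workflow
#'
#' @param ids Registered filter ids (any order; canonical order is applied).
#' @param params Named list: filter id -> named list of parameter overrides.
#' @param mass_tolerance Mass-match tolerance in Da.
#' @return A [WorkflowConfig-class] with `preset = "custom"`.
#' @export
buildWorkflow <- function(ids, params = list(), mass_tolerance = 0.1) {
    ids <- canonicalOrder(ids)
    filters <- lapply(ids, function(id) {
        p <- utils::modifyList(.filter_registry[[id]]$params,
                               params[[id]] %||% list())
        list(name = id, params = p)
    })
    new("WorkflowConfig", preset = "custom", filters = filters,
        toolVersion = .tool_version(), massTolerance = mass_tolerance)
}

#' @rdname accessors
#' @export
setMethod("workflowFilters", "WorkflowConfig", function(object)
    object@filters)

#' @rdname accessors
#' @export
setMethod("workflowPreset", "WorkflowConfig", function(object)
    object@preset)

setMethod("show", "WorkflowConfig", function(object) {
    cat("WorkflowConfig (preset: ", object@preset, ", ",
        length(object@filters), " filters, mass tolerance ",
        object@massTolerance, " Da)\n", sep = "")
    for (f in object@filters) cat("  -", f$name, "\n")
})

#' Run a cleaning pipeline
#'
#' Applies the workflow's filters, in canonical global order, to each
#' spectrum in turn. A filter returns a modified copy of the spectrum or
#' `NULL`; on `NULL` the spectrum is removed and attributed to that filter
#' (it never reaches later filters). The run is fully deterministic:
#' identical inputs and config give identical outputs and report.
#'
#' @param spectra List of [Spectrum-class].
#' @param config A [WorkflowConfig-class], e.g. from [buildPreset()].
#' @param backend Structure backend, see [defaultStructureBackend()].
#' @param resolver Compound-name resolver, see [tableNameResolver()]; the
#'   default resolves offline against the packaged compound table.
#' @param audit_repairs If `TRUE`, repair filters propose and record their
#'   changes (counted in the report and change log) but the spectrum is
#'   passed on unmodified - the audit mode used for error-rate estimation.
#' @param log_level `"none"`, `"info"` (per-filter summary messages) or
#'   `"debug"` (additionally one message per changed spectrum).
#' @return A list with elements `spectra` (surviving spectra), `report`
#'   (a [ProcessingReport-class]), `changes` (`data.frame` with columns
#'   `index`, `filter`, `event` - one row per recorded event) and
#'   `kept_indices` (input indices of the survivors).
#' @examples
#' s <- makeSpectrum(list(ionmode = "Pos", pepmass = 181.0707), 100, 1)
#' out <- runPipeline(list(s), buildPreset("basic"))
#' reportTotals(out$report)
#' @export
runPipeline <- function(spectra, config,
                        backend = defaultStructureBackend(),
                        resolver = defaultNameResolver(),
                        audit_repairs = FALSE,
                        log_level = c("none", "info", "debug")) {
    log_level <- match.arg(log_level)
    stopifnot(is(config, "WorkflowConfig"))
    ids <- vapply(config@filters, `[[`, character(1), "name")
    params <- lapply(config@filters, `[[`, "params")
    ids_order <- canonicalOrder(ids)
    ord <- match(ids_order, ids)
    ids <- ids[ord]; params <- params[ord]
    ctx <- list(backend = backend, resolver = resolver,
                mass_tolerance = config@massTolerance)

    counters <- data.frame(filter = ids, removed = 0L, metadata_changed = 0L,
                           peaks_changed = 0L, stringsAsFactors = FALSE)
    changes <- list()
    kept <- list(); kept_idx <- integer(0)
    repair_ids <- .repair_filter_ids()
    n_repaired_spectra <- 0L

    for (i in seq_along(spectra)) {
        s <- spectra[[i]]
        if (!is(s, "Spectrum"))
            stop("input ", i, " is not a Spectrum")
        removed <- FALSE
        touched_by_repair <- FALSE
        for (j in seq_along(ids)) {
            id <- ids[j]
            out <- tryCatch(
                .filter_registry[[id]]$fn(s, params[[j]], ctx),
                error = function(e)
                    stop("filter '", id, "' failed on spectrum ", i, ": ",
                         conditionMessage(e)))
            outcome <- diffSpectra(s, out, id)
            if (outcome@removed) {
                counters$removed[j] <- counters$removed[j] + 1L
                changes[[length(changes) + 1L]] <-
                    list(index = i, filter = id, event = "removed")
                if (log_level == "debug")
                    message("spectrum ", i, ": removed by ", id)
                removed <- TRUE
                break
            }
            if (outcome@metadataChanged) {
                counters$metadata_changed[j] <-
                    counters$metadata_changed[j] + 1L
                changes[[length(changes) + 1L]] <-
                    list(index = i, filter = id, event = "metadata_changed")
                if (id %in% repair_ids) touched_by_repair <- TRUE
                if (log_level == "debug")
                    message("spectrum ", i, ": metadata changed by ", id)
            }
            if (outcome@peaksChanged) {
                counters$peaks_changed[j] <- counters$peaks_changed[j] + 1L
                changes[[length(changes) + 1L]] <-
                    list(index = i, filter = id, event = "peaks_changed")
                if (log_level == "debug")
                    message("spectrum ", i, ": peaks changed by ", id)
            }
            if (!(audit_repairs && id %in% repair_ids))
                s <- out
        }
        if (!removed) {
            kept[[length(kept) + 1L]] <- s
            kept_idx <- c(kept_idx, i)
            if (touched_by_repair)
                n_repaired_spectra <- n_repaired_spectra + 1L
        }
    }

    if (log_level %in% c("info", "debug"))
        for (j in seq_along(ids))
            message(sprintf("%-45s removed %5d  metadata %5d  peaks %5d",
                            ids[j], counters$removed[j],
                            counters$metadata_changed[j],
                            counters$peaks_changed[j]))

    changes_df <- if (length(changes))
        data.frame(index = vapply(changes, function(x)
                       as.integer(x$index), integer(1)),
                   filter = vapply(changes, `[[`, character(1), "filter"),
                   event = vapply(changes, `[[`, character(1), "event"),
                   stringsAsFactors = FALSE)
    else data.frame(index = integer(0), filter = character(0),
                    event = character(0), stringsAsFactors = FALSE)

    report <- new("ProcessingReport", counts = counters,
                  spectraIn = length(spectra), spectraOut = length(kept),
                  spectraWithRepair = n_repaired_spectra,
                  toolVersion = .tool_version())
    list(spectra = kept, report = report, changes = changes_df,
         kept_indices = kept_idx)
}

.default_resolver_cache <- new.env(parent = emptyenv())

#' @rdname nameResolver
#' @export
defaultNameResolver <- function() {
    if (is.null(.default_resolver_cache$resolver))
        .default_resolver_cache$resolver <- tableNameResolver()
    .default_resolver_cache$resolver
}

#' @rdname accessors
#' @export
setMethod("reportCounts", "ProcessingReport", function(object) object@counts)

#' @rdname accessors
#' @export
setMethod("reportTotals", "ProcessingReport", function(object) {
    c(spectra_in = object@spectraIn, spectra_out = object@spectraOut,
      spectra_removed = sum(object@counts$removed),
      spectra_with_any_repair = object@spectraWithRepair)
})

setMethod("show", "ProcessingReport", function(object) {
    t <- reportTotals(object)
    cat("ProcessingReport:", t[["spectra_in"]], "spectra in,",
        t[["spectra_out"]], "out,", t[["spectra_removed"]], "removed,",
        t[["spectra_with_any_repair"]], "repaired\n")
    print(object@counts, row.names = FALSE)
})

# --- workflow YAML -----------------------------------------------------------

#' Serialize / load a workflow as YAML
#'
#' A cleaning run's complete configuration - every filter with its
#' parameters, the mass tolerance and the tool version - round-trips
#' through a human-readable YAML file that can be shared and used directly
#' to rerun the pipeline. On load, filter ids are validated against the
#' registry (unknown ids are an error), the canonical order is restored,
#' and a tool-version mismatch warns but proceeds.
#'
#' @param config A [WorkflowConfig-class].
#' @param path YAML file path.
#' @return `readWorkflowYaml()` returns a [WorkflowConfig-class];
#'   `writeWorkflowYaml()` invisibly returns `path`.
#' @examples
#' p <- tempfile(fileext = ".yaml")
#' writeWorkflowYaml(buildPreset("basic"), p)
#' readWorkflowYaml(p)
#' @export
writeWorkflowYaml <- function(config, path) {
    stopifnot(is(config, "WorkflowConfig"))
    doc <- list(
        tool = "speclean",
        tool_version = config@toolVersion,
        preset = config@preset,
        mass_tolerance = config@massTolerance,
        filters = lapply(config@filters, function(f)
            list(name = f$name,
                 params = if (length(f$params)) f$params else NULL)))
    yaml::write_yaml(doc, path)
    invisible(path)
}

#' @rdname writeWorkflowYaml
#' @export
readWorkflowYaml <- function(path) {
    doc <- yaml::read_yaml(path)
    if (is.null(doc$filters))
        stop("workflow YAML has no 'filters' list: ", path)
    ids <- vapply(doc$filters, function(f) as.character(f$name), character(1))
    unknown <- setdiff(ids, names(.filter_registry))
    if (length(unknown))
        stop("workflow YAML names unknown filter(s): ",
             paste(unknown, collapse = ", "))
    ver <- doc$tool_version %||% "unknown"
    if (!identical(ver, .tool_version()))
        warning("workflow was written by tool version ", ver,
                ", running version is ", .tool_version())
    params <- stats::setNames(
        lapply(doc$filters, function(f) as.list(f$params %||% list())), ids)
    ids_c <- canonicalOrder(ids)
    filters <- lapply(ids_c, function(id)
        list(name = id,
             params = utils::modifyList(.filter_registry[[id]]$params,
                                        params[[id]])))
    new("WorkflowConfig",
        preset = doc$preset %||% "custom",
        filters = filters,
        toolVersion = .tool_version(),
        massTolerance = as.numeric(doc$mass_tolerance %||% 0.1))
}

# --- report files ------------------------------------------------------------

#' Write a processing report to a file
#'
#' One row per filter with the removed / metadata-changed / peaks-changed
#' counters, followed by a totals block; rows follow the canonical filter
#' order, so output is deterministic. The TSV and markdown renderings encode
#' identical numbers.
#'
#' @param report A [ProcessingReport-class].
#' @param path Output path.
#' @param format `"tsv"` or `"markdown"`.
#' @return Invisibly, `path`.
#' @export
writeReport <- function(report, path, format = c("tsv", "markdown")) {
    format <- match.arg(format)
    stopifnot(is(report, "ProcessingReport"))
    cts <- report@counts
    t <- reportTotals(report)
    lines <- if (format == "tsv") {
        c(paste0("# speclean processing report (tool version ",
                 report@toolVersion, ")"),
          "filter\tremoved\tmetadata_changed\tpeaks_changed",
          sprintf("%s\t%d\t%d\t%d", cts$filter, cts$removed,
                  cts$metadata_changed, cts$peaks_changed),
          sprintf("#total\t%s\t%d", names(t), unname(t)))
    } else {
        c(paste0("# Processing report (tool version ",
                 report@toolVersion, ")"),
          "",
          "| filter | removed | metadata changed | peaks changed |",
          "|---|---|---|---|",
          sprintf("| %s | %d | %d | %d |", cts$filter, cts$removed,
                  cts$metadata_changed, cts$peaks_changed),
          "",
          sprintf("- %s: %d", names(t), unname(t)))
    }
    con <- file(path, open = "wb")
    on.exit(close(con))
    writeLines(lines, con, sep = "\n", useBytes = TRUE)
    invisible(path)
}
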