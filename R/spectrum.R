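# Spectrum construction, metadata harmonization and change classification.

.pkg_cache <- new.env(parent = emptyenv())

# Key alias table: raw key (lowercased, separators -> "_") -> harmonized key.
# Shipped as editable two-column TSV under inst/extdata.
.key_aliases <- function() {
    if (is.null(.pkg_cache$key_aliases)) {
        path <- system.file("extdata", "metadata_key_aliases.tsv",
                            package = "speclean", mustWork = TRUE)
        tab <- utils::read.delim(path, comment.char = "#",
                                 stringsAsFactors = FALSE)
        .pkg_cache$key_aliases <- stats::setNames(tab$harmonized, tab$raw)
    }
    .pkg_cache$key_aliases
}

.harmonize_key <- function(key) {
    k <- tolower(trimws(key))
    k <- gsub("[ \\-]+", "_", k)
    aliases <- .key_aliases()
    if (k %in% names(aliases)) unname(aliases[[k]]) else k
}

.is_plain_number <- function(s) {
    grepl("^[+-]?([0-9]+\\.?[0-9]*|\\.[0-9]+)([eE][+-]?[0-9]+)?$", trimws(s))
}

# Parse one raw metadata value. Numbers become doubles; charge strings like
# "2-" become signed numbers (losslessly invertible under the writer's
# conventions).
.parse_metadata_value <- function(key, value) {
    if (is.null(value) || (length(value) == 1L && is.na(value)))
        return(NULL)
    if (is.numeric(value))
        return(as.numeric(value))
    if (!is.character(value) || length(value) != 1L)
        return(value)
    s <- trimws(value)
    if (!nzchar(s))
        return(NULL)
    if (key == "charge") {
        m <- regexec("^([+-]?)([0-9]+)([+-]?)$", s)[[1]]
        if (m[1] != -1) {
            g <- regmatches(s, list(m))[[1]]
            sign <- if (g[2] == "-" || g[4] == "-") -1 else 1
            return(sign * as.numeric(g[3]))
        }
        return(s)
    }
    if (.is_plain_number(s))
        return(as.numeric(s))
    s
}

#' Construct a Spectrum
#'
#' Builds a valid [Spectrum-class] from raw metadata and peak arrays. Raw
#' metadata keys of arbitrary case and spelling are lowercased and mapped
#' through the packaged key-alias table (e.g. `PEPMASS` -> `precursor_mz`);
#' numeric-looking values are parsed to numbers; peaks are sorted by
#' ascending m/z with ties kept in input order. Harmonization is idempotent:
#' rebuilding a spectrum from its own metadata changes nothing.
#'
#' @param metadata Named list (or vector) of raw metadata.
#' @param mz Numeric vector of fragment m/z (Da).
#' @param intensities Numeric vector of fragment intensities, same length.
#' @return A [Spectrum-class].
#' @examples
#' s <- makeSpectrum(list(PEPMASS = "181.0707"), c(81, 109), c(10, 100))
#' metadataValue(s, "precursor_mz")
#' @export
makeSpectrum <- function(metadata = list(), mz = numeric(0),
                         intensities = numeric(0)) {
    if (length(mz) != length(intensities))
        stop("mz and intensities must have the same length")
    mz <- as.numeric(mz)
    intensities <- as.numeric(intensities)
    if (any(is.na(mz)) || any(is.na(intensities)))
        stop("peaks must not contain NA")
    if (any(intensities < 0))
        stop("intensities must be >= 0")
    md <- as.list(metadata)
    out <- list()
    for (i in seq_along(md)) {
        key <- .harmonize_key(names(md)[i])
        if (!nzchar(key)) stop("empty metadata key")
        value <- .parse_metadata_value(key, md[[i]])
        if (is.null(value)) next
        if (key %in% names(out)) {
            # keep first occurrence; aliases collapsing onto an existing
            # harmonized key must not overwrite it
            next
        }
        out[[key]] <- value
    }
    ord <- order(mz)  # stable in R: ties keep input order
    new("Spectrum", metadata = out, mz = mz[ord], intensity = intensities[ord])
}

#' @rdname accessors
#' @export
setMethod("spectrumMetadata", "Spectrum", function(object) object@metadata)

#' @rdname accessors
#' @export
setMethod("metadataValue", "Spectrum", function(object, key, default = NULL) {
    v <- object@metadata[[key]]
    if (is.null(v)) default else v
})

#' @rdname accessors
#' @export
setMethod("peaksMz", "Spectrum", function(object) object@mz)

#' @rdname accessors
#' @export
setMethod("peaksIntensity", "Spectrum", function(object) object@intensity)

#' @rdname accessors
#' @export
setMethod("peakCount", "Spectrum", function(object) length(object@mz))

setMethod("show", "Spectrum", function(object) {
    cat("Spectrum with", length(object@mz), "peaks\n")
    keys <- c("compound_name", "precursor_mz", "parent_mass", "adduct",
              "ionmode", "smiles")
    for (k in intersect(keys, names(object@metadata)))
        cat(" ", k, ": ", format(object@metadata[[k]]), "\n", sep = "")
    extra <- setdiff(names(object@metadata), keys)
    if (length(extra))
        cat("  (+", length(extra), "more metadata fields)\n")
})

# --- internal metadata helpers (copy-on-write) -------------------------------

.md_get <- function(s, key) {
    v <- s@metadata[[key]]
    if (is.null(v) || (length(v) == 1L && is.na(v))) NULL else v
}

.md_num <- function(s, key) {
    v <- .md_get(s, key)
    if (is.null(v) || !is.numeric(v)) NULL else v
}

.md_chr <- function(s, key) {
    v <- .md_get(s, key)
    if (is.null(v)) NULL else as.character(v)
}

.md_set <- function(s, key, value) {
    md <- s@metadata
    md[[key]] <- value
    initialize(s, metadata = md)
}

.md_drop <- function(s, keys) {
    md <- s@metadata
    md[keys] <- NULL
    initialize(s, metadata = md)
}

# --- change classification ---------------------------------------------------

.metadata_equal <- function(a, b) {
    a <- a[!vapply(a, is.null, logical(1))]
    b <- b[!vapply(b, is.null, logical(1))]
    if (!setequal(names(a), names(b))) return(FALSE)
    for (k in names(a)) {
        va <- a[[k]]; vb <- b[[k]]
        if (is.numeric(va) && is.numeric(vb)) {
            if (!isTRUE(all.equal(as.numeric(va), as.numeric(vb),
                                  tolerance = 0)))
                return(FALSE)
        } else if (!identical(va, vb)) {
            return(FALSE)
        }
    }
    TRUE
}

.peaks_equal <- function(a, b) {
    identical(a@mz, b@mz) && identical(a@intensity, b@intensity)
}

#' Classify what a filter did to a spectrum
#'
#' Compares a spectrum before and after one filter and returns a
#' [FilterOutcome-class]: removal when `after` is `NULL`, otherwise
#' metadata and/or peak change flags; both are recorded when both differ.
#'
#' @param before The input [Spectrum-class].
#' @param after The filter output: a [Spectrum-class] or `NULL` for removal.
#' @param filter_name Registered filter id, recorded in the outcome.
#' @return A [FilterOutcome-class].
#' @examples
#' s <- makeSpectrum(list(ionmode = "Pos"))
#' outcomeStatus(diffSpectra(s, s, "noop"))
#' @export
diffSpectra <- function(before, after, filter_name) {
    stopifnot(is(before, "Spectrum"))
    if (is.null(after))
        return(new("FilterOutcome", filterName = filter_name, removed = TRUE,
                   metadataChanged = FALSE, peaksChanged = FALSE,
                   detail = NA_character_))
    stopifnot(is(after, "Spectrum"))
    new("FilterOutcome", filterName = filter_name, removed = FALSE,
        metadataChanged = !.metadata_equal(before@metadata, after@metadata),
        peaksChanged = !.peaks_equal(before, after),
        detail = NA_character_)
}

#' @rdname accessors
#' @export
setMethod("outcomeStatus", "FilterOutcome", function(object) {
    if (object@removed) return("removed")
    ev <- c(if (object@metadataChanged) "metadata_changed",
            if (object@peaksChanged) "peaks_changed")
    if (is.null(ev)) "unchanged" else ev
})

setMethod("show", "FilterOutcome", function(object) {
    cat("FilterOutcome [", object@filterName, "]: ",
        paste(outcomeStatus(object), collapse = " + "), "\n", sep = "")
})

#' @rdname accessors
#' @export
setMethod("adductName", "AdductSpec", function(object) object@name)

#' @rdname accessors
#' @export
setMethod("adductIonmode", "AdductSpec", function(object) object@ionmode)

#' @rdname accessors
#' @export
setMethod("adductCharge", "AdductSpec", function(object) object@charge)

#' @rdname accessors
#' @export
setMethod("adductMultiplier", "AdductSpec", function(object) object@multiplier)

#' @rdname accessors
#' @export
setMethod("adductMassShift", "AdductSpec", function(object) object@massShift)

setMethod("show", "AdductSpec", function(object) {
    cat("AdductSpec ", object@name, " (z=", object@charge,
        ", x=", object@multiplier,
        ", delta=", sprintf("%.6f", object@massShift), " Da)\n", sep = "")
})
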