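# Reading and writing spectral libraries: MGF, MSP and a JSON record dialect.
#
# All three readers preserve unknown metadata keys verbatim (lowercased and
# alias-harmonized); the writers emit metadata in a fixed canonical key order
# with fixed float precision, so two writes of the same library are
# byte-identical. Encoding is UTF-8, line ending "\n".

.canonical_key_head <- c(
    "compound_name", "precursor_mz", "parent_mass", "charge", "ionmode",
    "adduct", "formula", "smiles", "inchi", "inchikey", "spectrum_id")

.ordered_keys <- function(md) {
    keys <- names(md)
    c(intersect(.canonical_key_head, keys),
      sort(setdiff(keys, .canonical_key_head)))
}

.render_value <- function(key, v, dialect = c("mgf", "msp")) {
    if (is.numeric(v)) {
        if (key == "charge" && v == round(v)) {
            return(paste0(abs(v), if (v < 0) "-" else "+"))
        }
        return(sprintf("%.6f", v))
    }
    as.character(v)
}

.detect_format <- function(path) {
    ext <- tolower(tools::file_ext(path))
    switch(ext, mgf = "mgf", msp = "msp", json = "json",
           stop("cannot detect library format from extension '.", ext, "'"))
}

#' Read a spectral library
#'
#' Reads an annotated MS/MS library from MGF (`BEGIN IONS`/`END IONS`
#' blocks), MSP (`Name:`/`Num Peaks:` records) or a JSON array of
#' `{"metadata": ..., "mz": ..., "intensities": ...}` records. Every record
#' becomes a harmonized [Spectrum-class]; unknown metadata keys are kept
#' verbatim (lowercased). An empty file yields an empty list.
#'
#' @param path File path.
#' @param format `"auto"` (detect from extension), `"mgf"`, `"msp"` or
#'   `"json"`.
#' @return List of [Spectrum-class].
#' @seealso [writeLibrary()]
#' @export
readLibrary <- function(path, format = c("auto", "mgf", "msp", "json")) {
    format <- match.arg(format)
    if (!file.exists(path)) stop("no such file: ", path)
    if (format == "auto") format <- .detect_format(path)
    switch(format,
           mgf = .read_mgf(path),
           msp = .read_msp(path),
           json = .read_json(path))
}

#' Write a spectral library
#'
#' Writes spectra in MGF, MSP or the JSON record dialect. Metadata keys are
#' written in a fixed canonical order, masses with 6 decimals, charge in
#' `"1+"`/`"2-"` notation (MGF/MSP); absent fields are omitted entirely.
#' Output is deterministic: writing the same library twice produces
#' byte-identical files.
#'
#' @param spectra List of [Spectrum-class].
#' @param path Output file path.
#' @param format `"mgf"`, `"msp"` or `"json"` (default: from extension).
#' @return Invisibly, `path`.
#' @export
writeLibrary <- function(spectra, path, format = c("auto", "mgf", "msp",
                                                   "json")) {
    format <- match.arg(format)
    if (format == "auto") format <- .detect_format(path)
    stopifnot(all(vapply(spectra, is, logical(1), "Spectrum")))
    txt <- switch(format,
                  mgf = .format_mgf(spectra),
                  msp = .format_msp(spectra),
                  json = .format_json(spectra))
    con <- file(path, open = "wb")
    on.exit(close(con))
    writeLines(txt, con, sep = "\n", useBytes = TRUE)
    invisible(path)
}

# --- MGF ---------------------------------------------------------------------

.read_mgf <- function(path) {
    lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
    spectra <- list()
    i <- 1L; n <- length(lines); rec <- 0L
    while (i <= n) {
        line <- trimws(lines[i])
        if (line == "BEGIN IONS") {
            rec <- rec + 1L
            md <- list(); mz <- numeric(0); int <- numeric(0)
            i <- i + 1L
            closed <- FALSE
            while (i <= n) {
                line <- trimws(lines[i])
                if (line == "END IONS") { closed <- TRUE; break }
                if (nzchar(line) && !startsWith(line, "#")) {
                    if (grepl("=", line, fixed = TRUE)) {
                        kv <- regmatches(line, regexpr("=", line),
                                         invert = TRUE)[[1]]
                        key <- kv[1]; val <- kv[2]
                        if (toupper(key) == "PEPMASS") {
                            # tolerate "mz intensity" tuple; first element
                            val <- strsplit(trimws(val), "[[:space:]]+")[[1]][1]
                        }
                        md[[key]] <- val
                    } else {
                        parts <- strsplit(line, "[[:space:]]+")[[1]]
                        vals <- suppressWarnings(as.numeric(parts))
                        if (length(parts) < 2L || anyNA(vals[1:2]))
                            stop("malformed peak line in MGF record ", rec,
                                 ": '", line, "'")
                        mz <- c(mz, vals[1]); int <- c(int, vals[2])
                    }
                }
                i <- i + 1L
            }
            if (!closed)
                stop("MGF record ", rec, " is missing END IONS")
            spectra[[rec]] <- tryCatch(
                makeSpectrum(md, mz, int),
                error = function(e) stop("malformed MGF record ", rec, ": ",
                                         conditionMessage(e)))
        }
        i <- i + 1L
    }
    spectra
}

.format_mgf <- function(spectra) {
    out <- character(0)
    for (s in spectra) {
        md <- s@metadata
        lines <- c("BEGIN IONS")
        for (k in .ordered_keys(md)) {
            mgf_key <- switch(k, precursor_mz = "PEPMASS", toupper(k))
            lines <- c(lines, paste0(mgf_key, "=",
                                     .render_value(k, md[[k]], "mgf")))
        }
        lines <- c(lines,
                   sprintf("%.6f %.6f", s@mz, s@intensity),
                   "END IONS", "")
        out <- c(out, lines)
    }
    out
}

# --- MSP ---------------------------------------------------------------------

.read_msp <- function(path) {
    lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
    spectra <- list()
    i <- 1L; n <- length(lines); rec <- 0L
    while (i <= n) {
        while (i <= n && !nzchar(trimws(lines[i]))) i <- i + 1L
        if (i > n) break
        rec <- rec + 1L
        md <- list(); npeaks <- NA_integer_
        while (i <= n && nzchar(trimws(lines[i]))) {
            line <- trimws(lines[i])
            m <- regexec("^([^:]+):[[:space:]]*(.*)$", line)[[1]]
            if (m[1] == -1)
                stop("malformed header line in MSP record ", rec, ": '",
                     line, "'")
            g <- regmatches(line, list(m))[[1]]
            key <- trimws(g[2]); val <- g[3]
            if (tolower(gsub("[ \\-]", "_", key)) == "num_peaks") {
                npeaks <- as.integer(val)
                i <- i + 1L
                break
            }
            md[[key]] <- val
            i <- i + 1L
        }
        if (is.na(npeaks))
            stop("MSP record ", rec, " has no 'Num Peaks:' line")
        mz <- numeric(0); int <- numeric(0)
        while (i <= n && nzchar(trimws(lines[i]))) {
            pairs <- strsplit(trimws(lines[i]), ";")[[1]]
            for (p in pairs) {
                p <- trimws(p)
                if (!nzchar(p)) next
                parts <- strsplit(p, "[[:space:]]+")[[1]]
                vals <- suppressWarnings(as.numeric(parts))
                if (length(parts) < 2L || anyNA(vals[1:2]))
                    stop("malformed peak line in MSP record ", rec, ": '",
                         p, "'")
                mz <- c(mz, vals[1]); int <- c(int, vals[2])
            }
            i <- i + 1L
        }
        if (length(mz) != npeaks)
            stop("MSP record ", rec, " declares ", npeaks, " peaks but has ",
                 length(mz))
        spectra[[rec]] <- tryCatch(
            makeSpectrum(md, mz, int),
            error = function(e) stop("malformed MSP record ", rec, ": ",
                                     conditionMessage(e)))
    }
    spectra
}

.format_msp <- function(spectra) {
    out <- character(0)
    for (s in spectra) {
        md <- s@metadata
        lines <- character(0)
        for (k in .ordered_keys(md)) {
            msp_key <- switch(k, compound_name = "Name",
                              precursor_mz = "PrecursorMZ", k)
            lines <- c(lines, paste0(msp_key, ": ",
                                     .render_value(k, md[[k]], "msp")))
        }
        lines <- c(lines, paste0("Num Peaks: ", length(s@mz)),
                   sprintf("%.6f %.6f", s@mz, s@intensity), "")
        out <- c(out, lines)
    }
    out
}

# --- JSON --------------------------------------------------------------------

.read_json <- function(path) {
    txt <- paste(readLines(path, encoding = "UTF-8", warn = FALSE),
                 collapse = "\n")
    if (!nzchar(trimws(txt))) return(list())
    recs <- jsonlite::fromJSON(txt, simplifyVector = FALSE)
    lapply(seq_along(recs), function(i) {
        r <- recs[[i]]
        if (!is.list(r) || is.null(r$mz) || is.null(r$intensities))
            stop("malformed JSON record ", i)
        tryCatch(
            makeSpectrum(r$metadata %||% list(),
                         unlist(r$mz) %||% numeric(0),
                         unlist(r$intensities) %||% numeric(0)),
            error = function(e) stop("malformed JSON record ", i, ": ",
                                     conditionMessage(e)))
    })
}

.format_json <- function(spectra) {
    recs <- lapply(spectra, function(s) {
        md <- s@metadata[.ordered_keys(s@metadata)]
        list(metadata = md, mz = s@mz, intensities = s@intensity)
    })
    jsonlite::toJSON(recs, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                     null = "null")
}

#' Metadata equivalence of two spectra
#'
#' Two spectra are metadata-equivalent when their harmonized metadata maps
#' have the same keys and equal values, comparing numbers within a
#' tolerance. This is the round-trip guarantee of [writeLibrary()] /
#' [readLibrary()]: fixed-precision rendering may perturb masses at the
#' sub-ppm level but never changes what the metadata says.
#'
#' @param a,b [Spectrum-class] objects.
#' @param tolerance Absolute numeric tolerance.
#' @return Logical.
#' @export
metadataEquivalent <- function(a, b, tolerance = 1e-6) {
    ma <- a@metadata[!vapply(a@metadata, is.null, logical(1))]
    mb <- b@metadata[!vapply(b@metadata, is.null, logical(1))]
    if (!setequal(names(ma), names(mb))) return(FALSE)
    for (k in names(ma)) {
        va <- ma[[k]]; vb <- mb[[k]]
        if (is.numeric(va) && is.numeric(vb)) {
            if (abs(va - vb) > tolerance) return(FALSE)
        } else if (!identical(as.character(va), as.character(vb))) {
            return(FALSE)
        }
    }
    TRUE
}
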