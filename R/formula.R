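# Molecular-formula parsing and mass summation.

#' Parse a molecular formula
#'
#' Parses a Hill-style molecular formula ("C6H12O6", "H2O") into a named
#' integer vector of element counts. Multi-letter element symbols are
#' supported; isotope labels, charges, parentheses and hydrate dots are not.
#'
#' @param text A single formula string.
#' @return Named integer vector, element symbol -> count (all counts >= 1).
#' @examples
#' parseFormula("C6H12O6")
#' @export
parseFormula <- function(text) {
    if (!is.character(text) || length(text) != 1L || is.na(text))
        stop("formula must be a single string")
    text <- trimws(text)
    if (!nzchar(text))
        stop("empty formula")
    matches <- gregexpr("[A-Z][a-z]?[0-9]*", text)[[1]]
    tokens <- regmatches(text, list(matches))[[1]]
    if (sum(attr(matches, "match.length")) != nchar(text))
        stop("cannot parse formula: '", text, "'")
    counts <- integer(0)
    known <- .element_masses$element
    for (tok in tokens) {
        sym <- gsub("[0-9]+", "", tok)
        n <- sub("^[A-Za-z]+", "", tok)
        n <- if (nzchar(n)) as.integer(n) else 1L
        if (!(sym %in% known))
            stop("unknown element '", sym, "' in formula '", text, "'")
        if (n < 1L)
            stop("zero count for element '", sym, "' in formula '", text, "'")
        counts[sym] <- (if (sym %in% names(counts)) counts[[sym]] else 0L) + n
    }
    counts
}

.formula_mass <- function(f, column) {
    if (is.character(f))
        f <- parseFormula(f)
    idx <- match(names(f), .element_masses$element)
    if (anyNA(idx))
        stop("unknown element(s): ",
             paste(names(f)[is.na(idx)], collapse = ", "))
    sum(as.numeric(f) * .element_masses[[column]][idx])
}

#' Monoisotopic and average mass of a formula
#'
#' `monoisotopicMass()` sums the masses of the most abundant isotopes;
#' `averageMass()` sums standard atomic weights (the molar mass). The
#' difference between the two is a recurring source of parent-mass errors in
#' public spectral libraries.
#'
#' @param f A formula string or a named count vector from [parseFormula()].
#' @return Mass in Da.
#' @examples
#' monoisotopicMass("C6H12O6")  # 180.0634
#' averageMass("C6H12O6")       # 180.156
#' @export
monoisotopicMass <- function(f) .formula_mass(f, "monoisotopic")

#' @rdname monoisotopicMass
#' @export
averageMass <- function(f) .formula_mass(f, "average")

# Number of non-hydrogen atoms; used as a tie-break when several salt-component
# subsets explain the same parent mass.
.heavy_atom_count <- function(f) {
    if (is.character(f))
        f <- parseFormula(f)
    sum(as.numeric(f[names(f) != "H"]))
}

# Render a count vector back to a Hill-order formula string (C, H, then
# alphabetical). Used for report detail strings.
.formula_string <- function(f) {
    syms <- names(f)
    ord <- c(intersect(c("C", "H"), syms), sort(setdiff(syms, c("C", "H"))))
    paste0(vapply(ord, function(s)
        paste0(s, if (f[[s]] > 1L) f[[s]] else ""), character(1)),
        collapse = "")
}
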