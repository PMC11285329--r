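# Adduct grammar and precursor <-> parent mass algebra.
#
# An adduct [xM+A-B]z+/- defines the arithmetic between the neutral
# (monoisotopic) parent mass M and the precursor m/z of the measured ion:
#
#     precursor_mz = (x * M + delta) / |z|
#
# where delta is the summed mass of gained minus lost species, corrected for
# the electrons implied by the charge z.

# Neutral-species aliases tolerated inside adduct tokens.
.adduct_species_aliases <- c(
    FA = "CH2O2", HCOOH = "CH2O2", Hac = "C2H4O2", HAc = "C2H4O2",
    AcOH = "C2H4O2", ACN = "C2H3N", MeOH = "CH4O", CH3OH = "CH4O",
    DMSO = "C2H6OS", TFA = "C2HF3O2", IsoProp = "C3H8O", H2O = "H2O"
)

# Implied charge per unit of a gained species, used when the surface form
# carries no explicit charge suffix ("M+H", "M+Na", "M-H").
.adduct_species_charge <- c(
    H = 1L, Na = 1L, K = 1L, Li = 1L, NH4 = 1L,
    Cl = -1L, Br = -1L, I = -1L, F = -1L
)

.normalize_adduct_text <- function(text) {
    text <- gsub("[−–—]", "-", text)  # unicode minus/dashes
    gsub("[[:space:]]", "", text)
}

# Parse one gain/loss token like "+2H" or "-H2O" into count, formula, charge
# contribution and a canonical token string.
.parse_adduct_token <- function(sign_chr, body) {
    sign <- if (sign_chr == "+") 1L else -1L
    count <- 1L
    m <- regexpr("^[0-9]+", body)
    if (m > 0) {
        count <- as.integer(regmatches(body, m))
        body <- sub("^[0-9]+", "", body)
    }
    species <- if (body %in% names(.adduct_species_aliases))
        .adduct_species_aliases[[body]] else body
    f <- tryCatch(parseFormula(species), error = function(e) NULL)
    if (is.null(f) || count < 1L)
        stop("cannot parse adduct component '", sign_chr, body, "'")
    implied <- if (body %in% names(.adduct_species_charge))
        .adduct_species_charge[[body]] else 0L
    list(sign = sign, count = count, body = body, formula = f,
         mass = monoisotopicMass(f),
         implied_charge = sign * count * implied,
         canonical = paste0(sign_chr, if (count > 1L) count else "", body))
}

#' Parse an adduct string
#'
#' Accepts the common surface forms of adduct notation ("\[M+H\]+", "M+H",
#' "\[M+H\]1+", "\[2M+Na\]+", "M-H2O+H", unicode minus signs, stray
#' whitespace) and returns a fully resolved [AdductSpec-class]. Adducts in
#' the built-in common-adduct table are canonicalized to the table spelling;
#' other grammatical adducts get their mass shift computed from the parsed
#' gain/loss formulas with proton/electron accounting.
#'
#' @param text Adduct string.
#' @return An [AdductSpec-class] object.
#' @examples
#' parseAdduct("M+H")
#' parseAdduct("[2M+Na]+")
#' @export
parseAdduct <- function(text) {
    if (!is.character(text) || length(text) != 1L || is.na(text))
        stop("adduct must be a single string")
    raw <- text
    text <- .normalize_adduct_text(text)
    pat <- "^\\[?([0-9]*)M((?:[+-][A-Za-z0-9]+)*)\\]?([0-9]*)([+-]?)$"
    m <- regexec(pat, text)[[1]]
    if (m[1] == -1)
        stop("unparseable adduct: '", raw, "'")
    g <- regmatches(text, list(m))[[1]]
    mult <- if (nzchar(g[2])) as.integer(g[2]) else 1L
    token_str <- g[3]
    zmag <- if (nzchar(g[4])) as.integer(g[4]) else NA_integer_
    zsign_chr <- g[5]

    tokens <- list()
    if (nzchar(token_str)) {
        tm <- gregexpr("[+-][A-Za-z0-9]+", token_str)[[1]]
        parts <- regmatches(token_str, list(tm))[[1]]
        tokens <- lapply(parts, function(p)
            .parse_adduct_token(substr(p, 1, 1), substring(p, 2)))
    }

    implied <- sum(vapply(tokens, `[[`, integer(1), "implied_charge"), 0L)
    if (nzchar(zsign_chr)) {
        zs <- if (zsign_chr == "+") 1L else -1L
        z <- zs * (if (is.na(zmag)) 1L else zmag)
    } else {
        if (implied == 0L)
            stop("unparseable adduct: '", raw,
                 "' (no charge given and none implied)")
        z <- implied
    }
    if (z == 0L)
        stop("unparseable adduct: '", raw, "' (zero charge)")
    if (mult < 1L)
        stop("unparseable adduct: '", raw, "' (bad multiplier)")

    shift <- sum(vapply(tokens, function(t) t$sign * t$count * t$mass,
                        numeric(1)), 0) - z * .ELECTRON_MASS
    canon <- paste0(
        "[", if (mult > 1L) mult else "", "M",
        paste0(vapply(tokens, `[[`, character(1), "canonical"),
               collapse = ""),
        "]", if (abs(z) > 1L) abs(z) else "", if (z > 0) "+" else "-")

    known <- canon %in% .common_adduct_names()
    new("AdductSpec", name = canon,
        ionmode = if (z > 0) "positive" else "negative",
        charge = z, multiplier = mult, massShift = shift, known = known)
}

# The built-in common-adduct table: the set a practitioner would call the
# usual suspects, used by the adduct-repair scan and canonicalization.
# [M+H]+/[M-H]- come first: they get priority on ties.
.common_adduct_defs <- c(
    "[M+H]+", "[M+Na]+", "[M+K]+", "[M+NH4]+", "[M+H-H2O]+",
    "[2M+H]+", "[M+2H]2+",
    "[M-H]-", "[M+Cl]-", "[M+FA-H]-", "[2M-H]-", "[M-2H]2-"
)

.common_adduct_names <- function() .common_adduct_defs

.common_adduct_cache <- new.env(parent = emptyenv())

#' Built-in common adducts
#'
#' The packaged table of common adducts used by adduct repair and
#' canonicalization, as a list of [AdductSpec-class] objects in priority
#' order (protonated/deprotonated species first).
#'
#' @param ionmode Optional `"positive"` or `"negative"` to restrict the list.
#' @return List of [AdductSpec-class].
#' @examples
#' names(commonAdducts())
#' @export
commonAdducts <- function(ionmode = NULL) {
    if (is.null(.common_adduct_cache$list)) {
        lst <- lapply(.common_adduct_defs, parseAdduct)
        names(lst) <- .common_adduct_defs
        .common_adduct_cache$list <- lst
    }
    lst <- .common_adduct_cache$list
    if (!is.null(ionmode))
        lst <- lst[vapply(lst, adductIonmode, character(1)) == ionmode]
    lst
}

#' Precursor m/z and parent mass algebra
#'
#' `parentMassFromPrecursor()` inverts the adduct relation to recover the
#' neutral monoisotopic mass M from a measured precursor m/z;
#' `precursorFromParent()` is the forward direction
#' `(x * M + delta) / |z|`.
#'
#' @param precursor_mz Precursor m/z in Da (> 0).
#' @param M Neutral monoisotopic mass in Da (> 0).
#' @param adduct An [AdductSpec-class] or an adduct string.
#' @return Mass (or m/z) in Da.
#' @examples
#' parentMassFromPrecursor(181.070664, "[M+H]+")  # glucose
#' @export
parentMassFromPrecursor <- function(precursor_mz, adduct) {
    if (is.character(adduct)) adduct <- parseAdduct(adduct)
    stopifnot(is(adduct, "AdductSpec"))
    if (!is.numeric(precursor_mz) || precursor_mz <= 0)
        stop("precursor_mz must be > 0")
    M <- (precursor_mz * abs(adduct@charge) - adduct@massShift) /
        adduct@multiplier
    if (M <= 0)
        stop("adduct ", adduct@name, " gives non-positive parent mass for ",
             "precursor m/z ", precursor_mz)
    M
}

#' @rdname parentMassFromPrecursor
#' @export
precursorFromParent <- function(M, adduct) {
    if (is.character(adduct)) adduct <- parseAdduct(adduct)
    stopifnot(is(adduct, "AdductSpec"))
    if (!is.numeric(M) || M <= 0)
        stop("parent mass must be > 0")
    (adduct@multiplier * M + adduct@massShift) / abs(adduct@charge)
}

# Non-throwing parse used by filters on messy metadata.
.parse_adduct_or_null <- function(text) {
    if (is.null(text) || is.na(text) || !is.character(text) || !nzchar(text))
        return(NULL)
    tryCatch(parseAdduct(text), error = function(e) NULL)
}
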