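# Atomic mass reference data used by all mass arithmetic.
#
# Monoisotopic masses are the masses of the most abundant natural isotope;
# average masses are IUPAC standard atomic weights (conventional values for
# interval elements). Units: Da.

#' Element mass table
#'
#' Returns the packaged table of per-element monoisotopic masses (mass of the
#' most abundant natural isotope) and standard average atomic masses, in Da.
#'
#' @return A `data.frame` with columns `element`, `monoisotopic`, `average`.
#' @examples
#' elementMasses()[elementMasses()$element == "C", ]
#' @export
elementMasses <- function() {
    .element_masses
}

.element_masses <- data.frame(
    element = c("H", "C", "N", "O", "P", "S", "F", "Cl", "Br", "I",
                "Na", "K", "Ca", "Mg", "Fe", "Zn", "Si", "Se", "B",
                "Li", "Al", "Cu"),
    monoisotopic = c(
        1.0078250319,   # 1H
        12.0,           # 12C, exact by definition
        14.0030740052,  # 14N
        15.9949146221,  # 16O
        30.97376151,    # 31P
        31.97207069,    # 32S
        18.99840320,    # 19F
        34.96885271,    # 35Cl
        78.9183376,     # 79Br
        126.904468,     # 127I
        22.98976928,    # 23Na
        38.9637069,     # 39K
        39.9625912,     # 40Ca
        23.9850419,     # 24Mg
        55.9349421,     # 56Fe
        63.9291466,     # 64Zn
        27.9769265,     # 28Si
        79.9165218,     # 80Se
        11.0093055,     # 11B
        7.0160040,      # 7Li
        26.9815386,     # 27Al
        62.9296011      # 63Cu
    ),
    average = c(
        1.008, 12.011, 14.007, 15.999, 30.973762, 32.06, 18.998403,
        35.45, 79.904, 126.90447, 22.98977, 39.0983, 40.078, 24.305,
        55.845, 65.38, 28.085, 78.971, 10.81, 6.94, 26.9815385, 63.546
    ),
    stringsAsFactors = FALSE
)

# Charge-carrier masses (Da). Adduct mass shifts account for electrons so that
# precursor m/z algebra is exact at the sub-mDa level.
.PROTON_MASS <- 1.00727646
.ELECTRON_MASS <- 0.00054858

#' @rdname elementMasses
#' @export
protonMass <- function() .PROTON_MASS

#' @rdname elementMasses
#' @export
electronMass <- function() .ELECTRON_MASS
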