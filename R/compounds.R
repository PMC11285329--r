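# Packaged reference compounds: the offline stand-in for a compound-name ->
# structure resolution service, and the chemistry truth source for the
# table structure backend and the synthetic library generator.

# Common salt counterions / small components, with the formula (including
# implicit hydrogens) each SMILES component expands to.
.counterion_table <- data.frame(
    smiles = c("Cl", "Br", "I", "O", "[Na+]", "[K+]", "[Li+]",
               "[Cl-]", "[Br-]", "[NH4+]"),
    formula = c("ClH", "BrH", "IH", "H2O", "Na", "K", "Li",
                "Cl", "Br", "NH4"),
    stringsAsFactors = FALSE)

#' Packaged compound table
#'
#' A curated table of reference compounds (135-828 Da) with mutually
#' consistent name, molecular formula, monoisotopic and average mass, SMILES,
#' InChI and InChIKey, plus the corresponding hydrochloride-salt forms. It
#' backs the offline name resolver, the deterministic table structure
#' backend and the synthetic dirty-library generator.
#'
#' @return A `data.frame`, one row per compound.
#' @examples
#' head(compoundTable()[, c("name", "formula", "monoisotopic_mass")])
#' @export
compoundTable <- function() {
    if (is.null(.pkg_cache$compounds)) {
        path <- system.file("extdata", "compounds.tsv",
                            package = "speclean", mustWork = TRUE)
        .pkg_cache$compounds <- utils::read.delim(
            path, stringsAsFactors = FALSE, colClasses = "character")
        num <- c("monoisotopic_mass", "average_mass", "salt_monoisotopic_mass")
        for (cn in num)
            .pkg_cache$compounds[[cn]] <- as.numeric(.pkg_cache$compounds[[cn]])
    }
    .pkg_cache$compounds
}
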