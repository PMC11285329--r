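# Synthetic dirty-library generator: emits spectral libraries carrying the
# error classes the repair and require filters target, together with a
# ground-truth ledger of the injected error and the expected pipeline fate
# of every spectrum. Peak lists are random within the precursor range -
# realistic fragmentation is deliberately not simulated, because only peak
# counts and relative intensities matter to the filters under test.

.ERROR_CLASSES <- c("none", "wrong_default_adduct", "molar_parent_mass",
                    "salt_counterion", "name_only_annotation",
                    "inconsistent_inchi", "too_few_peaks",
                    "ionmode_adduct_conflict", "unrepairable_garbage")

.EXPECTED_FATE <- c(
    none = "kept_unchanged",
    wrong_default_adduct = "repaired_then_kept",
    molar_parent_mass = "repaired_then_kept",
    salt_counterion = "repaired_then_kept",
    name_only_annotation = "repaired_then_kept",
    inconsistent_inchi = "repaired_then_kept",
    too_few_peaks = "removed",
    ionmode_adduct_conflict = "removed",
    unrepairable_garbage = "removed")

# Adducts the generator draws from; single-M species so that every injected
# error stays within reach of the repair filters' common-adduct scan.
.GEN_ADDUCTS <- list(positive = c("[M+H]+", "[M+Na]+", "[M+K]+", "[M+NH4]+"),
                     negative = c("[M-H]-", "[M+Cl]-"))

#' Default error-class mix of the synthetic generator
#'
#' Class probabilities of the `"mixed"` profile. Real-world class
#' frequencies in public libraries are unknown; this mix is an arbitrary
#' but fixed blend that exercises every repair and every removal path.
#'
#' @return Named numeric vector summing to 1.
#' @export
mixedErrorProfile <- function() {
    c(none = 0.40, wrong_default_adduct = 0.10, molar_parent_mass = 0.08,
      salt_counterion = 0.08, name_only_annotation = 0.10,
      inconsistent_inchi = 0.08, too_few_peaks = 0.06,
      ionmode_adduct_conflict = 0.05, unrepairable_garbage = 0.05)
}

.with_seed <- function(seed, code) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (had) get(".Random.seed", envir = globalenv())
    on.exit({
        if (had) assign(".Random.seed", old, envir = globalenv())
        else if (exists(".Random.seed", envir = globalenv(),
                        inherits = FALSE))
            rm(".Random.seed", envir = globalenv())
    })
    set.seed(seed)
    force(code)
}

.gen_peaks <- function(n_peaks, precursor) {
    mz <- sort(stats::runif(n_peaks, 50, max(60, precursor)))
    intensity <- stats::runif(n_peaks, 0.05, 1)
    list(mz = mz, intensity = intensity)
}

#' Generate a synthetic dirty spectral library
#'
#' Draws `n` spectra from the packaged compound table. Clean spectra are
#' fully self-consistent: adduct drawn from a common-adduct pool, precursor
#' m/z computed by exact adduct algebra from the monoisotopic mass, 5-40
#' fragments whose intensities all clear the high-peak requirement. Each
#' error class perturbs exactly the fields its repair (or removal) filter
#' targets:
#'
#' * `wrong_default_adduct`: the stored adduct stays at the submitter
#'   default \[M+H\]+ while precursor m/z and parent mass follow the true
#'   adduct.
#' * `molar_parent_mass`: the parent mass is the average (molar) mass
#'   instead of the monoisotopic mass.
#' * `salt_counterion`: SMILES/InChI/InChIKey describe the hydrochloride
#'   salt while the measured parent mass is the free compound.
#' * `name_only_annotation`: all structure fields missing; only the
#'   compound name (resolvable offline) is present.
#' * `inconsistent_inchi`: InChI and InChIKey belong to a different
#'   compound than the SMILES; only the SMILES matches the parent mass.
#' * `too_few_peaks`: only 3 fragments.
#' * `ionmode_adduct_conflict`: positive adduct but ion mode "negative".
#' * `unrepairable_garbage`: unresolvable compound name, no structure
#'   fields.
#'
#' @param n Number of spectra.
#' @param class_probabilities Named probabilities over the error classes
#'   (must sum to 1); default [mixedErrorProfile()].
#' @param seed Integer seed; the same seed reproduces the identical library
#'   and ledger.
#' @param compounds Compound table, see [compoundTable()].
#' @return List with `spectra` (list of [Spectrum-class]) and `ledger`
#'   (`data.frame` with columns `index`, `compound`, `error_class`,
#'   `expected_fate`).
#' @examples
#' lib <- generateLibrary(5, c(none = 1), seed = 1)
#' lib$ledger
#' @export
generateLibrary <- function(n, class_probabilities = mixedErrorProfile(),
                            seed, compounds = compoundTable()) {
    probs <- class_probabilities
    if (is.null(names(probs)) || !all(names(probs) %in% .ERROR_CLASSES))
        stop("class probabilities must be named with known error classes")
    if (any(probs < 0) || abs(sum(probs) - 1) > 1e-8)
        stop("class probabilities must be >= 0 and sum to 1")
    if (nrow(compounds) < 20L)
        stop("compound table must have at least 20 entries")

    # compounds whose molar-monoisotopic gap is resolvable at the default
    # 0.1 Da tolerance; the molar-mass error class only makes sense there
    molar_ok <- which(abs(compounds$average_mass -
                          compounds$monoisotopic_mass) > 0.12)

    .with_seed(seed, {
        classes <- sample(names(probs), n, replace = TRUE, prob = probs)
        spectra <- vector("list", n)
        rows <- vector("list", n)
        for (i in seq_len(n)) {
            cls <- classes[i]
            ci <- if (cls == "molar_parent_mass") sample(molar_ok, 1)
                  else sample(nrow(compounds), 1)
            cmp <- compounds[ci, ]
            mode <- if (cls == "ionmode_adduct_conflict") "positive"
                    else sample(c("positive", "negative"), 1)
            true_adduct <- if (cls == "wrong_default_adduct")
                sample(setdiff(.GEN_ADDUCTS$positive, "[M+H]+"), 1)
            else sample(.GEN_ADDUCTS[[mode]], 1)
            if (cls == "wrong_default_adduct") mode <- "positive"
            adduct <- parseAdduct(true_adduct)
            mono <- cmp$monoisotopic_mass
            precursor <- precursorFromParent(mono, adduct)
            n_peaks <- if (cls == "too_few_peaks") 3L else sample(5:40, 1)
            peaks <- .gen_peaks(n_peaks, precursor)

            md <- list(
                spectrum_id = sprintf("SYN%06d", i),
                compound_name = cmp$name,
                precursor_mz = precursor,
                parent_mass = mono,
                adduct = adduct@name,
                ionmode = mode,
                charge = adduct@charge,
                smiles = cmp$smiles,
                inchi = cmp$inchi,
                inchikey = cmp$inchikey)

            if (cls == "wrong_default_adduct") {
                md$adduct <- "[M+H]+"
                # submitters who never update the default adduct typically
                # also store the parent mass it implies
                md$parent_mass <- parentMassFromPrecursor(
                    precursor, parseAdduct("[M+H]+"))
                md$charge <- 1
            } else if (cls == "molar_parent_mass") {
                md$parent_mass <- cmp$average_mass
            } else if (cls == "salt_counterion") {
                md$smiles <- cmp$salt_smiles
                md$inchi <- cmp$salt_inchi
                md$inchikey <- cmp$salt_inchikey
            } else if (cls == "name_only_annotation") {
                md$smiles <- NULL; md$inchi <- NULL; md$inchikey <- NULL
            } else if (cls == "inconsistent_inchi") {
                # pick a donor compound at least 1 Da away in mass
                donors <- which(abs(compounds$monoisotopic_mass - mono) > 1)
                di <- donors[sample(length(donors), 1)]
                md$inchi <- compounds$inchi[di]
                md$inchikey <- compounds$inchikey[di]
            } else if (cls == "ionmode_adduct_conflict") {
                md$ionmode <- "negative"
            } else if (cls == "unrepairable_garbage") {
                md$smiles <- NULL; md$inchi <- NULL; md$inchikey <- NULL
                md$compound_name <- sprintf("unknown compound %d", i)
            }

            spectra[[i]] <- makeSpectrum(md, peaks$mz, peaks$intensity)
            rows[[i]] <- data.frame(
                index = i, compound = cmp$name, error_class = cls,
                expected_fate = unname(.EXPECTED_FATE[cls]),
                stringsAsFactors = FALSE)
        }
        list(spectra = spectra, ledger = do.call(rbind, rows))
    })
}

#' Observed per-spectrum fates of a pipeline run
#'
#' Derives, for each input spectrum of a [runPipeline()] result, the fate
#' in the ledger vocabulary: `"removed"`, `"repaired_then_kept"` (kept and
#' changed by at least one repair filter) or `"kept_unchanged"`.
#'
#' @param result A [runPipeline()] result.
#' @param n Number of input spectra.
#' @return Character vector of length `n`.
#' @export
observedFates <- function(result, n) {
    fates <- rep("kept_unchanged", n)
    fates[setdiff(seq_len(n), result$kept_indices)] <- "removed"
    repair_events <- result$changes[
        result$changes$filter %in% .repair_filter_ids() &
        result$changes$event == "metadata_changed", , drop = FALSE]
    repaired <- intersect(unique(repair_events$index), result$kept_indices)
    fates[repaired] <- "repaired_then_kept"
    fates
}

#' Score a cleaning run against the ground-truth ledger
#'
#' Compares the observed fate of every spectrum with the ledger's expected
#' fate and summarizes repair and removal performance: per-class repair
#' recall, the false-repair rate on clean spectra, and overall fractions.
#'
#' @param ledger Ledger `data.frame` from [generateLibrary()].
#' @param result Matching [runPipeline()] result.
#' @return Named list of metrics; `per_class` is a `data.frame` with one
#'   row per error class present.
#' @export
scoreCleaning <- function(ledger, result) {
    n <- nrow(ledger)
    if (result$report@spectraIn != n)
        stop("ledger (", n, " spectra) does not match the run (",
             result$report@spectraIn, ")")
    fates <- observedFates(result, n)
    clean <- ledger$error_class == "none"
    per_class <- do.call(rbind, lapply(split(seq_len(n), ledger$error_class),
        function(idx) {
            expect <- ledger$expected_fate[idx[1]]
            data.frame(error_class = ledger$error_class[idx[1]],
                       n = length(idx),
                       fate_match = mean(fates[idx] == expect),
                       repaired = mean(fates[idx] == "repaired_then_kept"),
                       removed = mean(fates[idx] == "removed"),
                       stringsAsFactors = FALSE)
        }))
    rownames(per_class) <- NULL
    list(
        n = n,
        fates = fates,
        fate_accuracy = mean(fates == ledger$expected_fate),
        false_repair_rate = if (any(clean))
            mean(fates[clean] == "repaired_then_kept") else NA_real_,
        fraction_repaired = mean(fates == "repaired_then_kept"),
        fraction_removed = mean(fates == "removed"),
        per_class = per_class)
}

#' Write / read a ground-truth ledger as TSV
#'
#' @param ledger Ledger `data.frame`.
#' @param path File path.
#' @return `readLedger()` returns the ledger `data.frame`.
#' @export
writeLedger <- function(ledger, path) {
    utils::write.table(ledger, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' @rdname writeLedger
#' @export
readLedger <- function(path) {
    utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Replicate the annotation-derivation audit on a library
#'
#' The error-estimation protocol for name-based annotation: take spectra
#' that already carry a valid annotation and a compound name, strip the
#' structure fields, re-derive them from the compound name alone, and
#' compare the re-derived 2D structure (InChIKey first block) with the
#' original. Returns the fraction of spectra whose annotation could be
#' re-derived and, among those, the fraction annotated with a different 2D
#' structure.
#'
#' @param spectra List of annotated [Spectrum-class] (with `smiles` and
#'   `compound_name` present).
#' @param resolver Name resolver, see [tableNameResolver()].
#' @param mass_tolerance Mass-match tolerance in Da.
#' @param backend Structure backend.
#' @return List with `n`, `derived_fraction`, `mismatch_fraction`.
#' @export
auditNameDerivation <- function(spectra, resolver = defaultNameResolver(),
                                mass_tolerance = 0.1,
                                backend = defaultStructureBackend()) {
    eligible <- 0L; derived <- 0L; mismatched <- 0L
    for (s in spectra) {
        orig <- .md_chr(s, "smiles")
        if (is.null(orig) || is.null(.md_chr(s, "compound_name"))) next
        orig_block <- .first_block(orig, "smiles", backend)
        if (is.na(orig_block)) next
        eligible <- eligible + 1L
        stripped <- .md_drop(s, c("smiles", "inchi", "inchikey"))
        rederived <- deriveAnnotationFromCompoundName(stripped, resolver,
                                                      mass_tolerance)
        new_smiles <- .md_chr(rederived, "smiles")
        if (is.null(new_smiles)) next
        derived <- derived + 1L
        new_block <- .first_block(new_smiles, "smiles", backend)
        if (is.na(new_block) || new_block != orig_block)
            mismatched <- mismatched + 1L
    }
    list(n = eligible,
         derived_fraction = if (eligible) derived / eligible else NA_real_,
         mismatch_fraction = if (derived) mismatched / derived else NA_real_)
}
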