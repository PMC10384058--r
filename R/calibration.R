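#' Calibrate similarity cutoffs from reference species
#'
#' Computes all pairwise identities among region-trimmed reference species
#' (via [pairwiseIdentity()]) and averages them within three strata: pairs
#' sharing a genus (species cutoff), pairs sharing a family but not a genus
#' (genus cutoff), and pairs in different families (family cutoff). Means are
#' unweighted over species pairs and rounded to two decimals. A stratum with
#' no pairs is an error: at least two genera in at least two families are
#' needed for all three averages to exist. If the stratum means violate the
#' ordering species >= genus >= family the calibration fails loudly rather
#' than clamping.
#'
#' @param refs An ungapped [AmpliconSet-class] of reference species: names are
#'   binomials, lineages annotated through genus (family and genus nonempty).
#' @param digits Rounding applied to the stratum means (default 2, matching
#'   the conventional percentage cutoffs).
#' @return A [CutoffSet-class] carrying the pair counts used.
#' @seealso [pairwiseIdentity()], [hierarchicalTIC()]
#' @export
calibrateCutoffs <- function(refs, digits = 2) {
    stopifnot(methods::is(refs, "AmpliconSet"))
    n <- length(refs)
    if (n < 2L) stop("calibration needs at least two reference species")
    lin <- lapply(refs@lineage, parseLineage)
    fam <- vapply(lin, `[[`, "", "family")
    gen <- vapply(lin, `[[`, "", "genus")
    if (any(fam == "") || any(gen == ""))
        stop("reference lineages must be annotated through family and genus")
    seqs <- as.character(refs@seqs)
    sums <- c(species = 0, genus = 0, family = 0)
    cnts <- c(species = 0L, genus = 0L, family = 0L)
    for (i in seq_len(n - 1L)) {
        idsI <- identityToMany(seqs[i], seqs[(i + 1L):n])
        for (k in seq_along(idsI)) {
            j <- i + k
            stratum <- if (gen[i] == gen[j]) "species"
                else if (fam[i] == fam[j]) "genus" else "family"
            sums[stratum] <- sums[stratum] + idsI[k]
            cnts[stratum] <- cnts[stratum] + 1L
        }
    }
    empty <- names(cnts)[cnts == 0L]
    if (length(empty))
        stop("no reference pairs in stratum: ", paste(empty, collapse = ", "))
    mns <- round(sums / cnts, digits)
    if (!(mns["family"] <= mns["genus"] && mns["genus"] <= mns["species"]))
        stop(sprintf(
            "calibrated means are not ordered (species %.3f, genus %.3f, family %.3f)",
            mns["species"], mns["genus"], mns["family"]))
    cutoffSet(unname(mns["species"]), unname(mns["genus"]),
              unname(mns["family"]), pairCounts = cnts)
}

# "domain;phylum;class;order;family;genus" -> named list, missing ranks ""
parseLineage <- function(x) {
    parts <- strsplit(x, ";", fixed = TRUE)[[1]]
    parts <- trimws(parts)
    length(parts) <- length(RANKS)
    parts[is.na(parts)] <- ""
    stats::setNames(as.list(parts), RANKS)
}

unparseLineage <- function(parts) paste(unlist(parts), collapse = ";")
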