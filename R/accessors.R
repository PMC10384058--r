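#' Construct an AmpliconSet
#'
#' @param seqs A \code{\link[Biostrings]{DNAStringSet}} (or character vector)
#'   named by record id.
#' @param lineage Ranked taxonomy strings (\code{domain;...;genus}); recycled
#'   empty when missing.
#' @param sampleId Source-sample id per record; \code{NA} when unknown.
#' @param multiplicity Integer multiplicities (default 1).
#' @param gapped Whether the records are rows of one alignment.
#' @return An [AmpliconSet-class].
#' @examples
#' ampliconSet(c(r1 = "AC-G", r2 = "ACCG"), gapped = TRUE)
#' @export
ampliconSet <- function(seqs, lineage = NULL, sampleId = NULL,
                        multiplicity = NULL, gapped = FALSE) {
    if (!methods::is(seqs, "DNAStringSet"))
        seqs <- Biostrings::DNAStringSet(seqs)
    n <- length(seqs)
    if (is.null(lineage)) lineage <- rep("", n)
    if (is.null(sampleId)) sampleId <- rep(NA_character_, n)
    if (is.null(multiplicity)) multiplicity <- rep(1L, n)
    methods::new("AmpliconSet", seqs = seqs, lineage = as.character(lineage),
        sampleId = as.character(sampleId),
        multiplicity = as.integer(multiplicity), gapped = isTRUE(gapped))
}

#' @describeIn ampliconSet Number of records.
#' @param x,object An \code{AmpliconSet}.
#' @export
setMethod("length", "AmpliconSet", function(x) length(x@seqs))

#' @describeIn ampliconSet Record ids.
#' @export
setMethod("names", "AmpliconSet", function(x) names(x@seqs))

#' @describeIn ampliconSet Subset records (by index, id or logical mask).
#' @param i Index vector.
#' @param j,drop,... Ignored (matrix-style subsetting is not supported).
#' @export
setMethod("[", "AmpliconSet", function(x, i, j, ..., drop = TRUE) {
    idx <- if (is.character(i)) match(i, names(x@seqs)) else i
    methods::initialize(x, seqs = x@seqs[idx], lineage = x@lineage[idx],
        sampleId = x@sampleId[idx], multiplicity = x@multiplicity[idx])
})

#' @export
setMethod("show", "AmpliconSet", function(object) {
    cat(sprintf("AmpliconSet of %d %s record(s)", length(object),
        if (object@gapped) "gapped" else "ungapped"))
    if (length(object) > 0 && object@gapped)
        cat(sprintf(", alignment width %d", Biostrings::width(object@seqs)[1]))
    cat("\n")
    if (length(object) > 0) {
        k <- min(3L, length(object))
        for (i in seq_len(k))
            cat(sprintf("  %s [%s] x%d\n", names(object)[i],
                substr(as.character(object@seqs[[i]]), 1, 40),
                object@multiplicity[i]))
        if (length(object) > k) cat(sprintf("  ... and %d more\n",
                                            length(object) - k))
    }
})

#' Sequences, lineages, sample ids and multiplicities of an AmpliconSet
#'
#' @param x An [AmpliconSet-class].
#' @return \code{ampliconSeqs}: the \code{DNAStringSet}; the others: character
#'   or integer vectors parallel to the records.
#' @export
ampliconSeqs <- function(x) x@seqs

#' @rdname ampliconSeqs
#' @export
lineages <- function(x) stats::setNames(x@lineage, names(x@seqs))

#' @rdname ampliconSeqs
#' @export
sampleIds <- function(x) stats::setNames(x@sampleId, names(x@seqs))

#' @rdname ampliconSeqs
#' @export
multiplicities <- function(x) stats::setNames(x@multiplicity, names(x@seqs))

#' Construct a RegionWindow
#'
#' @param start,end 0-based half-open column bounds.
#' @param expectedBases Ungapped bases of the designated reference inside the
#'   window (see [expectedBasesInWindow()]); \code{NA} when unknown.
#' @param minFraction Fraction of \code{expectedBases} that must be exceeded
#'   (default 0.8).
#' @param minBases Optional absolute base-count override.
#' @return A [RegionWindow-class].
#' @examples
#' regionWindow(10, 250, expectedBases = 282L)
#' @export
regionWindow <- function(start, end, expectedBases = NA_integer_,
                         minFraction = 0.8, minBases = NA_integer_) {
    methods::new("RegionWindow", start = as.integer(start),
        end = as.integer(end), expectedBases = as.integer(expectedBases),
        minFraction = as.numeric(minFraction), minBases = as.integer(minBases))
}

#' @export
setMethod("show", "RegionWindow", function(object) {
    cat(sprintf("RegionWindow [%d, %d) (%d columns)\n", object@start,
        object@end, object@end - object@start))
    cat(sprintf("  expected bases: %s; keep if bases %s\n",
        ifelse(is.na(object@expectedBases), "unset", object@expectedBases),
        if (!is.na(object@minBases)) sprintf(">= %d (override)", object@minBases)
        else sprintf("> %.0f%% of expectation", 100 * object@minFraction)))
})

#' Construct a CutoffSet
#'
#' @param species,genus,family Similarity cutoffs in (0, 1], ordered
#'   \code{family <= genus <= species}.
#' @param pairCounts Named integer vector of calibration pair counts.
#' @return A [CutoffSet-class].
#' @examples
#' cutoffSet(0.96, 0.92, 0.90)
#' @export
cutoffSet <- function(species, genus, family,
                      pairCounts = c(species = 0L, genus = 0L, family = 0L)) {
    methods::new("CutoffSet", species = species, genus = genus,
        family = family, pairCounts = as.integer(pairCounts))
}

#' @rdname cutoffSet
#' @param x A \code{CutoffSet}.
#' @return \code{cutoffs()}: named numeric vector
#'   \code{c(species=, genus=, family=)}.
#' @export
cutoffs <- function(x) c(species = x@species, genus = x@genus,
                         family = x@family)

#' @export
setMethod("show", "CutoffSet", function(object) {
    cat(sprintf("CutoffSet: species %.3f / genus %.3f / family %.3f\n",
        object@species, object@genus, object@family))
    if (sum(object@pairCounts) > 0)
        cat(sprintf("  calibrated from %s reference pairs\n",
            paste(object@pairCounts, collapse = "/")))
})

#' Assignment table, representatives and label taxonomy
#'
#' @param x An [OTUAssignment-class].
#' @return \code{otuTable}: the per-record label \code{data.frame};
#'   \code{representatives}: named character vector label -> founder id;
#'   \code{otuTaxonomy}: label/rank/taxon \code{data.frame}.
#' @export
otuTable <- function(x) x@table

#' @rdname otuTable
#' @export
representatives <- function(x) x@representatives

#' @rdname otuTable
#' @export
otuTaxonomy <- function(x) x@taxonomy

#' @export
setMethod("show", "OTUAssignment", function(object) {
    tb <- object@table
    cat(sprintf(
        "OTUAssignment: %d records -> %d fOTUs / %d gOTUs / %d sOTUs\n",
        nrow(tb), length(unique(tb$fOTU)), length(unique(tb$gOTU)),
        length(unique(tb$sOTU))))
    cat(sprintf("  cutoffs %.3f/%.3f/%.3f (species/genus/family)\n",
        object@cutoffs@species, object@cutoffs@genus, object@cutoffs@family))
})

#' @export
setMethod("show", "SimulationConfig", function(object) {
    cat(sprintf(
        "SimulationConfig: %d families x %d genera x %d species, seed %d\n",
        object@nFamilies, object@generaPerFamily, object@speciesPerGenus,
        object@seed))
    cat(sprintf("  identity ladder %.3f/%.3f/%.3f/%.3f over %d bases\n",
        object@withinSpeciesIdentity, object@withinGenusIdentity,
        object@withinFamilyIdentity, object@acrossFamilyIdentity,
        object@regionLength))
    cat(sprintf("  %d fragment window(s), %d fragments/species, %d samples\n",
        length(object@fragmentWindows), object@fragmentsPerSpecies,
        object@nSamples))
})

#' @export
setMethod("show", "SyntheticCommunity", function(object) {
    cat(sprintf(
        "SyntheticCommunity: %d fragments, %d planted species, %d samples\n",
        length(object@records), length(object@references), nrow(object@samples)))
    cat(sprintf("  planted analysis region [%d, %d) (ungapped coordinates)\n",
        object@plantedRegion[1], object@plantedRegion[2]))
})
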