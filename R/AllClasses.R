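#' @import methods
#' @importFrom Rcpp sourceCpp
#' @useDynLib ampliTIC, .registration = TRUE
NULL

RANKS <- c("domain", "phylum", "class", "order", "family", "genus")

#' Collection of (optionally gapped) amplicon records
#'
#' An \code{AmpliconSet} holds a set of 16S rRNA gene records together with
#' their ranked taxonomy annotation and source-sample identifier. Records may
#' be gapped rows of a common multiple sequence alignment (all widths equal)
#' or ungapped, region-trimmed sequences.
#'
#' @slot seqs A \code{\link[Biostrings]{DNAStringSet}} over \code{{A,C,G,T,N,-}},
#'   named by record id (ids unique).
#' @slot lineage Character vector of semicolon-separated ranked taxonomy
#'   strings (domain;phylum;class;order;family;genus; ranks may be empty),
#'   parallel to \code{seqs}.
#' @slot sampleId Character vector of source-sample identifiers, parallel to
#'   \code{seqs}.
#' @slot multiplicity Integer vector of record multiplicities (from
#'   dereplication; 1 for raw records), parallel to \code{seqs}.
#' @slot gapped Logical scalar; \code{TRUE} when records are alignment rows.
#'
#' @seealso [ampliconSet()], [dereplicate()], [trimAndFilter()]
#' @export
setClass("AmpliconSet",
    representation(
        seqs = "ANY",
        lineage = "character",
        sampleId = "character",
        multiplicity = "integer",
        gapped = "logical"
    )
)

setValidity("AmpliconSet", function(object) {
    msg <- character()
    n <- length(object@seqs)
    if (!methods::is(object@seqs, "DNAStringSet"))
        msg <- c(msg, "'seqs' must be a DNAStringSet")
    if (length(object@lineage) != n || length(object@sampleId) != n ||
        length(object@multiplicity) != n)
        msg <- c(msg, "lineage, sampleId and multiplicity must match length(seqs)")
    ids <- names(object@seqs)
    if (n > 0 && (is.null(ids) || anyNA(ids) || any(ids == "")))
        msg <- c(msg, "all records must be named by a non-empty id")
    if (n > 0 && anyDuplicated(ids))
        msg <- c(msg, "record ids must be unique within a collection")
    if (isTRUE(object@gapped) && n > 0 &&
        length(unique(Biostrings::width(object@seqs))) != 1L)
        msg <- c(msg, "gapped records must share one alignment width")
    if (length(msg)) msg else TRUE
})

#' Half-open column window of the master alignment
#'
#' A \code{RegionWindow} is a 0-based, half-open interval \code{[start, end)}
#' of alignment columns plus the length-filter expectation derived from a
#' designated reference record: a trimmed record is kept when its base count
#' reaches the threshold (see [trimAndFilter()]).
#'
#' @slot start,end Integer column bounds, 0-based, half-open,
#'   \code{0 <= start < end}.
#' @slot expectedBases Integer; ungapped bases the designated reference record
#'   carries inside the window (\code{NA} when no reference was supplied).
#' @slot minFraction Fraction of \code{expectedBases} a record must exceed
#'   (default 0.8, i.e. "more than 80 percent").
#' @slot minBases Optional absolute base-count override of the fraction rule
#'   (\code{NA} when unset).
#'
#' @seealso [regionWindow()], [selectRepresentedRegion()]
#' @export
setClass("RegionWindow",
    representation(
        start = "integer", end = "integer",
        expectedBases = "integer", minFraction = "numeric",
        minBases = "integer"
    )
)

setValidity("RegionWindow", function(object) {
    msg <- character()
    if (length(object@start) != 1L || length(object@end) != 1L ||
        is.na(object@start) || is.na(object@end))
        msg <- c(msg, "start and end must be scalar integers")
    else if (object@start < 0L || object@start >= object@end)
        msg <- c(msg, "need 0 <= start < end")
    if (!is.na(object@expectedBases) && object@expectedBases < 1L)
        msg <- c(msg, "expectedBases must be >= 1 when supplied")
    if (object@minFraction <= 0 || object@minFraction > 1)
        msg <- c(msg, "minFraction must be in (0, 1]")
    if (length(msg)) msg else TRUE
})

#' Similarity cutoffs for the selected region
#'
#' The three clustering cutoffs derived from reference species over the
#' selected region: mean identity among species of the same genus (species
#' cutoff), among species across genera of one family (genus cutoff), and
#' among species of different families (family cutoff).
#'
#' @slot species,genus,family Fractions in (0, 1] with
#'   \code{family <= genus <= species}.
#' @slot pairCounts Named integer vector: number of reference pairs behind
#'   each stratum mean (zero when the cutoffs were supplied, not calibrated).
#'
#' @seealso [cutoffSet()], [calibrateCutoffs()]
#' @export
setClass("CutoffSet",
    representation(
        species = "numeric", genus = "numeric", family = "numeric",
        pairCounts = "integer"
    )
)

setValidity("CutoffSet", function(object) {
    msg <- character()
    v <- c(object@family, object@genus, object@species)
    if (any(is.na(v)) || any(v <= 0) || any(v > 1))
        msg <- c(msg, "cutoffs must be fractions in (0, 1]")
    else if (!(object@family <= object@genus && object@genus <= object@species))
        msg <- c(msg, "need family <= genus <= species cutoff")
    if (length(msg)) msg else TRUE
})

#' Nested molecular-taxon assignment
#'
#' Per-record fOTU/gOTU/sOTU labels produced by taxonomy-informed hierarchical
#' incremental clustering, with founder representatives and the annotated
#' taxonomy each label inherited from its bin.
#'
#' @slot table \code{data.frame} with columns \code{id}, \code{bin},
#'   \code{fOTU}, \code{gOTU}, \code{sOTU}.
#' @slot representatives Named character vector mapping every OTU label to the
#'   id of its founding record.
#' @slot taxonomy \code{data.frame} with columns \code{label}, \code{rank},
#'   \code{taxon}: the annotated taxon an OTU carries at its bounding rank
#'   (novel OTUs carry \code{NA}).
#' @slot cutoffs The [CutoffSet-class] the assignment was clustered at.
#'
#' @seealso [hierarchicalTIC()], [validateAssignment()]
#' @export
setClass("OTUAssignment",
    representation(
        table = "data.frame",
        representatives = "character",
        taxonomy = "data.frame",
        cutoffs = "CutoffSet"
    )
)

setValidity("OTUAssignment", function(object) {
    msg <- character()
    need <- c("id", "bin", "fOTU", "gOTU", "sOTU")
    if (!all(need %in% names(object@table)))
        msg <- c(msg, "table must have columns id, bin, fOTU, gOTU, sOTU")
    else {
        tb <- object@table
        if (anyDuplicated(tb$id)) msg <- c(msg, "record ids must be unique")
        # nesting: an sOTU lives inside exactly one gOTU, a gOTU inside one fOTU
        if (nrow(tb) > 0) {
            if (any(tapply(tb$gOTU, tb$sOTU, function(x) length(unique(x))) != 1L))
                msg <- c(msg, "records sharing an sOTU must share a gOTU")
            if (any(tapply(tb$fOTU, tb$gOTU, function(x) length(unique(x))) != 1L))
                msg <- c(msg, "records sharing a gOTU must share an fOTU")
        }
        labs <- unique(c(tb$fOTU, tb$gOTU, tb$sOTU))
        if (!all(labs %in% names(object@representatives)))
            msg <- c(msg, "every OTU label needs a representative")
    }
    if (length(msg)) msg else TRUE
})

#' Synthetic community simulation settings
#'
#' All knobs of the synthetic amplicon community generator: the planted
#' family > genus > species hierarchy, the pairwise-identity ladder over the
#' analysis region, the fragment windows, and the sample/abundance model.
#' See [simulationConfig()] for defaults and units.
#'
#' @seealso [simulationConfig()], [simulateCommunity()]
#' @export
setClass("SimulationConfig",
    representation(
        seed = "integer",
        nFamilies = "integer", generaPerFamily = "integer",
        speciesPerGenus = "integer",
        regionLength = "integer",
        withinSpeciesIdentity = "numeric", withinGenusIdentity = "numeric",
        withinFamilyIdentity = "numeric", acrossFamilyIdentity = "numeric",
        nSamples = "integer", environments = "character",
        fragmentWindows = "list", windowWeights = "numeric",
        fragmentsPerSpecies = "integer", shortFragmentRate = "numeric",
        abundanceAlpha = "numeric"
    )
)

setValidity("SimulationConfig", function(object) {
    msg <- character()
    cnt <- c(object@nFamilies, object@generaPerFamily, object@speciesPerGenus,
             object@regionLength, object@nSamples, object@fragmentsPerSpecies)
    if (any(is.na(cnt)) || any(cnt < 1L))
        msg <- c(msg, "all counts must be >= 1")
    idn <- c(object@withinSpeciesIdentity, object@withinGenusIdentity,
             object@withinFamilyIdentity, object@acrossFamilyIdentity)
    if (any(is.na(idn)) || any(idn <= 0) || any(idn > 1))
        msg <- c(msg, "identity targets must be fractions in (0, 1]")
    else if (!all(diff(idn) < 0))
        msg <- c(msg, paste("identity ladder must be strictly ordered:",
                            "species > genus > family > across-family"))
    if (object@shortFragmentRate < 0 || object@shortFragmentRate > 1)
        msg <- c(msg, "shortFragmentRate must be in [0, 1]")
    if (object@abundanceAlpha <= 0)
        msg <- c(msg, "abundanceAlpha must be positive")
    if (length(object@environments) < 1L)
        msg <- c(msg, "at least one environment label is required")
    if (length(object@fragmentWindows) < 1L)
        msg <- c(msg, "at least one fragment window is required")
    if (length(object@windowWeights) != length(object@fragmentWindows) ||
        any(object@windowWeights <= 0))
        msg <- c(msg, "windowWeights must be positive, one per fragment window")
    for (w in object@fragmentWindows)
        if (length(w) != 2L || w[1] < 0 || w[2] <= w[1] ||
            w[2] > object@regionLength)
            msg <- c(msg, "fragment windows must be [start,end) within the region")
    if (length(msg)) msg else TRUE
})

#' Synthetic community with planted ground truth
#'
#' Output of [simulateCommunity()]: gapped fragment records, the planted
#' (family, genus, species) truth label per record, one full-length reference
#' per planted species, the sample table and the relative-abundance matrix.
#'
#' @slot records Gapped [AmpliconSet-class] of amplicon fragments.
#' @slot truth \code{data.frame}: \code{id}, \code{family}, \code{genus},
#'   \code{species} per record.
#' @slot references Gapped [AmpliconSet-class]: one full-length row per planted
#'   species, named by binomial, annotated to genus.
#' @slot samples \code{data.frame}: \code{sample_id}, \code{raw_label}.
#' @slot abundance Numeric matrix, samples x species, relative fractions with
#'   row sums <= 1.
#' @slot config The [SimulationConfig-class] used.
#' @slot plantedRegion Integer 2-vector: the ungapped [start,end) interval the
#'   identity ladder was planted on (the region selection should recover it).
#'
#' @export
setClass("SyntheticCommunity",
    representation(
        records = "AmpliconSet",
        truth = "data.frame",
        references = "AmpliconSet",
        samples = "data.frame",
        abundance = "matrix",
        config = "SimulationConfig",
        plantedRegion = "integer"
    )
)

setValidity("SyntheticCommunity", function(object) {
    msg <- character()
    if (!identical(sort(object@truth$id), sort(names(object@records@seqs))))
        msg <- c(msg, "truth labels must cover exactly the record ids")
    if (!all(names(object@references@seqs) %in% object@truth$species))
        msg <- c(msg, "every planted species needs at least one record")
    if (nrow(object@abundance) != nrow(object@samples))
        msg <- c(msg, "abundance rows must match the sample table")
    if (any(rowSums(object@abundance) > 1 + 1e-9))
        msg <- c(msg, "per-sample relative abundances must sum to <= 1")
    if (length(msg)) msg else TRUE
})
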