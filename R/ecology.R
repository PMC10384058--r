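#' Environment categories
#'
#' The fixed category vocabulary used throughout the ecological analysis.
#' \code{"excluded"} marks manually assembled systems (removed from every
#' summary); \code{"other"} collects labels no rule matches.
#'
#' @return Character vector of category names in the fixed tie-break order.
#' @export
environmentCategories <- function() {
    c("saline water", "freshwater", "soil", "air", "plant", "host",
      "plant saline water", "host saline water", "bioreactor", "other",
      "excluded")
}

# ordered keyword rules; first match wins (checked top to bottom)
.ENV_RULES <- list(
    excluded = c("laboratory", "lab-assembled", "lab-cultivated",
                 "manually assembled", "synthetic community",
                 "polymer material"),
    bioreactor = c("sludge", "wastewater", "bioreactor", "digester",
                   "fermentation", "anammox", "treatment plant"),
    `host saline water` = c("sponge", "coral", "fish", "marine invertebrate",
                            "sea cucumber", "oyster", "marine host"),
    `plant saline water` = c("alga", "seagrass", "kelp", "seaweed",
                             "marine plant"),
    `saline water` = c("marine", "sea", "ocean", "saline", "beach sand",
                       "estuar", "brine", "salt"),
    freshwater = c("freshwater", "lake", "river", "pond", "stream",
                   "groundwater"),
    soil = c("soil", "rhizosphere", "permafrost", "compost"),
    air = c("air", "aerosol", "dust"),
    plant = c("plant", "leaf", "root", "phyllosphere", "flower"),
    host = c("gut", "host", "faec", "fecal", "skin", "human", "mouse",
             "animal", "insect", "rumen")
)

#' Categorize a raw environment label
#'
#' Deterministic keyword mapping of free-text sample origin labels onto the
#' fixed category vocabulary. Manually assembled systems (laboratory mats,
#' biofilms on polymer surfaces, ...) map to \code{"excluded"}; labels no
#' rule matches map to \code{"other"} with a warning. Rules are checked in a
#' fixed order (exclusions first, bioreactor-related terms before water
#' terms, saline before fresh), and the shipped table can be extended.
#'
#' @param rawLabel Character vector of free-text labels.
#' @param extraRules Optional named list (category -> keyword vector)
#'   consulted before the shipped rules.
#' @param quiet Suppress the unmatched-label warning.
#' @return Character vector of categories (see [environmentCategories()]).
#' @examples
#' categorizeEnvironment(c("marine sediment", "activated sludge"))
#' @export
categorizeEnvironment <- function(rawLabel, extraRules = NULL, quiet = FALSE) {
    rules <- c(extraRules, .ENV_RULES)
    out <- vapply(tolower(as.character(rawLabel)), function(lab) {
        for (cat in names(rules))
            for (kw in rules[[cat]])
                if (grepl(kw, lab, fixed = TRUE)) return(cat)
        NA_character_
    }, "", USE.NAMES = FALSE)
    if (anyNA(out)) {
        if (!quiet)
            warning("unmatched environment label(s): ",
                    paste(unique(rawLabel[is.na(out)]), collapse = ", "),
                    " -> 'other'")
        out[is.na(out)] <- "other"
    }
    out
}

#' Build the sample table with categories
#'
#' @param samples \code{data.frame} with \code{sample_id} and
#'   \code{raw_label}.
#' @param ... Passed to [categorizeEnvironment()].
#' @return The table with an added \code{category} column.
#' @export
categorizeSamples <- function(samples, ...) {
    stopifnot(all(c("sample_id", "raw_label") %in% names(samples)))
    samples$category <- categorizeEnvironment(samples$raw_label, ...)
    samples
}

# drop excluded samples and align matrix rows with the sample table
.activeSamples <- function(abundance, samples) {
    if (!"category" %in% names(samples)) samples <- categorizeSamples(samples)
    stopifnot(!is.null(rownames(abundance)),
              all(rownames(abundance) %in% samples$sample_id))
    samples <- samples[match(rownames(abundance), samples$sample_id), ]
    keep <- samples$category != "excluded"
    list(abundance = abundance[keep, , drop = FALSE],
         samples = samples[keep, , drop = FALSE])
}

#' Positivity of the target order per environment category
#'
#' A sample is positive when any target sOTU has abundance > 0 in it.
#' Positivity per category is positives over totals among non-excluded
#' samples of the category; categories without samples are omitted. The
#' overall positivity is returned under \code{"overall"}.
#'
#' @param abundance Numeric matrix, samples x sOTUs (relative fractions),
#'   rownames = sample ids.
#' @param samples Sample table (\code{sample_id}, \code{raw_label}, optional
#'   precomputed \code{category}).
#' @param sotus Optional character vector restricting the target sOTU set
#'   (default: all columns).
#' @return Named numeric vector of positivity fractions (categories present,
#'   plus \code{"overall"}).
#' @export
computePositivity <- function(abundance, samples, sotus = NULL) {
    act <- .activeSamples(abundance, samples)
    ab <- act$abundance
    if (!is.null(sotus)) ab <- ab[, intersect(colnames(ab), sotus),
                                  drop = FALSE]
    pos <- rowSums(ab > 0) > 0
    cat <- act$samples$category
    res <- vapply(split(pos, cat), mean, numeric(1))
    c(res, overall = mean(pos))
}

#' Per-sOTU ecological summary
#'
#' For every sOTU: the number of positive samples (abundance > 0), the number
#' at or above the abundance threshold (default 0.1 percent, boundary
#' inclusive), the dominant environment (most frequent category among
#' positive samples; ties broken by the larger summed abundance, then the
#' fixed category order), the maximum abundance and its sample's category,
#' and the cosmopolitan flag (positive in at least \code{cosmopolitanMin}
#' samples, default 50). Excluded samples influence nothing; sOTUs absent
#' from the matrix get a zero-filled row.
#'
#' @inheritParams computePositivity
#' @param threshold Abundance gate (fraction; default 0.001 = 0.1 percent).
#' @param cosmopolitanMin Minimum positive samples for the cosmopolitan flag.
#' @param dominantFrom Compute the dominant environment over \code{"positive"}
#'   samples (default) or only \code{"threshold"} samples.
#' @return \code{data.frame}: \code{sOTU}, \code{nPositive},
#'   \code{nPositiveGeThreshold}, \code{dominantEnvironment},
#'   \code{maxAbundance}, \code{maxAbundanceEnvironment},
#'   \code{cosmopolitan}.
#' @export
summarizeSotuEcology <- function(abundance, samples, sotus = NULL,
                                 threshold = 0.001, cosmopolitanMin = 50L,
                                 dominantFrom = c("positive", "threshold")) {
    stopifnot(threshold > 0, cosmopolitanMin > 0)
    dominantFrom <- match.arg(dominantFrom)
    act <- .activeSamples(abundance, samples)
    ab <- act$abundance
    cat <- act$samples$category
    if (is.null(sotus)) sotus <- colnames(ab)
    catOrder <- environmentCategories()
    out <- lapply(sotus, function(s) {
        v <- if (s %in% colnames(ab)) ab[, s] else rep(0, nrow(ab))
        pos <- v > 0
        ge <- v >= threshold
        domPos <- if (dominantFrom == "positive") pos else ge
        dom <- NA_character_
        if (any(domPos)) {
            counts <- table(cat[domPos])
            best <- names(counts)[counts == max(counts)]
            if (length(best) > 1L) {
                sums <- vapply(best, function(b)
                    sum(v[domPos & cat == b]), numeric(1))
                best <- best[sums == max(sums)]
                if (length(best) > 1L)
                    best <- best[order(match(best, catOrder))]
            }
            dom <- best[1L]
        }
        mx <- if (any(pos)) max(v) else 0
        mxEnv <- if (any(pos)) cat[which.max(v)] else NA_character_
        data.frame(sOTU = s, nPositive = sum(pos),
            nPositiveGeThreshold = sum(ge), dominantEnvironment = dom,
            maxAbundance = mx, maxAbundanceEnvironment = mxEnv,
            cosmopolitan = sum(pos) >= cosmopolitanMin,
            stringsAsFactors = FALSE)
    })
    do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' sOTUs reaching the abundance gate
#'
#' Keeps the sOTUs whose summary shows at least one sample at or above the
#' threshold the summaries were computed with (the ">= 0.1 percent in at
#' least one sample" rule).
#'
#' @param summaries Output of [summarizeSotuEcology()].
#' @return Character vector of retained sOTU labels.
#' @export
filterByAbundance <- function(summaries) {
    summaries$sOTU[summaries$nPositiveGeThreshold >= 1L]
}
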