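#' Collapse identical aligned records
#'
#' Exact dereplication: two records merge iff their gapped column strings are
#' byte-identical. The retained record keeps the lexicographically smallest
#' member id; its multiplicity is the sum over members (taking prior
#' multiplicities into account). A multiplicity map preserves every original
#' id.
#'
#' @param records A gapped [AmpliconSet-class].
#' @return A list with \code{unique} (dereplicated \code{AmpliconSet}) and
#'   \code{map} (named character vector: original id -> retained id).
#' @examples
#' x <- ampliconSet(c(s1 = "AC-G", s2 = "AC-G", s3 = "ACCG"), gapped = TRUE)
#' dereplicate(x)$unique
#' @export
dereplicate <- function(records) {
    stopifnot(methods::is(records, "AmpliconSet"))
    if (length(records) == 0L)
        return(list(unique = records, map = stats::setNames(character(0),
                                                            character(0))))
    if (records@gapped &&
        length(unique(Biostrings::width(records@seqs))) != 1L)
        stop("aligned records must share one width")
    key <- as.character(records@seqs)
    ids <- names(records)
    grp <- split(seq_along(ids), key)
    keep <- vapply(grp, function(ix)
        ix[order(ids[ix], method = "radix")[1L]], integer(1))
    mult <- vapply(grp, function(ix) sum(records@multiplicity[ix]), integer(1))
    ord <- order(match(keep, seq_along(ids))) # preserve input order
    keep <- keep[ord]; mult <- mult[ord]; grp <- grp[ord]
    uniq <- records[keep]
    uniq@multiplicity <- as.integer(mult)
    map <- stats::setNames(rep(ids[keep], lengths(grp)),
                           ids[unlist(grp, use.names = FALSE)])
    list(unique = uniq, map = map[ids])
}

#' Per-column base coverage of an alignment
#'
#' Counts, for every alignment column, the records carrying a sequenced base
#' there. \code{N} counts as a base (a sequenced position); gaps (\code{-})
#' and leading/trailing padding do not.
#'
#' @param records Non-empty gapped [AmpliconSet-class].
#' @return Integer vector of per-column counts.
#' @examples
#' positionCoverage(ampliconSet(c(a = "AC-", b = "A-C", c = "ACC"),
#'                              gapped = TRUE)) # 3 2 2
#' @export
positionCoverage <- function(records) {
    stopifnot(methods::is(records, "AmpliconSet"))
    if (length(records) == 0L) stop("coverage of an empty collection")
    if (length(unique(Biostrings::width(records@seqs))) != 1L)
        stop("aligned records must share one width")
    cm <- Biostrings::consensusMatrix(records@seqs)
    gaps <- if ("-" %in% rownames(cm)) cm["-", ] else 0L
    as.integer(length(records) - gaps)
}

#' Locate the most-represented alignment region
#'
#' Finds the longest contiguous run of columns whose coverage reaches
#' \code{plateauFraction} of the maximum column coverage; ties on length go to
#' the leftmost run. A manual override window may be supplied instead.
#'
#' @param coverage Integer vector from [positionCoverage()].
#' @param plateauFraction Fraction of the coverage maximum a column must reach
#'   to belong to the plateau (default 0.8).
#' @param override Optional integer 2-vector \code{c(start, end)} (0-based,
#'   half-open) forcing the window.
#' @return A [RegionWindow-class] (without a base-count expectation yet).
#' @examples
#' selectRepresentedRegion(c(1, 5, 5, 5, 1)) # [1, 4)
#' @export
selectRepresentedRegion <- function(coverage, plateauFraction = 0.8,
                                    override = NULL) {
    if (length(coverage) == 0L) stop("empty coverage vector")
    if (plateauFraction <= 0 || plateauFraction > 1)
        stop("plateauFraction must be in (0, 1]")
    if (!is.null(override))
        return(regionWindow(override[1], override[2]))
    mx <- max(coverage)
    if (mx == 0L) stop("all-zero coverage: no sequenced bases in the alignment")
    ok <- coverage >= plateauFraction * mx
    r <- rle(ok)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    cand <- which(r$values)
    best <- cand[which.max(r$lengths[cand])] # which.max is leftmost on ties
    regionWindow(starts[best] - 1L, ends[best])
}

#' Ungapped bases of a reference inside a window
#'
#' The basis of the length filter: how many sequenced bases the designated
#' reference record (E. coli in the original workflow) contributes inside the
#' selected window.
#'
#' @param reference A single gapped record ([AmpliconSet-class] of length 1,
#'   or a gapped character scalar).
#' @param window A [RegionWindow-class].
#' @return Integer base count.
#' @examples
#' expectedBasesInWindow("A-CG-T", regionWindow(0, 6)) # 4
#' @export
expectedBasesInWindow <- function(reference, window) {
    s <- if (methods::is(reference, "AmpliconSet")) {
        stopifnot(length(reference) == 1L)
        as.character(reference@seqs[[1]])
    } else as.character(reference)
    if (nchar(s) < window@end) stop("window extends past the reference record")
    piece <- substr(s, window@start + 1L, window@end)
    sum(strsplit(piece, "")[[1]] != "-")
}

#' Trim records to a window and filter by base count
#'
#' Slices every record to the window columns, removes gaps, and keeps records
#' whose base count reaches the threshold: \code{minBases} when set, otherwise
#' the smallest integer strictly greater than
#' \code{minFraction * expectedBases} ("more than 80 percent of the reference
#' expectation"). Discarded records are logged with their base counts. Output
#' order follows input order; an empty keep-set is legal.
#'
#' @param records Gapped [AmpliconSet-class] matching the window's alignment.
#' @param window A [RegionWindow-class] carrying \code{expectedBases} (or a
#'   \code{minBases} override).
#' @return List with \code{kept} (ungapped \code{AmpliconSet}) and
#'   \code{discarded} (\code{data.frame}: id, bases, reason).
#' @export
trimAndFilter <- function(records, window) {
    stopifnot(methods::is(records, "AmpliconSet"),
              methods::is(window, "RegionWindow"))
    if (length(records) > 0 &&
        any(Biostrings::width(records@seqs) < window@end))
        stop("records are narrower than the window")
    thr <- filterThreshold(window)
    sl <- Biostrings::subseq(records@seqs, start = window@start + 1L,
                             end = window@end)
    ungapped <- Biostrings::DNAStringSet(gsub("-", "", as.character(sl)))
    names(ungapped) <- names(records)
    nb <- Biostrings::width(ungapped)
    keep <- nb >= thr
    kept <- methods::initialize(records, seqs = ungapped[keep],
        lineage = records@lineage[keep], sampleId = records@sampleId[keep],
        multiplicity = records@multiplicity[keep], gapped = FALSE)
    discarded <- data.frame(id = names(records)[!keep], bases = nb[!keep],
        reason = rep(sprintf("bases < %d", thr), sum(!keep)),
        stringsAsFactors = FALSE)
    list(kept = kept, discarded = discarded)
}

#' @rdname trimAndFilter
#' @param window A [RegionWindow-class].
#' @return \code{filterThreshold}: the minimal base count a kept record needs.
#' @export
filterThreshold <- function(window) {
    if (!is.na(window@minBases)) return(window@minBases)
    if (is.na(window@expectedBases))
        stop("window carries neither an expectation nor a minBases override")
    # smallest integer strictly greater than fraction * expectation
    as.integer(floor(window@minFraction * window@expectedBases + 1e-9)) + 1L
}
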