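#' Bin sequences by annotated taxonomy
#'
#' First stage of taxonomy-informed clustering: entries are grouped by their
#' deepest non-empty annotated rank path (at most genus). Entries unannotated
#' below some rank fall into an \code{"<prefix>/unclassified"} child bin under
#' their deepest annotated ancestor, so novel diversity is clustered inside
#' the taxon it was annotated to and never merged across annotated lineages.
#'
#' @param entries An ungapped [AmpliconSet-class].
#' @return Named list: \code{bins} (bin key -> character vector of record
#'   ids, a partition of the input) and \code{info} (\code{data.frame} with
#'   columns \code{bin}, \code{family}, \code{genus}; \code{NA} where the bin
#'   is not annotated at that rank).
#' @export
binByTaxonomy <- function(entries) {
    stopifnot(methods::is(entries, "AmpliconSet"))
    ids <- names(entries)
    keys <- character(length(ids))
    fams <- gens <- character(length(ids))
    for (i in seq_along(ids)) {
        lin <- parseLineage(entries@lineage[i])
        ranks <- unlist(lin)[seq_len(match("genus", RANKS))]
        nonempty <- which(ranks != "")
        depth <- if (length(nonempty)) max(nonempty) else 0L
        prefix <- if (depth > 0L) paste(ranks[seq_len(depth)], collapse = ";")
                  else "Root"
        keys[i] <- if (depth < match("genus", RANKS))
            paste0(prefix, "/unclassified") else prefix
        fams[i] <- if (depth >= match("family", RANKS)) ranks["family"]
                   else NA_character_
        gens[i] <- if (depth >= match("genus", RANKS)) ranks["genus"]
                   else NA_character_
    }
    bins <- split(ids, keys)
    first <- vapply(split(seq_along(ids), keys), `[[`, integer(1), 1L)
    info <- data.frame(bin = names(bins), family = fams[first],
                       genus = gens[first], stringsAsFactors = FALSE)
    list(bins = bins, info = info)
}

# canonical processing order: multiplicity desc, length desc, id asc
canonicalOrder <- function(entries) {
    order(-entries@multiplicity, -Biostrings::width(entries@seqs),
          names(entries), method = "radix")
}

#' Greedy incremental clustering within one taxonomy bin
#'
#' Entries are processed in canonical order (multiplicity descending, then
#' length descending, then id ascending). Each entry joins the first existing
#' cluster whose founding representative it matches at
#' \code{pairwiseIdentity >= cutoff}; otherwise it founds a new cluster with
#' itself as representative. Representatives are founders and are never
#' updated, so the procedure is deterministic and order-independent with
#' respect to the input permutation.
#'
#' @param entries Ungapped [AmpliconSet-class] (one taxonomy bin).
#' @param cutoff Identity cutoff in (0, 1].
#' @param bestHit Join the highest-identity representative above the cutoff
#'   instead of the first one (default \code{FALSE}: classic incremental
#'   semantics).
#' @return List with \code{clusters} (list of member-id vectors, founding
#'   order) and \code{representatives} (character vector of founder ids,
#'   parallel to \code{clusters}).
#' @export
incrementalCluster <- function(entries, cutoff, bestHit = FALSE) {
    stopifnot(methods::is(entries, "AmpliconSet"))
    if (cutoff <= 0 || cutoff > 1) stop("cutoff must be in (0, 1]")
    n <- length(entries)
    if (n == 0L) return(list(clusters = list(), representatives = character(0)))
    ord <- canonicalOrder(entries)
    seqs <- as.character(entries@seqs)
    ids <- names(entries)
    repSeq <- character(0)
    repId <- character(0)
    members <- list()
    for (i in ord) {
        hit <- 0L
        if (length(repSeq)) {
            idn <- identityToMany(seqs[i], repSeq)
            ok <- which(idn >= cutoff)
            if (length(ok))
                hit <- if (bestHit) ok[which.max(idn[ok])] else ok[1L]
        }
        if (hit > 0L) {
            members[[hit]] <- c(members[[hit]], ids[i])
        } else {
            repSeq <- c(repSeq, seqs[i])
            repId <- c(repId, ids[i])
            members[[length(repSeq)]] <- ids[i]
        }
    }
    list(clusters = members, representatives = repId)
}

#' Reference implementation of the greedy clustering (small bins)
#'
#' Exhaustively simulates the incremental process from the canonical order
#' using a precomputed all-pairs identity matrix. Intended as an independent
#' check of [incrementalCluster()]; refuses bins larger than 40 entries.
#'
#' @inheritParams incrementalCluster
#' @return Same structure as [incrementalCluster()].
#' @export
oracleCluster <- function(entries, cutoff, bestHit = FALSE) {
    stopifnot(methods::is(entries, "AmpliconSet"))
    n <- length(entries)
    if (n > 40L) stop("oracleCluster is limited to bins of at most 40 entries")
    if (n == 0L) return(list(clusters = list(), representatives = character(0)))
    seqs <- as.character(entries@seqs)
    ids <- names(entries)
    idm <- matrix(1, n, n)
    for (i in seq_len(n)) for (j in seq_len(n)) if (i != j)
        idm[i, j] <- pairwiseIdentity(seqs[i], seqs[j])
    ord <- canonicalOrder(entries)
    reps <- integer(0)
    members <- list()
    for (i in ord) {
        ok <- which(idm[i, reps] >= cutoff)
        if (length(ok)) {
            hit <- if (bestHit) ok[which.max(idm[i, reps[ok]])] else ok[1L]
            members[[hit]] <- c(members[[hit]], ids[i])
        } else {
            reps <- c(reps, i)
            members[[length(reps)]] <- ids[i]
        }
    }
    list(clusters = members, representatives = ids[reps])
}

#' Taxonomy-informed hierarchical incremental clustering
#'
#' Clusters trimmed sequences into nested molecular families, genera and
#' species. Within every taxonomy bin (see [binByTaxonomy()]) the entries are
#' clustered incrementally at the family cutoff into fOTUs; within each fOTU
#' at the genus cutoff into gOTUs; within each gOTU at the species cutoff
#' into sOTUs. Labels are stable zero-padded ordinals (\code{FOTU01},
#' \code{GOTU01}, \code{SOTU001}, ...) issued in canonical processing order
#' (bins sorted by key, clusters in founding order), so permuting the input
#' records leaves the assignment unchanged. Bins annotated at family or genus
#' rank pass that named taxon on to their OTUs.
#'
#' @param entries Ungapped [AmpliconSet-class] of filtered, trimmed sequences
#'   with multiplicities from dereplication.
#' @param cutoffs A [CutoffSet-class] (calibrated or supplied).
#' @param bestHit See [incrementalCluster()].
#' @return An [OTUAssignment-class].
#' @examples
#' x <- ampliconSet(c(a = "ACGTACGTAC", b = "ACGTACGTAC", c = "TTGTACCTAC"))
#' hierarchicalTIC(x, cutoffSet(0.97, 0.95, 0.90))
#' @export
hierarchicalTIC <- function(entries, cutoffs, bestHit = FALSE) {
    stopifnot(methods::is(entries, "AmpliconSet"),
              methods::is(cutoffs, "CutoffSet"))
    methods::validObject(cutoffs)
    if (length(entries) == 0L)
        return(methods::new("OTUAssignment",
            table = data.frame(id = character(0), bin = character(0),
                fOTU = character(0), gOTU = character(0), sOTU = character(0),
                stringsAsFactors = FALSE),
            representatives = character(0),
            taxonomy = data.frame(label = character(0), rank = character(0),
                taxon = character(0), stringsAsFactors = FALSE),
            cutoffs = cutoffs))
    bt <- binByTaxonomy(entries)
    keys <- sort(names(bt$bins), method = "radix")
    rows <- list()
    reps <- character(0)
    tax <- list()
    nF <- nG <- nS <- 0L
    for (key in keys) {
        sub <- entries[bt$bins[[key]]]
        info <- bt$info[bt$info$bin == key, ]
        fcl <- incrementalCluster(sub, cutoffs@family, bestHit)
        for (fi in seq_along(fcl$clusters)) {
            nF <- nF + 1L
            fLab <- paste0("F", nF)
            reps[fLab] <- fcl$representatives[fi]
            tax[[fLab]] <- data.frame(label = fLab, rank = "family",
                taxon = info$family, stringsAsFactors = FALSE)
            subF <- sub[fcl$clusters[[fi]]]
            gcl <- incrementalCluster(subF, cutoffs@genus, bestHit)
            for (gi in seq_along(gcl$clusters)) {
                nG <- nG + 1L
                gLab <- paste0("G", nG)
                reps[gLab] <- gcl$representatives[gi]
                tax[[gLab]] <- data.frame(label = gLab, rank = "genus",
                    taxon = info$genus, stringsAsFactors = FALSE)
                subG <- subF[gcl$clusters[[gi]]]
                scl <- incrementalCluster(subG, cutoffs@species, bestHit)
                for (si in seq_along(scl$clusters)) {
                    nS <- nS + 1L
                    sLab <- paste0("S", nS)
                    reps[sLab] <- scl$representatives[si]
                    rows[[sLab]] <- data.frame(id = scl$clusters[[si]],
                        bin = key, fOTU = fLab, gOTU = gLab, sOTU = sLab,
                        stringsAsFactors = FALSE)
                }
            }
        }
    }
    tb <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
    relabel <- function(x, prefix, total) {
        k <- as.integer(sub("^[FGS]", "", x))
        sprintf("%s%0*d", prefix, max(2L, nchar(total)), k)
    }
    old <- names(reps)
    lvl <- substr(old, 1, 1)
    new <- ifelse(lvl == "F", relabel(old, "FOTU", nF),
           ifelse(lvl == "G", relabel(old, "GOTU", nG), relabel(old, "SOTU", nS)))
    names(reps) <- new
    tb$fOTU <- relabel(tb$fOTU, "FOTU", nF)
    tb$gOTU <- relabel(tb$gOTU, "GOTU", nG)
    tb$sOTU <- relabel(tb$sOTU, "SOTU", nS)
    taxdf <- do.call(rbind, c(tax, list(make.row.names = FALSE)))
    taxdf$label <- new[match(taxdf$label, old)]
    # order table by input record order
    tb <- tb[match(names(entries), tb$id), , drop = FALSE]
    rownames(tb) <- NULL
    methods::new("OTUAssignment", table = tb, representatives = reps,
                 taxonomy = taxdf, cutoffs = cutoffs)
}

#' Post-hoc validation of an OTU assignment
#'
#' Asserts, against the entries it was computed from, the three contracts of
#' the clustering: label nesting (sOTU within gOTU within fOTU), the taxonomy
#' bound (no OTU mixes records whose annotated lineages conflict at or above
#' its bounding rank), and the representative bound (every member matches its
#' OTU representative at or above the level cutoff).
#'
#' @param assignment An [OTUAssignment-class].
#' @param entries The ungapped [AmpliconSet-class] that was clustered.
#' @return \code{TRUE} invisibly, or an error describing the violation.
#' @export
validateAssignment <- function(assignment, entries) {
    methods::validObject(assignment)
    tb <- assignment@table
    seqs <- stats::setNames(as.character(entries@seqs), names(entries))
    cs <- c(fOTU = assignment@cutoffs@family, gOTU = assignment@cutoffs@genus,
            sOTU = assignment@cutoffs@species)
    for (level in names(cs)) {
        for (lab in unique(tb[[level]])) {
            mem <- tb$id[tb[[level]] == lab]
            rp <- assignment@representatives[[lab]]
            idn <- identityToMany(seqs[rp], seqs[mem])
            if (any(idn < cs[level] - 1e-12))
                stop(sprintf("%s member below cutoff (%.4f < %.2f) in %s",
                             level, min(idn), cs[level], lab))
        }
    }
    # taxonomy bound: one bin per OTU is sufficient (bins never mix lineages)
    for (level in c("fOTU", "gOTU", "sOTU"))
        if (any(tapply(tb$bin, tb[[level]], function(x)
                length(unique(x))) != 1L))
            stop("an OTU mixes records from different taxonomy bins")
    invisible(TRUE)
}
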