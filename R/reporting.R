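#' Percentage with half-up rounding
#'
#' \code{100 * part / whole}, rounded half-up to two decimals (the convention
#' behind printed table percentages, where e.g. 4483 of 15049 renders as
#' 29.79\%). \code{percentLabel()} renders the value with a trailing percent
#' sign.
#'
#' @param part,whole Non-negative counts, \code{part <= whole},
#'   \code{whole > 0} (vectorised).
#' @param digits Decimals kept (default 2).
#' @return \code{percentage}: numeric value(s); \code{percentLabel}:
#'   character.
#' @examples
#' percentage(4483, 15049) # 29.79
#' percentLabel(1565, 118062) # "1.33%"
#' @export
percentage <- function(part, whole, digits = 2) {
    if (any(whole == 0)) stop("percentage of a zero whole")
    if (any(part < 0) || any(part > whole))
        stop("need 0 <= part <= whole")
    roundHalfUp(100 * part / whole, digits)
}

#' @rdname percentage
#' @export
percentLabel <- function(part, whole, digits = 2) {
    sprintf(paste0("%.", digits, "f%%"), percentage(part, whole, digits))
}

# round half away from zero (base round() is half-even); the epsilon absorbs
# binary representation error of decimal ratios
roundHalfUp <- function(x, digits = 0) {
    p <- 10^digits
    sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

#' Diversity summary tables
#'
#' Counts known vs predicted molecular families, genera and species, overall
#' and restricted to the abundance-retained sOTU set, and breaks genera and
#' species down per known family (with an "Unknown families" row), with
#' percentage columns computed by [percentage()].
#'
#' @param assignment An [OTUAssignment-class].
#' @param retained Character vector of retained sOTU labels (e.g. from
#'   [filterByAbundance()]); \code{NULL} for no abundance restriction.
#' @param knownTaxa \code{data.frame} of described taxa with columns
#'   \code{family}, \code{genus}, \code{species} (one row per described
#'   species). Used for the "known" counts and to recognise known families.
#' @return List of \code{data.frame}s: \code{overall} (rank, known,
#'   predicted, predictedRetained), \code{generaByFamily} and
#'   \code{speciesByFamily} (family, predicted, predictedPct, retained,
#'   retainedPct).
#' @export
diversityTable <- function(assignment, retained = NULL, knownTaxa = NULL) {
    tb <- otuTable(assignment)
    if (is.null(retained)) retained <- unique(tb$sOTU)
    sub <- tb[tb$sOTU %in% retained, , drop = FALSE]
    known <- function(col) if (is.null(knownTaxa)) 0L
        else length(unique(knownTaxa[[col]]))
    overall <- data.frame(
        rank = c("families", "genera", "species"),
        known = c(known("family"), known("genus"), known("species")),
        predicted = c(length(unique(tb$fOTU)), length(unique(tb$gOTU)),
                      length(unique(tb$sOTU))),
        predictedRetained = c(length(unique(sub$fOTU)),
                              length(unique(sub$gOTU)),
                              length(unique(sub$sOTU))),
        stringsAsFactors = FALSE)
    famOf <- .labelTaxon(assignment, "family")
    knownFams <- if (is.null(knownTaxa)) character(0)
                 else unique(knownTaxa$family)
    famName <- function(f) {
        x <- famOf[f]
        ifelse(!is.na(x) & x %in% knownFams, x, "Unknown families")
    }
    breakdown <- function(level) {
        fam <- famName(tb$fOTU[!duplicated(tb[[level]])])
        lab <- tb[[level]][!duplicated(tb[[level]])]
        famR <- famName(sub$fOTU[!duplicated(sub[[level]])])
        rows <- c(knownFams, "Unknown families")
        pred <- vapply(rows, function(f) sum(fam == f), integer(1))
        ret <- vapply(rows, function(f) sum(famR == f), integer(1))
        keep <- pred > 0 | rows %in% knownFams
        data.frame(family = rows[keep], predicted = pred[keep],
            predictedPct = if (sum(pred) > 0)
                percentage(pred[keep], sum(pred)) else 0,
            retained = ret[keep],
            retainedPct = if (sum(ret) > 0)
                percentage(ret[keep], sum(ret)) else 0,
            stringsAsFactors = FALSE)
    }
    list(overall = overall, generaByFamily = breakdown("gOTU"),
         speciesByFamily = breakdown("sOTU"))
}

.labelTaxon <- function(assignment, rank) {
    tx <- otuTaxonomy(assignment)
    tx <- tx[tx$rank == rank, ]
    stats::setNames(tx$taxon, tx$label)
}

#' Species-per-taxon histogram
#'
#' Bins the number of molecular species per molecular genus (or family) into
#' the classes 1, 2-10, 11-50 and >=51 species. Taxa with zero retained
#' species are omitted; a taxon with exactly 51 species falls in the top bin.
#'
#' @inheritParams diversityTable
#' @param level \code{"genus"} (default) or \code{"family"}.
#' @return Named integer vector over the four bins.
#' @export
speciesHistogram <- function(assignment, level = c("genus", "family"),
                             retained = NULL) {
    level <- match.arg(level)
    tb <- otuTable(assignment)
    if (!is.null(retained)) tb <- tb[tb$sOTU %in% retained, , drop = FALSE]
    col <- if (level == "genus") "gOTU" else "fOTU"
    per <- tapply(tb$sOTU, tb[[col]], function(x) length(unique(x)))
    bins <- cut(as.integer(per), breaks = c(0, 1, 10, 50, Inf),
                labels = c("1", "2-10", "11-50", ">=51"))
    stats::setNames(as.integer(table(bins)), levels(bins))
}

#' Top prevalent and top abundant molecular species
#'
#' Ranks ecological summaries into the two headline tables: the \code{n} most
#' prevalent sOTUs (by positive-sample count, descending) and the \code{n}
#' most abundant (by maximum abundance, descending); ties break by sOTU
#' label. Optional species names and label taxonomy decorate the rows.
#'
#' @param summaries Output of [summarizeSotuEcology()].
#' @param n Rows per table (default 20).
#' @param names Optional output of [assignKnownSpecies()] (adds a
#'   \code{name} column).
#' @param assignment Optional [OTUAssignment-class] (adds \code{family} and
#'   \code{genus} label columns).
#' @return List of two \code{data.frame}s, \code{prevalent} and
#'   \code{abundant}.
#' @export
topTables <- function(summaries, n = 20, names = NULL, assignment = NULL) {
    stopifnot(n >= 1)
    dec <- summaries
    if (!is.null(names))
        dec$name <- names$name[match(dec$sOTU, names$sOTU)]
    if (!is.null(assignment)) {
        tb <- otuTable(assignment)
        ix <- match(dec$sOTU, tb$sOTU)
        famOf <- .labelTaxon(assignment, "family")
        genOf <- .labelTaxon(assignment, "genus")
        fam <- famOf[tb$fOTU[ix]]
        gen <- genOf[tb$gOTU[ix]]
        dec$family <- ifelse(is.na(fam), tb$fOTU[ix], fam)
        dec$genus <- ifelse(is.na(gen), tb$gOTU[ix], gen)
    }
    take <- function(key) {
        o <- order(-dec[[key]], dec$sOTU, method = "radix")
        head <- dec[o[seq_len(min(n, nrow(dec)))], , drop = FALSE]
        rownames(head) <- NULL
        head
    }
    list(prevalent = take("nPositive"), abundant = take("maxAbundance"))
}

#' Write a table as TSV and Markdown
#'
#' @param df A \code{data.frame}.
#' @param path Output path without extension; writes \code{<path>.tsv} and
#'   \code{<path>.md}.
#' @return Invisibly, the two paths written.
#' @export
writeReportTable <- function(df, path) {
    tsv <- paste0(path, ".tsv")
    md <- paste0(path, ".md")
    utils::write.table(df, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
    fmt <- vapply(df, function(col)
        if (is.numeric(col)) format(col, trim = TRUE) else as.character(col),
        character(nrow(df)))
    if (nrow(df) == 1L) fmt <- matrix(fmt, nrow = 1)
    lines <- c(paste0("| ", paste(names(df), collapse = " | "), " |"),
               paste0("|", paste(rep("---", ncol(df)), collapse = "|"), "|"),
               apply(fmt, 1, function(r)
                   paste0("| ", paste(r, collapse = " | "), " |")))
    writeLines(lines, md)
    invisible(c(tsv, md))
}
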