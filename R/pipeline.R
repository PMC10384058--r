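#' Run the integrative diversity pipeline on a synthetic community
#'
#' Executes the full workflow on a [SyntheticCommunity-class]: exact
#' dereplication, column-coverage computation, most-represented-region
#' selection, trimming with the reference-based length filter, cutoff
#' calibration from the planted references, taxonomy-informed hierarchical
#' clustering, known-species assignment, and the ecological summaries and
#' report tables. Every stage is deterministic, so a fixed community yields
#' byte-identical outputs.
#'
#' @param community A [SyntheticCommunity-class].
#' @param plateauFraction Coverage fraction defining the plateau (default
#'   0.8).
#' @param minFraction Length-filter fraction (default 0.8, "more than 80
#'   percent").
#' @param minBases Optional absolute base-count override of the filter.
#' @param cutoffs Optional [CutoffSet-class]; when \code{NULL} the cutoffs
#'   are calibrated from the trimmed references.
#' @param referenceId Reference used for the base-count expectation (default:
#'   first planted reference).
#' @param threshold Abundance gate for the ecological analysis (default
#'   0.001).
#' @param cosmopolitanMin Cosmopolitan rule (default 50 positive samples).
#' @param assignmentThreshold Known-species assignment identity (default
#'   0.98).
#' @param topN Rows of the top-prevalence/abundance tables.
#' @return A list with elements \code{window} ([RegionWindow-class]),
#'   \code{derep}, \code{kept}, \code{discarded}, \code{cutoffs},
#'   \code{assignment} ([OTUAssignment-class]), \code{species}
#'   (known-species table), \code{sotuAbundance}, \code{summaries},
#'   \code{retained}, \code{positivity}, \code{diversity}, \code{histogram},
#'   \code{top}, and \code{evaluation} (recovered vs planted counts and
#'   truth-label agreement).
#' @export
runPipeline <- function(community, plateauFraction = 0.8, minFraction = 0.8,
                        minBases = NA_integer_, cutoffs = NULL,
                        referenceId = NULL, threshold = 0.001,
                        cosmopolitanMin = 50L, assignmentThreshold = 0.98,
                        topN = 20L) {
    stopifnot(methods::is(community, "SyntheticCommunity"))
    dr <- dereplicate(community@records)
    cov <- positionCoverage(dr$unique)
    win <- selectRepresentedRegion(cov, plateauFraction)
    ref <- if (is.null(referenceId)) community@references[1]
           else community@references[referenceId]
    win@expectedBases <- as.integer(expectedBasesInWindow(ref, win))
    win@minFraction <- minFraction
    win@minBases <- as.integer(minBases)
    tf <- trimAndFilter(dr$unique, win)
    refTrim <- trimAndFilter(community@references,
                             regionWindow(win@start, win@end, minBases = 1L))
    if (is.null(cutoffs)) cutoffs <- calibrateCutoffs(refTrim$kept)
    assignment <- hierarchicalTIC(tf$kept, cutoffs)
    reps <- representatives(assignment)
    sotuLabs <- sort(unique(otuTable(assignment)$sOTU), method = "radix")
    repSeqs <- stats::setNames(as.character(
        tf$kept@seqs[reps[sotuLabs]]), sotuLabs)
    species <- assignKnownSpecies(repSeqs, refTrim$kept,
                                  threshold = assignmentThreshold)
    sotuAb <- sotuAbundanceMatrix(community, assignment, dr$map)
    summaries <- summarizeSotuEcology(sotuAb, community@samples,
        threshold = threshold, cosmopolitanMin = cosmopolitanMin)
    retained <- filterByAbundance(summaries)
    positivity <- computePositivity(sotuAb, community@samples)
    knownTaxa <- unique(community@truth[c("family", "genus", "species")])
    diversity <- diversityTable(assignment, retained, knownTaxa)
    histogram <- speciesHistogram(assignment, "genus")
    top <- topTables(summaries, topN, names = species,
                     assignment = assignment)
    evaluation <- evaluateAssignment(community, assignment)
    list(window = win, derep = dr, kept = tf$kept, discarded = tf$discarded,
         cutoffs = cutoffs, assignment = assignment, species = species,
         sotuAbundance = sotuAb, summaries = summaries, retained = retained,
         positivity = positivity, diversity = diversity,
         histogram = histogram, top = top, evaluation = evaluation)
}

#' Map the planted abundance matrix onto recovered sOTUs
#'
#' The generator's abundance matrix is keyed by planted species; after
#' clustering, each species' column is attributed to the sOTU holding its
#' surviving records (majority vote over members; species whose records were
#' all filtered out are dropped; species merged into one sOTU are summed).
#'
#' @param community A [SyntheticCommunity-class].
#' @param assignment An [OTUAssignment-class] from the pipeline.
#' @param derepMap Original-id to retained-id map from [dereplicate()]
#'   (identity mapping when omitted).
#' @return Numeric matrix, samples x sOTUs.
#' @export
sotuAbundanceMatrix <- function(community, assignment, derepMap = NULL) {
    tb <- otuTable(assignment)
    truth <- community@truth
    ids <- if (is.null(derepMap)) truth$id else unname(derepMap[truth$id])
    sotu <- tb$sOTU[match(ids, tb$id)]
    ok <- !is.na(sotu)
    if (!any(ok)) stop("no clustered records trace back to planted species")
    vote <- table(truth$species[ok], sotu[ok])
    spToSotu <- colnames(vote)[apply(vote, 1, which.max)]
    names(spToSotu) <- rownames(vote)
    ab <- community@abundance[, names(spToSotu), drop = FALSE]
    out <- vapply(sort(unique(spToSotu), method = "radix"), function(s)
        rowSums(ab[, spToSotu == s, drop = FALSE]),
        numeric(nrow(ab)))
    out
}

#' Compare a clustering against the planted truth
#'
#' Counts recovered fOTUs/gOTUs/sOTUs against the planted family/genus/
#' species counts, and measures truth-label agreement: the fraction of
#' clustered records whose sOTU (gOTU, fOTU) co-members all share the
#' record's planted species (genus, family) and vice versa, i.e. exact
#' partition agreement restricted to surviving records.
#'
#' @inheritParams sotuAbundanceMatrix
#' @return List: \code{planted} and \code{recovered} (named count vectors),
#'   \code{agreement} (named fraction vector per level).
#' @export
evaluateAssignment <- function(community, assignment) {
    tb <- otuTable(assignment)
    truth <- community@truth
    # clustered entries are dereplicated: map every clustered id to truth via
    # its own id (retained ids are original ids by construction)
    ix <- match(tb$id, truth$id)
    stopifnot(!anyNA(ix))
    planted <- c(families = length(unique(truth$family)),
                 genera = length(unique(truth$genus)),
                 species = length(unique(truth$species)))
    recovered <- c(families = length(unique(tb$fOTU)),
                   genera = length(unique(tb$gOTU)),
                   species = length(unique(tb$sOTU)))
    agree <- function(lab, tru) {
        pure <- tapply(tru, lab, function(x) length(unique(x)) == 1L)
        complete <- tapply(lab, tru, function(x) length(unique(x)) == 1L)
        mean(pure[lab] & complete[tru])
    }
    agreement <- c(
        families = agree(tb$fOTU, truth$family[ix]),
        genera = agree(tb$gOTU, truth$genus[ix]),
        species = agree(tb$sOTU, truth$species[ix]))
    list(planted = planted, recovered = recovered, agreement = agreement)
}

#' Write the pipeline outputs
#'
#' Writes the trimmed sequences, discard log, cutoffs, assignment table,
#' representative FASTA per level, known-species table, ecological summary
#' and report tables into a directory as TSV/FASTA/JSON/Markdown.
#'
#' @param result Output of [runPipeline()].
#' @param dir Output directory.
#' @return Invisibly, the directory.
#' @export
writePipelineResults <- function(result, dir) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    pth <- function(f) file.path(dir, f)
    writeAmpliconFasta(result$kept, pth("trimmed.fasta"))
    utils::write.table(result$discarded, pth("discarded.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    writeCutoffs(result$cutoffs, pth("cutoffs.json"))
    tb <- otuTable(result$assignment)
    reps <- representatives(result$assignment)
    tb$representative <- tb$id %in% reps
    utils::write.table(tb, pth("assignment.tsv"), sep = "\t", quote = FALSE,
                       row.names = FALSE)
    for (level in c("fOTU", "gOTU", "sOTU")) {
        labs <- sort(unique(tb[[level]]), method = "radix")
        seqs <- result$kept@seqs[reps[labs]]
        names(seqs) <- labs
        Biostrings::writeXStringSet(seqs,
            pth(sprintf("representatives_%s.fasta", level)), width = 20000L)
    }
    utils::write.table(result$species, pth("known_species.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(result$summaries, pth("ecology.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    writeReportTable(result$diversity$overall, pth("diversity_overall"))
    writeReportTable(result$diversity$generaByFamily,
                     pth("diversity_genera_by_family"))
    writeReportTable(result$diversity$speciesByFamily,
                     pth("diversity_species_by_family"))
    writeReportTable(result$top$prevalent, pth("top_prevalent"))
    writeReportTable(result$top$abundant, pth("top_abundant"))
    invisible(dir)
}
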