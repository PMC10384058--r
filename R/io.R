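#' Read and write amplicon collections
#'
#' FASTA IO goes through Biostrings. Record names are written as
#' \code{<id>|<sample_id>} when a sample id is present; taxonomy travels in a
#' side-car TSV (\code{id}, \code{lineage}).
#'
#' @param x An [AmpliconSet-class].
#' @param fasta Path to the FASTA file.
#' @param taxonomy Optional path to the taxonomy TSV.
#' @return \code{writeAmpliconFasta}: invisibly, the paths written;
#'   \code{readAmpliconFasta}: an [AmpliconSet-class].
#' @export
writeAmpliconFasta <- function(x, fasta, taxonomy = NULL) {
    seqs <- x@seqs
    nm <- names(seqs)
    withSample <- !is.na(x@sampleId)
    names(seqs)[withSample] <- paste0(nm[withSample], "|",
                                      x@sampleId[withSample])
    Biostrings::writeXStringSet(seqs, fasta, width = 20000L)
    if (!is.null(taxonomy))
        utils::write.table(
            data.frame(id = nm, lineage = x@lineage,
                       stringsAsFactors = FALSE),
            taxonomy, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(c(fasta, taxonomy))
}

#' @rdname writeAmpliconFasta
#' @param gapped Whether the FASTA holds alignment rows.
#' @export
readAmpliconFasta <- function(fasta, taxonomy = NULL, gapped = FALSE) {
    seqs <- Biostrings::readDNAStringSet(fasta)
    parts <- strsplit(names(seqs), "|", fixed = TRUE)
    ids <- vapply(parts, `[[`, "", 1L)
    sids <- vapply(parts, function(p)
        if (length(p) > 1L) p[[2L]] else NA_character_, "")
    names(seqs) <- ids
    lin <- rep("", length(seqs))
    if (!is.null(taxonomy)) {
        tx <- utils::read.delim(taxonomy, stringsAsFactors = FALSE)
        lin <- tx$lineage[match(ids, tx$id)]
        lin[is.na(lin)] <- ""
    }
    ampliconSet(seqs, lineage = lin, sampleId = sids, gapped = gapped)
}

#' Write a synthetic community to plain-text files
#'
#' Writes \code{aligned.fasta} (+ \code{taxonomy.tsv}),
#' \code{references.fasta} (+ \code{reference_taxonomy.tsv}),
#' \code{samples.tsv}, \code{abundance.tsv}, \code{truth.tsv} and
#' \code{config.json} into a directory.
#'
#' @param community A [SyntheticCommunity-class].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the directory.
#' @export
writeCommunity <- function(community, dir) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    pth <- function(f) file.path(dir, f)
    writeAmpliconFasta(community@records, pth("aligned.fasta"),
                       pth("taxonomy.tsv"))
    writeAmpliconFasta(community@references, pth("references.fasta"),
                       pth("reference_taxonomy.tsv"))
    utils::write.table(community@samples, pth("samples.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    ab <- data.frame(sample_id = rownames(community@abundance),
                     community@abundance, check.names = FALSE,
                     stringsAsFactors = FALSE)
    utils::write.table(ab, pth("abundance.tsv"), sep = "\t", quote = FALSE,
                       row.names = FALSE)
    utils::write.table(community@truth, pth("truth.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    cfg <- community@config
    cfgList <- list(seed = cfg@seed, n_families = cfg@nFamilies,
        genera_per_family = cfg@generaPerFamily,
        species_per_genus = cfg@speciesPerGenus,
        region_length = cfg@regionLength,
        within_species_identity = cfg@withinSpeciesIdentity,
        within_genus_identity = cfg@withinGenusIdentity,
        within_family_identity = cfg@withinFamilyIdentity,
        across_family_identity = cfg@acrossFamilyIdentity,
        n_samples = cfg@nSamples, environments = cfg@environments,
        fragment_windows = cfg@fragmentWindows,
        window_weights = cfg@windowWeights,
        fragments_per_species = cfg@fragmentsPerSpecies,
        short_fragment_rate = cfg@shortFragmentRate,
        abundance_alpha = cfg@abundanceAlpha)
    jsonlite::write_json(cfgList, pth("config.json"), auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
    invisible(dir)
}

#' Write a calibrated cutoff set as JSON
#'
#' @param x A [CutoffSet-class].
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
writeCutoffs <- function(x, path) {
    jsonlite::write_json(list(species = x@species, genus = x@genus,
        family = x@family, pair_counts = as.list(x@pairCounts)),
        path, auto_unbox = TRUE, digits = NA)
    invisible(path)
}

#' @rdname writeCutoffs
#' @export
readCutoffs <- function(path) {
    j <- jsonlite::read_json(path, simplifyVector = TRUE)
    cutoffSet(j$species, j$genus, j$family,
              pairCounts = unlist(j$pair_counts))
}
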