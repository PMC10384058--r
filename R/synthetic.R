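#' Simulation settings for a synthetic amplicon community
#'
#' Builds a [SimulationConfig-class]. The defaults describe the study
#' conditions the package's validation runs on: a planted hierarchy of 3
#' families x 3 genera x 3 species over a 282-base analysis region, an
#' identity ladder of 0.99 / 0.96 / 0.92 / 0.90 (within species / within
#' genus / within family / across families, measured over the planted
#' analysis region), two fragment windows \code{[0,220)} and \code{[60,282)}
#' (ungapped region coordinates) drawn with 60/40 weights, 18 fragments per
#' species of which 10 percent are truncated below the length filter, and 60
#' samples with long-tailed relative abundances (Dirichlet-like shape 0.3)
#' straddling the 0.1 percent threshold by construction.
#'
#' @param seed Integer RNG seed; the whole simulation is deterministic in it.
#' @param nFamilies,generaPerFamily,speciesPerGenus Planted hierarchy sizes.
#' @param regionLength Ungapped bases of the master region (default 282).
#' @param withinSpeciesIdentity Target pairwise identity of fragment variants
#'   of one species over their fragment window.
#' @param withinGenusIdentity,withinFamilyIdentity,acrossFamilyIdentity
#'   Target pairwise identities among planted species sequences over the
#'   analysis region, strictly decreasing.
#' @param nSamples Number of samples.
#' @param environments Environment categories raw sample labels are drawn
#'   from (via a built-in synonym table of realistic free-text labels).
#' @param fragmentWindows List of ungapped \code{c(start, end)} intervals of
#'   the master region.
#' @param windowWeights Window assignment probabilities.
#' @param fragmentsPerSpecies Fragments generated per planted species.
#' @param shortFragmentRate Fraction of fragments truncated below the length
#'   filter.
#' @param abundanceAlpha Gamma shape of the long-tailed abundance model.
#' @return A validated [SimulationConfig-class].
#' @export
simulationConfig <- function(seed = 1L, nFamilies = 3L, generaPerFamily = 3L,
        speciesPerGenus = 3L, regionLength = 282L,
        withinSpeciesIdentity = 0.99, withinGenusIdentity = 0.96,
        withinFamilyIdentity = 0.92, acrossFamilyIdentity = 0.90,
        nSamples = 60L,
        environments = c("saline water", "freshwater", "soil", "host",
                         "bioreactor", "excluded"),
        fragmentWindows = list(c(0L, 220L), c(60L, 282L)),
        windowWeights = c(0.6, 0.4), fragmentsPerSpecies = 18L,
        shortFragmentRate = 0.1, abundanceAlpha = 0.3) {
    cfg <- methods::new("SimulationConfig", seed = as.integer(seed),
        nFamilies = as.integer(nFamilies),
        generaPerFamily = as.integer(generaPerFamily),
        speciesPerGenus = as.integer(speciesPerGenus),
        regionLength = as.integer(regionLength),
        withinSpeciesIdentity = withinSpeciesIdentity,
        withinGenusIdentity = withinGenusIdentity,
        withinFamilyIdentity = withinFamilyIdentity,
        acrossFamilyIdentity = acrossFamilyIdentity,
        nSamples = as.integer(nSamples), environments = environments,
        fragmentWindows = lapply(fragmentWindows, as.integer),
        windowWeights = windowWeights,
        fragmentsPerSpecies = as.integer(fragmentsPerSpecies),
        shortFragmentRate = shortFragmentRate,
        abundanceAlpha = abundanceAlpha)
    methods::validObject(cfg)
    cfg
}

# evaluate code under a given seed, restoring the caller's RNG state
withSeed <- function(seed, code) {
    has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                      envir = globalenv()))
    set.seed(as.integer(seed))
    code
}

# --- gapped master layout -------------------------------------------------
# The ungapped master region is embedded in a wider alignment: 8 gap columns
# on each side plus a 4-column all-gap block at an interior position, so that
# column coverage varies and gapped slicing is exercised without modelling
# indel evolution.
masterLayout <- function(config) {
    L <- config@regionLength
    padLeft <- 8L; padRight <- 8L; gapBlock <- 4L
    gapAt <- min(30L, L)
    width <- L + padLeft + padRight + gapBlock
    colOf <- function(p) padLeft + p + ifelse(p >= gapAt, gapBlock, 0L)
    list(L = L, padLeft = padLeft, gapBlock = gapBlock, gapAt = gapAt,
         width = width, colOf = colOf)
}

# longest gap-free ungapped run inside the intersection of the fragment
# windows: the region the coverage-based selection recovers, and the region
# the identity ladder is planted on
plantedAnalysisRegion <- function(config) {
    lay <- masterLayout(config)
    s <- max(vapply(config@fragmentWindows, `[[`, integer(1), 1L))
    e <- min(vapply(config@fragmentWindows, `[[`, integer(1), 2L))
    if (e <= s) stop("fragment windows do not overlap")
    runs <- if (lay$gapAt > s && lay$gapAt < e)
        list(c(s, lay$gapAt), c(lay$gapAt, e)) else list(c(s, e))
    len <- vapply(runs, diff, integer(1))
    as.integer(runs[[which.max(len)]])
}

.mutate <- function(seq, sites, offsets = NULL) {
    bases <- c("A", "C", "G", "T")
    for (k in seq_along(sites)) {
        p <- sites[k] + 1L # 1-based
        alt <- setdiff(bases, seq[p])
        seq[p] <- if (is.null(offsets)) sample(alt, 1L) else
            alt[(offsets[k] - 1L) %% 3L + 1L]
    }
    seq
}

#' Plant the reference hierarchy
#'
#' Generates one full-length sequence per planted species by mutating a
#' random root: every family, genus and species branch substitutes a fixed
#' number of dedicated sites inside the analysis region (the longest gap-free
#' run shared by all fragment windows), sized so that mean pairwise
#' identities among species sequences within a genus, within a family and
#' across families land on the configured targets (within +/-1.5 percentage
#' points; the generator verifies every pair to +/- max(1 pp, 3/region) and
#' redraws on failure). Family and genus sites are globally disjoint; species
#' sites are disjoint within each genus and drawn from a shared pool across
#' genera, which is why the verification pass exists. Deterministic for a
#' fixed seed.
#'
#' @param config A [SimulationConfig-class].
#' @return List: \code{speciesSeqs} (named character vector of ungapped
#'   full-length species sequences), \code{taxonomy} (\code{data.frame}
#'   family/genus/species), \code{region} (planted \code{c(start, end)}),
#'   \code{config}.
#' @export
simulateReferenceHierarchy <- function(config) {
    methods::validObject(config)
    withSeed(config@seed, .simulateHierarchy(config))
}

.simulateHierarchy <- function(config) {
    region <- plantedAnalysisRegion(config)
    C <- region[2] - region[1]
    nF <- config@nFamilies; nG <- config@generaPerFamily
    nS <- config@speciesPerGenus
    wg <- config@withinGenusIdentity; wf <- config@withinFamilyIdentity
    af <- config@acrossFamilyIdentity
    dS <- max(1L, as.integer(round((1 - wg) * C / 2)))
    dG <- max(1L, as.integer(round((wg - wf) * C / 2)))
    dF <- max(1L, as.integer(round((wf - af) * C / 2)))
    nBranch <- nF * dF + nF * nG * dG
    if (nBranch + nS * dS > C)
        stop(sprintf(paste("identity ladder infeasible for this region:",
            "%d family/genus sites plus %d species sites per genus exceed",
            "%d analysis-region bases"), nBranch, nS * dS, C))
    tol <- max(0.01, 3 / C)
    for (attempt in seq_len(30L)) {
        res <- .plantOnce(config, region, C, dS, dG, dF)
        dev <- .ladderDeviation(res$speciesSeqs, res$taxonomy, region,
                                c(wg = wg, wf = wf, af = af))
        if (dev <= tol)
            return(list(speciesSeqs = res$speciesSeqs,
                        taxonomy = res$taxonomy, region = region,
                        config = config))
    }
    stop(sprintf(paste("identity ladder could not be realised within",
        "+/-%.3f after 30 attempts (targets too close for %d bases)"),
        tol, C))
}

.plantOnce <- function(config, region, C, dS, dG, dF) {
    nF <- config@nFamilies; nG <- config@generaPerFamily
    nS <- config@speciesPerGenus
    L <- config@regionLength
    bases <- c("A", "C", "G", "T")
    root <- sample(bases, L, replace = TRUE)
    allPos <- seq.int(region[1], region[2] - 1L)
    corePos <- allPos[sample.int(length(allPos))] # shuffled, 0-based
    take <- function(n) {
        on.exit(corePos <<- corePos[-seq_len(n)])
        corePos[seq_len(n)]
    }
    famSites <- lapply(seq_len(nF), function(f) take(dF))
    genSites <- lapply(seq_len(nF * nG), function(g) take(dG))
    # species sites: disjoint within a genus; across genera the shared pool
    # is recycled least-used-first, and a reused position is forced to a
    # different substitution than its first use, so pool reuse can shrink a
    # cross-genus distance by at most one per shared site
    freePool <- corePos
    useCount <- integer(length(freePool))
    usedAlt <- vector("list", length(freePool))
    mutateSpecies <- function(seq, sites) {
        for (p in sites) {
            k <- match(p, freePool)
            taboo <- c(seq[p + 1L], usedAlt[[k]])
            alt <- setdiff(bases, taboo)
            if (length(alt) == 0L) alt <- setdiff(bases, seq[p + 1L])
            b <- alt[sample.int(length(alt), 1L)]
            usedAlt[[k]] <<- c(usedAlt[[k]], b)
            seq[p + 1L] <- b
        }
        seq
    }
    seqs <- character(0)
    fams <- gens <- sps <- character(0)
    gi <- 0L
    for (f in seq_len(nF)) {
        famName <- sprintf("Fam%02d", f)
        famSeq <- .mutate(root, famSites[[f]])
        for (g in seq_len(nG)) {
            gi <- gi + 1L
            genName <- sprintf("%sGen%02d", famName, g)
            genSeq <- .mutate(famSeq, genSites[[gi]])
            ord <- order(useCount, stats::runif(length(freePool)))
            pick <- ord[seq_len(nS * dS)]
            useCount[pick] <- useCount[pick] + 1L
            spSites <- freePool[pick]
            for (s in seq_len(nS)) {
                spName <- sprintf("%s sp%02d", genName, s)
                sites <- spSites[((s - 1L) * dS + 1L):(s * dS)]
                spSeq <- mutateSpecies(genSeq, sites)
                seqs <- c(seqs, paste(spSeq, collapse = ""))
                fams <- c(fams, famName); gens <- c(gens, genName)
                sps <- c(sps, spName)
            }
        }
    }
    names(seqs) <- sps
    list(speciesSeqs = seqs,
         taxonomy = data.frame(family = fams, genus = gens, species = sps,
                               stringsAsFactors = FALSE))
}

# worst per-pair deviation of realized identity from its stratum target,
# measured over the planted region (hamming identity: sequences are gapless
# and equal length by construction)
.ladderDeviation <- function(speciesSeqs, taxonomy, region, targets) {
    core <- substr(speciesSeqs, region[1] + 1L, region[2])
    C <- region[2] - region[1]
    n <- length(core)
    worst <- 0
    m <- do.call(rbind, strsplit(core, ""))
    for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
        idn <- 1 - sum(m[i, ] != m[j, ]) / C
        target <- if (taxonomy$genus[i] == taxonomy$genus[j]) targets["wg"]
            else if (taxonomy$family[i] == taxonomy$family[j]) targets["wf"]
            else targets["af"]
        worst <- max(worst, abs(idn - target))
    }
    worst
}

#' Realized identity ladder of a planted hierarchy
#'
#' Mean pairwise identity among planted species sequences per stratum,
#' measured over the planted analysis region with [pairwiseIdentity()].
#'
#' @param hierarchy Output of [simulateReferenceHierarchy()] (or a
#'   [SyntheticCommunity-class]).
#' @return Named numeric vector: \code{withinGenus}, \code{withinFamily},
#'   \code{acrossFamily}.
#' @export
realizedIdentities <- function(hierarchy) {
    if (methods::is(hierarchy, "SyntheticCommunity"))
        hierarchy <- list(
            speciesSeqs = stats::setNames(
                vapply(seq_len(length(hierarchy@references)), function(i)
                    gsub("-", "", as.character(hierarchy@references@seqs[[i]])),
                    ""), names(hierarchy@references)),
            taxonomy = unique(hierarchy@truth[c("family", "genus", "species")]),
            region = hierarchy@plantedRegion)
    tx <- hierarchy$taxonomy[match(names(hierarchy$speciesSeqs),
                                   hierarchy$taxonomy$species), ]
    core <- substr(hierarchy$speciesSeqs, hierarchy$region[1] + 1L,
                   hierarchy$region[2])
    n <- length(core)
    acc <- c(withinGenus = 0, withinFamily = 0, acrossFamily = 0)
    cnt <- c(withinGenus = 0L, withinFamily = 0L, acrossFamily = 0L)
    for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
        s <- if (tx$genus[i] == tx$genus[j]) "withinGenus"
            else if (tx$family[i] == tx$family[j]) "withinFamily"
            else "acrossFamily"
        acc[s] <- acc[s] + pairwiseIdentity(core[i], core[j])
        cnt[s] <- cnt[s] + 1L
    }
    ifelse(cnt > 0, acc / pmax(cnt, 1L), NA_real_)
}

# embed an ungapped full-length sequence (character scalar) into the gapped
# master row, keeping only positions in `covered` (0-based ungapped set)
.embedRow <- function(seqChars, lay, covered = NULL) {
    row <- rep("-", lay$width)
    pos <- if (is.null(covered)) seq.int(0L, lay$L - 1L) else covered
    row[lay$colOf(pos) + 1L] <- seqChars[pos + 1L]
    paste(row, collapse = "")
}

#' Fragment planted species into gapped amplicon records
#'
#' Emulates amplicon collections pooled across studies that target different
#' subregions with different primers: every record is a copy of a planted
#' species sequence restricted to one fragment window (chosen with the
#' configured weights), embedded as a row of the gapped master alignment. A
#' \code{shortFragmentRate} fraction is truncated to the first 45 percent of
#' its window, guaranteed below the downstream length filter. Within-species
#' variability is applied to a fraction of records as substitutions confined
#' to the window outside the shared analysis region, sized so two variant
#' records of one species agree at about \code{withinSpeciesIdentity} over
#' their window; the analysis region itself stays exact so planted cluster
#' structure is recoverable. Records are annotated to order rank only (the
#' planted families and genera are novel diversity); truth labels live in
#' the returned table. Deterministic in \code{seed}.
#'
#' @param hierarchy Output of [simulateReferenceHierarchy()].
#' @param windows,weights Fragment windows (ungapped \code{c(start,end)})
#'   and their probabilities; default from the hierarchy's config.
#' @param shortFragmentRate,fragmentsPerSpecies Defaults from the config.
#' @param seed RNG seed (default: config seed + 1).
#' @return List: \code{records} (gapped [AmpliconSet-class], ids
#'   \code{seq0001, ...}), \code{truth} (\code{data.frame} id, family, genus,
#'   species, window).
#' @export
fragmentRecords <- function(hierarchy, windows = NULL, weights = NULL,
                            shortFragmentRate = NULL,
                            fragmentsPerSpecies = NULL, seed = NULL) {
    config <- hierarchy$config
    if (is.null(windows)) windows <- config@fragmentWindows
    if (length(windows) == 0L) stop("at least one fragment window is required")
    if (is.null(weights)) weights <- config@windowWeights
    if (is.null(shortFragmentRate)) shortFragmentRate <- config@shortFragmentRate
    if (is.null(fragmentsPerSpecies))
        fragmentsPerSpecies <- config@fragmentsPerSpecies
    if (is.null(seed)) seed <- config@seed + 1L
    lay <- masterLayout(config)
    region <- hierarchy$region
    orderLineage <- "Bacteria;Bacteroidota;Saprospiria;Saprospirales;;"
    withSeed(seed, {
        rows <- character(0); ids <- character(0)
        tFam <- tGen <- tSp <- character(0); tWin <- integer(0)
        k <- 0L
        for (sp in names(hierarchy$speciesSeqs)) {
            chars <- strsplit(hierarchy$speciesSeqs[[sp]], "")[[1]]
            tx <- hierarchy$taxonomy[hierarchy$taxonomy$species == sp, ]
            for (i in seq_len(fragmentsPerSpecies)) {
                k <- k + 1L
                w <- sample.int(length(windows), 1L, prob = weights)
                win <- windows[[w]]
                wpos <- seq.int(win[1], win[2] - 1L)
                frag <- chars
                # variant records: substitutions outside the analysis region
                flank <- setdiff(wpos, seq.int(region[1], region[2] - 1L))
                noisy <- length(flank) > 0 &&
                    config@withinSpeciesIdentity < 1 && i %% 3L != 1L
                if (noisy) {
                    r <- min(length(flank), max(1L, round(
                        (1 - config@withinSpeciesIdentity) * length(wpos) / 2)))
                    frag <- .mutate(frag, flank[sample.int(length(flank), r)])
                }
                short <- stats::runif(1) < shortFragmentRate
                if (short) wpos <- wpos[seq_len(floor(0.45 * length(wpos)))]
                rows <- c(rows, .embedRow(frag, lay, wpos))
                ids <- c(ids, sprintf("seq%04d", k))
                tFam <- c(tFam, tx$family); tGen <- c(tGen, tx$genus)
                tSp <- c(tSp, sp); tWin <- c(tWin, w)
            }
        }
        records <- ampliconSet(stats::setNames(rows, ids),
            lineage = rep(orderLineage, length(ids)), gapped = TRUE)
        list(records = records,
             truth = data.frame(id = ids, family = tFam, genus = tGen,
                 species = tSp, window = tWin, stringsAsFactors = FALSE))
    })
}

# realistic free-text origin labels per category
.RAW_LABELS <- list(
    "saline water" = c("marine water", "coastal seawater", "marine sediment",
        "beach sand", "saline lagoon"),
    freshwater = c("lake water", "river sediment biofilm", "freshwater pond",
        "alpine stream"),
    soil = c("agricultural soil", "forest soil", "rhizosphere"),
    air = c("outdoor air filter", "urban aerosol"),
    plant = c("plant leaf surface", "phyllosphere"),
    host = c("human gut", "insect gut", "mouse skin"),
    "plant saline water" = c("seagrass blade", "kelp surface"),
    "host saline water" = c("marine sponge tissue", "coral mucus"),
    bioreactor = c("activated sludge", "wastewater treatment plant",
        "anaerobic digester", "nitrifying bioreactor"),
    excluded = c("laboratory-cultivated photosynthetic mat",
        "biofilm on polymer material surface"),
    other = c("unspecified environmental sample")
)

#' Simulate sample metadata and relative abundances
#'
#' Draws one raw free-text environment label per sample (from a built-in
#' synonym table over the configured categories, so the categorizer is
#' exercised non-trivially) and a long-tailed relative-abundance matrix:
#' every species gets a Beta-distributed occupancy probability, present
#' species receive Gamma(\code{abundanceAlpha}) weights scaled to a random
#' total target fraction per sample (row sums stay below 1; the remainder is
#' non-target taxa). By construction at least one species stays below the
#' 0.1 percent threshold in every sample and at least one reaches it.
#'
#' @param species Character vector of species ids (or the output of
#'   [simulateReferenceHierarchy()]).
#' @param config A [SimulationConfig-class].
#' @param seed RNG seed (default: config seed + 2).
#' @return List: \code{samples} (\code{data.frame} sample_id, raw_label),
#'   \code{abundance} (samples x species matrix of fractions).
#' @export
simulateAbundanceProfiles <- function(species, config, seed = NULL) {
    if (is.list(species) && !is.null(species$speciesSeqs))
        species <- names(species$speciesSeqs)
    stopifnot(config@nSamples >= 1L, length(config@environments) >= 1L)
    if (is.null(seed)) seed <- config@seed + 2L
    withSeed(seed, {
        n <- config@nSamples
        ids <- sprintf("S%03d", seq_len(n))
        cats <- sample(config@environments, n, replace = TRUE)
        raw <- vapply(cats, function(cat) {
            pool <- .RAW_LABELS[[cat]]
            if (is.null(pool)) cat else pool[sample.int(length(pool), 1L)]
        }, "", USE.NAMES = FALSE)
        samples <- data.frame(sample_id = ids, raw_label = raw,
                              stringsAsFactors = FALSE)
        p <- length(species)
        occupancy <- stats::rbeta(p, 0.7, 1.1)
        ab <- matrix(0, n, p, dimnames = list(ids, species))
        for (i in seq_len(n)) {
            present <- stats::runif(p) < occupancy
            if (!any(present)) present[sample.int(p, 1L)] <- TRUE
            w <- stats::rgamma(sum(present), shape = config@abundanceAlpha)
            if (sum(w) == 0) w <- rep(1, length(w))
            total <- stats::runif(1, 0.1, 0.7)
            ab[i, present] <- w / sum(w) * total
        }
        # plant species straddling the 0.1% threshold
        mx <- apply(ab, 2, max)
        if (p >= 2L && all(mx >= 0.001)) {
            j <- which.min(mx)
            ab[, j] <- ab[, j] * (8e-4 / mx[j])
        }
        mx <- apply(ab, 2, max)
        if (all(mx < 0.001)) {
            j <- which.max(mx)
            ab[, j] <- ab[, j] * (1.5e-3 / mx[j])
        }
        list(samples = samples, abundance = ab)
    })
}

#' Simulate a full synthetic community
#'
#' Orchestrates [simulateReferenceHierarchy()], [fragmentRecords()] and
#' [simulateAbundanceProfiles()] into a [SyntheticCommunity-class]: gapped
#' fragment records with source samples (drawn proportionally to the
#' species' abundance profile), planted truth labels, one gapped full-length
#' reference row per planted species (annotated to genus, named by
#' binomial), the sample table and the abundance matrix. Identical config
#' and seed give byte-identical output.
#'
#' @param config A [SimulationConfig-class].
#' @return A [SyntheticCommunity-class].
#' @examples
#' cm <- simulateCommunity(simulationConfig(seed = 7, nFamilies = 1,
#'     generaPerFamily = 1, speciesPerGenus = 2, fragmentsPerSpecies = 4,
#'     nSamples = 5))
#' cm
#' @export
simulateCommunity <- function(config) {
    methods::validObject(config)
    hier <- simulateReferenceHierarchy(config)
    frag <- fragmentRecords(hier)
    prof <- simulateAbundanceProfiles(names(hier$speciesSeqs), config)
    lay <- masterLayout(config)
    refRows <- vapply(hier$speciesSeqs, function(s)
        .embedRow(strsplit(s, "")[[1]], lay), "")
    refLineage <- sprintf("Bacteria;Bacteroidota;Saprospiria;Saprospirales;%s;%s",
        hier$taxonomy$family, hier$taxonomy$genus)
    references <- ampliconSet(refRows, lineage = refLineage, gapped = TRUE)
    records <- frag$records
    withSeed(config@seed + 3L, {
        sid <- vapply(frag$truth$species, function(sp) {
            w <- prof$abundance[, sp]
            if (sum(w) == 0) w <- rep(1, length(w))
            sample(prof$samples$sample_id, 1L, prob = w)
        }, "", USE.NAMES = FALSE)
        records@sampleId <- sid
    })
    methods::new("SyntheticCommunity", records = records, truth = frag$truth,
        references = references, samples = prof$samples,
        abundance = prof$abundance, config = config,
        plantedRegion = hier$region)
}
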