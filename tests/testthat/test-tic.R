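linOf <- function(fam = "", gen = "") sprintf(
    "Bacteria;Bacteroidota;Saprospiria;Saprospirales;%s;%s", fam, gen)

test_that("taxonomy binning partitions records by deepest annotated rank", {
    x <- entrySet(c(a = "ACGT", b = "ACGA", c = "ACGC", d = "ACGG"),
        lineage = c(linOf("F1", "G1"), linOf("F1", "G2"), linOf("F1"),
                    orderLin))
    bt <- binByTaxonomy(x)
    expect_length(bt$bins, 4)
    expect_true(any(grepl("F1;G1$", names(bt$bins))))
    expect_true(any(grepl("F1/unclassified$", names(bt$bins))))
    expect_true(any(grepl("Saprospirales/unclassified$", names(bt$bins))))
    # partition: every id in exactly one bin
    expect_setequal(unlist(bt$bins), names(x))
    expect_equal(sum(lengths(bt$bins)), length(x))
    info <- bt$info
    expect_equal(info$genus[grepl("F1;G1$", info$bin)], "G1")
    expect_true(is.na(info$family[grepl("unclassified$", info$bin) &
                                  grepl("Saprospirales/", info$bin)]))
})

test_that("greedy clustering separates at the cutoff", {
    set.seed(431)
    s1 <- randomSeq(100)
    s2 <- mutatedCopy(s1, 3)   # ~0.97 to s1
    s3 <- mutatedCopy(s1, 12)  # ~0.88-0.91 to both
    x <- entrySet(c(s1 = s1, s2 = s2, s3 = s3))
    cl <- incrementalCluster(x, 0.96)
    expect_length(cl$clusters, 2)
    expect_setequal(cl$clusters[[1]], c("s1", "s2"))
    expect_equal(cl$clusters[[2]], "s3")
    # single entry founds a singleton
    one <- incrementalCluster(entrySet(c(z = s1)), 0.96)
    expect_equal(one$representatives, "z")
    # a permissive cutoff yields one cluster
    all1 <- incrementalCluster(x, 0.80)
    expect_length(all1$clusters, 1)
    # identical sequences always co-cluster
    same <- incrementalCluster(entrySet(c(a = s1, b = s1, c = s1)), 1)
    expect_length(same$clusters, 1)
})

test_that("incremental clustering equals the oracle on random bins", {
    set.seed(432)
    for (k in 1:30) {
        n <- sample(2:25, 1)
        base <- randomSeq(60)
        seqs <- vapply(seq_len(n), function(i)
            mutatedCopy(base, sample.int(12, 1)), "")
        names(seqs) <- sprintf("e%02d", seq_len(n))
        mult <- sample.int(5, n, replace = TRUE)
        x <- entrySet(seqs, multiplicity = mult)
        cutoff <- sample(c(0.9, 0.93, 0.96), 1)
        expect_identical(incrementalCluster(x, cutoff),
                         oracleCluster(x, cutoff))
    }
    expect_error(oracleCluster(entrySet(
        stats::setNames(rep("ACGT", 41), sprintf("x%02d", 1:41))), 0.9),
        "40")
})

test_that("hierarchical clustering recovers a small planted hierarchy", {
    cfg <- simulationConfig(seed = 61, nFamilies = 2, generaPerFamily = 2,
        speciesPerGenus = 2, withinSpeciesIdentity = 0.97,
        withinGenusIdentity = 0.93, withinFamilyIdentity = 0.905,
        acrossFamilyIdentity = 0.88, fragmentsPerSpecies = 8,
        nSamples = 10, fragmentWindows = list(c(0L, 274L), c(8L, 282L)))
    cm <- simulateCommunity(cfg)
    res <- runPipeline(cm, cutoffs = cutoffSet(0.96, 0.92, 0.90))
    expect_equal(unname(res$evaluation$recovered), c(2L, 4L, 8L))
    expect_equal(unname(res$evaluation$agreement), c(1, 1, 1))
    expect_true(validateAssignment(res$assignment, res$kept))
})

test_that("annotated lineages bound the clustering", {
    set.seed(433)
    s <- randomSeq(80)
    x <- entrySet(c(a = s, b = s), # identical sequences ...
        lineage = c(linOf("FamA", "G1"), linOf("FamB", "G2")))
    asg <- hierarchicalTIC(x, cutoffSet(0.97, 0.95, 0.90))
    tb <- otuTable(asg)
    # ... in different known families never share an fOTU
    expect_equal(length(unique(tb$fOTU)), 2L)
    expect_equal(otuTaxonomy(asg)$taxon[otuTaxonomy(asg)$rank == "family"],
                 c("FamA", "FamB"))
})

test_that("assignment is invariant to record permutation", {
    set.seed(434)
    base <- randomSeq(70)
    seqs <- vapply(1:20, function(i) mutatedCopy(base, sample.int(10, 1)), "")
    names(seqs) <- sprintf("r%02d", 1:20)
    x <- entrySet(seqs, lineage = rep(orderLin, 20),
                  multiplicity = sample.int(4, 20, replace = TRUE))
    cs <- cutoffSet(0.97, 0.94, 0.90)
    a <- hierarchicalTIC(x, cs)
    perm <- sample(20)
    b <- hierarchicalTIC(x[perm], cs)
    ta <- otuTable(a); tb <- otuTable(b)
    tb <- tb[match(ta$id, tb$id), ]
    rownames(tb) <- NULL
    expect_identical(ta, tb)
    expect_identical(representatives(a), representatives(b))
})

test_that("raising the species cutoff never decreases the sOTU count", {
    set.seed(435)
    base <- randomSeq(90)
    seqs <- vapply(1:25, function(i) mutatedCopy(base, sample.int(15, 1)), "")
    names(seqs) <- sprintf("r%02d", 1:25)
    x <- entrySet(seqs, lineage = rep(orderLin, 25))
    counts <- vapply(c(0.90, 0.93, 0.95, 0.97, 0.99, 1), function(cs)
        length(unique(otuTable(
            hierarchicalTIC(x, cutoffSet(cs, 0.88, 0.85)))$sOTU)),
        integer(1))
    expect_true(all(diff(counts) >= 0))
})

test_that("member-to-representative identity respects every level cutoff", {
    cfg <- simulationConfig(seed = 62, nFamilies = 2, generaPerFamily = 2,
        speciesPerGenus = 2, fragmentsPerSpecies = 6, nSamples = 8)
    cm <- simulateCommunity(cfg)
    res <- runPipeline(cm)
    expect_true(validateAssignment(res$assignment, res$kept))
})

test_that("disordered cutoffs are rejected", {
    expect_error(cutoffSet(0.90, 0.92, 0.96), "family <= genus <= species")
})
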