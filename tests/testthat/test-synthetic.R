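test_that("a degenerate hierarchy yields exactly one reference", {
    cfg <- simulationConfig(seed = 5, nFamilies = 1, generaPerFamily = 1,
        speciesPerGenus = 1, fragmentsPerSpecies = 3, nSamples = 4)
    cm <- simulateCommunity(cfg)
    expect_length(cm@references, 1)
    expect_equal(length(cm@records), 3L)
    expect_true(all(cm@truth$species == names(cm@references)))
})

test_that("the identity ladder lands on its targets for a 2x2x2 hierarchy", {
    cfg <- simulationConfig(seed = 7, nFamilies = 2, generaPerFamily = 2,
        speciesPerGenus = 2)
    hier <- simulateReferenceHierarchy(cfg)
    expect_length(hier$speciesSeqs, 8)
    ids <- realizedIdentities(hier)
    expect_lt(abs(ids["withinGenus"] - 0.96), 0.015)
    expect_lt(abs(ids["withinFamily"] - 0.92), 0.015)
    expect_lt(abs(ids["acrossFamily"] - 0.90), 0.015)
    # strict ordering of the realized ladder
    expect_true(ids["withinGenus"] > ids["withinFamily"])
    expect_true(ids["withinFamily"] > ids["acrossFamily"])
})

test_that("simulation is byte-identical under a fixed config and seed", {
    cfg <- simulationConfig(seed = 9, nFamilies = 2, generaPerFamily = 2,
        speciesPerGenus = 2, fragmentsPerSpecies = 6, nSamples = 10)
    a <- simulateCommunity(cfg)
    b <- simulateCommunity(cfg)
    expect_identical(as.character(ampliconSeqs(a@records)),
                     as.character(ampliconSeqs(b@records)))
    expect_identical(a@truth, b@truth)
    expect_identical(a@abundance, b@abundance)
    expect_identical(a@samples, b@samples)
    da <- file.path(tempdir(), "cm_a"); db <- file.path(tempdir(), "cm_b")
    writeCommunity(a, da); writeCommunity(b, db)
    for (f in list.files(da)) {
        expect_identical(readLines(file.path(da, f)),
                         readLines(file.path(db, f)), label = f)
    }
    unlink(c(da, db), recursive = TRUE)
})

test_that("an unorderable or infeasible ladder fails loudly", {
    expect_error(simulationConfig(withinGenusIdentity = 0.90,
        withinFamilyIdentity = 0.92), "ordered")
    cfg <- simulationConfig(speciesPerGenus = 45L) # demands > region bases
    expect_error(simulateReferenceHierarchy(cfg), "infeasible")
})

test_that("ground truth traces every fragment to one planted species", {
    cm <- simulateCommunity(simulationConfig(seed = 13,
        fragmentsPerSpecies = 6, nSamples = 10))
    expect_setequal(cm@truth$id, names(cm@records))
    expect_false(anyDuplicated(cm@truth$id) > 0)
    tx <- unique(cm@truth[c("family", "genus", "species")])
    expect_equal(nrow(tx), 27) # one row per planted species
    expect_true(all(table(tx$genus) == 3), info = "3 species per genus")
    expect_true(all(table(tx$family) == 9))
})

test_that("window choice follows the configured weights", {
    cfg <- simulationConfig(seed = 21, nFamilies = 1, generaPerFamily = 1,
        speciesPerGenus = 1, fragmentsPerSpecies = 1000L,
        shortFragmentRate = 0)
    hier <- simulateReferenceHierarchy(cfg)
    frag <- fragmentRecords(hier)
    n1 <- sum(frag$truth$window == 1L)
    expect_gte(n1, qbinom(0.005, 1000, 0.6))
    expect_lte(n1, qbinom(0.995, 1000, 0.6))
})

test_that("short fragments are removed by the filter, full ones kept", {
    base <- simulationConfig(seed = 23, nFamilies = 1, generaPerFamily = 1,
        speciesPerGenus = 2, fragmentsPerSpecies = 20L)
    hier <- simulateReferenceHierarchy(base)
    region <- hier$region
    win <- regionWindow(ampliTIC:::masterLayout(base)$colOf(region[1]),
        ampliTIC:::masterLayout(base)$colOf(region[2] - 1L) + 1L,
        expectedBases = region[2] - region[1])
    full <- fragmentRecords(hier, shortFragmentRate = 0)
    expect_length(trimAndFilter(full$records, win)$kept,
                  length(full$records))
    short <- fragmentRecords(hier, shortFragmentRate = 1,
                             windows = list(c(0L, 282L)), weights = 1)
    expect_length(trimAndFilter(short$records, win)$kept, 0)
})

test_that("abundance profiles are normalised and straddle the gate", {
    cfg <- simulationConfig(seed = 31, nSamples = 100L)
    prof <- simulateAbundanceProfiles(sprintf("sp%02d", 1:27), cfg)
    expect_true(all(rowSums(prof$abundance) <= 1 + 1e-12))
    mx <- apply(prof$abundance, 2, max)
    expect_true(any(mx < 0.001))
    expect_true(any(mx >= 0.001))
    expect_equal(nrow(prof$samples), 100L)
    expect_true(all(nchar(prof$samples$raw_label) > 0))
    one <- simulateAbundanceProfiles("spA",
        simulationConfig(seed = 32, nSamples = 1L))
    expect_equal(sum(one$abundance > 0), 1L)
})

test_that("the coverage profile is bimodal at the window occupancies", {
    cfg <- simulationConfig(seed = 33, nFamilies = 1, generaPerFamily = 1,
        speciesPerGenus = 1, fragmentsPerSpecies = 400L,
        shortFragmentRate = 0)
    hier <- simulateReferenceHierarchy(cfg)
    frag <- fragmentRecords(hier)
    cov <- positionCoverage(frag$records)
    lay <- ampliTIC:::masterLayout(cfg)
    n1 <- sum(frag$truth$window == 1L); n2 <- 400L - n1
    # core covered by every fragment, exclusive zones by their window's share
    expect_equal(cov[lay$colOf(100L) + 1L], 400L)
    expect_equal(cov[lay$colOf(10L) + 1L], n1)
    expect_equal(cov[lay$colOf(250L) + 1L], n2)
    expect_equal(cov[lay$padLeft], 0L) # pad column is all-gap
})
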