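sampleTable <- function(labels) data.frame(
    sample_id = sprintf("S%02d", seq_along(labels)), raw_label = labels,
    stringsAsFactors = FALSE)

test_that("raw labels map onto the fixed category vocabulary", {
    expect_equal(categorizeEnvironment("marine sediment"), "saline water")
    expect_equal(categorizeEnvironment("beach sand"), "saline water")
    expect_equal(categorizeEnvironment("activated sludge"), "bioreactor")
    expect_equal(categorizeEnvironment("wastewater treatment plant"),
                 "bioreactor")
    expect_equal(
        categorizeEnvironment("laboratory-cultivated photosynthetic mat"),
        "excluded")
    expect_equal(categorizeEnvironment("biofilm on polymer material"),
                 "excluded")
    expect_equal(categorizeEnvironment("freshwater sediment"), "freshwater")
    expect_equal(categorizeEnvironment("marine sponge tissue"),
                 "host saline water")
    expect_equal(categorizeEnvironment("seagrass blade"),
                 "plant saline water")
    expect_warning(out <- categorizeEnvironment("volcanic glass"),
                   "unmatched")
    expect_equal(out, "other")
    expect_equal(categorizeEnvironment("volcanic glass",
        extraRules = list(soil = "volcanic"), quiet = TRUE), "soil")
})

test_that("positivity is positives over totals per category", {
    samples <- sampleTable(rep("lake water", 4))
    ab <- matrix(c(0.2, 0.1, 0, 0), 4, 1,
                 dimnames = list(samples$sample_id, "SOTU1"))
    pos <- computePositivity(ab, samples)
    expect_equal(unname(pos["freshwater"]), 0.5)
    expect_equal(unname(pos["overall"]), 0.5)
    zero <- computePositivity(ab * 0, samples)
    expect_equal(unname(zero["overall"]), 0)
})

test_that("category positives partition the overall positives", {
    set.seed(451)
    labels <- sample(c("marine water", "lake water", "forest soil",
                       "activated sludge", "human gut"), 80, replace = TRUE)
    samples <- sampleTable(labels)
    ab <- matrix(rbinom(80 * 10, 1, 0.3) * runif(800), 80, 10,
                 dimnames = list(samples$sample_id, sprintf("SOTU%02d", 1:10)))
    pos <- computePositivity(ab, samples)
    cats <- categorizeEnvironment(labels)
    perCat <- pos[setdiff(names(pos), "overall")]
    totals <- table(cats)[names(perCat)]
    expect_equal(sum(perCat * as.integer(totals)),
                 unname(pos["overall"]) * 80)
})

test_that("a summary row reads the matrix directly, boundary inclusive", {
    samples <- sampleTable(c("marine water", "forest soil", "lake water"))
    ab <- matrix(c(0.002, 0.0009, 0, 0.001, 0, 0), 3, 2,
                 dimnames = list(samples$sample_id, c("SOTU1", "SOTU2")))
    sm <- summarizeSotuEcology(ab, samples)
    r1 <- sm[sm$sOTU == "SOTU1", ]
    expect_equal(r1$nPositive, 2L)
    expect_equal(r1$nPositiveGeThreshold, 1L)
    expect_equal(r1$maxAbundanceEnvironment, "saline water")
    expect_equal(r1$maxAbundance, 0.002)
    # abundance exactly 0.1% counts toward the gate
    r2 <- sm[sm$sOTU == "SOTU2", ]
    expect_equal(r2$nPositiveGeThreshold, 1L)
    # absent sOTU: zero-filled summary
    sm0 <- summarizeSotuEcology(ab, samples, sotus = c("SOTU1", "SOTU9"))
    r9 <- sm0[sm0$sOTU == "SOTU9", ]
    expect_equal(r9$nPositive, 0L)
    expect_equal(r9$maxAbundance, 0)
    expect_true(is.na(r9$dominantEnvironment))
})

test_that("excluded samples influence no statistic", {
    samples <- sampleTable(c("marine water",
                             "laboratory-cultivated photosynthetic mat"))
    ab <- matrix(c(0.001, 0.9), 2, 1,
                 dimnames = list(samples$sample_id, "SOTU1"))
    sm <- summarizeSotuEcology(ab, samples)
    expect_equal(sm$nPositive, 1L)
    expect_equal(sm$maxAbundance, 0.001)
    expect_equal(sm$maxAbundanceEnvironment, "saline water")
    pos <- computePositivity(ab, samples)
    expect_false("excluded" %in% names(pos))
})

test_that("dominant-environment ties break by summed abundance then order", {
    samples <- sampleTable(c("marine water", "marine water", "lake water",
                             "lake water"))
    ab <- matrix(c(0.01, 0.01, 0.05, 0.02), 4, 1,
                 dimnames = list(samples$sample_id, "SOTU1"))
    sm <- summarizeSotuEcology(ab, samples)
    expect_equal(sm$dominantEnvironment, "freshwater") # larger summed mass
    ab2 <- matrix(c(0.02, 0.02, 0.02, 0.02), 4, 1,
                  dimnames = list(samples$sample_id, "SOTU1"))
    sm2 <- summarizeSotuEcology(ab2, samples)
    expect_equal(sm2$dominantEnvironment, "saline water") # fixed order
})

test_that("abundance retention follows the gate and is threshold-monotone", {
    samples <- sampleTable(c("marine water", "forest soil"))
    ab <- matrix(c(0.0011, 0, 0, 0.0009), 2, 2,
                 dimnames = list(samples$sample_id, c("keep", "drop")))
    sm <- summarizeSotuEcology(ab, samples)
    expect_equal(filterByAbundance(sm), "keep")
    set.seed(452)
    big <- matrix(runif(50 * 30, 0, 0.01), 50, 30,
                  dimnames = list(sprintf("S%02d", 1:50),
                                  sprintf("SOTU%02d", 1:30)))
    samples50 <- sampleTable(rep("marine water", 50))
    kept <- vapply(c(0.0005, 0.002, 0.005, 0.009, 0.02), function(thr)
        length(filterByAbundance(summarizeSotuEcology(big, samples50,
                                                      threshold = thr))),
        integer(1))
    expect_true(all(diff(kept) <= 0))
})

test_that("summaries equal a brute-force recount on random data", {
    set.seed(453)
    n <- 60; p <- 25
    labels <- sample(unlist(ampliTIC:::.RAW_LABELS), n, replace = TRUE)
    samples <- sampleTable(labels)
    ab <- matrix(rbinom(n * p, 1, 0.4) * runif(n * p, 0, 0.01), n, p,
                 dimnames = list(samples$sample_id, sprintf("SOTU%02d", 1:p)))
    ab[sample(length(ab), 5)] <- 0.001 # plant exact-boundary cells
    cats <- categorizeEnvironment(labels, quiet = TRUE)
    samples$category <- cats
    sm <- summarizeSotuEcology(ab, samples, cosmopolitanMin = 10L)
    keep <- cats != "excluded"
    for (k in seq_len(p)) {
        v <- ab[keep, k]; cc <- cats[keep]
        expect_equal(sm$nPositive[k], sum(v > 0))
        expect_equal(sm$nPositiveGeThreshold[k], sum(v >= 0.001))
        expect_equal(sm$maxAbundance[k], max(v, 0))
        expect_equal(sm$cosmopolitan[k], sum(v > 0) >= 10)
        if (any(v > 0)) {
            expect_equal(sm$maxAbundanceEnvironment[k], cc[which.max(v)])
            counts <- table(cc[v > 0])
            expect_true(sm$dominantEnvironment[k] %in%
                        names(counts)[counts == max(counts)])
        }
    }
})
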