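# Independent pure-R Needleman-Wunsch oracle (match +1, mismatch -1, gap -1,
# canonical traceback diagonal > up > left), used to check the compiled
# implementation. Kept deliberately naive: full matrix, explicit loops.
dpIdentityOracle <- function(a, b) {
    # same canonicalisation as the operation under test: smaller string first
    if (a > b) { tmp <- a; a <- b; b <- tmp }
    av <- strsplit(a, "")[[1]]
    bv <- strsplit(b, "")[[1]]
    n <- length(av); m <- length(bv)
    H <- matrix(0L, n + 1, m + 1)
    H[1, ] <- -(0:m)
    H[, 1] <- -(0:n)
    for (i in 1:n) for (j in 1:m) {
        s <- if (av[i] == bv[j]) 1L else -1L
        H[i + 1, j + 1] <- max(H[i, j] + s, H[i, j + 1] - 1L,
                               H[i + 1, j] - 1L)
    }
    i <- n; j <- m; matches <- 0L; columns <- 0L
    while (i > 0 || j > 0) {
        if (i > 0 && j > 0) {
            s <- if (av[i] == bv[j]) 1L else -1L
            if (H[i + 1, j + 1] == H[i, j] + s) {
                if (s == 1L) matches <- matches + 1L
                i <- i - 1L; j <- j - 1L; columns <- columns + 1L
                next
            }
        }
        if (i > 0 && H[i + 1, j + 1] == H[i, j + 1] - 1L) {
            i <- i - 1L
        } else {
            j <- j - 1L
        }
        columns <- columns + 1L
    }
    list(identity = matches / columns, matches = matches, columns = columns,
         score = H[n + 1, m + 1])
}

randomSeq <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                      replace = TRUE), collapse = "")

# random point-substituted copy (k sites, guaranteed different bases)
mutatedCopy <- function(seq, k) {
    v <- strsplit(seq, "")[[1]]
    sites <- sample.int(length(v), k)
    for (p in sites) v[p] <- sample(setdiff(c("A", "C", "G", "T"), v[p]), 1)
    paste(v, collapse = "")
}

# small ungapped AmpliconSet with optional lineages/multiplicities
entrySet <- function(seqs, lineage = NULL, multiplicity = NULL) {
    ampliconSet(seqs, lineage = lineage, multiplicity = multiplicity,
                gapped = FALSE)
}

orderLin <- "Bacteria;Bacteroidota;Saprospiria;Saprospirales;;"

# the separated-ladder study configuration used for recovery checks: wide
# fragment windows so the 27-species ladder fits the analysis region
recoveryConfig <- function(seed) {
    simulationConfig(seed = seed, withinSpeciesIdentity = 0.97,
        withinGenusIdentity = 0.93, withinFamilyIdentity = 0.905,
        acrossFamilyIdentity = 0.88,
        fragmentWindows = list(c(0L, 274L), c(8L, 282L)))
}
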