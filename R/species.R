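#' Name molecular species after described species
#'
#' Maps every reference species to its best-matching sOTU representative by
#' global identity and, where that identity reaches the threshold ("above
#' 98 percent" in the original workflow; here \code{>=} by default, strict
#' \code{>} via \code{strict}), names the sOTU after it. When two or more
#' references land on one sOTU, the species are indistinguishable over the
#' region and the sOTU carries the slash-joined species epithets in reference
#' input order (e.g. \code{"Neolewinella marina/litorea"}). sOTUs that attract
#' no reference stay \code{"Unknown species"}. Each reference is assigned to
#' at most one sOTU (its best hit; identity ties go to the smaller sOTU
#' label).
#'
#' @param representatives Named character vector (or ungapped
#'   [AmpliconSet-class]) of sOTU representative sequences, names = sOTU
#'   labels, trimmed to the same region as the references.
#' @param refs Ungapped, region-trimmed [AmpliconSet-class] of reference
#'   species; names are binomials ("Genus epithet"). May be empty (all sOTUs
#'   stay unknown).
#' @param threshold Assignment threshold (default 0.98).
#' @param strict Use \code{identity > threshold} instead of \code{>=}.
#' @return \code{data.frame}: \code{sOTU}, \code{name}, \code{identity}
#'   (best reference identity, \code{NA} if no reference), \code{merged}
#'   (more than one reference mapped).
#' @export
assignKnownSpecies <- function(representatives, refs, threshold = 0.98,
                               strict = FALSE) {
    if (methods::is(representatives, "AmpliconSet"))
        representatives <- stats::setNames(
            as.character(representatives@seqs), names(representatives))
    sotus <- sort(names(representatives), method = "radix")
    representatives <- representatives[sotus]
    out <- data.frame(sOTU = sotus, name = "Unknown species",
        identity = NA_real_, merged = FALSE, stringsAsFactors = FALSE)
    nref <- if (is.null(refs)) 0L else length(refs)
    if (nref == 0L) return(out)
    stopifnot(methods::is(refs, "AmpliconSet"))
    hits <- vector("list", length(sotus))
    names(hits) <- sotus
    pass <- function(idn) if (strict) idn > threshold else idn >= threshold
    for (k in seq_len(nref)) {
        idn <- identityToMany(as.character(refs@seqs[[k]]), representatives)
        best <- which(idn == max(idn))[1L] # ties: smallest label (sorted)
        if (pass(idn[best]))
            hits[[best]] <- rbind(hits[[best]],
                data.frame(ref = names(refs)[k], identity = idn[best],
                           order = k, stringsAsFactors = FALSE))
    }
    for (s in seq_along(sotus)) {
        h <- hits[[s]]
        if (is.null(h)) next
        h <- h[order(h$order), , drop = FALSE]
        out$name[s] <- mergeBinomials(h$ref)
        out$identity[s] <- max(h$identity)
        out$merged[s] <- nrow(h) > 1L
    }
    out
}

# "Neolewinella marina", "Neolewinella litorea" -> "Neolewinella marina/litorea"
mergeBinomials <- function(names) {
    if (length(names) == 1L) return(names)
    parts <- strsplit(names, " +")
    genus <- parts[[1]][1]
    epithets <- vapply(parts, function(p) paste(p[-1], collapse = " "), "")
    paste0(genus, " ", paste(epithets, collapse = "/"))
}
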