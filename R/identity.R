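#' Global-alignment sequence identity
#'
#' Aligns two ungapped sequences end to end (Needleman-Wunsch, match +1,
#' mismatch -1, gap -1, linear gap cost) and returns identity as matched
#' columns over total alignment columns, so gaps penalise identity. The
#' traceback is canonical (diagonal preferred over a gap in the second
#' sequence, over a gap in the first), and the pair is canonicalised
#' (lexicographically smaller sequence first), making the value deterministic
#' among co-optimal alignments and exactly symmetric. In [0, 1].
#'
#' @param a,b Ungapped nucleotide sequences (character scalars,
#'   \code{DNAString} or length-1 \code{DNAStringSet}).
#' @param details When \code{TRUE} return \code{c(matches, columns, score)}
#'   instead of the identity fraction.
#' @return Identity fraction, or the detail vector.
#' @examples
#' pairwiseIdentity("ACGT", "ACGT") # 1
#' pairwiseIdentity("ACGT", "ACGA") # 0.75
#' @export
pairwiseIdentity <- function(a, b, details = FALSE) {
    a <- .asBases(a); b <- .asBases(b)
    if (nchar(a) == 0L || nchar(b) == 0L)
        stop("pairwise identity requires two non-empty sequences")
    v <- .nwIdentity(a, b)
    if (details) v else unname(v["matches"] / v["columns"])
}

# identity of one query against an ordered set of subjects
identityToMany <- function(a, subjects) {
    a <- .asBases(a)
    if (length(subjects) == 0L) return(numeric(0))
    .nwIdentityMany(a, as.character(subjects))
}

.asBases <- function(x) {
    if (methods::is(x, "DNAStringSet")) x <- x[[1]]
    toupper(as.character(x))
}
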