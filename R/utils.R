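# Internal numeric and sequence helpers.

# log(sum(exp(x))) along rows of a matrix, guarded against -Inf rows
.logSumExpRows <- function(L) {
    m <- L[cbind(seq_len(nrow(L)), max.col(L, ties.method = "first"))]
    m[!is.finite(m)] <- 0
    m + log(rowSums(exp(L - m)))
}

.logMeanExpRows <- function(L) .logSumExpRows(L) - log(ncol(L))

# TRUE when, for every biomarker, its events appear in increasing waypoint
# order along the sequence
.validSequence <- function(s, spec) {
    bio <- eventBiomarker(spec)
    for (i in unique(bio)) {
        ev <- which(bio == i)          # event ids in increasing-waypoint order
        if (is.unsorted(match(ev, s))) return(FALSE)
    }
    TRUE
}

# random valid event sequence: random permutation with within-biomarker
# occurrences re-sorted into waypoint order
.randomSequence <- function(spec) {
    bio <- eventBiomarker(spec)
    s <- sample(length(bio))
    for (i in unique(bio)) {
        ev <- which(bio == i)
        s[which(bio[s] == i)] <- ev
    }
    s
}

# exact maximum-overlap matching of fitted subtype labels onto true labels;
# C is small so all permutations are enumerated
.permutations <- function(n) {
    if (n == 1L) return(matrix(1L, 1L, 1L))
    sub <- .permutations(n - 1L)
    out <- matrix(0L, 0L, n)
    for (i in seq_len(n)) {
        rest <- setdiff(seq_len(n), i)
        out <- rbind(out, cbind(i, matrix(rest[sub], nrow(sub))))
    }
    unname(out)
}

#' Match fitted subtype labels to reference labels
#'
#' Exhaustive maximum-overlap matching (exact for the small C used here):
#' returns the permutation \code{p} such that fitted label \code{s}
#' corresponds to reference label \code{p[s]}, maximizing the number of
#' agreeing subjects.
#'
#' @param fitted integer fitted subtype labels.
#' @param reference integer reference subtype labels (same length).
#' @param C number of subtype labels (defaults to the larger observed).
#' @return integer permutation vector of length \code{C}.
#' @export
matchSubtypes <- function(fitted, reference, C = max(fitted, reference)) {
    stopifnot(length(fitted) == length(reference))
    perms <- .permutations(C)
    best <- 1L
    bestHits <- -1L
    for (r in seq_len(nrow(perms))) {
        hits <- sum(perms[r, fitted] == reference)
        if (hits > bestHits) { bestHits <- hits; best <- r }
    }
    perms[best, ]
}

#' Normalized Kendall rank correlation between two event sequences
#'
#' Computes Kendall's tau between the event positions implied by two
#' sequences of the same event set; 1 means identical orderings, -1 a full
#' reversal. Used as the sequence-recovery metric.
#'
#' @param s1,s2 integer event sequences (position -> event id).
#' @return numeric scalar in [-1, 1].
#' @export
sequenceKendall <- function(s1, s2) {
    stopifnot(length(s1) == length(s2),
              identical(sort(s1), sort(s2)))
    cor(match(seq_along(s1), s1), match(seq_along(s2), s2),
        method = "kendall")
}

# deterministic derived seed, kept within 32-bit range
.subSeed <- function(seed, offset) (as.integer(seed) + offset) %% 2147483647L
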