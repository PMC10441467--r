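# Greedy maximum-likelihood fitting of event sequences, with hierarchical
# subtype splitting and alternating (responsibility / fraction) refinement.

# weighted marginal log-likelihood of one sequence
.weightedSeqLogLik <- function(X, sequence, spec, weights) {
    sum(weights * .subtypeLogLik(X, sequence, spec))
}

# factory for a fast weighted-marginal-log-likelihood evaluator with the
# data-dependent terms precomputed (hot path of the greedy fitter)
.seqEvaluator <- function(X, spec, weights) {
    sig <- spec@sigma
    scale <- any(sig != 1)
    Xs <- if (scale) sweep(X, 2L, sig, "/") else X
    rx <- rowSums(Xs * Xs)
    n <- nrow(X)
    N <- nEvents(spec)
    const <- -sum(log(sig)) - ncol(X) / 2 * log(2 * pi) - log(N + 1)
    function(s) {
        M <- .seqMeans(s, spec)
        if (scale) M <- sweep(M, 2L, sig, "/")
        L <- tcrossprod(Xs, M) - 0.5 * rx
        L <- L - rep(0.5 * rowSums(M * M), each = n)
        m <- L[cbind(seq_len(n), max.col(L, ties.method = "first"))]
        sum(weights * (m + log(rowSums(exp(L - m))) + const))
    }
}

# one greedy pass-to-convergence from a given starting sequence: relocate
# each event (random order per sweep) to its likelihood-maximizing valid
# position, ties broken toward the earliest position
.greedyFromStart <- function(X, spec, start, weights, maxSweeps = 100L) {
    s <- start
    evalSeq <- .seqEvaluator(X, spec, weights)
    best <- evalSeq(s)
    N <- length(s)
    bio <- eventBiomarker(spec)
    repeat {
        improved <- FALSE
        for (e in sample(N)) {
            base <- s[s != e]
            # within a biomarker, lower event ids are earlier waypoints, so
            # e may only be inserted between its waypoint neighbours
            sib <- which(bio[base] == bio[e])
            earlier <- sib[base[sib] < e]
            later <- sib[base[sib] > e]
            lo <- if (length(earlier)) max(earlier) + 1L else 1L
            hi <- if (length(later)) min(later) else N
            cand <- -Inf
            candSeq <- NULL
            for (p in lo:hi) {
                trial <- append(base, e, after = p - 1L)
                ll <- evalSeq(trial)
                if (ll > cand + 1e-12) { cand <- ll; candSeq <- trial }
            }
            if (cand > best + 1e-9) {
                best <- cand
                s <- candSeq
                improved <- TRUE
            }
        }
        if (!improved) break
        maxSweeps <- maxSweeps - 1L
        if (maxSweeps <= 0L) break
    }
    list(sequence = s, logLik = best)
}

.greedyFit <- function(X, spec, nRestarts, weights = NULL) {
    if (is.null(weights)) weights <- rep(1, nrow(X))
    best <- NULL
    for (r in seq_len(nRestarts)) {
        fit <- .greedyFromStart(X, spec, .randomSequence(spec), weights)
        if (is.null(best) || fit$logLik > best$logLik) best <- fit
    }
    best
}

#' Fit a single-subtype event sequence by greedy search with restarts
#'
#' From each random initial permutation, every event is greedily relocated
#' to its likelihood-maximizing position (respecting within-biomarker
#' waypoint order) until no move improves; the best sequence over restarts
#' is returned. On small event grids this attains the exhaustive maximum
#' over all orderings.
#'
#' @param X numeric matrix, subjects x biomarkers (w-score scale).
#' @param spec a \linkS4class{TrajectorySpec}.
#' @param nRestarts number of random restarts (default 25).
#' @param seed RNG seed.
#' @return a single-subtype \linkS4class{SubtypeModel}.
#' @export
fitSingleSubtype <- function(X, spec, nRestarts = 25L, seed = 1L) {
    X <- as.matrix(X)
    if (nrow(X) < 1L) stop("at least one subject is required")
    if (nRestarts < 1L) stop("nRestarts must be >= 1")
    set.seed(seed)
    fit <- .greedyFit(X, spec, nRestarts)
    subtypeModel(spec, list(fit$sequence), 1, logLik = fit$logLik)
}

# responsibilities (n x C) under the current model, via log-space softmax
.responsibilities <- function(X, spec, sequences, fractions) {
    LL <- vapply(sequences, function(s) .subtypeLogLik(X, s, spec),
                 numeric(nrow(X)))
    LL <- matrix(LL, nrow = nrow(X))
    L <- sweep(LL, 2L, log(fractions), "+")
    tot <- .logSumExpRows(L)
    list(resp = exp(L - tot), logLik = sum(tot))
}

# alternating refinement: responsibility-weighted greedy sequence refits and
# fraction updates f_s propto sum_j P(s | x_j)
.emRefine <- function(X, spec, sequences, fractions, maxIter = 30L,
                      tol = 1e-4) {
    r <- .responsibilities(X, spec, sequences, fractions)
    for (it in seq_len(maxIter)) {
        fractions <- pmax(colMeans(r$resp), 1e-8)
        fractions <- fractions / sum(fractions)
        for (s in seq_along(sequences))
            sequences[[s]] <- .greedyFromStart(X, spec, sequences[[s]],
                                               r$resp[, s])$sequence
        rNew <- .responsibilities(X, spec, sequences, fractions)
        if (rNew$logLik - r$logLik < tol) { r <- rNew; break }
        r <- rNew
    }
    list(sequences = sequences, fractions = fractions, logLik = r$logLik)
}

#' Fit a C-subtype piecewise-linear SuStaIn model
#'
#' For C = 1 this reduces exactly to \code{\link{fitSingleSubtype}}. For
#' C > 1 the model is grown hierarchically: each subtype of the (C-1)-model
#' is tentatively split by refitting two sequences on its MAP-assigned
#' subjects, all C sequences and the mixture fractions are then jointly
#' refined by alternating responsibility-weighted sequence refits and
#' fraction updates, and the best-likelihood split is kept.
#'
#' @param X numeric matrix, subjects x biomarkers.
#' @param spec a \linkS4class{TrajectorySpec}.
#' @param C number of subtypes.
#' @param nRestarts greedy restarts per sequence fit (default 25).
#' @param seed RNG seed.
#' @param nSplits random split attempts per subtype when growing the model.
#' @return a \linkS4class{SubtypeModel}.
#' @export
fitSubtypes <- function(X, spec, C, nRestarts = 25L, seed = 1L,
                        nSplits = max(3L, nRestarts %/% 5L)) {
    X <- as.matrix(X)
    if (C < 1L) stop("C must be >= 1")
    if (C > nrow(X)) stop("C must not exceed the number of subjects")
    if (C == 1L) return(fitSingleSubtype(X, spec, nRestarts, seed))
    parent <- fitSubtypes(X, spec, C - 1L, nRestarts, seed, nSplits)
    r <- .responsibilities(X, spec, parent@sequences, parent@fractions)
    map <- max.col(r$resp, ties.method = "first")
    best <- NULL
    set.seed(.subSeed(seed, 977L * C))
    for (cSplit in seq_len(C - 1L)) {
        idx <- which(map == cSplit)
        if (length(idx) < 4L) next
        Xc <- X[idx, , drop = FALSE]
        for (attempt in seq_len(nSplits)) {
            # split initialisation: a 2-subtype EM on the subset started
            # from a random pair of sequences; dispersed random starts
            # break the symmetry that makes both halves of a random
            # bisection converge to the same average ordering
            sub <- .emRefine(Xc, spec,
                             list(.randomSequence(spec),
                                  .randomSequence(spec)), c(0.5, 0.5))
            seqs <- parent@sequences
            seqs[[cSplit]] <- sub$sequences[[1]]
            seqs[[C]] <- sub$sequences[[2]]
            fit <- .emRefine(X, spec, seqs, rep(1 / C, C))
            if (is.null(best) || fit$logLik > best$logLik) best <- fit
        }
    }
    if (is.null(best)) stop("no subtype had enough subjects to split")
    subtypeModel(spec, best$sequences, best$fractions, logLik = best$logLik)
}
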