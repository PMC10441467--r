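# Cross-validated selection of the number of subtypes via the
# cross-validation information criterion CVIC = -2 * sum of out-of-sample
# log-likelihoods.

#' Select the number of subtypes by 10-fold cross-validation and CVIC
#'
#' Subjects are split into \code{nFolds} seeded folds of near-equal size.
#' For each candidate C and each fold, a C-subtype model is fitted on the
#' training folds (greedy fit only, no MCMC) and evaluated on the held-out
#' fold; CVIC(C) = -2 * sum of test log-likelihoods. Moving to a larger C
#' requires a CVIC decrease greater than \code{deltaCvic} (default 6), the
#' conventional parsimony rule; otherwise the smaller C is kept.
#'
#' @param X numeric matrix, subjects x biomarkers.
#' @param spec a \linkS4class{TrajectorySpec}.
#' @param CMax largest candidate number of subtypes.
#' @param nFolds number of folds (default 10).
#' @param nRestarts greedy restarts inside each fold fit.
#' @param seed RNG seed (controls folds and fits).
#' @param deltaCvic CVIC improvement required to adopt a larger C.
#' @return a \linkS4class{SelectionResult}.
#' @export
crossvalSelect <- function(X, spec, CMax, nFolds = 10L, nRestarts = 10L,
                           seed = 1L, deltaCvic = 6) {
    X <- as.matrix(X)
    n <- nrow(X)
    if (CMax < 1L) stop("CMax must be >= 1")
    if (nFolds < 2L) stop("nFolds must be >= 2")
    if (n < nFolds) stop("more folds than subjects")
    set.seed(.subSeed(seed, 11L))
    folds <- sample(rep_len(seq_len(nFolds), n))
    testLL <- matrix(NA_real_, CMax, nFolds,
                     dimnames = list(paste0("C", seq_len(CMax)),
                                     paste0("fold", seq_len(nFolds))))
    for (C in seq_len(CMax)) {
        for (f in seq_len(nFolds)) {
            train <- X[folds != f, , drop = FALSE]
            test <- X[folds == f, , drop = FALSE]
            fit <- fitSubtypes(train, spec, C, nRestarts = nRestarts,
                               seed = .subSeed(seed, 31L * C + f))
            testLL[C, f] <- modelLogLik(test, fit)
        }
    }
    cvicVals <- -2 * rowSums(testLL)
    chosen <- 1L
    for (C in seq_len(CMax)[-1])
        if (cvicVals[chosen] - cvicVals[C] > deltaCvic) chosen <- C
    new("SelectionResult", testLogLik = testLL, cvic = unname(cvicVals),
        chosenC = chosen, folds = as.integer(folds),
        seed = as.integer(seed))
}

#' @rdname SelectionResult-class
#' @aliases cvic,SelectionResult-method
#' @export
setMethod("cvic", "SelectionResult", function(object)
    setNames(object@cvic, rownames(object@testLogLik)))

#' @rdname SelectionResult-class
#' @aliases chosenSubtypes,SelectionResult-method
#' @export
setMethod("chosenSubtypes", "SelectionResult",
          function(object) object@chosenC)

setMethod("show", "SelectionResult", function(object) {
    cat("SelectionResult: chosen C =", object@chosenC, "\n")
    print(round(cvic(object), 2))
})
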