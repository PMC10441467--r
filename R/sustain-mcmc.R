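# Metropolis-Hastings sampling over event-sequence permutations and mixture
# fractions, and the positional-variance summary of the sequence posterior.

#' Metropolis-Hastings sampling of sequence and fraction uncertainty
#'
#' Each iteration proposes, for one uniformly chosen subtype, relocating one
#' uniformly chosen event to a uniformly chosen new position (proposals that
#' break within-biomarker waypoint order are rejected), together with a
#' Gaussian perturbation of the mixture fractions re-normalized onto the
#' simplex (SD \code{fractionSd}); the proposal is accepted with probability
#' min(1, L'/L). Every iteration's state is retained; sample 1 is the
#' initial model.
#'
#' @param X numeric matrix, subjects x biomarkers.
#' @param model a fitted \linkS4class{SubtypeModel} (the chain start).
#' @param nIter number of iterations (default 100000, as used for
#'   uncertainty estimation at full scale).
#' @param seed RNG seed.
#' @param fractionSd SD of the Gaussian fraction proposal (default 0.01).
#' @return an \linkS4class{MCMCChain}.
#' @export
runMCMC <- function(X, model, nIter = 100000L, seed = 1L,
                    fractionSd = 0.01) {
    X <- as.matrix(X)
    spec <- model@spec
    C <- nSubtypes(model)
    N <- nEvents(spec)
    if (nIter < 0L) stop("nIter must be >= 0")
    set.seed(seed)

    seqs <- model@sequences
    fracs <- model@fractions
    perSub <- vapply(seqs, function(s) .subtypeLogLik(X, s, spec),
                     numeric(nrow(X)))
    perSub <- matrix(perSub, nrow = nrow(X))
    curLL <- sum(.logSumExpRows(sweep(perSub, 2L, log(fracs), "+")))

    seqSamples <- array(NA_integer_, c(nIter + 1L, C, N))
    fracSamples <- matrix(NA_real_, nIter + 1L, C)
    llTrace <- numeric(nIter + 1L)
    accepted <- rep(NA, nIter + 1L)
    store <- function(i) {
        for (s in seq_len(C)) seqSamples[i, s, ] <<- seqs[[s]]
        fracSamples[i, ] <<- fracs
        llTrace[i] <<- curLL
    }
    store(1L)

    for (it in seq_len(nIter)) {
        cSel <- sample.int(C, 1L)
        e <- sample.int(N, 1L)
        p <- sample.int(N, 1L)
        trial <- append(seqs[[cSel]][seqs[[cSel]] != e], e, after = p - 1L)
        fTrial <- fracs
        if (C > 1L) {
            fTrial <- fracs + rnorm(C, 0, fractionSd)
        }
        ok <- .validSequence(trial, spec) && all(fTrial > 0)
        if (ok) {
            fTrial <- fTrial / sum(fTrial)
            llSub <- .subtypeLogLik(X, trial, spec)
            trialPerSub <- perSub
            trialPerSub[, cSel] <- llSub
            newLL <- sum(.logSumExpRows(
                sweep(trialPerSub, 2L, log(fTrial), "+")))
            if (log(runif(1)) < newLL - curLL) {
                seqs[[cSel]] <- trial
                fracs <- fTrial
                perSub <- trialPerSub
                curLL <- newLL
                accepted[it + 1L] <- TRUE
            } else accepted[it + 1L] <- FALSE
        } else accepted[it + 1L] <- FALSE
        store(it + 1L)
    }

    new("MCMCChain", spec = spec, seqSamples = seqSamples,
        fracSamples = fracSamples, logLik = llTrace, accepted = accepted,
        seed = as.integer(seed))
}

#' @rdname MCMCChain-class
#' @param object,x an \linkS4class{MCMCChain}.
#' @export
setMethod("nSubtypes", "MCMCChain",
          function(object) dim(object@seqSamples)[2])

#' @rdname MCMCChain-class
#' @export
setMethod("nStages", "MCMCChain", function(x) dim(x@seqSamples)[3])

setMethod("show", "MCMCChain", function(object) {
    ns <- dim(object@seqSamples)[1]
    cat("MCMCChain:", ns, "samples,", nSubtypes(object), "subtype(s)\n")
    acc <- mean(object@accepted, na.rm = TRUE)
    if (!is.nan(acc)) cat("  acceptance rate:", sprintf("%.3f", acc), "\n")
})

# indices of post-burn-in samples, optionally thinned to at most maxSamples
.retainedIdx <- function(chain, burninFrac = 0.1, maxSamples = Inf) {
    ns <- dim(chain@seqSamples)[1]
    from <- min(ns, floor(burninFrac * ns) + 1L)
    idx <- from:ns
    if (length(idx) > maxSamples)
        idx <- idx[unique(round(seq(1L, length(idx),
                                    length.out = maxSamples)))]
    idx
}

#' Positional variance of a subtype's event sequence
#'
#' Fraction of post-burn-in MCMC samples placing each event at each sequence
#' position — the positional variance diagram that visualizes ordering
#' uncertainty (rows are events and sum to 1).
#'
#' @param chain an \linkS4class{MCMCChain}.
#' @param subtype subtype index.
#' @param burninFrac fraction of initial samples discarded (default 0.1).
#' @return numeric events x positions probability matrix.
#' @export
positionalVariance <- function(chain, subtype = 1L, burninFrac = 0.1) {
    N <- nStages(chain)
    idx <- .retainedIdx(chain, burninFrac)
    P <- matrix(0, N, N)
    for (i in idx) {
        s <- chain@seqSamples[i, subtype, ]
        P[cbind(s, seq_len(N))] <- P[cbind(s, seq_len(N))] + 1
    }
    P <- P / length(idx)
    bio <- eventBiomarker(chain@spec)
    rownames(P) <- paste0(chain@spec@biomarkers[bio], "_w",
                          eventWaypoint(chain@spec))
    colnames(P) <- paste0("stage", seq_len(N))
    P
}
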