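# Per-subject posterior subtype/stage assignment, averaged over post-burn-in
# MCMC samples, with the stage-0 "normal-appearing" rule.

#' Assign subjects to subtypes and stages
#'
#' For each subject the joint posterior over (subtype s, stage k) is
#' proportional to f_s (N+1)^-1 p(x | S_s, k), averaged over post-burn-in
#' MCMC samples (thinned to at most \code{maxSamples}). The subtype
#' posterior marginalizes over stages; the stage posterior is conditioned
#' on the MAP subtype. MAP labels take the maximum posterior (ties toward
#' the lower index), and subjects whose MAP stage is 0 are flagged
#' normal-appearing regardless of their subtype posterior — every subject
#' is exactly one of normal-appearing or one of the atrophy subtypes.
#'
#' @param X numeric matrix, subjects x biomarkers.
#' @param chain an \linkS4class{MCMCChain}.
#' @param ids subject identifiers (defaults to rownames of X).
#' @param burninFrac fraction of initial samples discarded.
#' @param maxSamples cap on averaged samples (evenly thinned).
#' @return an \code{S4Vectors::DataFrame} with per-subject MAP labels,
#'   posterior maxima, the normal-appearing flag, and full posterior
#'   matrices in columns \code{subtypePosterior} and \code{stagePosterior}.
#' @export
assignSubjects <- function(X, chain, ids = NULL, burninFrac = 0.1,
                           maxSamples = 1000L) {
    X <- as.matrix(X)
    spec <- chain@spec
    if (ncol(X) != length(spec@biomarkers))
        stop("X must have one column per model biomarker")
    if (is.null(ids))
        ids <- if (!is.null(rownames(X))) rownames(X)
               else paste0("subject", seq_len(nrow(X)))
    C <- nSubtypes(chain)
    N <- nStages(chain)
    n <- nrow(X)
    idx <- .retainedIdx(chain, burninFrac, maxSamples)

    # fixed per-subject scaling so densities from different samples share a
    # common scale before averaging
    refSeq <- chain@seqSamples[1L, 1L, ]
    offset <- apply(.stageLogLikMatrix(X, refSeq, spec), 1L, max)

    joint <- array(0, c(n, N + 1L, C))
    for (i in idx) {
        f <- chain@fracSamples[i, ]
        for (s in seq_len(C)) {
            L <- .stageLogLikMatrix(X, chain@seqSamples[i, s, ], spec)
            joint[, , s] <- joint[, , s] +
                f[s] / (N + 1) * exp(L - offset)
        }
    }
    joint <- joint / length(idx)

    subPost <- apply(joint, c(1L, 3L), sum)
    subPost <- matrix(subPost, n, C)
    subPost <- subPost / rowSums(subPost)
    mapSubtype <- max.col(subPost, ties.method = "first")
    stagePost <- t(vapply(seq_len(n), function(j) {
        p <- joint[j, , mapSubtype[j]]
        p / sum(p)
    }, numeric(N + 1L)))
    colnames(stagePost) <- paste0("stage", 0:N)
    colnames(subPost) <- paste0("subtype", seq_len(C))
    mapStage <- max.col(stagePost, ties.method = "first") - 1L

    S4Vectors::DataFrame(
        id = ids,
        mapSubtype = mapSubtype,
        mapStage = mapStage,
        normalAppearing = mapStage == 0L,
        subtypeProb = subPost[cbind(seq_len(n), mapSubtype)],
        stageProb = stagePost[cbind(seq_len(n), mapStage + 1L)],
        subtypePosterior = I(subPost),
        stagePosterior = I(stagePost))
}

#' Cross-tabulate subtype assignments by group
#'
#' Counts and percentages of each assignment outcome (normal-appearing or
#' atrophy subtype) within each group (e.g., clinical diagnosis) — the
#' per-diagnosis assignment-proportion table.
#'
#' @param assignments output of \code{\link{assignSubjects}}.
#' @param groups factor-like group label per subject.
#' @return data.frame with columns group, label, count and percent
#'   (percent within group).
#' @export
assignmentProportions <- function(assignments, groups) {
    lab <- ifelse(assignments$normalAppearing, "normal-appearing",
                  paste0("subtype", assignments$mapSubtype))
    tab <- table(group = as.character(groups), label = lab)
    df <- as.data.frame(tab, stringsAsFactors = FALSE)
    tot <- rowSums(tab)
    df$percent <- 100 * df$Freq / tot[df$group]
    names(df)[names(df) == "Freq"] <- "count"
    df
}
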