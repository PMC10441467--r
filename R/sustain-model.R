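#' Construct a piecewise-linear trajectory specification
#'
#' The w-score SuStaIn event grid: every biomarker crosses each of its
#' waypoints once, so the total number of events (= number of non-zero
#' stages) is the number of biomarkers times the number of waypoints —
#' 13 clusters x waypoints {1,2,3} gives 39 stages. The expected trajectory
#' of a biomarker rises linearly from 0 at stage 0 through its waypoints at
#' the stages where its events sit, reaching \code{zMax} at the final stage
#' (with the default \code{zMax} equal to the last waypoint the trajectory
#' is flat after the final event).
#'
#' @param biomarkers character vector of biomarker (cluster) names, or an
#'   integer count.
#' @param waypoints strictly increasing positive numeric w-score waypoints,
#'   shared across biomarkers (default \code{c(1, 2, 3)}).
#' @param zMax trajectory maximum per biomarker (default the last waypoint).
#' @param sigma per-biomarker noise SD; 1 for w-score inputs.
#' @return a \linkS4class{TrajectorySpec}.
#' @examples
#' spec <- trajectorySpec(13)
#' nStages(spec)  # 39
#' @export
trajectorySpec <- function(biomarkers, waypoints = c(1, 2, 3),
                           zMax = max(waypoints), sigma = 1) {
    if (is.numeric(biomarkers) && length(biomarkers) == 1L)
        biomarkers <- paste0("biomarker", seq_len(biomarkers))
    I <- length(biomarkers)
    new("TrajectorySpec", biomarkers = as.character(biomarkers),
        waypoints = rep(list(as.numeric(waypoints)), I),
        zMax = rep(as.numeric(zMax), length.out = I),
        sigma = rep(as.numeric(sigma), length.out = I))
}

#' @describeIn trajectorySpec biomarker index of each event, in canonical
#'   event order (biomarker-major, waypoints ascending).
#' @param spec a \linkS4class{TrajectorySpec}.
#' @export
eventBiomarker <- function(spec) {
    rep(seq_along(spec@biomarkers),
        vapply(spec@waypoints, length, integer(1)))
}

#' @describeIn trajectorySpec waypoint value of each event.
#' @export
eventWaypoint <- function(spec) unlist(spec@waypoints, use.names = FALSE)

#' @rdname TrajectorySpec-class
#' @aliases nEvents nEvents,TrajectorySpec-method
#' @export
setMethod("nEvents", "TrajectorySpec",
          function(x) length(eventBiomarker(x)))

#' @rdname TrajectorySpec-class
#' @aliases nStages,TrajectorySpec-method
#' @export
setMethod("nStages", "TrajectorySpec", function(x) nEvents(x))

setMethod("show", "TrajectorySpec", function(object) {
    cat("TrajectorySpec:", length(object@biomarkers), "biomarkers,",
        nEvents(object), "events/stages\n")
    cat("  waypoints:", paste(object@waypoints[[1]], collapse = ", "),
        " zMax:", object@zMax[1], " sigma:", object@sigma[1], "\n")
})

#' Expected biomarker value along a subtype trajectory
#'
#' Linear interpolation through the control points (0, 0),
#' (k_1, z_1), ..., (k_R, z_R), (N, zMax), where k_r is the sequence
#' position of the biomarker's r-th waypoint event.
#'
#' @param sequence integer event sequence (position -> event id).
#' @param spec a \linkS4class{TrajectorySpec}.
#' @param biomarker biomarker index.
#' @param stage integer stage(s) in 0..N.
#' @return expected w-score value(s) at the given stage(s).
#' @export
expectedValue <- function(sequence, spec, biomarker, stage) {
    N <- nEvents(spec)
    if (any(stage < 0) || any(stage > N))
        stop("stage must lie in 0..", N)
    bio <- eventBiomarker(spec)
    ev <- which(bio == biomarker)
    pos <- sort(match(ev, sequence))
    xs <- c(0, pos)
    ys <- c(0, spec@waypoints[[biomarker]])
    if (max(xs) < N) {
        xs <- c(xs, N)
        ys <- c(ys, spec@zMax[biomarker])
    }
    .interpolate(xs, ys, stage)
}

# piecewise-linear interpolation over distinct increasing breakpoints
.interpolate <- function(xs, ys, at) {
    ii <- findInterval(at, xs)
    ii[ii >= length(xs)] <- length(xs) - 1L
    x0 <- xs[ii]
    y0 <- ys[ii]
    y0 + (ys[ii + 1L] - y0) * (at - x0) / (xs[ii + 1L] - x0)
}

# (N+1) x I matrix of expected values at stages 0..N (hot path)
.seqMeans <- function(sequence, spec) {
    N <- length(sequence)
    I <- length(spec@biomarkers)
    M <- matrix(0, N + 1L, I)
    pos <- match(seq_len(N), sequence)        # event -> position
    stages <- 0:N
    e <- 0L
    for (i in seq_len(I)) {
        R <- length(spec@waypoints[[i]])
        xs <- c(0, sort.int(pos[e + seq_len(R)]))
        ys <- c(0, spec@waypoints[[i]])
        if (xs[R + 1L] < N) {
            xs <- c(xs, N)
            ys <- c(ys, spec@zMax[i])
        }
        M[, i] <- .interpolate(xs, ys, stages)
        e <- e + R
    }
    M
}

# n x (N+1) matrix of per-stage Gaussian log-densities for data X (n x I)
.stageLogLikMatrix <- function(X, sequence, spec) {
    M <- .seqMeans(sequence, spec)
    sig <- spec@sigma
    if (any(sig != 1)) {
        X <- sweep(X, 2L, sig, "/")
        M <- sweep(M, 2L, sig, "/")
    }
    const <- -sum(log(sig)) - ncol(X) / 2 * log(2 * pi)
    cross <- tcrossprod(X, M)                         # n x (N+1)
    -0.5 * (outer(rowSums(X^2), rowSums(M^2), "+") - 2 * cross) + const
}

#' Likelihood of a biomarker vector at a given stage
#'
#' Product of independent Gaussian densities of each biomarker around its
#' expected trajectory value at the stage.
#'
#' @param x numeric biomarker vector (one subject).
#' @param sequence integer event sequence.
#' @param spec a \linkS4class{TrajectorySpec}.
#' @param stage integer stage in 0..N.
#' @return the density (not log).
#' @export
stageLikelihood <- function(x, sequence, spec, stage) {
    if (any(!is.finite(x))) stop("biomarker values must be finite")
    if (length(x) != length(spec@biomarkers))
        stop("x must have one value per biomarker")
    exp(.stageLogLikMatrix(matrix(x, 1L), sequence, spec)[1L, stage + 1L])
}

# per-subject log marginal likelihood under one sequence (uniform stage prior)
.subtypeLogLik <- function(X, sequence, spec) {
    .logMeanExpRows(.stageLogLikMatrix(X, sequence, spec))
}

#' Log-likelihood of data under a subtype mixture model
#'
#' Each subject's likelihood is a mixture over subtypes (mixture fractions
#' f) and, within subtype, a uniform prior over the discrete stages 0..N:
#' sum over subjects of log sum_s f_s (N+1)^-1 sum_k p(x | S_s, k).
#'
#' @param X numeric matrix, subjects x biomarkers.
#' @param model a \linkS4class{SubtypeModel}.
#' @return numeric scalar log-likelihood.
#' @export
modelLogLik <- function(X, model) {
    X <- as.matrix(X)
    if (nrow(X) < 1L) stop("X must contain at least one subject")
    if (ncol(X) != length(model@spec@biomarkers))
        stop("X columns must match the model's biomarkers")
    LL <- vapply(model@sequences,
                 function(s) .subtypeLogLik(X, s, model@spec),
                 numeric(nrow(X)))
    LL <- matrix(LL, nrow = nrow(X))
    sum(.logSumExpRows(sweep(LL, 2L, log(model@fractions), "+")))
}

#' Construct a subtype model from sequences and fractions
#'
#' @param spec a \linkS4class{TrajectorySpec}.
#' @param sequences list of integer event sequences.
#' @param fractions mixture fractions (default uniform).
#' @param logLik optional training log-likelihood.
#' @return a \linkS4class{SubtypeModel}.
#' @export
subtypeModel <- function(spec, sequences,
                         fractions = rep(1 / length(sequences),
                                         length(sequences)),
                         logLik = NA_real_) {
    new("SubtypeModel", spec = spec,
        sequences = lapply(sequences, as.integer),
        fractions = as.numeric(fractions), logLik = as.numeric(logLik))
}

#' @rdname SubtypeModel-class
#' @aliases eventSequences,SubtypeModel-method
#' @export
setMethod("eventSequences", "SubtypeModel", function(object) object@sequences)

#' @rdname SubtypeModel-class
#' @aliases mixtureFractions,SubtypeModel-method
#' @export
setMethod("mixtureFractions", "SubtypeModel",
          function(object) object@fractions)

#' @rdname SubtypeModel-class
#' @aliases nSubtypes,SubtypeModel-method
#' @export
setMethod("nSubtypes", "SubtypeModel",
          function(object) length(object@sequences))

#' @rdname SubtypeModel-class
#' @aliases nStages,SubtypeModel-method
#' @export
setMethod("nStages", "SubtypeModel", function(x) nStages(x@spec))

setMethod("show", "SubtypeModel", function(object) {
    cat("SubtypeModel:", nSubtypes(object), "subtype(s),",
        nStages(object), "stages\n")
    cat("  fractions:",
        paste(sprintf("%.3f", object@fractions), collapse = ", "), "\n")
    if (is.finite(object@logLik))
        cat("  log-likelihood:", format(object@logLik), "\n")
})

#' Enumerate all valid event sequences
#'
#' All orderings of the event set that respect increasing within-biomarker
#' waypoint order. Feasible only for small event grids; used as the
#' exhaustive oracle against the greedy fitter and the MCMC posterior.
#'
#' @param spec a \linkS4class{TrajectorySpec}.
#' @param maxSequences guard against combinatorial explosion.
#' @return list of integer sequences.
#' @export
enumerateSequences <- function(spec, maxSequences = 50000L) {
    bio <- eventBiomarker(spec)
    N <- length(bio)
    res <- list()
    recur <- function(prefix, remaining) {
        if (!length(remaining)) {
            res[[length(res) + 1L]] <<- prefix
            if (length(res) > maxSequences)
                stop("too many sequences to enumerate")
            return(invisible())
        }
        # an event is placeable when it is its biomarker's next waypoint
        for (e in remaining) {
            earlier <- remaining[bio[remaining] == bio[e]]
            if (e == min(earlier))
                recur(c(prefix, e), setdiff(remaining, e))
        }
    }
    recur(integer(0), seq_len(N))
    res
}
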