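#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames
#'   colData
#' @importFrom S4Vectors DataFrame
#' @importFrom stats approx coef cor cor.test cutree dist dnorm fisher.test
#'   hclust kmeans lm lm.fit model.matrix p.adjust pf pnorm quantile rbinom
#'   rlnorm rnorm runif sd setNames shapiro.test t.test chisq.test var
#'   wilcox.test as.dist
#' @importFrom utils read.csv write.csv head
NULL

#' Cohort container for regional brain volumes
#'
#' A \linkS4class{SummarizedExperiment} holding one assay named
#' \code{"volume"} (regions in rows, subject-visits in columns) whose
#' \code{colData} carries the normalization covariates \code{age} (years),
#' \code{sex} (0/1 indicator) and \code{icv} (intracranial volume, mm^3),
#' plus a subject \code{id}.
#'
#' @slot .Data inherited SummarizedExperiment representation.
#' @export
setClass("CohortExperiment", contains = "SummarizedExperiment")

setValidity("CohortExperiment", function(object) {
    msg <- character(0)
    if (!"volume" %in% SummarizedExperiment::assayNames(object))
        msg <- c(msg, "assay 'volume' is required")
    need <- c("id", "age", "sex", "icv")
    miss <- setdiff(need, colnames(SummarizedExperiment::colData(object)))
    if (length(miss))
        msg <- c(msg, paste0("colData lacks column(s): ",
                             paste(miss, collapse = ", ")))
    if (length(msg)) msg else TRUE
})

#' Control-referenced w-score model
#'
#' Per-region ordinary-least-squares fits of raw volume on covariates in a
#' healthy-control cohort, plus per-region residual standard deviations.
#' Applying the model converts volumes to sign-flipped w-scores
#' (positive = atrophy).
#'
#' @slot coefficients numeric matrix, one column per region, rows are the
#'   intercept and covariate coefficients.
#' @slot residualSd positive numeric, one residual SD per region
#'   (denominator n - p).
#' @slot regions character region identifiers.
#' @slot covariates character names of the colData covariates used.
#' @slot nControls integer number of control subjects used in the fit.
#' @export
setClass("WScoreModel",
    representation(coefficients = "matrix", residualSd = "numeric",
                   regions = "character", covariates = "character",
                   nControls = "integer"))

setValidity("WScoreModel", function(object) {
    msg <- character(0)
    if (ncol(object@coefficients) != length(object@regions))
        msg <- c(msg, "one coefficient vector per region required")
    if (length(object@residualSd) != length(object@regions))
        msg <- c(msg, "one residual SD per region required")
    if (any(!is.finite(object@residualSd)) || any(object@residualSd <= 0))
        msg <- c(msg, "residual SD must be positive and finite")
    if (length(msg)) msg else TRUE
})

#' Bootstrap co-clustering stability matrix
#'
#' Region-by-region matrix of co-clustering probabilities across bootstrap
#' resamples of subjects (BASC).
#'
#' @slot stability symmetric numeric matrix in [0, 1] with unit diagonal.
#' @slot B integer number of bootstrap resamples.
#' @slot k integer number of k-means clusters used inside each bootstrap.
#' @export
setClass("StabilityMatrix",
    representation(stability = "matrix", B = "integer", k = "integer"))

setValidity("StabilityMatrix", function(object) {
    S <- object@stability
    msg <- character(0)
    if (nrow(S) != ncol(S)) msg <- c(msg, "stability matrix must be square")
    else {
        if (max(abs(S - t(S))) > 1e-12) msg <- c(msg, "must be symmetric")
        if (max(abs(diag(S) - 1)) > 1e-12) msg <- c(msg, "diagonal must be 1")
        if (min(S) < -1e-12 || max(S) > 1 + 1e-12)
            msg <- c(msg, "entries must lie in [0, 1]")
    }
    if (object@B < 1L) msg <- c(msg, "B must be >= 1")
    if (length(msg)) msg else TRUE
})

#' Consensus clustering solution
#'
#' Consensus partition of regions derived from a stability matrix, with the
#' silhouette curve over the candidate numbers of clusters.
#'
#' @slot labels integer cluster label per region (named by region).
#' @slot k integer chosen number of clusters.
#' @slot silhouette named numeric, mean silhouette width per candidate k.
#' @slot stability the \linkS4class{StabilityMatrix} behind the chosen k.
#' @export
setClass("ClusterSolution",
    representation(labels = "integer", k = "integer",
                   silhouette = "numeric", stability = "StabilityMatrix"))

setValidity("ClusterSolution", function(object) {
    msg <- character(0)
    if (!all(object@labels %in% seq_len(object@k)))
        msg <- c(msg, "labels must lie in 1..k")
    if (length(unique(object@labels)) != object@k)
        msg <- c(msg, "every cluster in 1..k must be populated")
    if (length(msg)) msg else TRUE
})

#' Piecewise-linear trajectory specification
#'
#' Defines the biomarker event grid of the w-score SuStaIn model: each
#' biomarker crosses its waypoints (default w = 1, 2, 3) in order, and its
#' expected trajectory interpolates linearly between the stages at which the
#' waypoints are reached, plateauing at \code{zMax} (default 3, equal to the
#' final waypoint).
#'
#' @slot biomarkers character biomarker (cluster) names.
#' @slot waypoints list of strictly increasing positive numeric vectors,
#'   one per biomarker.
#' @slot zMax numeric per-biomarker trajectory maximum.
#' @slot sigma positive numeric per-biomarker noise SD (1 for w-scores).
#' @export
setClass("TrajectorySpec",
    representation(biomarkers = "character", waypoints = "list",
                   zMax = "numeric", sigma = "numeric"))

setValidity("TrajectorySpec", function(object) {
    msg <- character(0)
    I <- length(object@biomarkers)
    if (length(object@waypoints) != I || length(object@zMax) != I ||
        length(object@sigma) != I)
        msg <- c(msg, "waypoints, zMax and sigma must match biomarkers")
    ok <- vapply(object@waypoints, function(z)
        length(z) >= 1 && all(z > 0) && all(diff(z) > 0), logical(1))
    if (!all(ok))
        msg <- c(msg, "waypoints must be strictly increasing and positive")
    last <- vapply(object@waypoints, function(z) z[length(z)], numeric(1))
    if (any(object@zMax < last - 1e-12))
        msg <- c(msg, "zMax must be >= the final waypoint")
    if (any(object@sigma <= 0)) msg <- c(msg, "sigma must be positive")
    if (length(msg)) msg else TRUE
})

#' Subtype mixture of event sequences
#'
#' A fitted piecewise-linear SuStaIn model: C event sequences over the shared
#' (biomarker, waypoint) event set, with mixture fractions.
#'
#' @slot spec the \linkS4class{TrajectorySpec}.
#' @slot sequences list of C integer vectors; element p of a sequence is the
#'   event index occupying sequence position p.
#' @slot fractions positive numeric mixture fractions summing to one.
#' @slot logLik numeric model log-likelihood on the training data.
#' @export
setClass("SubtypeModel",
    representation(spec = "TrajectorySpec", sequences = "list",
                   fractions = "numeric", logLik = "numeric"))

setValidity("SubtypeModel", function(object) {
    msg <- character(0)
    N <- nEvents(object@spec)
    if (length(object@sequences) != length(object@fractions))
        msg <- c(msg, "one fraction per sequence required")
    if (abs(sum(object@fractions) - 1) > 1e-8 || any(object@fractions <= 0))
        msg <- c(msg, "fractions must be positive and sum to 1")
    for (s in object@sequences) {
        if (!identical(sort(s), seq_len(N))) {
            msg <- c(msg, "each sequence must contain every event exactly once")
            break
        }
        if (!.validSequence(s, object@spec)) {
            msg <- c(msg, "within-biomarker waypoints must appear in increasing order")
            break
        }
    }
    if (length(msg)) msg else TRUE
})

#' MCMC samples over event sequences and mixture fractions
#'
#' Metropolis-Hastings chain over sequence permutations (single-event
#' relocation proposals) and mixture fractions (Gaussian simplex proposals),
#' used for model uncertainty, positional variance diagrams and per-subject
#' posterior assignment.
#'
#' @slot spec the \linkS4class{TrajectorySpec}.
#' @slot seqSamples integer array (samples x subtypes x events); sample 1 is
#'   the initial model.
#' @slot fracSamples numeric matrix (samples x subtypes).
#' @slot logLik numeric log-likelihood trace, one value per sample.
#' @slot accepted logical acceptance indicator per iteration (sample 1 is NA).
#' @slot seed integer RNG seed used.
#' @export
setClass("MCMCChain",
    representation(spec = "TrajectorySpec", seqSamples = "array",
                   fracSamples = "matrix", logLik = "numeric",
                   accepted = "logical", seed = "integer"))

setValidity("MCMCChain", function(object) {
    msg <- character(0)
    ns <- dim(object@seqSamples)[1]
    if (length(object@logLik) != ns)
        msg <- c(msg, "log-likelihood trace must match retained samples")
    if (any(!is.finite(object@logLik)))
        msg <- c(msg, "log-likelihood must be finite for all samples")
    if (nrow(object@fracSamples) != ns)
        msg <- c(msg, "fraction samples must match retained samples")
    if (length(msg)) msg else TRUE
})

#' Cross-validated subtype-number selection result
#'
#' Per-fold out-of-sample log-likelihoods for each candidate number of
#' subtypes, the cross-validation information criterion
#' CVIC(C) = -2 * sum of test log-likelihoods, and the chosen C.
#'
#' @slot testLogLik numeric matrix (candidate C x folds) of held-out
#'   log-likelihoods.
#' @slot cvic numeric CVIC per candidate C.
#' @slot chosenC integer selected number of subtypes.
#' @slot folds integer fold assignment per subject.
#' @slot seed integer RNG seed.
#' @export
setClass("SelectionResult",
    representation(testLogLik = "matrix", cvic = "numeric",
                   chosenC = "integer", folds = "integer", seed = "integer"))

setValidity("SelectionResult", function(object) {
    msg <- character(0)
    if (length(object@cvic) != nrow(object@testLogLik))
        msg <- c(msg, "one CVIC per candidate C required")
    if (any(!is.finite(object@cvic))) msg <- c(msg, "CVIC must be finite")
    tab <- tabulate(object@folds)
    if (max(tab) - min(tab) > 1L)
        msg <- c(msg, "fold sizes must differ by at most 1")
    if (length(msg)) msg else TRUE
})

#' Synthetic cohort configuration
#'
#' Parameters of the synthetic ALS-FTD-spectrum cohort generator. Defaults
#' define the reference recovery cohort: 200 controls, 300 patients, 24
#' regions collapsing into 6 true clusters, 2 latent subtypes with fractions
#' (0.6, 0.4), waypoints {1, 2, 3}, unit w-score noise, a 30% stage-0
#' (normal-appearing) mass with a uniform prior over the remaining stages,
#' and log-normal follow-up intervals with median 17.5 months.
#'
#' @slot nControls,nPatients,nRegions,nTrueClusters,nSubtypes integer counts.
#' @slot trueFractions numeric subtype mixture, sums to 1.
#' @slot waypoints numeric increasing w-score waypoints (shared).
#' @slot stage0Mass numeric probability mass at stage 0.
#' @slot stageDistribution numeric optional explicit categorical over
#'   0..N; empty means stage0Mass + uniform.
#' @slot noiseSd numeric w-score-scale noise SD around trajectories
#'   (marginal, per region).
#' @slot clusterNoiseCor numeric in [0, 1): correlation of the severity
#'   noise between regions of the same true cluster (anatomical
#'   covariation; regions in different clusters stay independent).
#' @slot covariateEffects named numeric mean effects of age, sex, icv on
#'   raw volume (mm^3 per unit covariate).
#' @slot regionNoiseSd numeric control residual SD as a fraction of the
#'   region's baseline volume.
#' @slot followupFraction numeric probability a patient has a follow-up.
#' @slot followupMedianMonths,followupSdlog numeric log-normal interval
#'   parameters (median months, log-scale SD).
#' @slot stageDriftPerYear numeric non-negative latent stage drift.
#' @slot clinicalEffects list of clinical-label effect sizes (see
#'   \code{\link{generateClinicalLabels}}).
#' @slot seed integer master seed; every generator is a pure function of
#'   (config, seed).
#' @export
setClass("SimConfig",
    representation(nControls = "integer", nPatients = "integer",
                   nRegions = "integer", nTrueClusters = "integer",
                   nSubtypes = "integer", trueFractions = "numeric",
                   waypoints = "numeric", stage0Mass = "numeric",
                   stageDistribution = "numeric", noiseSd = "numeric",
                   clusterNoiseCor = "numeric",
                   covariateEffects = "numeric", regionNoiseSd = "numeric",
                   followupFraction = "numeric",
                   followupMedianMonths = "numeric", followupSdlog = "numeric",
                   stageDriftPerYear = "numeric", clinicalEffects = "list",
                   seed = "integer"))

setValidity("SimConfig", function(object) {
    msg <- character(0)
    if (object@nControls < 1L || object@nPatients < 1L ||
        object@nRegions < 1L || object@nTrueClusters < 1L ||
        object@nSubtypes < 1L)
        msg <- c(msg, "all counts must be positive")
    if (object@nTrueClusters > object@nRegions)
        msg <- c(msg, "nTrueClusters must not exceed nRegions")
    if (length(object@trueFractions) != object@nSubtypes ||
        abs(sum(object@trueFractions) - 1) > 1e-8 ||
        any(object@trueFractions <= 0))
        msg <- c(msg, "trueFractions must be positive and sum to 1")
    if (length(object@stageDistribution)) {
        N <- object@nTrueClusters * length(object@waypoints)
        if (length(object@stageDistribution) != N + 1L)
            msg <- c(msg, "stageDistribution must have length N+1")
        if (abs(sum(object@stageDistribution) - 1) > 1e-8)
            msg <- c(msg, "stageDistribution must sum to 1")
    }
    if (object@stage0Mass < 0 || object@stage0Mass >= 1)
        msg <- c(msg, "stage0Mass must lie in [0, 1)")
    if (object@noiseSd < 0) msg <- c(msg, "noiseSd must be non-negative")
    if (object@clusterNoiseCor < 0 || object@clusterNoiseCor >= 1)
        msg <- c(msg, "clusterNoiseCor must lie in [0, 1)")
    if (object@followupFraction < 0 || object@followupFraction > 1)
        msg <- c(msg, "followupFraction must lie in [0, 1]")
    if (object@followupMedianMonths <= 0)
        msg <- c(msg, "followupMedianMonths must be positive")
    if (object@stageDriftPerYear < 0)
        msg <- c(msg, "stageDriftPerYear must be non-negative")
    if (length(msg)) msg else TRUE
})

#' Ground truth of a synthetic cohort
#'
#' Latent quantities behind a generated patient cohort, kept for recovery
#' testing: per-patient subtype and stage, per-region true cluster, and the
#' true per-subtype event sequences.
#'
#' @slot subtype integer latent subtype per patient.
#' @slot stage integer latent stage per patient (0..N).
#' @slot clusterLabels integer true cluster per region.
#' @slot sequences list of true event sequences (one per subtype).
#' @slot spec the \linkS4class{TrajectorySpec} of the generator.
#' @export
setClass("CohortTruth",
    representation(subtype = "integer", stage = "integer",
                   clusterLabels = "integer", sequences = "list",
                   spec = "TrajectorySpec"))

setValidity("CohortTruth", function(object) {
    msg <- character(0)
    N <- nEvents(object@spec)
    if (any(object@stage < 0L) || any(object@stage > N))
        msg <- c(msg, "stages must lie in 0..N")
    for (s in object@sequences)
        if (!identical(sort(s), seq_len(N))) {
            msg <- c(msg, "each sequence must contain every event exactly once")
            break
        }
    if (length(msg)) msg else TRUE
})
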