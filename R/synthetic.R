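# Synthetic ALS-FTD-spectrum cohort generator with full ground truth.
# Atrophy is injected in raw-volume space so that the downstream w-score
# normalization is genuinely exercised, and every generator is a pure
# function of (config, seed).

#' Synthetic cohort configuration
#'
#' See \linkS4class{SimConfig} for the meaning and defaults of every
#' parameter; the defaults define the reference recovery cohort
#' (200 controls, 300 patients, 24 regions in 6 true clusters, 2 subtypes
#' with fractions 0.6/0.4, waypoints {1,2,3}, unit w-score noise, 30%
#' stage-0 mass).
#'
#' @param nControls,nPatients,nRegions,nTrueClusters,nSubtypes counts.
#' @param trueFractions subtype mixture fractions.
#' @param waypoints increasing w-score waypoints.
#' @param stage0Mass probability of latent stage 0 (normal-appearing).
#' @param stageDistribution optional explicit stage prior over 0..N.
#' @param noiseSd marginal w-score-scale trajectory noise SD per region.
#' @param clusterNoiseCor within-cluster correlation of the severity noise;
#'   regions of the same anatomical cluster share a common per-subject
#'   noise component (this correlated covariation is what makes the
#'   clusters stable, as in real regional volumes), while the marginal
#'   per-region noise SD stays \code{noiseSd}.
#' @param covariateEffects named mean effects (age, sex, icv) on raw volume.
#' @param regionNoiseSd control residual SD as a fraction of base volume.
#' @param followupFraction probability of a follow-up visit.
#' @param followupMedianMonths,followupSdlog log-normal interval parameters.
#' @param stageDriftPerYear latent stage drift per year at follow-up.
#' @param clinicalEffects list of clinical effect sizes; see
#'   \code{\link{generateClinicalLabels}}.
#' @param seed master RNG seed.
#' @return a validated \linkS4class{SimConfig}.
#' @export
simConfig <- function(nControls = 200L, nPatients = 300L, nRegions = 24L,
                      nTrueClusters = 6L, nSubtypes = 2L,
                      trueFractions = NULL, waypoints = c(1, 2, 3),
                      stage0Mass = 0.3, stageDistribution = numeric(0),
                      noiseSd = 1, clusterNoiseCor = 0.7,
                      covariateEffects = c(age = -15, sex = 400,
                                           icv = 0.003),
                      regionNoiseSd = 0.05, followupFraction = 0.2,
                      followupMedianMonths = 17.5, followupSdlog = 0.5,
                      stageDriftPerYear = 2, clinicalEffects = list(),
                      seed = 1L) {
    if (is.null(trueFractions))
        trueFractions <- if (nSubtypes == 2L) c(0.6, 0.4)
                         else rep(1 / nSubtypes, nSubtypes)
    defaults <- list(mmseBase = 29, mmseSlope = 0.35, mmseSd = 1,
                     alsfrsBase = 46, alsfrsSlope = 1.2, alsfrsSd = 2,
                     durationBase = 8, durationSlope = 1.5, durationSd = 4,
                     genotypeRates = NULL)
    clinicalEffects <- utils::modifyList(defaults, clinicalEffects)
    new("SimConfig", nControls = as.integer(nControls),
        nPatients = as.integer(nPatients), nRegions = as.integer(nRegions),
        nTrueClusters = as.integer(nTrueClusters),
        nSubtypes = as.integer(nSubtypes),
        trueFractions = as.numeric(trueFractions),
        waypoints = as.numeric(waypoints), stage0Mass = stage0Mass,
        stageDistribution = as.numeric(stageDistribution),
        noiseSd = noiseSd, clusterNoiseCor = clusterNoiseCor,
        covariateEffects = covariateEffects,
        regionNoiseSd = regionNoiseSd, followupFraction = followupFraction,
        followupMedianMonths = followupMedianMonths,
        followupSdlog = followupSdlog,
        stageDriftPerYear = stageDriftPerYear,
        clinicalEffects = clinicalEffects, seed = as.integer(seed))
}

#' @describeIn simConfig the trajectory specification implied by a config
#'   (one biomarker per true cluster).
#' @param config a \linkS4class{SimConfig}.
#' @export
simTrajectorySpec <- function(config)
    trajectorySpec(paste0("cluster", seq_len(config@nTrueClusters)),
                   waypoints = config@waypoints)

# per-region true generative model, deterministic in config@seed:
# baseline volume, covariate coefficients (jitter proportional to the mean
# effect so zero effects stay exactly zero), raw residual SD, true cluster
.regionModel <- function(config) {
    set.seed(.subSeed(config@seed, 104729L))
    R <- config@nRegions
    eff <- config@covariateEffects
    base <- runif(R, 4000, 16000)
    data.frame(
        region = paste0("region", seq_len(R)),
        beta0 = base,
        betaAge = rnorm(R, eff[["age"]], abs(eff[["age"]]) * 0.2),
        betaSex = rnorm(R, eff[["sex"]], abs(eff[["sex"]]) * 0.2),
        betaIcv = rnorm(R, eff[["icv"]], abs(eff[["icv"]]) * 0.2),
        sdRaw = base * config@regionNoiseSd,
        cluster = sort(rep_len(seq_len(config@nTrueClusters), R)))
}

.drawCovariates <- function(n, prefix) {
    data.frame(id = paste0(prefix, seq_len(n)),
               age = rnorm(n, 60, 10),
               sex = rbinom(n, 1L, 0.5),
               icv = rnorm(n, 1.4e6, 1.2e5))
}

.predictVolumes <- function(rm, info) {
    # regions x subjects expected volume from the true covariate model
    t(cbind(1, info$age, info$sex, info$icv) %*%
          t(as.matrix(rm[, c("beta0", "betaAge", "betaSex", "betaIcv")])))
}

#' Generate a healthy-control cohort
#'
#' Raw regional volumes v = b0 + b_age age + b_sex sex + b_icv ICV + e,
#' e ~ Normal(0, s_region), with age ~ N(60, 10) years, sex ~ Bernoulli(0.5)
#' and ICV ~ N(1.4e6, 1.2e5) mm^3.
#'
#' @param config a \linkS4class{SimConfig}.
#' @return a \linkS4class{CohortExperiment}.
#' @export
generateControls <- function(config) {
    stopifnot(is(config, "SimConfig"))
    validObject(config)
    if (config@nControls < 8L)
        stop("nControls must be at least twice the number of covariates")
    set.seed(.subSeed(config@seed, 1L))
    rm <- .regionModel(config)
    info <- .drawCovariates(config@nControls, "ctrl")
    vol <- .predictVolumes(rm, info) +
        matrix(rnorm(config@nRegions * config@nControls, 0, rm$sdRaw),
               config@nRegions, config@nControls)
    rownames(vol) <- rm$region
    cohortExperiment(vol, info)
}

#' Planted per-subtype event sequences
#'
#' Deterministic well-separated orderings with a staggered progression:
#' each subtype ranks the biomarkers by a priority permutation (identity
#' for subtype 1, reversed for subtype 2, seeded shuffles beyond) and
#' high-priority biomarkers run through their waypoints early while
#' low-priority ones start later — mirroring observed atrophy cascades in
#' which the subtype's seed regions reach severe w-scores while other
#' regions are still normal. Event order is by the key
#' priority + (waypoint index - 1) * stagger.
#'
#' @param spec a \linkS4class{TrajectorySpec}.
#' @param C number of subtypes.
#' @param seed RNG seed (used only for subtypes beyond the second).
#' @param stagger spacing between successive waypoints of one biomarker,
#'   in priority units (default half the number of biomarkers).
#' @return list of C integer event sequences.
#' @export
plantedSequences <- function(spec, C, seed = 1L,
                             stagger = length(spec@biomarkers) / 3) {
    bio <- eventBiomarker(spec)
    I <- length(spec@biomarkers)
    wpIdx <- unlist(lapply(spec@waypoints, seq_along), use.names = FALSE)
    set.seed(.subSeed(seed, 2L))
    perms <- lapply(seq_len(C), function(cc) {
        if (cc == 1L) seq_len(I)
        else if (cc == 2L) rev(seq_len(I))
        else sample(I)
    })
    lapply(perms, function(perm) {
        priority <- match(bio, perm)
        order(priority + (wpIdx - 1L) * stagger, priority, wpIdx)
    })
}

# severity noise (regions x n): within-cluster shared component plus an
# independent component; marginal SD = noiseSd, within-cluster correlation
# = clusterNoiseCor
.severityNoise <- function(config, clusters, n) {
    sdShared <- config@noiseSd * sqrt(config@clusterNoiseCor)
    sdIndep <- config@noiseSd * sqrt(1 - config@clusterNoiseCor)
    K <- max(clusters)
    shared <- matrix(rnorm(K * n, 0, sdShared), K, n)
    shared[clusters, , drop = FALSE] +
        matrix(rnorm(length(clusters) * n, 0, sdIndep),
               length(clusters), n)
}

.stagePrior <- function(config) {
    N <- config@nTrueClusters * length(config@waypoints)
    if (length(config@stageDistribution)) return(config@stageDistribution)
    c(config@stage0Mass, rep((1 - config@stage0Mass) / N, N))
}

#' Generate a patient cohort with latent subtypes and stages
#'
#' Each patient draws a latent subtype from \code{trueFractions} and a
#' latent stage from the stage prior (30% stage-0 mass by default). The
#' atrophy severity of region r is the expected trajectory value of its
#' cluster's biomarker at that stage plus Normal(0, noiseSd) w-scale noise,
#' and the raw volume is the control-model prediction minus severity times
#' the region's control residual SD — so downstream sign-flipped w-scores
#' recover the planted severities.
#'
#' @param config a \linkS4class{SimConfig}.
#' @param sequences optional list of per-subtype event sequences (defaults
#'   to \code{\link{plantedSequences}}).
#' @return list with elements \code{cohort} (a
#'   \linkS4class{CohortExperiment}) and \code{truth} (a
#'   \linkS4class{CohortTruth}).
#' @export
generatePatients <- function(config, sequences = NULL) {
    stopifnot(is(config, "SimConfig"))
    validObject(config)
    spec <- simTrajectorySpec(config)
    if (is.null(sequences))
        sequences <- plantedSequences(spec, config@nSubtypes, config@seed)
    if (length(sequences) != config@nSubtypes)
        stop("one sequence per subtype required")
    N <- nEvents(spec)
    ref <- sort(sequences[[1]])
    for (s in sequences)
        if (!identical(sort(s), ref))
            stop("sequences must cover identical event sets")
    set.seed(.subSeed(config@seed, 3L))
    rm <- .regionModel(config)
    n <- config@nPatients
    info <- .drawCovariates(n, "pat")
    subtype <- sample.int(config@nSubtypes, n, replace = TRUE,
                          prob = config@trueFractions)
    stage <- sample(0:N, n, replace = TRUE, prob = .stagePrior(config))
    meansBySub <- lapply(sequences, .seqMeans, spec = spec)
    sev <- vapply(seq_len(n), function(j)
        meansBySub[[subtype[j]]][stage[j] + 1L, rm$cluster],
        numeric(config@nRegions))               # regions x patients
    sev <- sev + .severityNoise(config, rm$cluster, n)
    vol <- .predictVolumes(rm, info) - sev * rm$sdRaw
    rownames(vol) <- rm$region
    truth <- new("CohortTruth", subtype = as.integer(subtype),
                 stage = as.integer(stage),
                 clusterLabels = as.integer(rm$cluster),
                 sequences = sequences, spec = spec)
    list(cohort = cohortExperiment(vol, info), truth = truth)
}

#' Generate follow-up visits with forward stage drift
#'
#' A seeded subset of patients (probability \code{followupFraction}) gets a
#' follow-up visit after a log-normal interval; the latent stage advances by
#' round(stageDriftPerYear x interval in years), capped at N, and volumes
#' are regenerated at the new stage (age advanced by the interval; the same
#' latent subtype).
#'
#' @param baseline the baseline patient \linkS4class{CohortExperiment}.
#' @param truth the matching \linkS4class{CohortTruth}.
#' @param config the \linkS4class{SimConfig} used at baseline.
#' @return list with \code{cohort} (follow-up visits; colData carries
#'   \code{intervalMonths}) and \code{truth} (their advanced latent states).
#' @export
generateLongitudinal <- function(baseline, truth, config) {
    stopifnot(is(config, "SimConfig"))
    validObject(config)
    set.seed(.subSeed(config@seed, 4L))
    rm <- .regionModel(config)
    info <- subjectInfo(baseline)
    n <- nrow(info)
    take <- which(runif(n) < config@followupFraction)
    if (!length(take)) stop("no follow-up visits drawn; raise followupFraction")
    interval <- rlnorm(length(take), log(config@followupMedianMonths),
                       config@followupSdlog)
    if (any(interval <= 0)) stop("follow-up intervals must be positive")
    N <- nEvents(truth@spec)
    newStage <- pmin(N, truth@stage[take] +
                         as.integer(round(config@stageDriftPerYear *
                                              interval / 12)))
    fuInfo <- info[take, , drop = FALSE]
    fuInfo$age <- fuInfo$age + interval / 12
    fuInfo$intervalMonths <- interval
    meansBySub <- lapply(truth@sequences, .seqMeans, spec = truth@spec)
    sev <- vapply(seq_along(take), function(j)
        meansBySub[[truth@subtype[take[j]]]][newStage[j] + 1L, rm$cluster],
        numeric(config@nRegions))
    sev <- sev + .severityNoise(config, rm$cluster, length(take))
    vol <- .predictVolumes(rm, fuInfo) - sev * rm$sdRaw
    rownames(vol) <- rm$region
    fuTruth <- new("CohortTruth", subtype = truth@subtype[take],
                   stage = as.integer(newStage),
                   clusterLabels = truth@clusterLabels,
                   sequences = truth@sequences, spec = truth@spec)
    list(cohort = cohortExperiment(vol, fuInfo), truth = fuTruth)
}

#' Generate clinical, genotype and onset labels from the latent truth
#'
#' Emits diagnosis, genotype, onset site, MMSE, ALSFRS-R and disease
#' duration with configurable subtype- and stage-dependent effects whose
#' defaults follow the qualitative directions seen in ALS-FTD cohorts:
#' stage-0 patients are mostly ALS with lower-motor-neuron onset, cognition
#' (MMSE) declines with stage, C9orf72/GRN variants are enriched in subtype
#' 1 and TBK1/TARDBP in subtype 2.
#'
#' @param truth a \linkS4class{CohortTruth}.
#' @param config the generating \linkS4class{SimConfig}; effect sizes come
#'   from \code{config@clinicalEffects} (\code{mmseBase}, \code{mmseSlope},
#'   \code{mmseSd}, \code{alsfrsBase}, \code{alsfrsSlope}, \code{alsfrsSd},
#'   \code{durationBase}, \code{durationSlope}, \code{durationSd},
#'   \code{genotypeRates} — a carrier-probability matrix genes x subtypes).
#' @return data.frame with one row per patient.
#' @export
generateClinicalLabels <- function(truth, config) {
    stopifnot(is(config, "SimConfig"))
    set.seed(.subSeed(config@seed, 5L))
    ce <- config@clinicalEffects
    n <- length(truth@subtype)
    stage <- truth@stage
    subtype <- truth@subtype
    diagP <- function(s, k) {
        if (k == 0L) c(ALS = 0.85, `ALS-FTD` = 0.08, bvFTD = 0.07)
        else if (s == 1L) c(ALS = 0.40, `ALS-FTD` = 0.22, bvFTD = 0.38)
        else c(ALS = 0.28, `ALS-FTD` = 0.32, bvFTD = 0.40)
    }
    diagnosis <- vapply(seq_len(n), function(j) {
        p <- diagP(subtype[j], stage[j])
        sample(names(p), 1L, prob = p)
    }, character(1))
    onsetP <- function(k) {
        if (k == 0L) c(LMN = 0.6, UMN = 0.25, cognitive = 0.15)
        else c(LMN = 0.35, UMN = 0.3, cognitive = 0.35)
    }
    onset <- vapply(stage, function(k)
        sample(names(onsetP(k)), 1L, prob = onsetP(k)), character(1))
    mmse <- pmin(30, pmax(0, round(ce$mmseBase - ce$mmseSlope * stage +
                                       rnorm(n, 0, ce$mmseSd))))
    alsfrs <- pmin(48, pmax(0, round(ce$alsfrsBase - ce$alsfrsSlope * stage +
                                         rnorm(n, 0, ce$alsfrsSd))))
    duration <- pmax(1, ce$durationBase + ce$durationSlope * stage +
                         rnorm(n, 0, ce$durationSd))
    rates <- ce$genotypeRates
    if (is.null(rates))
        rates <- rbind(C9orf72 = c(0.15, 0.05), GRN = c(0.10, 0.01),
                       TBK1 = c(0.01, 0.08), TARDBP = c(0.01, 0.08))
    geno <- rep("none", n)
    for (g in rownames(rates)) {
        pr <- rates[g, pmin(subtype, ncol(rates))]
        hit <- geno == "none" & runif(n) < pr
        geno[hit] <- g
    }
    data.frame(id = paste0("pat", seq_len(n)), diagnosis = diagnosis,
               onsetSite = onset, genotype = geno, mmse = mmse,
               alsfrsR = alsfrs, durationMonths = duration)
}
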