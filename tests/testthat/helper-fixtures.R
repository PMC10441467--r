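# Shared fixtures, built once per test run and memoized across test files.

.fixtureCache <- new.env(parent = emptyenv())

memoFixture <- function(name, builder) {
    if (!exists(name, envir = .fixtureCache))
        assign(name, builder(), envir = .fixtureCache)
    get(name, envir = .fixtureCache)
}

# translate true event sequences into the biomarker indexing of a fitted
# cluster solution (consensus cluster c <-> true cluster map[c])
remapTrueSequences <- function(truth, solution, spec) {
    tab <- table(clusterLabels(solution), truth@clusterLabels)
    map <- apply(tab, 1L, which.max)
    inv <- match(seq_along(map), map)
    bio <- eventBiomarker(spec)
    wp <- eventWaypoint(spec)
    lapply(truth@sequences, function(s)
        vapply(s, function(e) which(bio == inv[bio[e]] & wp == wp[e]),
               integer(1)))
}

# reference recovery cohort: generator defaults (24 regions in 6 true
# clusters, 30% stage-0 mass, drift 2/yr), taken through the full pipeline
defaultCohortFixture <- function() memoFixture("defaultCohort", function() {
    cfg <- simConfig(seed = 7L)
    ctrl <- generateControls(cfg)
    pat <- generatePatients(cfg)
    wm <- fitWScoreModel(ctrl)
    w <- applyWScore(wm, pat$cohort)
    sol <- selectClusterNumber(w, kRange = 2:10, B = 100L, seed = 3L)
    b <- reduceFeatures(w, sol)
    spec <- simTrajectorySpec(cfg)
    fit <- fitSubtypes(b, spec, C = 2L, nRestarts = 8L, seed = 5L)
    chain <- runMCMC(b, fit, nIter = 15000L, seed = 6L)
    asg <- assignSubjects(b, chain)
    list(cfg = cfg, ctrl = ctrl, pat = pat, truth = pat$truth, wm = wm,
         w = w, sol = sol, b = b, spec = spec,
         trueSeqs = remapTrueSequences(pat$truth, sol, spec),
         fit = fit, chain = chain, asg = asg)
})

# follow-up visits for the default cohort at a given stage drift, assigned
# with the baseline model
defaultLongitudinalFixture <- function(drift) {
    name <- paste0("defaultLong", drift)
    fx <- defaultCohortFixture()
    memoFixture(name, function() {
        cfg <- fx$cfg
        cfg@stageDriftPerYear <- drift
        fu <- generateLongitudinal(fx$pat$cohort, fx$truth, cfg)
        bFu <- reduceFeatures(applyWScore(fx$wm, fu$cohort), fx$sol)
        aFu <- assignSubjects(bFu, fx$chain,
                              ids = subjectInfo(fu$cohort)$id)
        longitudinalRecords(fx$asg, aFu,
                            subjectInfo(fu$cohort)$intervalMonths)
    })
}

# model-matched subtype-recovery cohort: biomarker-level regions (singleton
# clusters), unit noise, uniform stage prior — the conditions under which
# the piecewise-linear model is correctly specified
recoveryCohortFixture <- function() memoFixture("recoveryCohort", function() {
    N <- 18L
    cfg <- simConfig(nRegions = 6L, nTrueClusters = 6L, nPatients = 300L,
                     stageDistribution = rep(1 / (N + 1), N + 1),
                     seed = 11L)
    ctrl <- generateControls(cfg)
    pat <- generatePatients(cfg)
    wm <- fitWScoreModel(ctrl)
    w <- applyWScore(wm, pat$cohort)
    spec <- simTrajectorySpec(cfg)
    colnames(w) <- spec@biomarkers
    fit <- fitSubtypes(w, spec, C = 2L, nRestarts = 8L, seed = 5L)
    chain <- runMCMC(w, fit, nIter = 15000L, seed = 6L)
    asg <- assignSubjects(w, chain)
    list(cfg = cfg, ctrl = ctrl, pat = pat, truth = pat$truth, wm = wm,
         w = w, spec = spec, fit = fit, chain = chain, asg = asg)
})

recoverySelectionFixture <- function() memoFixture("recoverySel", function() {
    fx <- recoveryCohortFixture()
    crossvalSelect(fx$w, fx$spec, CMax = 3L, nFolds = 3L, nRestarts = 5L,
                   seed = 9L)
})

# follow-up table of the published cohort: 62 visits — 55 keep their
# baseline label, 2 progress normal -> subtype 1, 2 progress normal ->
# subtype 2, 3 switch atrophy subtype; among the 59 stable, 6 retrogress
# to an earlier stage
publishedFollowupRecords <- function() {
    mk <- function(n, blSub, blNorm, blStage, fuSub, fuNorm, fuStage)
        data.frame(blSub = rep(blSub, n), blNorm = blNorm,
                   blStage = blStage, fuSub = fuSub, fuNorm = fuNorm,
                   fuStage = fuStage)
    rec <- rbind(
        mk(10, 1L, TRUE, 0L, 1L, TRUE, 0L),     # stay normal-appearing
        mk(25, 1L, FALSE, 10L, 1L, FALSE, 12L), # same subtype, advance
        mk(14, 2L, FALSE, 8L, 2L, FALSE, 8L),   # same subtype, same stage
        mk(4, 1L, FALSE, 9L, 1L, FALSE, 7L),    # same subtype, retrogress
        mk(2, 2L, FALSE, 11L, 2L, FALSE, 9L),   # same subtype, retrogress
        mk(2, 1L, TRUE, 0L, 1L, FALSE, 3L),     # normal -> subtype 1
        mk(2, 1L, TRUE, 0L, 2L, FALSE, 2L),     # normal -> subtype 2
        mk(3, 1L, FALSE, 6L, 2L, FALSE, 8L))    # subtype switch: unstable
    baseline <- data.frame(id = paste0("p", seq_len(nrow(rec))),
                           mapSubtype = rec$blSub, mapStage = rec$blStage,
                           normalAppearing = rec$blNorm)
    followup <- data.frame(id = baseline$id, mapSubtype = rec$fuSub,
                           mapStage = rec$fuStage,
                           normalAppearing = rec$fuNorm)
    longitudinalRecords(baseline, followup, rep(17.5, nrow(rec)))
}

# coefficient-recovery z-scores of the control OLS against the generating
# model, across all regions
coefRecoveryZ <- function(cfg) {
    ctrl <- generateControls(cfg)
    rm <- wSuStaIn:::.regionModel(cfg)
    info <- subjectInfo(ctrl)
    unlist(lapply(seq_len(cfg@nRegions), function(r) {
        f <- lm(regionVolumes(ctrl)[r, ] ~ age + sex + icv, data = info)
        (coef(f) - unlist(rm[r, c("beta0", "betaAge", "betaSex",
                                  "betaIcv")])) / sqrt(diag(vcov(f)))
    }))
}

# small biomarker matrix laid out along a known sequence (no w-scoring)
biomarkerDataAlong <- function(sequence, spec, stages, noiseSd = 0,
                               seed = NULL) {
    if (!is.null(seed)) set.seed(seed)
    I <- length(spec@biomarkers)
    X <- t(vapply(stages, function(k)
        vapply(seq_len(I), function(i)
            expectedValue(sequence, spec, i, k), numeric(1)),
        numeric(I)))
    if (noiseSd > 0) X <- X + matrix(rnorm(length(X), 0, noiseSd),
                                     nrow(X), ncol(X))
    colnames(X) <- spec@biomarkers
    X
}
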