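# Synthetic cohort generator: determinism, generative contracts, and
# recovery of the planted statistical structure.

test_that("generators are pure functions of (config, seed)", {
    cfg <- simConfig(nControls = 30L, nPatients = 40L, seed = 42L)
    c1 <- generateControls(cfg)
    c2 <- generateControls(cfg)
    expect_identical(regionVolumes(c1), regionVolumes(c2))
    expect_identical(subjectInfo(c1), subjectInfo(c2))
    p1 <- generatePatients(cfg)
    p2 <- generatePatients(cfg)
    expect_identical(regionVolumes(p1$cohort), regionVolumes(p2$cohort))
    expect_identical(p1$truth@stage, p2$truth@stage)
    cfg2 <- simConfig(nControls = 30L, nPatients = 40L, seed = 43L)
    expect_false(identical(regionVolumes(generateControls(cfg2)),
                           regionVolumes(c1)))
})

test_that("zero noise and zero covariate effects give constant volumes", {
    cfg <- simConfig(nControls = 25L, regionNoiseSd = 0,
                     covariateEffects = c(age = 0, sex = 0, icv = 0),
                     seed = 1L)
    vol <- regionVolumes(generateControls(cfg))
    expect_true(all(apply(vol, 1L, function(v) max(v) - min(v)) == 0))
})

test_that("OLS on generated controls recovers the true coefficients", {
    cfg <- simConfig(nControls = 500L, seed = 9L)
    z <- coefRecoveryZ(cfg)
    # calibrated recovery: ~95% of coefficient errors within 2 SE
    expect_gte(mean(abs(z) < 2), 0.9)
    expect_lt(max(abs(z)), 5)
})

test_that("stage-0 noiseless patients sit exactly on control predictions", {
    N <- 6L * 3L
    cfg <- simConfig(nPatients = 20L, noiseSd = 0,
                     stageDistribution = c(1, rep(0, N)), seed = 2L)
    pat <- generatePatients(cfg)
    rm <- wSuStaIn:::.regionModel(cfg)
    pred <- wSuStaIn:::.predictVolumes(rm, subjectInfo(pat$cohort))
    expect_true(all(pat$truth@stage == 0L))
    expect_equal(unname(regionVolumes(pat$cohort)), unname(pred))
})

test_that("final-stage noiseless patients reach severity z_max everywhere", {
    N <- 6L * 3L
    cfg <- simConfig(nPatients = 15L, noiseSd = 0,
                     stageDistribution = c(rep(0, N), 1), seed = 3L)
    pat <- generatePatients(cfg)
    rm <- wSuStaIn:::.regionModel(cfg)
    pred <- wSuStaIn:::.predictVolumes(rm, subjectInfo(pat$cohort))
    sev <- (pred - regionVolumes(pat$cohort)) / rm$sdRaw
    expect_equal(unname(sev), matrix(3, nrow(sev), ncol(sev)))
})

test_that("subtype draws match the planted mixture fractions", {
    cfg <- simConfig(nPatients = 300L, trueFractions = c(0.6, 0.4),
                     seed = 4L)
    truth <- generatePatients(cfg)$truth
    phat <- mean(truth@subtype == 1L)
    expect_true(abs(phat - 0.6) < 1.96 * sqrt(0.6 * 0.4 / 300))
})

test_that("sequences with mismatched event sets are rejected", {
    cfg <- simConfig(seed = 1L)
    spec <- simTrajectorySpec(cfg)
    good <- plantedSequences(spec, 2L)
    bad <- good
    bad[[2]] <- bad[[2]][-1]
    expect_error(generatePatients(cfg, bad), "identical event sets")
})

test_that("follow-up stages advance by round(drift x years), capped at N", {
    cfg <- simConfig(nPatients = 60L, followupFraction = 1,
                     followupMedianMonths = 18, followupSdlog = 0,
                     stageDriftPerYear = 2, seed = 5L)
    pat <- generatePatients(cfg)
    fu <- generateLongitudinal(pat$cohort, pat$truth, cfg)
    N <- nEvents(pat$truth@spec)
    expect_equal(fu$truth@stage,
                 pmin(N, pat$truth@stage + 3L))   # round(2 * 18/12) = 3
    cfg0 <- cfg
    cfg0@stageDriftPerYear <- 0
    fu0 <- generateLongitudinal(pat$cohort, pat$truth, cfg0)
    expect_identical(fu0$truth@stage, pat$truth@stage)
})

test_that("follow-up count is binomial in followupFraction", {
    cfg <- simConfig(nPatients = 300L, followupFraction = 0.2, seed = 6L)
    pat <- generatePatients(cfg)
    fu <- generateLongitudinal(pat$cohort, pat$truth, cfg)
    n <- ncol(fu$cohort)
    expect_true(abs(n - 60) < 1.96 * sqrt(300 * 0.2 * 0.8) + 1)
    expect_true(all(subjectInfo(fu$cohort)$intervalMonths > 0))
})

test_that("clinical labels carry the configured stage and subtype effects", {
    cfg <- simConfig(nPatients = 400L, seed = 8L)
    truth <- generatePatients(cfg)$truth
    clin <- generateClinicalLabels(truth, cfg)
    # cognition declines with stage
    expect_lt(cor(truth@stage, clin$mmse), -0.5)
    # no slope, no correlation
    cfgFlat <- simConfig(nPatients = 400L, seed = 8L,
                         clinicalEffects = list(mmseSlope = 0))
    clinFlat <- generateClinicalLabels(truth, cfgFlat)
    expect_lt(abs(cor(truth@stage, clinFlat$mmse)), 3 / sqrt(400))
})

test_that("genotype enrichment odds ratio is recovered", {
    cfg <- simConfig(nPatients = 3000L, seed = 10L)
    truth <- generatePatients(cfg)$truth
    clin <- generateClinicalLabels(truth, cfg)
    tab <- table(clin$genotype == "C9orf72", truth@subtype)
    orHat <- (tab[2, 1] / tab[1, 1]) / (tab[2, 2] / tab[1, 2])
    # planted carrier rates 0.15 (subtype 1) vs 0.05 (subtype 2)
    orTrue <- (0.15 / 0.85) / (0.05 / 0.95)
    seLog <- sqrt(sum(1 / tab))
    expect_true(abs(log(orHat) - log(orTrue)) < 3 * seLog)
})

test_that("invalid configurations are rejected", {
    expect_error(simConfig(nPatients = 0L), "positive")
    expect_error(simConfig(trueFractions = c(0.7, 0.7)), "sum to 1")
    expect_error(simConfig(nTrueClusters = 30L, nRegions = 24L),
                 "nTrueClusters")
    expect_error(simConfig(followupMedianMonths = -1), "positive")
})
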