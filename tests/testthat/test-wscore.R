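# Control-referenced w-score normalization.

test_that("fitted coefficients recover the generating model", {
    cfg <- simConfig(nControls = 500L, seed = 21L)
    model <- fitWScoreModel(generateControls(cfg))
    expect_true(all(model@residualSd > 0))
    # recovery is calibrated: coefficient errors in SE units are standard
    # normal across regions (roughly 95% within 2 SE, none grossly off)
    z <- coefRecoveryZ(cfg)
    expect_gte(mean(abs(z) < 2), 0.9)
    expect_lt(max(abs(z)), 5)
    expect_lt(abs(mean(z)), 0.25)
})

test_that("w-score definition: 0 at prediction, +1 one residual SD below", {
    cfg <- simConfig(nControls = 50L, nRegions = 5L, nTrueClusters = 5L,
                     seed = 22L)
    model <- fitWScoreModel(generateControls(cfg))
    info <- data.frame(id = "s1", age = 62, sex = 1L, icv = 1.45e6)
    pred <- drop(cbind(1, 62, 1, 1.45e6) %*% model@coefficients)
    atPred <- cohortExperiment(matrix(pred, ncol = 1,
                                      dimnames = list(model@regions, NULL)),
                               info)
    expect_equal(unname(applyWScore(model, atPred)[1, ]), rep(0, 5))
    below <- cohortExperiment(matrix(pred - model@residualSd, ncol = 1,
                                     dimnames = list(model@regions, NULL)),
                              info)
    expect_equal(unname(applyWScore(model, below)[1, ]), rep(1, 5))
})

test_that("lower volume strictly increases w (atrophy orientation)", {
    cfg <- simConfig(nControls = 40L, nRegions = 3L, nTrueClusters = 3L,
                     seed = 23L)
    model <- fitWScoreModel(generateControls(cfg))
    info <- data.frame(id = "s", age = 60, sex = 0L, icv = 1.4e6)
    mk <- function(v) cohortExperiment(
        matrix(v, ncol = 1, dimnames = list(model@regions, NULL)), info)
    w1 <- applyWScore(model, mk(c(5000, 5000, 5000)))
    w2 <- applyWScore(model, mk(c(4900, 5000, 5000)))
    expect_gt(w2[1, 1], w1[1, 1])
    expect_equal(w2[1, 2:3], w1[1, 2:3])
})

test_that("w-scores are invariant to covariate rescaling", {
    cfg <- simConfig(nControls = 60L, seed = 24L)
    ctrl <- generateControls(cfg)
    pat <- generatePatients(cfg)$cohort
    w1 <- applyWScore(fitWScoreModel(ctrl), pat)
    # ICV in cm^3 instead of mm^3, in both cohorts
    rescale <- function(x) {
        cd <- SummarizedExperiment::colData(x)
        cd$icv <- cd$icv / 1000
        SummarizedExperiment::colData(x) <- cd
        x
    }
    w2 <- applyWScore(fitWScoreModel(rescale(ctrl)), rescale(pat))
    expect_equal(w1, w2, tolerance = 1e-8)
})

test_that("rank-deficient designs fail naming the collinear columns", {
    cfg <- simConfig(nControls = 40L, seed = 25L)
    ctrl <- generateControls(cfg)
    cd <- SummarizedExperiment::colData(ctrl)
    cd$age2 <- cd$age * 2
    SummarizedExperiment::colData(ctrl) <- cd
    expect_error(fitWScoreModel(ctrl, covariates = c("age", "sex", "icv",
                                                     "age2")),
                 "age2")
})

test_that("constant covariates and zero-residual regions are errors", {
    cfg <- simConfig(nControls = 40L, seed = 26L)
    ctrl <- generateControls(cfg)
    cd <- SummarizedExperiment::colData(ctrl)
    cd$sex <- 1L
    SummarizedExperiment::colData(ctrl) <- cd
    expect_error(fitWScoreModel(ctrl), "constant covariate.*sex")

    vol <- matrix(c(rep(100, 20), rnorm(20, 5000, 100)), nrow = 2,
                  byrow = TRUE, dimnames = list(c("flat", "ok"), NULL))
    ce <- cohortExperiment(vol, data.frame(id = paste0("c", 1:20),
                                           age = rnorm(20, 60, 5),
                                           sex = rep(0:1, 10),
                                           icv = rnorm(20, 1.4e6, 1e5)))
    expect_error(fitWScoreModel(ce), "zero residual SD.*flat")
})

test_that("held-out controls are calibrated: mean ~0, SD ~1 per region", {
    # a large fitting cohort so the held-out error is dominated by the
    # n = 200 sampling bound rather than by model-estimation error
    cfg <- simConfig(nControls = 2200L, seed = 27L)
    ctrl <- generateControls(cfg)
    model <- fitWScoreModel(ctrl[, 1:2000])
    w <- applyWScore(model, ctrl[, 2001:2200])
    expect_lt(mean(abs(colMeans(w))), 0.15)
    sds <- apply(w, 2L, sd)
    expect_true(all(sds > 0.85 & sds < 1.15))
})

test_that("missing regions or covariates are reported by name", {
    cfg <- simConfig(nControls = 40L, seed = 28L)
    ctrl <- generateControls(cfg)
    model <- fitWScoreModel(ctrl)
    sub <- ctrl[-3, ]
    expect_error(applyWScore(model, sub), "region3")
})
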