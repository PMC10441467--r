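# Piecewise-linear trajectories, stage likelihood and the mixture
# log-likelihood, checked against closed forms and enumeration oracles.

test_that("the event grid multiplies biomarkers by waypoints", {
    expect_equal(nStages(trajectorySpec(13)), 39L)
    expect_equal(nStages(trajectorySpec(6)), 18L)
    expect_equal(nEvents(trajectorySpec(4, waypoints = c(1, 2))), 8L)
})

test_that("trajectory interpolation hits waypoints and plateaus", {
    # one biomarker, waypoints {1,2,3} at positions 1,2,3 (N = 3)
    spec1 <- trajectorySpec(1)
    s <- 1:3
    expect_equal(expectedValue(s, spec1, 1, 0), 0)
    expect_equal(expectedValue(s, spec1, 1, 2), 2)
    expect_equal(expectedValue(s, spec1, 1, 3), 3)
    # three biomarkers, one waypoint each; biomarker 2's event at position 2
    spec3 <- trajectorySpec(3, waypoints = 1)
    s3 <- c(1L, 2L, 3L)
    expect_equal(expectedValue(s3, spec3, 2, 1), 0.5)
    expect_equal(expectedValue(s3, spec3, 2, 2), 1)
    expect_equal(expectedValue(s3, spec3, 2, 3), 1)   # flat after event
    expect_error(expectedValue(s3, spec3, 1, 4), "stage")
})

test_that("trajectories are non-decreasing in stage", {
    set.seed(41)
    for (rep in 1:10) {
        spec <- trajectorySpec(sample(2:5, 1),
                               waypoints = cumsum(runif(sample(1:3, 1),
                                                        0.5, 1.5)))
        s <- wSuStaIn:::.randomSequence(spec)
        for (i in seq_along(spec@biomarkers))
            expect_true(all(diff(expectedValue(s, spec, i,
                                               0:nEvents(spec))) >= 0))
    }
})

test_that("stage likelihood is the product of Gaussian densities", {
    spec <- trajectorySpec(4)
    s <- wSuStaIn:::.randomSequence(spec)
    # on-trajectory point at the Gaussian peak
    x <- vapply(1:4, function(i) expectedValue(s, spec, i, 5), numeric(1))
    expect_equal(stageLikelihood(x, s, spec, 5), (2 * pi)^(-2))
    # independent oracle: plain dnorm sum on a random instance
    set.seed(42)
    x2 <- rnorm(4, 1, 2)
    k <- 7L
    oracle <- exp(sum(dnorm(x2, vapply(1:4, function(i)
        expectedValue(s, spec, i, k), numeric(1)), 1, log = TRUE)))
    expect_equal(stageLikelihood(x2, s, spec, k), oracle,
                 tolerance = 1e-10)
    expect_gt(stageLikelihood(rep(8, 4), s, spec, 0), 0)
    expect_error(stageLikelihood(c(1, NA, 1, 1), s, spec, 0), "finite")
})

test_that("model log-likelihood matches hand enumeration for N = 2", {
    spec <- trajectorySpec(2, waypoints = 1)    # 2 events, N = 2
    s <- c(1L, 2L)
    m <- subtypeModel(spec, list(s), 1)
    x <- c(0, 0)
    # g_i(k): expected values per stage, enumerated by hand
    g <- rbind(c(0, 1, 1), c(0, 0.5, 1))       # biomarker x stage 0..2
    oracle <- log(mean(apply(g, 2L, function(gk)
        prod(dnorm(x, gk, 1)))))
    expect_equal(modelLogLik(matrix(x, 1), m), oracle, tolerance = 1e-12)
})

test_that("log-likelihood is additive and subtype-relabel invariant", {
    spec <- trajectorySpec(3)
    set.seed(43)
    X <- matrix(rnorm(20 * 3, 1), 20, 3)
    s1 <- wSuStaIn:::.randomSequence(spec)
    s2 <- wSuStaIn:::.randomSequence(spec)
    m <- subtypeModel(spec, list(s1, s2), c(0.7, 0.3))
    expect_equal(modelLogLik(rbind(X, X), m), 2 * modelLogLik(X, m))
    mSwap <- subtypeModel(spec, list(s2, s1), c(0.3, 0.7))
    expect_equal(modelLogLik(X, m), modelLogLik(X, mSwap))
    expect_error(modelLogLik(X[0, , drop = FALSE], m), "at least one")
})

test_that("sequence enumeration respects within-biomarker order", {
    spec <- trajectorySpec(3, waypoints = 1)
    expect_length(enumerateSequences(spec), 6L)      # 3!
    spec22 <- trajectorySpec(2, waypoints = c(1, 2))
    seqs <- enumerateSequences(spec22)
    expect_length(seqs, 6L)                          # 4!/(2!2!)
    for (s in seqs) expect_true(wSuStaIn:::.validSequence(s, spec22))
})

test_that("invalid sequences and fractions are rejected by validity", {
    spec <- trajectorySpec(2, waypoints = c(1, 2))
    expect_error(subtypeModel(spec, list(c(2L, 1L, 3L, 4L)), 1),
                 "increasing order")
    good <- c(1L, 2L, 3L, 4L)
    expect_error(subtypeModel(spec, list(good, good), c(0.5, 0.6)),
                 "sum to 1")
})
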