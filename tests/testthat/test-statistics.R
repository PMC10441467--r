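# Group-comparison layer: normality-gated tests, categorical tests with the
# expected-count rule, FDR-corrected regional contrasts, correlations and
# the Progression index.

test_that("normal groups route to the t-test, separation is detected", {
    set.seed(71)
    x <- rnorm(50)
    y <- rnorm(50, 2)
    res <- compareContinuous(x, y)
    expect_equal(res$test, "two-sample t-test")
    expect_lt(res$p.value, 0.001)
    expect_equal(res$direction, "x < y")
})

test_that("identical groups give p ~ 1", {
    set.seed(72)
    x <- rnorm(30)
    res <- compareContinuous(x, x)
    expect_gt(res$p.value, 0.99)
    expect_lt(abs(res$statistic), 1e-10)
})

test_that("heavy-tailed samples route to Mann-Whitney", {
    set.seed(73)
    x <- exp(rnorm(60, 0, 1.5))
    y <- exp(rnorm(60, 0.5, 1.5))
    res <- compareContinuous(x, y)
    expect_equal(res$test, "Mann-Whitney")
})

test_that("constant input falls back to Mann-Whitney with a note", {
    res <- compareContinuous(rep(1, 10), rnorm(10, 5))
    expect_equal(res$test, "Mann-Whitney")
    expect_match(res$note, "Shapiro-Wilk undefined")
    expect_error(compareContinuous(1:2, rnorm(5)), "at least 3")
})

test_that("categorical gate: chi-squared when expected counts allow", {
    res <- compareCategorical(matrix(c(10, 10, 10, 10), 2))
    expect_equal(res$test, "chi-squared")
    expect_equal(res$p.value, 1)
    sparse <- matrix(c(0, 11, 99, 46), 2)
    expect_equal(compareCategorical(sparse)$test, "Fisher exact")
    expect_error(compareCategorical(matrix(0, 2, 2)), "empty")
    expect_error(compareCategorical(matrix(c(1.5, 1, 1, 1), 2)),
                 "integers")
})

test_that("Fisher p equals the exact hypergeometric tail sum", {
    tab <- matrix(c(1, 9, 10, 4), 2)
    res <- compareCategorical(tab)
    expect_equal(res$test, "Fisher exact")
    # brute force: sum hypergeometric probabilities of all tables with the
    # same margins that are no more probable than the observed one
    m <- sum(tab[1, ]); n2 <- sum(tab[2, ]); k <- sum(tab[, 1])
    pObs <- dhyper(tab[1, 1], m, n2, k)
    pAll <- vapply(max(0, k - n2):min(k, m), function(a)
        dhyper(a, m, n2, k), numeric(1))
    expect_equal(res$p.value, sum(pAll[pAll <= pObs + 1e-12]),
                 tolerance = 1e-10)
})

test_that("Benjamini-Hochberg matches the closed form and brute force", {
    expect_equal(p.adjust(c(0.01, 0.02, 0.03, 0.04), "BH"),
                 rep(0.04, 4))
    bruteBH <- function(p) {
        m <- length(p)
        o <- order(p)
        adj <- p[o] * m / seq_len(m)
        adj <- rev(cummin(rev(adj)))
        pmin(1, adj)[order(o)]
    }
    set.seed(74)
    for (rep in 1:10) {
        p <- runif(sample(2:10, 1))
        expect_equal(p.adjust(p, "BH"), bruteBH(p))
    }
})

test_that("planted regional effects are detected and nulls are not", {
    set.seed(75)
    n <- 120L
    groups <- rep(c("a", "b"), each = n / 2)
    w <- matrix(rnorm(n * 12), n, 12)
    w[groups == "b", 1:6] <- w[groups == "b", 1:6] + 1.2
    colnames(w) <- paste0("r", 1:12)
    res <- regionalVolumeContrast(w, groups)
    expect_true(all(res$significant[1:6]))
    expect_true(all(!res$significant[7:12]))
    expect_equal(res$p.adjusted, p.adjust(res$p.value, "BH"))
})

test_that("stage-adjusted contrasts remove a stage-driven difference", {
    set.seed(76)
    n <- 150L
    stage <- sample(0:10, n, replace = TRUE)
    groups <- ifelse(stage > 5, "late", "early")   # groups confounded
    w <- matrix(0.4 * stage + rnorm(n * 6), n, 6)
    colnames(w) <- paste0("r", 1:6)
    raw <- regionalVolumeContrast(w, groups)
    adj <- regionalVolumeContrast(w, groups, stage = stage)
    expect_gt(sum(raw$significant), sum(adj$significant))
})

test_that("singular designs are rejected", {
    w <- matrix(rnorm(30), 10, 3)
    expect_error(regionalVolumeContrast(w, rep("a", 10)), "2 groups")
})

test_that("correlations behave at the limits and under independence", {
    x <- 1:20
    expect_equal(correlateStage(x, x)$statistic, 1)
    expect_equal(correlateStage(x, -x)$statistic, -1)
    set.seed(77)
    res <- correlateStage(rnorm(100), rnorm(100))
    expect_lt(abs(res$statistic), 0.3)
    expect_gt(res$p.value, 0.001)
    expect_error(correlateStage(rep(1, 10), rnorm(10)), "zero-variance")
    expect_equal(correlateStage(x, x + rnorm(20), method = "pearson")$test,
                 "pearson correlation")
})

test_that("the Progression index is (48 - score) / months", {
    expect_equal(progressionIndex(48, 10), 0)
    expect_equal(progressionIndex(36, 12), 1)
    expect_equal(progressionIndex(24, 48), 0.5)
    expect_error(progressionIndex(50, 10), "0..48")
    expect_error(progressionIndex(30, 0), "positive")
})
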