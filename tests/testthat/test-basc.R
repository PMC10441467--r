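# Bootstrap Analysis of Stable Clusters: stability matrices, consensus
# partitions, silhouette-based k selection and feature reduction.

plantedBlockW <- function(nSubjects = 60L, blocks = 4L, perBlock = 4L,
                          sep = 3, noise = 0.5, seed = 31L) {
    set.seed(seed)
    centers <- matrix(rnorm(nSubjects * blocks, 0, sep), nSubjects, blocks)
    w <- centers[, rep(seq_len(blocks), each = perBlock)] +
        matrix(rnorm(nSubjects * blocks * perBlock, 0, noise),
               nSubjects, blocks * perBlock)
    colnames(w) <- paste0("region", seq_len(ncol(w)))
    attr(w, "truth") <- rep(seq_len(blocks), each = perBlock)
    w
}

test_that("identical region profiles always co-cluster", {
    set.seed(32)
    w <- matrix(rnorm(40 * 6), 40, 6)
    w <- cbind(w, w[, 1])   # region 7 duplicates region 1
    colnames(w) <- paste0("r", 1:7)
    S <- stabilityMatrix(bootstrapStability(w, k = 3L, B = 20L, seed = 1L))
    expect_equal(S[1, 7], 1)
    expect_equal(S[7, 1], 1)
})

test_that("stability matrices satisfy their invariants; B=1 is binary", {
    w <- plantedBlockW()
    S1 <- bootstrapStability(w, k = 4L, B = 1L, seed = 2L)
    expect_true(all(stabilityMatrix(S1) %in% c(0, 1)))
    S <- stabilityMatrix(bootstrapStability(w, k = 4L, B = 25L, seed = 2L))
    expect_equal(S, t(S))
    expect_equal(unname(diag(S)), rep(1, ncol(w)))
    expect_true(all(S >= 0 & S <= 1))
})

test_that("planted blocks are more stable within than between", {
    w <- plantedBlockW()
    truth <- attr(w, "truth")
    S <- stabilityMatrix(bootstrapStability(w, k = 4L, B = 100L, seed = 3L))
    same <- outer(truth, truth, "==") & upper.tri(S)
    diff <- outer(truth, truth, "!=") & upper.tri(S)
    expect_gte(mean(S[same]) - mean(S[diff]), 0.5)
})

test_that("consensus partition recovers block-diagonal stability exactly", {
    S <- kronecker(diag(3), matrix(1, 4, 4))
    dimnames(S) <- list(paste0("r", 1:12), paste0("r", 1:12))
    sm <- new("StabilityMatrix", stability = S, B = 10L, k = 3L)
    sol <- consensusPartition(sm, 3L)
    expect_equal(mclust::adjustedRandIndex(clusterLabels(sol),
                                           rep(1:3, each = 4)), 1)
    # k = n_regions gives singletons
    solN <- consensusPartition(sm, 12L)
    expect_equal(sort(unname(clusterLabels(solN))), 1:12)
})

test_that("noisy planted blocks are recovered with high ARI", {
    w <- plantedBlockW(blocks = 6L, perBlock = 4L, seed = 34L)
    S <- bootstrapStability(w, k = 6L, B = 100L, seed = 4L)
    sol <- consensusPartition(S, 6L)
    expect_gte(mclust::adjustedRandIndex(clusterLabels(sol),
                                         attr(w, "truth")), 0.9)
})

test_that("silhouette selects the planted number of clusters", {
    w <- plantedBlockW(blocks = 6L, perBlock = 4L, seed = 35L)
    sol <- selectClusterNumber(w, kRange = 2:10, B = 50L, seed = 5L)
    expect_equal(sol@k, 6L)
    expect_length(silhouetteCurve(sol), 9L)
    expect_named(silhouetteCurve(sol), as.character(2:10))
})

test_that("identical regions make the silhouette degenerate", {
    w <- matrix(1, 30, 8)
    w <- w + rnorm(30)       # same column repeated: zero between-region dist
    colnames(w) <- paste0("r", 1:8)
    expect_error(selectClusterNumber(w, kRange = 2:4, B = 5L, seed = 1L),
                 "identical")
})

test_that("kRange and k are validated", {
    w <- plantedBlockW()
    expect_error(bootstrapStability(w, k = ncol(w), B = 5L, seed = 1L),
                 "smaller")
    expect_error(selectClusterNumber(w, kRange = integer(0)), "empty")
    expect_error(selectClusterNumber(w, kRange = c(2, ncol(w))), "kRange")
})

test_that("feature reduction averages member regions", {
    w <- matrix(c(1, 3, 5,
                  3, 5, 7), nrow = 2, byrow = TRUE)
    colnames(w) <- c("a", "b", "c")
    S <- structure(diag(3), dimnames = list(c("a", "b", "c"),
                                            c("a", "b", "c")))
    sol <- new("ClusterSolution",
               labels = c(a = 1L, b = 1L, c = 2L), k = 2L,
               silhouette = c(`2` = NA_real_),
               stability = new("StabilityMatrix", stability = S,
                               B = 1L, k = 2L))
    red <- reduceFeatures(w, sol)
    expect_equal(dim(red), c(2L, 2L))
    expect_equal(unname(red[, 1]), c(2, 4))     # mean of w = 1,3 and 3,5
    expect_equal(unname(red[, 2]), c(5, 7))     # singleton equals region w
})

test_that("region order does not change the consensus partition", {
    w <- plantedBlockW(blocks = 4L, seed = 36L)
    truth <- attr(w, "truth")
    perm <- sample(ncol(w))
    sol1 <- consensusPartition(
        bootstrapStability(w, 4L, B = 50L, seed = 7L), 4L)
    sol2 <- consensusPartition(
        bootstrapStability(w[, perm], 4L, B = 50L, seed = 7L), 4L)
    expect_equal(mclust::adjustedRandIndex(
        clusterLabels(sol1)[perm], clusterLabels(sol2)), 1)
})
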