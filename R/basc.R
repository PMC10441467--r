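# Bootstrap Analysis of Stable Clusters: co-clustering stability of brain
# regions over bootstrap resamples of subjects, consensus partition by
# average-linkage clustering of 1 - stability, silhouette-based choice of k,
# and cluster-level biomarker extraction.

#' Bootstrap co-clustering stability of regions
#'
#' For each of B bootstraps, subjects are resampled with replacement and
#' k-means is run on the regions (observations = regions, features = the
#' resampled subjects' w-scores); the stability matrix is the frequency
#' with which each pair of regions lands in the same cluster.
#'
#' @param w numeric subjects x regions w-score matrix.
#' @param k number of k-means clusters per bootstrap.
#' @param B number of bootstrap resamples (1000 at full scale).
#' @param seed RNG seed.
#' @param nstart k-means restarts per bootstrap.
#' @return a \linkS4class{StabilityMatrix}.
#' @export
bootstrapStability <- function(w, k, B = 1000L, seed = 1L, nstart = 3L) {
    w <- as.matrix(w)
    R <- ncol(w)
    if (k >= R) stop("k must be smaller than the number of regions")
    if (k < 2L) stop("k must be at least 2")
    if (B < 1L) stop("B must be >= 1")
    set.seed(seed)
    S <- matrix(0, R, R)
    for (b in seq_len(B)) {
        idx <- sample.int(nrow(w), replace = TRUE)
        km <- kmeans(t(w[idx, , drop = FALSE]), centers = k,
                     nstart = nstart, iter.max = 100L)
        co <- outer(km$cluster, km$cluster, "==")
        S <- S + co
    }
    S <- S / B
    dimnames(S) <- list(colnames(w), colnames(w))
    new("StabilityMatrix", stability = S, B = as.integer(B),
        k = as.integer(k))
}

#' @rdname StabilityMatrix-class
#' @aliases stabilityMatrix,StabilityMatrix-method
#' @export
setMethod("stabilityMatrix", "StabilityMatrix",
          function(object) object@stability)

setMethod("show", "StabilityMatrix", function(object) {
    cat("StabilityMatrix:", nrow(object@stability), "regions, B =",
        object@B, ", k =", object@k, "\n")
})

# mean silhouette width of a partition under a distance matrix
.meanSilhouette <- function(labels, d) {
    d <- as.matrix(d)
    if (max(d[upper.tri(d)]) <= 1e-12)
        stop("all regions are identical; silhouette is undefined")
    sil <- cluster::silhouette(labels, dmatrix = d)
    mean(sil[, "sil_width"])
}

#' Consensus partition of the stability matrix
#'
#' Average-linkage hierarchical clustering on distance 1 - stability, cut at
#' k clusters. Labels are renumbered in order of first appearance.
#'
#' @param S a \linkS4class{StabilityMatrix}.
#' @param k number of consensus clusters.
#' @return a \linkS4class{ClusterSolution}.
#' @export
consensusPartition <- function(S, k) {
    M <- stabilityMatrix(S)
    R <- nrow(M)
    if (k < 1L || k > R) stop("k must lie in 1..", R)
    hc <- hclust(as.dist(1 - M), method = "average")
    labels <- cutree(hc, k = k)
    labels <- as.integer(match(labels, unique(labels)))
    names(labels) <- rownames(M)
    sil <- if (k >= 2L && k < R)
        tryCatch(.meanSilhouette(labels, 1 - M), error = function(e) NA_real_)
    else NA_real_
    new("ClusterSolution", labels = labels, k = as.integer(k),
        silhouette = setNames(sil, as.character(k)), stability = S)
}

#' Select the number of stable clusters by silhouette
#'
#' For each candidate k, the bootstrap stability matrix (with k clusters per
#' bootstrap, the BASC convention) and its consensus partition are computed;
#' the k maximizing the mean silhouette width of the consensus partition on
#' the Euclidean region-profile distance is returned, ties broken toward the
#' smaller k. (Silhouette is taken on the data geometry rather than on
#' 1 - stability: stability of the consensus cut is near-perfect for any
#' dominant low-k split, so it cannot rank candidate k.) Each candidate
#' reuses the same bootstrap seed so resamples are shared across k.
#'
#' @param w numeric subjects x regions w-score matrix.
#' @param kRange candidate numbers of clusters (default 2..20).
#' @param B bootstraps per candidate.
#' @param seed RNG seed.
#' @return a \linkS4class{ClusterSolution} for the selected k, carrying the
#'   full silhouette curve.
#' @export
selectClusterNumber <- function(w, kRange = 2:20, B = 1000L, seed = 1L) {
    w <- as.matrix(w)
    kRange <- sort(unique(as.integer(kRange)))
    if (!length(kRange)) stop("kRange must not be empty")
    if (min(kRange) < 2L || max(kRange) > ncol(w) - 1L)
        stop("kRange must lie within 2..(n_regions - 1)")
    sil <- setNames(numeric(length(kRange)), as.character(kRange))
    sols <- vector("list", length(kRange))
    d <- dist(t(w))
    if (max(d) <= 1e-12)
        stop("all regions are identical; silhouette is undefined")
    for (i in seq_along(kRange)) {
        S <- bootstrapStability(w, kRange[i], B = B, seed = seed)
        sols[[i]] <- consensusPartition(S, kRange[i])
        sil[i] <- .meanSilhouette(sols[[i]]@labels, d)
    }
    best <- sols[[which.max(sil)]]       # which.max: first max = smaller k
    initialize(best, silhouette = sil)
}

#' @rdname ClusterSolution-class
#' @aliases clusterLabels,ClusterSolution-method
#' @export
setMethod("clusterLabels", "ClusterSolution", function(object) object@labels)

#' @rdname ClusterSolution-class
#' @aliases silhouetteCurve,ClusterSolution-method
#' @export
setMethod("silhouetteCurve", "ClusterSolution",
          function(object) object@silhouette)

#' @rdname ClusterSolution-class
#' @aliases clusterMembers,ClusterSolution-method
#' @export
setMethod("clusterMembers", "ClusterSolution", function(object)
    split(names(object@labels), object@labels))

#' @rdname ClusterSolution-class
#' @aliases stabilityMatrix,ClusterSolution-method
#' @export
setMethod("stabilityMatrix", "ClusterSolution",
          function(object) stabilityMatrix(object@stability))

setMethod("show", "ClusterSolution", function(object) {
    cat("ClusterSolution: k =", object@k, "clusters over",
        length(object@labels), "regions\n")
    sizes <- table(object@labels)
    cat("  sizes:", paste(sizes, collapse = ", "), "\n")
})

#' Extract cluster-level biomarkers
#'
#' The biomarker value of a cluster is the mean w-score of its member
#' regions, per subject.
#'
#' @param w numeric subjects x regions w-score matrix.
#' @param solution a \linkS4class{ClusterSolution} covering the regions.
#' @return numeric subjects x k biomarker matrix, columns
#'   \code{cluster1..clusterK}.
#' @export
reduceFeatures <- function(w, solution) {
    w <- as.matrix(w)
    labels <- clusterLabels(solution)
    if (!is.null(colnames(w))) {
        miss <- setdiff(colnames(w), names(labels))
        if (length(miss))
            stop("unlabeled region(s): ", paste(miss, collapse = ", "))
        labels <- labels[colnames(w)]
    }
    out <- vapply(seq_len(solution@k), function(cl)
        rowMeans(w[, labels == cl, drop = FALSE]), numeric(nrow(w)))
    out <- matrix(out, nrow = nrow(w))
    dimnames(out) <- list(rownames(w),
                          paste0("cluster", seq_len(solution@k)))
    out
}
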