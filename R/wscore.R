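# Control-referenced w-score normalization: per-region OLS on healthy
# controls, then sign-flipped standardized residuals for patients.

#' Fit the control w-score model
#'
#' Per-region ordinary-least-squares regression of raw volume on the
#' covariates (default age, sex, intracranial volume) in healthy controls.
#' The residual standard deviation uses the unbiased denominator n - p.
#'
#' @param controls a \linkS4class{CohortExperiment} of healthy controls.
#' @param covariates covariate column names in \code{colData}.
#' @return a \linkS4class{WScoreModel}.
#' @export
fitWScoreModel <- function(controls, covariates = c("age", "sex", "icv")) {
    info <- subjectInfo(controls)
    miss <- setdiff(covariates, colnames(info))
    if (length(miss))
        stop("missing covariate column(s): ", paste(miss, collapse = ", "))
    n <- nrow(info)
    if (n < 10L) stop("at least 10 controls are required")
    constant <- covariates[vapply(info[covariates],
                                  function(v) var(as.numeric(v)) == 0,
                                  logical(1))]
    if (length(constant))
        stop("constant covariate column(s): ",
             paste(constant, collapse = ", "))
    design <- cbind(`(Intercept)` = 1,
                    as.matrix(info[, covariates, drop = FALSE]))
    qrD <- qr(design)
    if (qrD$rank < ncol(design)) {
        bad <- colnames(design)[qrD$pivot[(qrD$rank + 1L):ncol(design)]]
        stop("rank-deficient design; collinear column(s): ",
             paste(bad, collapse = ", "))
    }
    Y <- t(regionVolumes(controls))            # subjects x regions
    fit <- lm.fit(design, Y)
    res <- as.matrix(fit$residuals)
    p <- ncol(design)
    rsd <- sqrt(colSums(res^2) / (n - p))
    zero <- which(!is.finite(rsd) |
                      rsd <= 1e-8 * pmax(1, sqrt(colMeans(Y * Y))))
    if (length(zero))
        stop("zero residual SD in region(s): ",
             paste(rownames(regionVolumes(controls))[zero], collapse = ", "))
    new("WScoreModel", coefficients = as.matrix(fit$coefficients),
        residualSd = unname(rsd),
        regions = rownames(regionVolumes(controls)),
        covariates = covariates, nControls = as.integer(n))
}

#' Convert volumes to sign-flipped w-scores
#'
#' w = (predicted - observed) / residual SD, so a volume one residual SD
#' below its covariate-adjusted control prediction scores w = +1: positive
#' w denotes atrophy severity, matching the increasing waypoints of the
#' trajectory model. Follow-up visits are scored with the same baseline
#' control model.
#'
#' @param model a \linkS4class{WScoreModel}.
#' @param subjects a \linkS4class{CohortExperiment}.
#' @return numeric subjects x regions w-score matrix.
#' @export
applyWScore <- function(model, subjects) {
    info <- subjectInfo(subjects)
    miss <- setdiff(model@covariates, colnames(info))
    if (length(miss))
        stop("missing covariate column(s): ", paste(miss, collapse = ", "))
    missR <- setdiff(model@regions, rownames(regionVolumes(subjects)))
    if (length(missR))
        stop("missing region(s): ", paste(missR, collapse = ", "))
    design <- cbind(1, as.matrix(info[, model@covariates, drop = FALSE]))
    pred <- design %*% model@coefficients          # subjects x regions
    obs <- t(regionVolumes(subjects)[model@regions, , drop = FALSE])
    w <- sweep(pred - obs, 2L, model@residualSd, "/")
    dimnames(w) <- list(info$id, model@regions)
    w
}

setMethod("show", "WScoreModel", function(object) {
    cat("WScoreModel:", length(object@regions), "regions fitted on",
        object@nControls, "controls\n")
    cat("  covariates:", paste(object@covariates, collapse = ", "), "\n")
})
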