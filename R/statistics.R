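# Group-comparison statistics layer: normality-gated two-group tests,
# categorical tests with the expected-count rule, FDR-corrected regional
# contrasts, correlations, and the ALSFRS-R Progression index.

.statResult <- function(variable, groups, test, statistic, p,
                        adjusted = NA_real_, direction = NA_character_,
                        note = NA_character_) {
    data.frame(variable = variable, groups = groups, test = test,
               statistic = as.numeric(statistic), p.value = as.numeric(p),
               p.adjusted = as.numeric(adjusted), direction = direction,
               note = note, stringsAsFactors = FALSE)
}

#' Compare a continuous variable between two groups
#'
#' Shapiro-Wilk normality is tested in each group at alpha = 0.05; when both
#' groups look normal a two-sample t-test is used, otherwise the
#' Mann-Whitney test. All-identical values (Shapiro-Wilk undefined) fall
#' back to Mann-Whitney with a note. The test actually run is recorded.
#'
#' @param x,y numeric values of the two groups (each n >= 3).
#' @param variable,groups labels recorded in the result.
#' @param alpha normality-gate level.
#' @return one-row data.frame (variable, groups, test, statistic, p.value,
#'   direction, note).
#' @export
compareContinuous <- function(x, y, variable = "value", groups = "x vs y",
                              alpha = 0.05) {
    x <- x[!is.na(x)]; y <- y[!is.na(y)]
    if (length(x) < 3L || length(y) < 3L)
        stop("each group needs at least 3 values")
    note <- NA_character_
    swp <- function(v) {
        if (length(unique(v)) == 1L) return(NA_real_)
        shapiro.test(v)$p.value
    }
    p1 <- swp(x); p2 <- swp(y)
    if (is.na(p1) || is.na(p2)) {
        note <- "identical values; Shapiro-Wilk undefined, using Mann-Whitney"
        normal <- FALSE
    } else normal <- p1 > alpha && p2 > alpha
    dir <- if (mean(x) > mean(y)) "x > y"
           else if (mean(x) < mean(y)) "x < y" else "x = y"
    if (normal) {
        tt <- t.test(x, y, var.equal = TRUE)
        .statResult(variable, groups, "two-sample t-test", tt$statistic,
                    tt$p.value, direction = dir, note = note)
    } else {
        wt <- suppressWarnings(wilcox.test(x, y, exact = FALSE))
        .statResult(variable, groups, "Mann-Whitney", wt$statistic,
                    wt$p.value, direction = dir, note = note)
    }
}

#' Compare categorical variables across groups
#'
#' Fisher's exact test when any expected cell count is below 5, otherwise
#' the chi-squared test; two-sided.
#'
#' @param tab contingency table of non-negative integer counts.
#' @param variable,groups labels recorded in the result.
#' @return one-row data.frame recording the branch taken.
#' @export
compareCategorical <- function(tab, variable = "counts",
                               groups = "rows vs cols") {
    tab <- as.matrix(tab)
    if (!length(tab) || sum(tab) == 0) stop("empty contingency table")
    if (any(tab < 0) || any(tab != round(tab)))
        stop("counts must be non-negative integers")
    expected <- suppressWarnings(chisq.test(tab, correct = FALSE))$expected
    if (any(expected < 5)) {
        ft <- fisher.test(tab)
        .statResult(variable, groups, "Fisher exact", NA_real_, ft$p.value)
    } else {
        ct <- suppressWarnings(chisq.test(tab, correct = FALSE))
        .statResult(variable, groups, "chi-squared", ct$statistic,
                    ct$p.value)
    }
}

#' Region-wise group contrasts with FDR correction
#'
#' Per-region Gaussian linear model of the w-score on group (optionally
#' adjusting for SuStaIn stage), with an F-test for the group effect and
#' Benjamini-Hochberg adjustment across regions; significance at adjusted
#' p < 0.05.
#'
#' @param w numeric subjects x regions w-score matrix.
#' @param groups group label per subject (>= 2 levels).
#' @param stage optional numeric stage covariate per subject.
#' @param alpha adjusted-p significance level.
#' @return data.frame with one row per region: F statistic, p.value,
#'   p.adjusted, significant.
#' @export
regionalVolumeContrast <- function(w, groups, stage = NULL, alpha = 0.05) {
    w <- as.matrix(w)
    groups <- droplevels(as.factor(groups))
    if (nlevels(groups) < 2L) stop("at least 2 groups required")
    X1 <- if (is.null(stage)) model.matrix(~ groups)
          else model.matrix(~ groups + stage)
    X0 <- if (is.null(stage)) model.matrix(~ 1, data.frame(g = groups))
          else model.matrix(~ stage)
    if (qr(X1)$rank < ncol(X1)) stop("singular design matrix")
    rss <- function(X) colSums(qr.resid(qr(X), w)^2)
    rss1 <- rss(X1); rss0 <- rss(X0)
    df1 <- ncol(X1) - ncol(X0)
    df2 <- nrow(w) - ncol(X1)
    Fstat <- ((rss0 - rss1) / df1) / (rss1 / df2)
    p <- pf(Fstat, df1, df2, lower.tail = FALSE)
    padj <- p.adjust(p, method = "BH")
    data.frame(region = colnames(w) %||% paste0("region", seq_len(ncol(w))),
               statistic = Fstat, p.value = p, p.adjusted = padj,
               significant = padj < alpha, row.names = NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Correlation between stage and a clinical profile
#'
#' Rank-based (Spearman) by default since SuStaIn stage is ordinal; Pearson
#' and Kendall available.
#'
#' @param x,y paired numeric vectors (n >= 3).
#' @param method correlation method.
#' @param variable label recorded in the result.
#' @return one-row data.frame with the coefficient as \code{statistic}.
#' @export
correlateStage <- function(x, y, method = c("spearman", "pearson",
                                            "kendall"),
                           variable = "stage") {
    method <- match.arg(method)
    keep <- !is.na(x) & !is.na(y)
    x <- x[keep]; y <- y[keep]
    if (length(x) < 3L) stop("at least 3 paired values required")
    if (var(x) == 0 || var(y) == 0) stop("zero-variance input")
    ct <- suppressWarnings(cor.test(x, y, method = method))
    .statResult(variable, "correlation", paste0(method, " correlation"),
                ct$estimate, ct$p.value,
                direction = if (ct$estimate >= 0) "positive" else "negative")
}

#' ALSFRS-R Progression index
#'
#' (48 - ALSFRS-R score) divided by disease duration in months, in points
#' per month.
#'
#' @param alsfrsR ALSFRS-R total score(s), 0..48.
#' @param durationMonths positive disease duration in months.
#' @return numeric points/month.
#' @export
progressionIndex <- function(alsfrsR, durationMonths) {
    if (any(alsfrsR < 0 | alsfrsR > 48, na.rm = TRUE))
        stop("ALSFRS-R scores must lie in 0..48")
    if (any(durationMonths <= 0, na.rm = TRUE))
        stop("duration must be positive")
    (48 - alsfrsR) / durationMonths
}
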