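#' Construct a cohort of regional volumes
#'
#' Builds a \linkS4class{CohortExperiment} from a regions x subjects volume
#' matrix and a per-subject covariate table.
#'
#' @param volumes numeric matrix, regions in rows, subject-visits in columns.
#' @param subjects data.frame with one row per subject-visit; must contain
#'   \code{id}, \code{age}, \code{sex}, \code{icv}.
#' @return a \linkS4class{CohortExperiment}.
#' @export
cohortExperiment <- function(volumes, subjects) {
    volumes <- as.matrix(volumes)
    if (ncol(volumes) != nrow(subjects))
        stop("one subject row per volume column required")
    if (is.null(rownames(volumes)))
        rownames(volumes) <- paste0("region", seq_len(nrow(volumes)))
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(volume = volumes),
        colData = S4Vectors::DataFrame(subjects))
    colnames(se) <- as.character(subjects$id)
    new("CohortExperiment", se)
}

#' @describeIn cohortExperiment the regions x subjects volume matrix.
#' @param x a \linkS4class{CohortExperiment}.
#' @export
regionVolumes <- function(x) SummarizedExperiment::assay(x, "volume")

#' @describeIn cohortExperiment the subject covariate table (data.frame).
#' @export
subjectInfo <- function(x)
    as.data.frame(SummarizedExperiment::colData(x))

#' Read or write a cohort as CSV
#'
#' One row per subject-visit: \code{id}, covariate columns, then one column
#' per region. UTF-8, comma-separated, header row, "." decimal.
#'
#' @param path CSV file path.
#' @param regions region column names; defaults to every column after the
#'   covariates.
#' @return \code{readCohortCsv} returns a \linkS4class{CohortExperiment};
#'   \code{writeCohortCsv} invisibly returns the path.
#' @export
readCohortCsv <- function(path, regions = NULL) {
    if (!file.exists(path)) stop("input file not found: ", path)
    df <- read.csv(path, check.names = FALSE)
    covars <- intersect(c("id", "age", "sex", "icv", "intervalMonths",
                          "visit"), colnames(df))
    if (is.null(regions)) regions <- setdiff(colnames(df), covars)
    cohortExperiment(t(as.matrix(df[, regions, drop = FALSE])),
                     df[, covars, drop = FALSE])
}

#' @rdname readCohortCsv
#' @param cohort a \linkS4class{CohortExperiment} to write.
#' @export
writeCohortCsv <- function(cohort, path) {
    df <- cbind(subjectInfo(cohort), t(regionVolumes(cohort)))
    rownames(df) <- NULL
    write.csv(df, path, row.names = FALSE)
    invisible(path)
}

setMethod("show", "CohortExperiment", function(object) {
    cat("CohortExperiment:", nrow(object), "regions x", ncol(object),
        "subject-visits\n")
    cd <- SummarizedExperiment::colData(object)
    cat("  covariates:", paste(setdiff(colnames(cd), "id"),
                               collapse = ", "), "\n")
})
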