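# End-to-end orchestration: normalize -> cluster -> fit/select -> MCMC ->
# assign -> longitudinal validation -> group statistics, with a manifest
# recording seeds, input hashes and every artifact written.

#' Pipeline configuration
#'
#' Bundles input paths, stage parameters and explicit per-stage seeds for
#' \code{\link{runPipeline}}. All randomness flows through the named seeds.
#'
#' @param controls,patients CSV paths (see \code{\link{readCohortCsv}}).
#' @param followups optional follow-up CSV with an \code{intervalMonths}
#'   column.
#' @param clinical optional clinical table CSV keyed by \code{id}.
#' @param outputDir artifact directory (created if absent).
#' @param covariates w-score covariate columns.
#' @param kRange candidate cluster numbers for BASC.
#' @param B BASC bootstraps.
#' @param waypoints trajectory waypoints.
#' @param CMax largest candidate number of subtypes.
#' @param nFolds cross-validation folds.
#' @param nRestarts greedy restarts.
#' @param mcmcIter MCMC iterations.
#' @param seeds named integer seeds for stages \code{cluster}, \code{fit},
#'   \code{select}, \code{mcmc}.
#' @return a validated configuration list of class \code{PipelineConfig}.
#' @export
pipelineConfig <- function(controls, patients, followups = NULL,
                           clinical = NULL, outputDir = "wsustain-output",
                           covariates = c("age", "sex", "icv"),
                           kRange = 2:20, B = 1000L,
                           waypoints = c(1, 2, 3), CMax = 3L,
                           nFolds = 10L, nRestarts = 25L,
                           mcmcIter = 100000L,
                           seeds = c(cluster = 11L, fit = 21L,
                                     select = 31L, mcmc = 41L)) {
    cfg <- list(controls = controls, patients = patients,
                followups = followups, clinical = clinical,
                outputDir = outputDir, covariates = covariates,
                kRange = kRange, B = as.integer(B), waypoints = waypoints,
                CMax = as.integer(CMax), nFolds = as.integer(nFolds),
                nRestarts = as.integer(nRestarts),
                mcmcIter = as.integer(mcmcIter), seeds = seeds)
    need <- c("cluster", "fit", "select", "mcmc")
    if (!all(need %in% names(seeds)))
        stop("seeds must name: ", paste(need, collapse = ", "))
    for (p in c(cfg$controls, cfg$patients, cfg$followups, cfg$clinical))
        if (!is.null(p) && !file.exists(p))
            stop("input file not found: ", p)
    class(cfg) <- "PipelineConfig"
    cfg
}

.stageTry <- function(stage, expr) {
    tryCatch(expr, error = function(e)
        stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
             call. = FALSE))
}

#' Run the full subtyping-and-staging pipeline
#'
#' Executes normalize -> cluster -> select/fit -> MCMC -> assign
#' (-> longitudinal validation -> statistics when follow-up / clinical
#' inputs are given), writes every artifact as CSV/JSON under
#' \code{outputDir}, and returns a manifest recording the package version,
#' seeds, input MD5 hashes and artifact paths. Runs with identical
#' configuration are byte-identical.
#'
#' @param config a \code{\link{pipelineConfig}}.
#' @return the manifest, invisibly (also written as \code{manifest.json}).
#' @export
runPipeline <- function(config) {
    stopifnot(inherits(config, "PipelineConfig"))
    dir.create(config$outputDir, showWarnings = FALSE, recursive = TRUE)
    art <- function(f) file.path(config$outputDir, f)
    artifacts <- character(0)
    put <- function(name) artifacts[[name]] <<- art(name)

    controls <- .stageTry("normalize", readCohortCsv(config$controls))
    patients <- .stageTry("normalize", readCohortCsv(config$patients))
    wModel <- .stageTry("normalize",
                        fitWScoreModel(controls, config$covariates))
    w <- .stageTry("normalize", applyWScore(wModel, patients))
    write.csv(data.frame(id = rownames(w), w, check.names = FALSE),
              art("wscores.csv"), row.names = FALSE)
    put("wscores.csv")

    solution <- .stageTry("cluster",
        selectClusterNumber(w, kRange = config$kRange, B = config$B,
                            seed = config$seeds[["cluster"]]))
    write.csv(as.data.frame(stabilityMatrix(solution)),
              art("stability.csv"), row.names = TRUE)
    put("stability.csv")
    jsonlite::write_json(list(k = solution@k,
                              silhouette = as.list(silhouetteCurve(solution)),
                              members = clusterMembers(solution)),
                         art("clusters.json"), auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
    put("clusters.json")
    biomarkers <- reduceFeatures(w, solution)
    write.csv(data.frame(id = rownames(w), biomarkers,
                         check.names = FALSE),
              art("biomarkers.csv"), row.names = FALSE)
    put("biomarkers.csv")

    spec <- trajectorySpec(colnames(biomarkers),
                           waypoints = config$waypoints)
    selection <- .stageTry("select",
        crossvalSelect(biomarkers, spec, CMax = config$CMax,
                       nFolds = config$nFolds,
                       nRestarts = max(1L, config$nRestarts %/% 3L),
                       seed = config$seeds[["select"]]))
    jsonlite::write_json(list(chosenC = selection@chosenC,
                              cvic = selection@cvic,
                              testLogLik = selection@testLogLik,
                              folds = selection@folds),
                         art("selection.json"), auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
    put("selection.json")

    model <- .stageTry("fit",
        fitSubtypes(biomarkers, spec, C = chosenSubtypes(selection),
                    nRestarts = config$nRestarts,
                    seed = config$seeds[["fit"]]))
    jsonlite::write_json(list(sequences = eventSequences(model),
                              fractions = mixtureFractions(model),
                              logLik = model@logLik,
                              biomarkers = spec@biomarkers),
                         art("model.json"), auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    put("model.json")

    chain <- .stageTry("mcmc",
        runMCMC(biomarkers, model, nIter = config$mcmcIter,
                seed = config$seeds[["mcmc"]]))
    for (s in seq_len(nSubtypes(chain))) {
        f <- sprintf("positional_variance_subtype%d.csv", s)
        write.csv(as.data.frame(positionalVariance(chain, s)), art(f),
                  row.names = TRUE)
        put(f)
    }

    assignments <- .stageTry("assign", assignSubjects(biomarkers, chain))
    flat <- as.data.frame(assignments[, c("id", "mapSubtype", "mapStage",
                                          "normalAppearing", "subtypeProb",
                                          "stageProb")])
    write.csv(cbind(flat, as.data.frame(assignments$subtypePosterior),
                    as.data.frame(assignments$stagePosterior)),
              art("assignments.csv"), row.names = FALSE)
    put("assignments.csv")

    if (!is.null(config$followups)) {
        fu <- .stageTry("validate-longitudinal",
                        readCohortCsv(config$followups))
        wFu <- applyWScore(wModel, fu)
        bFu <- reduceFeatures(wFu, solution)
        aFu <- assignSubjects(bFu, chain, ids = subjectInfo(fu)$id)
        rec <- longitudinalRecords(assignments, aFu,
                                   subjectInfo(fu)$intervalMonths)
        stab <- subtypeStability(rec)
        rec$stable <- stab$stable
        rec$annualizedChange <- annualizedStageChange(rec)
        write.csv(rec, art("longitudinal.csv"), row.names = FALSE)
        put("longitudinal.csv")
    }

    if (!is.null(config$clinical)) {
        clin <- .stageTry("stats", read.csv(config$clinical))
        m <- match(assignments$id, clin$id)
        groups <- ifelse(assignments$normalAppearing, "normal-appearing",
                         paste0("subtype", assignments$mapSubtype))
        rows <- list()
        for (v in intersect(c("mmse", "alsfrsR", "durationMonths"),
                            colnames(clin))) {
            g <- split(clin[[v]][m], groups)
            g <- g[lengths(lapply(g, function(x) x[!is.na(x)])) >= 3L]
            if (length(g) >= 2L)
                rows[[length(rows) + 1L]] <- compareContinuous(
                    g[[1]], g[[2]], variable = v,
                    groups = paste(names(g)[1:2], collapse = " vs "))
            rows[[length(rows) + 1L]] <- correlateStage(
                assignments$mapStage, clin[[v]][m], variable = v)
        }
        for (v in intersect(c("diagnosis", "genotype", "onsetSite"),
                            colnames(clin)))
            rows[[length(rows) + 1L]] <- compareCategorical(
                table(clin[[v]][m], groups), variable = v,
                groups = "across assignments")
        stats <- do.call(rbind, rows)
        write.csv(stats, art("stats.csv"), row.names = FALSE)
        put("stats.csv")
        contrasts <- regionalVolumeContrast(w, groups,
                                            stage = assignments$mapStage)
        write.csv(contrasts, art("regional_contrasts.csv"),
                  row.names = FALSE)
        put("regional_contrasts.csv")
    }

    inputs <- c(controls = config$controls, patients = config$patients,
                followups = config$followups, clinical = config$clinical)
    manifest <- list(
        package = "wSuStaIn",
        version = as.character(utils::packageVersion("wSuStaIn")),
        seeds = as.list(config$seeds),
        parameters = config[c("covariates", "kRange", "B", "waypoints",
                              "CMax", "nFolds", "nRestarts", "mcmcIter")],
        inputs = lapply(inputs, function(p)
            list(path = p, md5 = unname(tools::md5sum(p)))),
        artifacts = as.list(artifacts))
    jsonlite::write_json(manifest, art("manifest.json"), auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
    invisible(manifest)
}
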