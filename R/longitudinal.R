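# Longitudinal subtype stability, staging reliability and annualized
# stage change between baseline and follow-up assignments.

#' Pair baseline and follow-up assignments into longitudinal records
#'
#' @param baseline,followup assignment tables from
#'   \code{\link{assignSubjects}} (or data.frames with \code{id},
#'   \code{mapSubtype}, \code{mapStage}, \code{normalAppearing}).
#' @param intervalMonths positive follow-up interval per follow-up row,
#'   in months.
#' @return data.frame with one row per followed-up subject.
#' @export
longitudinalRecords <- function(baseline, followup, intervalMonths) {
    baseline <- as.data.frame(baseline)[, c("id", "mapSubtype", "mapStage",
                                            "normalAppearing")]
    followup <- as.data.frame(followup)[, c("id", "mapSubtype", "mapStage",
                                            "normalAppearing")]
    if (length(intervalMonths) != nrow(followup))
        stop("one interval per follow-up row required")
    if (any(intervalMonths <= 0))
        stop("follow-up intervals must be positive")
    m <- match(followup$id, baseline$id)
    if (anyNA(m))
        stop("follow-up id(s) not found at baseline: ",
             paste(followup$id[is.na(m)], collapse = ", "))
    data.frame(id = followup$id,
               baselineSubtype = baseline$mapSubtype[m],
               baselineStage = baseline$mapStage[m],
               baselineNormal = baseline$normalAppearing[m],
               followupSubtype = followup$mapSubtype,
               followupStage = followup$mapStage,
               followupNormal = followup$normalAppearing,
               intervalMonths = as.numeric(intervalMonths))
}

# effective assignment label: normal-appearing overrides the subtype
.assignLabel <- function(subtype, normal)
    ifelse(normal, "normal", paste0("subtype", subtype))

#' Subtype stability across follow-up
#'
#' A follow-up visit is subtype-stable when it keeps the same assignment
#' label (same subtype, or normal-appearing at both visits) or progresses
#' from the normal-appearing group to an atrophy subtype; switches between
#' atrophy subtypes and retrogressions to normal-appearing are unstable.
#'
#' @param records output of \code{\link{longitudinalRecords}}.
#' @return list with \code{proportionStable}, \code{proportionSameLabel}
#'   (follow-ups keeping the identical label), and the per-record
#'   \code{stable} flags.
#' @export
subtypeStability <- function(records) {
    bl <- .assignLabel(records$baselineSubtype, records$baselineNormal)
    fu <- .assignLabel(records$followupSubtype, records$followupNormal)
    same <- bl == fu
    progressed <- records$baselineNormal & !records$followupNormal
    stable <- same | progressed
    list(proportionStable = mean(stable),
         proportionSameLabel = mean(same),
         stable = stable)
}

#' Staging reliability among subtype-stable follow-ups
#'
#' Restricted to subtype-stable records, a follow-up is stage-reliable when
#' its MAP stage is at or beyond the baseline MAP stage (advancing or
#' holding); retrogressions to an earlier stage are unreliable.
#'
#' @param records output of \code{\link{longitudinalRecords}}.
#' @return list with \code{proportionReliable}, \code{nStable},
#'   \code{nRetrogressed}, and the per-stable-record \code{reliable} flags.
#' @export
stageReliability <- function(records) {
    stable <- subtypeStability(records)$stable
    if (!any(stable)) stop("no subtype-stable records")
    rec <- records[stable, , drop = FALSE]
    reliable <- rec$followupStage >= rec$baselineStage
    list(proportionReliable = mean(reliable),
         nStable = nrow(rec),
         nRetrogressed = sum(!reliable),
         reliable = reliable)
}

#' Annualized change in stage
#'
#' (follow-up stage - baseline stage) / (interval in months / 12), in
#' stages per year.
#'
#' @param records output of \code{\link{longitudinalRecords}}.
#' @return numeric vector, one value per record.
#' @export
annualizedStageChange <- function(records) {
    if (any(records$intervalMonths <= 0))
        stop("follow-up intervals must be positive")
    (records$followupStage - records$baselineStage) /
        (records$intervalMonths / 12)
}
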