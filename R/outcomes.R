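#' Symptom-free status from an Insomnia Severity Index score
#'
#' Symptom-free is defined as an ISI score strictly below 8.
#'
#' @param isi_score ISI score(s) in \[0, 28\]; `NA` propagates.
#' @return logical vector.
#' @examples
#' symptom_free_status(c(7, 8, 28))  # TRUE FALSE FALSE
#' @export
symptom_free_status <- function(isi_score) {
  ok <- !is.na(isi_score)
  if (any(isi_score[ok] < 0 | isi_score[ok] > 28)) {
    stop("ISI scores must lie in [0, 28]", call. = FALSE)
  }
  isi_score < 8
}

#' QALYs by the area under a utility trajectory
#'
#' Trapezoid integral of linearly interpolated health utilities over
#' time measured in years: for a constant utility u over T years the
#' result is u * T.
#'
#' @param times assessment times in years since randomization, strictly
#'   increasing, length >= 2.
#' @param utilities utility values in \[0, 1\] aligned to `times`.
#' @return QALYs accrued between the first and last assessment.
#' @examples
#' qaly_auc(c(0, 0.5), c(0.72, 0.72))          # 0.36
#' qaly_auc(c(0, 0.25, 0.5), c(0.6, 0.8, 0.6)) # 0.35
#' @export
qaly_auc <- function(times, utilities) {
  if (length(times) < 2 || length(times) != length(utilities)) {
    stop("need >= 2 aligned time/utility points", call. = FALSE)
  }
  if (anyNA(times) || any(diff(times) <= 0)) {
    stop("'times' must be strictly increasing", call. = FALSE)
  }
  if (anyNA(utilities) || any(!is.finite(utilities))) {
    stop("'utilities' must be finite and non-missing", call. = FALSE)
  }
  if (any(utilities < 0 | utilities > 1)) {
    stop("'utilities' must lie in [0, 1]", call. = FALSE)
  }
  sum(diff(times) * (utilities[-length(utilities)] + utilities[-1]) / 2)
}

#' Per-participant outcome pair: symptom-free status and QALYs
#'
#' Symptom-free status is read from the final (6-month) ISI; QALYs from
#' the trapezoid area under the SF-6D utility trajectory. Participants
#' with a missing follow-up measurement get `NA` (to be imputed or
#' dropped downstream).
#'
#' @param cohort an `ee_cohort`.
#' @param utility_points which assessment utilities enter the area under
#'   the curve: all three by default, or baseline + 6 months.
#' @return data.frame `id`, `arm`, `symptom_free` (logical), `qaly`.
#' @export
cohort_outcomes <- function(cohort,
                            utility_points = c("t0", "t1", "t2")) {
  stopifnot(inherits(cohort, "ee_cohort"))
  utility_points <- match.arg(utility_points, c("t0", "t1", "t2"),
                              several.ok = TRUE)
  if (!all(c("t0", "t2") %in% utility_points)) {
    stop("utility points must span the horizon (include t0 and t2)",
         call. = FALSE)
  }
  p <- cohort$participants
  tms <- assessment_times()[utility_points]
  ucols <- paste0("utility_", utility_points)
  qaly <- vapply(seq_len(nrow(p)), function(i) {
    u <- as.numeric(p[i, ucols])
    if (anyNA(u)) return(NA_real_)
    qaly_auc(as.numeric(tms), u)
  }, numeric(1))
  data.frame(id = p$id, arm = p$arm,
             symptom_free = symptom_free_status(p$isi_t2),
             qaly = qaly, stringsAsFactors = FALSE)
}

#' Remission (symptom-free) rate in one arm
#'
#' Fraction of an arm's participants who are symptom-free at the final
#' follow-up, among those with an observed final ISI.
#'
#' @param cohort an `ee_cohort` or a data.frame with `arm` and
#'   `symptom_free` columns (e.g. from [cohort_outcomes()]).
#' @param arm `"intervention"` or `"control"`.
#' @return proportion in \[0, 1\].
#' @export
remission_rate <- function(cohort, arm = c("intervention", "control")) {
  arm <- match.arg(arm)
  out <- if (inherits(cohort, "ee_cohort")) cohort_outcomes(cohort) else cohort
  sf <- out$symptom_free[out$arm == arm]
  sf <- sf[!is.na(sf)]
  if (length(sf) == 0) {
    stop(sprintf("no observed outcomes in arm '%s'", arm), call. = FALSE)
  }
  mean(sf)
}
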