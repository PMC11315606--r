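as_lik_vector <- function(x) {
  if (inherits(x, "fit_result")) x$per_choice_lik else as.numeric(x)
}

#' Dominant-system label for every choice
#'
#' Labels a choice `"MB"` when the fitted model-based model assigns the
#' chosen action a strictly higher likelihood than the fitted model-free
#' model, `"MF"` otherwise. Exact ties therefore go to MF; ties are counted
#' in an attribute since they are expected to be measure-zero.
#'
#' @param fit_mb,fit_mf `fit_result` objects (or bare per-choice likelihood
#'   vectors) of equal length, aligned to the session's choice order.
#' @return character vector of labels with attribute `n_ties`.
#' @export
dominant_sequence <- function(fit_mb, fit_mf) {
  lmb <- as_lik_vector(fit_mb)
  lmf <- as_lik_vector(fit_mf)
  if (length(lmb) != length(lmf))
    stop("per-choice likelihood vectors differ in length")
  labels <- ifelse(lmb > lmf, "MB", "MF")
  attr(labels, "n_ties") <- sum(lmb == lmf)
  labels
}

#' System preference: percentage of MB-dominant choices
#'
#' @param labels output of [dominant_sequence()].
#' @param mask logical vector selecting the choices of one task condition
#'   (default: all choices).
#' @return percentage in \[0, 100\].
#' @export
system_preference <- function(labels, mask = rep(TRUE, length(labels))) {
  sel <- labels[mask]
  if (length(sel) == 0) stop("condition mask selects no choices")
  100 * mean(sel == "MB")
}

#' System switching: percentage of consecutive dominant-system changes
#'
#' Consecutive pairs are formed within the masked subsequence in session
#' order (crossing block boundaries of the same condition, never pairing
#' across conditions).
#'
#' @inheritParams system_preference
#' @return percentage of adjacent pairs whose dominant system differs.
#' @export
system_switching <- function(labels, mask = rep(TRUE, length(labels))) {
  sel <- labels[mask]
  if (length(sel) < 2) stop("condition mask must select at least 2 choices")
  100 * mean(sel[-1] != sel[-length(sel)])
}

#' Subject-level arbitration metrics
#'
#' Computes system preference and system switching per goal condition (and
#' split by transition uncertainty), together with task performance and
#' choice optimality, from one subject's session and independently fitted MB
#' and MF models. Both choices of a trial enter the choice sequence.
#'
#' @param session the subject's session data.frame.
#' @param fit_mb,fit_mf `fit_result` objects for the MB and MF models.
#' @param tree the `decision_tree` (for performance/optimality columns).
#' @return one-row data.frame with preference/switching for the specific and
#'   flexible conditions, their low/high-uncertainty splits, choice counts
#'   per condition, `performance` (coins per trial, overall and per
#'   condition) and `choice_optimality`.
#' @export
subject_metrics <- function(session, fit_mb, fit_mf, tree) {
  labels <- dominant_sequence(fit_mb, fit_mf)
  cond <- rep(session$goal_condition, each = 2L)
  unc <- rep(session$uncertainty, each = 2L)
  if (length(labels) != length(cond))
    stop("fits and session disagree on the number of choices")
  sp <- function(m) system_preference(labels, m)
  sw <- function(m) system_switching(labels, m)
  spec <- cond == "specific"; flex <- cond == "flexible"
  data.frame(
    preference_specific = sp(spec),
    preference_flexible = sp(flex),
    switching_specific = sw(spec),
    switching_flexible = sw(flex),
    preference_specific_low = sp(spec & unc == "low"),
    preference_specific_high = sp(spec & unc == "high"),
    preference_flexible_low = sp(flex & unc == "low"),
    preference_flexible_high = sp(flex & unc == "high"),
    switching_specific_low = sw(spec & unc == "low"),
    switching_specific_high = sw(spec & unc == "high"),
    switching_flexible_low = sw(flex & unc == "low"),
    switching_flexible_high = sw(flex & unc == "high"),
    n_choices_specific = sum(spec),
    n_choices_flexible = sum(flex),
    n_ties = attr(labels, "n_ties"),
    performance = task_performance(session),
    performance_specific =
      task_performance(session[session$goal_condition == "specific", ]),
    performance_flexible =
      task_performance(session[session$goal_condition == "flexible", ]),
    choice_optimality = choice_optimality(session, tree)
  )
}

#' Arbitration metrics for a whole cohort
#'
#' @param sessions named list of session data.frames.
#' @param fits output of [fit_cohort()] aligned to `sessions`.
#' @param tree the `decision_tree`.
#' @return data.frame, one row per subject, with a leading `subject` column.
#' @export
cohort_metrics <- function(sessions, fits, tree) {
  ids <- names(sessions) %||% as.character(seq_along(sessions))
  rows <- lapply(seq_along(sessions), function(i)
    cbind(subject = ids[i],
          subject_metrics(sessions[[i]], fits[[i]]$mb, fits[[i]]$mf, tree)))
  do.call(rbind, rows)
}
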