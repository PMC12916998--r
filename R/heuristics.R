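#' Take-the-best prediction for a task
#'
#' TTB inspects cues in descending validity order and decides by the first
#' cue whose values differ between the options; its validity is the
#' confidence prediction. Time is the elementary-information-process (EIP)
#' count accumulated up to and including the deciding cue (see
#' \code{\link{eip_time}}). If no cue discriminates, the predicted choice
#' is random with chance-level confidence .5.
#'
#' @param task a \code{pcs_task}.
#' @return list with \code{choice}, \code{confidence_raw}, \code{time_raw}.
#' @export
ttb_predict <- function(task) {
  stopifnot(inherits(task, "pcs_task"))
  d <- task$cue_matrix[, 1] - task$cue_matrix[, 2]
  disc <- which(d != 0)
  if (length(disc) == 0L)
    return(list(choice = "random", confidence_raw = 0.5,
                time_raw = eip_time("TTB", cues_examined = 4L)))
  k <- disc[1L]
  list(choice = if (d[k] > 0) "A" else "B",
       confidence_raw = task$validities[k],
       time_raw = eip_time("TTB", cues_examined = k))
}

#' Equal-weights prediction for a task
#'
#' EQW sums the unweighted cue values (+1/-1) per option and picks the
#' larger sum; confidence is the absolute difference between the two sums
#' (an even integer in 0..8). Equal sums give a random choice with
#' confidence 0. The time prediction is the constant EIP count of summing
#' all cues.
#'
#' @param task a \code{pcs_task}.
#' @return list with \code{choice}, \code{confidence_raw}, \code{time_raw}.
#' @export
eqw_predict <- function(task) {
  stopifnot(inherits(task, "pcs_task"))
  s <- colSums(task$cue_matrix)
  d <- s[["A"]] - s[["B"]]
  list(choice = if (d > 0) "A" else if (d < 0) "B" else "random",
       confidence_raw = abs(d),
       time_raw = eip_time("EQW"))
}

#' Chance-corrected weighted-additive prediction for a task
#'
#' WADD_c scores each option as the sum of its cue values weighted by the
#' chance-corrected validities (v_i - .5) and picks the higher score;
#' confidence is the absolute score difference. Equal scores give a random
#' choice. Time is the constant EIP count of the full weighted sum.
#'
#' @param task a \code{pcs_task}.
#' @return list with \code{choice}, \code{confidence_raw}, \code{time_raw}.
#' @export
waddc_predict <- function(task) {
  stopifnot(inherits(task, "pcs_task"))
  w <- task$validities - 0.5
  s <- as.vector(w %*% task$cue_matrix)
  d <- s[1L] - s[2L]
  list(choice = if (d > 0) "A" else if (d < 0) "B" else "random",
       confidence_raw = abs(d),
       time_raw = eip_time("WADDc"))
}

#' Elementary-information-process time counts
#'
#' Serial heuristics predict decision time by the number of elementary
#' operations they perform. The counting scheme (Payne-style) is: TTB
#' reads both cue values and compares them for each cue examined (3 EIPs
#' per cue, stopping at the first discriminating cue); EQW reads all 8 cue
#' values, performs 6 additions and 1 comparison (15, constant); WADD_c
#' reads 8 values, performs 8 multiplications by the weights, 6 additions
#' and 1 comparison (23, constant). Any strictly monotone recount yields
#' the same contrast predictions up to an affine transform, to which the
#' classification machinery is insensitive.
#'
#' @param strategy one of "TTB", "EQW", "WADDc".
#' @param cues_examined for TTB, how many cues were inspected (1-4).
#' @return integer EIP count.
#' @export
eip_time <- function(strategy, cues_examined = 4L) {
  switch(strategy,
         TTB = {
           stopifnot(cues_examined >= 1L, cues_examined <= 4L)
           3L * as.integer(cues_examined)
         },
         EQW = 15L,
         WADDc = 23L,
         stop("unknown strategy: ", strategy))
}

#' Naive Bayesian solution of a task
#'
#' The rational benchmark: with independent cues and equal priors, the
#' posterior odds of A over B are the product of validity likelihood
#' ratios v/(1-v) over cues favoring A divided by the product over cues
#' favoring B; non-discriminating cues cancel. The superior option is the
#' one with posterior probability above .5.
#'
#' @param task a \code{pcs_task}.
#' @return list with \code{posterior_A} and \code{superior} ("A", "B" or
#'   "tie").
#' @export
naive_bayes <- function(task) {
  stopifnot(inherits(task, "pcs_task"))
  d <- task$cue_matrix[, 1] - task$cue_matrix[, 2]  # +2 favors A, -2 favors B
  lo <- sum(sign(d) * log(task$validities / (1 - task$validities)))
  posterior_A <- stats::plogis(lo)
  list(posterior_A = posterior_A,
       superior = if (lo > 0) "A" else if (lo < 0) "B" else "tie")
}

#' Strategy predictions across a task set
#'
#' Computes the per-task prediction triple (choice, raw confidence, raw
#' time) of one strategy for every task in a set, plus the task-set-level
#' contrast vectors used in the MM-ML likelihood (see
#' \code{\link{contrastify}}).
#'
#' @param tasks a \code{task_set}.
#' @param strategy one of "TTB", "EQW", "WADDc", "PCS_fix", "PCS_fitted".
#' @param P,constants PCS parameters, used for the PCS strategies only;
#'   \code{P} defaults to 1.9 (the fixed variant).
#' @return data.frame with one row per task: \code{task_id}, \code{choice},
#'   \code{confidence_raw}, \code{time_raw}, \code{adiff} (signed
#'   activation difference, NA for non-PCS strategies), and the contrast
#'   columns \code{time_contrast}, \code{conf_contrast}. Carries the
#'   strategy name as attribute \code{"strategy"}.
#' @export
strategy_predictions <- function(tasks, strategy, P = 1.9,
                                 constants = pcs_constants()) {
  stopifnot(inherits(tasks, "task_set"), length(tasks) >= 1L)
  strategy <- match.arg(strategy, c("TTB", "EQW", "WADDc", "PCS_fix", "PCS_fitted"))
  fun <- switch(strategy,
                TTB = ttb_predict, EQW = eqw_predict, WADDc = waddc_predict,
                PCS_fix = , PCS_fitted = function(t) pcs_predict(t, P, constants))
  rows <- lapply(tasks, fun)
  out <- data.frame(
    task_id = vapply(tasks, `[[`, "", "id"),
    choice = vapply(rows, `[[`, "", "choice"),
    confidence_raw = vapply(rows, `[[`, 0, "confidence_raw"),
    time_raw = as.numeric(vapply(rows, `[[`, 0, "time_raw")),
    adiff = if (startsWith(strategy, "PCS"))
      vapply(rows, `[[`, 0, "adiff") else NA_real_,
    stringsAsFactors = FALSE)
  out$time_contrast <- contrastify(out$time_raw)
  out$conf_contrast <- contrastify(out$confidence_raw)
  attr(out, "strategy") <- strategy
  attr(out, "P") <- if (startsWith(strategy, "PCS")) P else NA_real_
  rownames(out) <- NULL
  out
}
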