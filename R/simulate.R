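#' Generate a random set of probabilistic inference tasks
#'
#' Rejection-samples tasks until the requested number of valid ones is
#' found. Validities are drawn uniformly from \code{validity_range} and
#' sorted descending; cue values are fair coin flips. Rejected are: tasks
#' with identical option columns, dominated tasks (one option at least as
#' good on every cue), duplicates (on validities rounded to 2 decimals
#' plus the cue matrix), and — by default — tasks where the naive Bayes
#' posterior ties, so that performance against the rational benchmark is
#' well defined on every task.
#'
#' @param n_tasks number of tasks (the study design uses 60).
#' @param validity_range numeric length-2 within (0.5, 1); the default
#'   spans the validities of the printed example tasks.
#' @param seed integer seed.
#' @param exclude_bayes_ties drop tasks with tied posteriors (default TRUE).
#' @param max_attempts sampling budget.
#' @return a \code{task_set} with ids "t01", "t02", ...
#' @export
generate_task_set <- function(n_tasks = 60L, validity_range = c(0.60, 0.94),
                              seed = 1L, exclude_bayes_ties = TRUE,
                              max_attempts = 1000L * n_tasks) {
  stopifnot(validity_range[1] > 0.5, validity_range[2] < 1,
            validity_range[1] <= validity_range[2])
  set.seed(seed)
  tasks <- list()
  seen <- character()
  attempts <- 0L
  while (length(tasks) < n_tasks) {
    attempts <- attempts + 1L
    if (attempts > max_attempts)
      stop("task sampling budget exceeded; relax the constraints")
    v <- sort(round(stats::runif(4, validity_range[1], validity_range[2]), 2),
              decreasing = TRUE)
    m <- matrix(sample(c(-1, 1), 8, replace = TRUE), 4, 2)
    if (all(m[, 1] == m[, 2])) next
    if (is_dominated(m)) next
    sig <- task_signature(v, m)
    if (sig %in% seen) next
    t <- make_task(v, m, id = sprintf("t%02d", length(tasks) + 1L))
    if (exclude_bayes_ties && naive_bayes(t)$superior == "tie") next
    seen <- c(seen, sig)
    tasks[[length(tasks) + 1L]] <- t
  }
  task_set(tasks)
}

#' Specify a simulated participant
#'
#' Bundles the generating strategy, its noise parameters, the time and
#' confidence measurement models, and the decision-mode condition.
#' Defaults emulate the structure of the two-condition study the analysis
#' pipeline targets: ln decision times center near the observed condition
#' means (5583 ms intuition, 9241 ms deliberation, a shift of
#' ln(9241/5583) on the log scale), the time and confidence slopes match
#' the magnitudes of the reported mixed-model coefficients (0.48 ln-units,
#' 10.69 slider points per unit contrast), deliberation halves the choice
#' error rate, and PCS agents use sensitivity values near the reported
#' condition means (P = 1.70 intuition, 1.97 deliberation).
#'
#' @param strategy generating strategy name (see
#'   \code{\link{strategy_predictions}}).
#' @param condition "intuition" or "deliberation".
#' @param epsilon choice error rate for deterministic strategies; default
#'   0.08, multiplied by \code{deliberation_epsilon_mult} under
#'   deliberation.
#' @param lambda determinism of PCS_fitted agents (logistic choices).
#' @param P sensitivity of PCS agents; default 1.70 (intuition) or 1.97
#'   (deliberation); PCS_fix agents always predict with P = 1.9 but may
#'   be generated at any P.
#' @param mu_T mean ln decision time (ln ms) in the intuition condition.
#' @param delta_mu_T additive ln-time shift under deliberation.
#' @param beta_T,sigma_T slope on the strategy's time contrast and
#'   residual SD, ln-ms scale.
#' @param mu_C,beta_C,sigma_C confidence model on the 50-100 slider scale.
#' @param deliberation_epsilon_mult error-rate multiplier (< 1) applied
#'   under deliberation.
#' @param order_drift linear ln-time drift per trial position (default 0),
#'   for order-effect testing.
#' @param seed integer seed used when this agent is simulated directly.
#' @return list of class \code{agent_spec}.
#' @export
agent_spec <- function(strategy,
                       condition = c("intuition", "deliberation"),
                       epsilon = 0.08, lambda = 4,
                       P = NULL,
                       mu_T = log(5583), delta_mu_T = log(9241 / 5583),
                       beta_T = 0.48, sigma_T = 0.35,
                       mu_C = 75, beta_C = 10.69, sigma_C = 10,
                       deliberation_epsilon_mult = 0.5,
                       order_drift = 0, seed = 1L) {
  strategy <- match.arg(strategy, strategy_names())
  condition <- match.arg(condition)
  if (is.null(P))
    P <- if (strategy == "PCS_fix") 1.9
         else if (condition == "deliberation") 1.97 else 1.70
  if (condition == "deliberation") epsilon <- epsilon * deliberation_epsilon_mult
  stopifnot(epsilon >= 0, epsilon <= 0.5, lambda >= 0, P >= 0,
            sigma_T >= 0, sigma_C >= 0)
  structure(list(strategy = strategy, condition = condition,
                 epsilon = epsilon, lambda = lambda, P = P,
                 mu_T = mu_T + if (condition == "deliberation") delta_mu_T else 0,
                 beta_T = beta_T, sigma_T = sigma_T,
                 mu_C = mu_C, beta_C = beta_C, sigma_C = sigma_C,
                 order_drift = order_drift, seed = as.integer(seed)),
            class = "agent_spec")
}

#' Simulate one participant's trial stream
#'
#' Computes the agent's strategy predictions on the task set, then draws
#' a randomized trial order, choices (predicted choice flipped with
#' probability epsilon, or sampled from the logistic rule for PCS_fitted
#' agents; fair coin where the strategy predicts random choice), ln-normal
#' decision times around mu_T + beta_T x time contrast (plus any order
#' drift), and confidences around mu_C + beta_C x confidence contrast,
#' clipped to the 50-100 slider range.
#'
#' @param spec an \code{\link{agent_spec}}.
#' @param tasks a \code{task_set}.
#' @param id participant identifier.
#' @param constants a \code{pcs_constants} list (PCS agents).
#' @param preds optional precomputed \code{\link{strategy_predictions}}
#'   table for this agent's strategy and P, to avoid rerunning the
#'   network when many agents share a task set.
#' @return list with \code{trials} (data.frame: participant, condition,
#'   trial_index, task_id, choice, rt_ms, confidence — no ground-truth
#'   columns) and \code{truth} (one-row data.frame with the generating
#'   parameters).
#' @export
simulate_participant <- function(spec, tasks, id = "p1",
                                 constants = pcs_constants(), preds = NULL) {
  stopifnot(inherits(spec, "agent_spec"), inherits(tasks, "task_set"))
  if (is.null(preds))
    preds <- strategy_predictions(tasks, spec$strategy, P = spec$P,
                                  constants = constants)
  else stopifnot(identical(attr(preds, "strategy"), spec$strategy))
  n <- nrow(preds)
  set.seed(spec$seed)
  ord <- sample.int(n)
  p <- preds[ord, , drop = FALSE]
  if (spec$strategy == "PCS_fitted") {
    p_A <- stats::plogis(spec$lambda * p$adiff)
    choice <- ifelse(stats::runif(n) < p_A, "A", "B")
  } else {
    flip <- stats::runif(n) < spec$epsilon
    choice <- ifelse(p$choice == "random",
                     ifelse(stats::runif(n) < 0.5, "A", "B"),
                     ifelse(flip, ifelse(p$choice == "A", "B", "A"), p$choice))
  }
  pos <- seq_len(n)
  lnrt <- spec$mu_T + spec$beta_T * p$time_contrast +
    spec$order_drift * (pos - (n + 1) / 2) +
    stats::rnorm(n, 0, spec$sigma_T)
  conf <- spec$mu_C + spec$beta_C * p$conf_contrast +
    stats::rnorm(n, 0, spec$sigma_C)
  conf <- pmin(pmax(conf, 50), 100)
  trials <- data.frame(participant = id, condition = spec$condition,
                       trial_index = pos, task_id = p$task_id,
                       choice = choice, rt_ms = exp(lnrt),
                       confidence = conf, stringsAsFactors = FALSE)
  truth <- data.frame(participant = id, strategy = spec$strategy,
                      condition = spec$condition, epsilon = spec$epsilon,
                      lambda = spec$lambda, P = spec$P, seed = spec$seed,
                      stringsAsFactors = FALSE)
  list(trials = trials, truth = truth)
}

#' Specify a simulated study
#'
#' @param n_intuition,n_deliberation participants per condition; defaults
#'   are the cell sizes of the target two-condition design (67 and 61).
#' @param mixture named strategy mixture proportions (must sum to 1);
#'   the default approximates the reported classification distribution
#'   (majority PCS, under a third weighted-additive, the rest simple
#'   heuristics).
#' @param n_tasks,validity_range task-set parameters
#'   (\code{\link{generate_task_set}}).
#' @param seed master seed; per-participant seeds are derived from it.
#' @param allocation "exact" assigns strategies by largest-remainder
#'   rounding, so the realized label counts reproduce the mixture
#'   deterministically; "multinomial" draws each participant's strategy
#'   independently from the mixture, which is what calibration studies of
#'   between-condition tests require.
#' @param ... further arguments passed to \code{\link{agent_spec}} for
#'   every agent (e.g. \code{epsilon}, \code{sigma_T}).
#' @return list of class \code{study_spec}.
#' @export
study_spec <- function(n_intuition = 67L, n_deliberation = 61L,
                       mixture = c(PCS_fitted = 0.30, PCS_fix = 0.29,
                                   WADDc = 0.28, EQW = 0.06, TTB = 0.07),
                       n_tasks = 60L, validity_range = c(0.60, 0.94),
                       seed = 1L, allocation = c("exact", "multinomial"),
                       ...) {
  allocation <- match.arg(allocation)
  stopifnot(abs(sum(mixture) - 1) < 1e-8, all(mixture >= 0),
            all(names(mixture) %in% strategy_names()))
  structure(list(n_intuition = as.integer(n_intuition),
                 n_deliberation = as.integer(n_deliberation),
                 mixture = mixture, n_tasks = as.integer(n_tasks),
                 validity_range = validity_range, seed = as.integer(seed),
                 allocation = allocation,
                 agent_args = list(...)),
            class = "study_spec")
}

# largest-remainder allocation so the realized counts match the mixture
allocate_mixture <- function(mixture, n) {
  raw <- mixture * n
  counts <- floor(raw)
  rem <- n - sum(counts)
  if (rem > 0) {
    extra <- order(raw - counts, decreasing = TRUE)[seq_len(rem)]
    counts[extra] <- counts[extra] + 1
  }
  counts
}

#' Simulate a complete two-condition study
#'
#' Generates the shared task set, allocates strategies to agents by the
#' mixture (largest-remainder rounding, so the realized label counts are
#' deterministic), and simulates every participant with a seed derived
#' from the master seed. Ground-truth labels are returned only in the
#' \code{truth} sidecar, never inside the trial table.
#'
#' @param spec a \code{\link{study_spec}}.
#' @param constants a \code{pcs_constants} list.
#' @return list with \code{tasks}, \code{trials} (all participants,
#'   row-bound), \code{truth} (per-participant generating parameters).
#' @export
simulate_study <- function(spec, constants = pcs_constants()) {
  stopifnot(inherits(spec, "study_spec"))
  tasks <- generate_task_set(spec$n_tasks, spec$validity_range,
                             seed = spec$seed)
  conds <- c(rep("intuition", spec$n_intuition),
             rep("deliberation", spec$n_deliberation))
  strategies <- if (identical(spec$allocation, "multinomial")) {
    set.seed(spec$seed)
    sample(names(spec$mixture), length(conds), replace = TRUE,
           prob = spec$mixture)
  } else {
    unlist(lapply(c("intuition", "deliberation"), function(cn) {
      n <- sum(conds == cn)
      rep(names(spec$mixture), allocate_mixture(spec$mixture, n))
    }))
  }
  out_trials <- vector("list", length(conds))
  out_truth <- vector("list", length(conds))
  for (i in seq_along(conds)) {
    a <- do.call(agent_spec,
                 c(list(strategy = strategies[i], condition = conds[i],
                        seed = (spec$seed * 10007L + i) %% 2147483647L),
                   spec$agent_args))
    sim <- simulate_participant(a, tasks, id = sprintf("p%03d", i),
                                constants = constants)
    out_trials[[i]] <- sim$trials
    out_truth[[i]] <- sim$truth
  }
  list(tasks = tasks,
       trials = do.call(rbind, out_trials),
       truth = do.call(rbind, out_truth))
}

#' Write / read simulated study data as plain text
#'
#' Trials go to a CSV; the ground-truth sidecar goes to a JSON file next
#' to it (same path with extension ".truth.json").
#'
#' @param study result of \code{\link{simulate_study}}.
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_study <- function(study, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(tasks = file.path(dir, "tasks.csv"),
             trials = file.path(dir, "trials.csv"),
             truth = file.path(dir, "truth.json"))
  write_tasks(study$tasks, paths[["tasks"]])
  utils::write.csv(study$trials, paths[["trials"]], row.names = FALSE)
  jsonlite::write_json(study$truth, paths[["truth"]], dataframe = "rows",
                       digits = NA)
  invisible(paths)
}

#' @rdname write_study
#' @export
read_study <- function(dir) {
  list(tasks = read_tasks(file.path(dir, "tasks.csv")),
       trials = utils::read.csv(file.path(dir, "trials.csv"),
                                stringsAsFactors = FALSE),
       truth = if (file.exists(file.path(dir, "truth.json")))
         as.data.frame(jsonlite::read_json(file.path(dir, "truth.json"),
                                           simplifyVector = TRUE))
       else NULL)
}
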