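#' Apply the study's exclusion rules
#'
#' Participant level: anyone solving fewer than \code{bayes_threshold}
#' (default 55%) of the tasks in accordance with the naive Bayesian
#' solution is removed (tie tasks do not count). Trial level, applied to
#' decision times only: trials slower than \code{rt_max_ms} (default
#' 60 s) and trials farther than \code{sd_mult} (default 3) standard
#' deviations from the grand mean across all kept participants are
#' censored by setting \code{rt_ms} to NA; choices and confidences are
#' retained. The 3-SD screen runs on the ln scale by default, consistent
#' with the downstream ln-time analyses; set \code{sd_scale = "raw"} for
#' raw milliseconds.
#'
#' @param trials trial table (columns participant, condition, trial_index,
#'   task_id, choice, rt_ms, confidence).
#' @param tasks the \code{task_set} the trials refer to.
#' @param bayes_threshold minimal proportion of Bayes-consistent choices.
#' @param rt_max_ms slow-trial cutoff in ms.
#' @param sd_mult SD multiplier of the grand-mean screen.
#' @param sd_scale "ln" or "raw".
#' @return list with \code{trials} (kept participants, censored RTs) and
#'   \code{log} (exclusion counts and ids).
#' @export
apply_exclusions <- function(trials, tasks, bayes_threshold = 0.55,
                             rt_max_ms = 60000, sd_mult = 3,
                             sd_scale = c("ln", "raw")) {
  sd_scale <- match.arg(sd_scale)
  nb <- vapply(tasks, function(t) naive_bayes(t)$superior, "")
  names(nb) <- vapply(tasks, `[[`, "", "id")
  correct <- trials$choice == nb[trials$task_id]
  scorable <- nb[trials$task_id] != "tie"
  rate <- tapply(correct[scorable], trials$participant[scorable], mean)
  excluded_participants <- names(rate)[rate < bayes_threshold]
  kept <- trials[!(trials$participant %in% excluded_participants), , drop = FALSE]
  slow <- is.finite(kept$rt_ms) & kept$rt_ms > rt_max_ms
  kept$rt_ms[slow] <- NA_real_
  x <- if (sd_scale == "ln") log(kept$rt_ms) else kept$rt_ms
  gm <- mean(x, na.rm = TRUE); gs <- stats::sd(x, na.rm = TRUE)
  outlier <- is.finite(x) & abs(x - gm) > sd_mult * gs
  kept$rt_ms[outlier] <- NA_real_
  list(trials = kept,
       log = list(participants_in = length(unique(trials$participant)),
                  participants_excluded = excluded_participants,
                  participants_kept = length(unique(kept$participant)),
                  bayes_rate = rate,
                  trials_in = nrow(kept),
                  trials_rt_max = sum(slow),
                  trials_sd = sum(outlier),
                  trials_excluded_total = sum(slow) + sum(outlier),
                  sd_scale = sd_scale))
}

#' Preprocess decision times
#'
#' ln-transforms decision times and partials out linear trial-order
#' effects per participant: \code{lnrt} holds the residual of ln RT
#' regressed on trial index, re-centered at the participant's mean ln RT.
#' Censored trials (NA \code{rt_ms}) stay NA.
#'
#' @param trials trial table (after \code{\link{apply_exclusions}}).
#' @return the trial table with an \code{lnrt} column.
#' @export
preprocess_times <- function(trials) {
  parts <- split(seq_len(nrow(trials)), trials$participant)
  trials$lnrt <- NA_real_
  for (idx in parts) {
    sub <- trials[idx, , drop = FALSE]
    if (sum(is.finite(sub$rt_ms)) < 3L)
      stop("fewer than 3 usable RT trials for participant ", sub$participant[1])
    trials$lnrt[idx] <- derive_lnrt(sub)
  }
  trials
}

# PCS_fitted predictions at a fitted P, reusing a grid cache when it covers P
fitted_predictions <- function(P, tasks, cache, constants) {
  key <- format_P(P)
  if (!is.null(cache) && key %in% names(cache)) return(cache[[key]])
  strategy_predictions(tasks, "PCS_fitted", P = P, constants = constants)
}

# strategy prediction tables for a task set, honoring per-participant
# fitted P for PCS_fitted
prediction_tables <- function(tasks, strategies, constants) {
  out <- lapply(strategies, function(s) {
    if (s == "PCS_fitted") NULL
    else strategy_predictions(tasks, s, P = 1.9, constants = constants)
  })
  names(out) <- strategies
  out
}

#' Per-condition choice adherence table
#'
#' Adherence is the proportion of a participant's choices matching a
#' strategy's deterministic predictions; trials on which the strategy
#' predicts random choice are excluded from the denominator. Participants
#' are averaged within condition. For PCS_fitted, per-participant fitted
#' P values must be supplied (adherence is to the fitted network's
#' preferred option).
#'
#' @param trials trial table.
#' @param tasks the \code{task_set}.
#' @param strategies strategies to score.
#' @param fitted_P named vector (participant -> fitted P), required when
#'   "PCS_fitted" is scored.
#' @param constants a \code{pcs_constants} list.
#' @param cache optional \code{\link{pcs_grid_predictions}} cache; reused
#'   for fitted-P predictions that lie on the cached grid.
#' @return data.frame: condition (plus "overall"), n, one column per
#'   strategy with mean adherence, and matching "se_" columns.
#' @export
adherence_table <- function(trials, tasks, strategies = strategy_names(),
                            fitted_P = NULL, constants = pcs_constants(),
                            cache = NULL) {
  if ("PCS_fitted" %in% strategies && is.null(fitted_P))
    stop("PCS_fitted adherence needs per-participant fitted P values")
  tabs <- prediction_tables(tasks, strategies, constants)
  per_part <- adherence_by_participant(trials, tasks, strategies, tabs,
                                       fitted_P, constants, cache)
  summarize_by_condition(per_part, strategies)
}

adherence_by_participant <- function(trials, tasks, strategies, tabs,
                                     fitted_P, constants, cache = NULL) {
  parts <- split(trials, trials$participant)
  rows <- lapply(names(parts), function(pid) {
    tr <- parts[[pid]]
    vals <- vapply(strategies, function(s) {
      preds <- if (s == "PCS_fitted")
        fitted_predictions(fitted_P[[pid]], tasks, cache, constants)
      else tabs[[s]]
      d <- align_trials(tr, preds)
      use <- d$pred_choice != "random"
      if (!any(use)) return(NA_real_)
      mean(d$choice[use] == d$pred_choice[use])
    }, 0)
    cbind(data.frame(participant = pid, condition = tr$condition[1],
                     stringsAsFactors = FALSE),
          as.data.frame(as.list(vals)))
  })
  do.call(rbind, rows)
}

summarize_by_condition <- function(per_part, cols) {
  groups <- c(split(per_part, per_part$condition), list(overall = per_part))
  out <- lapply(names(groups), function(g) {
    df <- groups[[g]]
    m <- vapply(cols, function(s) mean(df[[s]], na.rm = TRUE), 0)
    se <- vapply(cols, function(s) {
      x <- df[[s]][!is.na(df[[s]])]
      stats::sd(x) / sqrt(length(x))
    }, 0)
    row <- data.frame(condition = g, n = nrow(df))
    row[cols] <- as.list(m)
    row[paste0("se_", cols)] <- as.list(se)
    row
  })
  do.call(rbind, out)
}

#' Per-condition prediction-behavior correlation table
#'
#' For every participant and strategy, the Pearson correlation between
#' the preprocessed ln decision times and the strategy's time contrast,
#' and between confidence ratings and the confidence contrast. Individual
#' correlations are averaged within condition via the Fisher
#' z-transformation (mean of atanh(r), mapped back through tanh).
#' Correlations against a zero-variance contrast (the constant EIP time
#' predictions of EQW and WADD_c) are reported as 0.
#'
#' @inheritParams adherence_table
#' @return data.frame: measure ("time"/"confidence"), condition, n, one
#'   column per strategy.
#' @export
correlation_table <- function(trials, tasks, strategies = strategy_names(),
                              fitted_P = NULL, constants = pcs_constants(),
                              cache = NULL) {
  if ("PCS_fitted" %in% strategies && is.null(fitted_P))
    stop("PCS_fitted correlations need per-participant fitted P values")
  if (is.null(trials$lnrt)) trials <- preprocess_times(trials)
  tabs <- prediction_tables(tasks, strategies, constants)
  parts <- split(trials, trials$participant)
  safe_cor <- function(y, x) {
    ok <- is.finite(y) & is.finite(x)
    if (sum(ok) < 3L || stats::var(x[ok]) == 0 || stats::var(y[ok]) == 0)
      return(0)
    stats::cor(y[ok], x[ok])
  }
  per_part <- do.call(rbind, lapply(names(parts), function(pid) {
    tr <- parts[[pid]]
    rows <- lapply(strategies, function(s) {
      preds <- if (s == "PCS_fitted")
        fitted_predictions(fitted_P[[pid]], tasks, cache, constants)
      else tabs[[s]]
      d <- align_trials(tr, preds)
      data.frame(participant = pid, condition = tr$condition[1], strategy = s,
                 r_time = safe_cor(d$lnrt, d$pred_time_contrast),
                 r_conf = safe_cor(d$confidence, d$pred_conf_contrast),
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  }))
  fisher_mean <- function(r) {
    z <- atanh(pmin(pmax(r, -1 + 1e-12), 1 - 1e-12))
    tanh(mean(z, na.rm = TRUE))
  }
  groups <- c(split(per_part, per_part$condition), list(overall = per_part))
  out <- lapply(c("time", "confidence"), function(meas) {
    col <- if (meas == "time") "r_time" else "r_conf"
    do.call(rbind, lapply(names(groups), function(g) {
      df <- groups[[g]]
      row <- data.frame(measure = meas, condition = g,
                        n = length(unique(df$participant)))
      for (s in strategies)
        row[[s]] <- fisher_mean(df[[col]][df$strategy == s])
      row
    }))
  })
  do.call(rbind, out)
}

#' Performance against the naive Bayesian benchmark
#'
#' Proportion of trials on which the Bayes-superior option was chosen,
#' per participant, then averaged by condition. Tie tasks are skipped.
#'
#' @param trials trial table.
#' @param tasks the \code{task_set}.
#' @return data.frame: condition (plus "overall"), n, mean, sd.
#' @export
performance_scores <- function(trials, tasks) {
  nb <- vapply(tasks, function(t) naive_bayes(t)$superior, "")
  names(nb) <- vapply(tasks, `[[`, "", "id")
  use <- nb[trials$task_id] != "tie"
  correct <- trials$choice[use] == nb[trials$task_id[use]]
  per <- tapply(correct, trials$participant[use], mean)
  cond <- tapply(trials$condition[use], trials$participant[use], `[`, 1)
  df <- data.frame(participant = names(per), condition = as.vector(cond),
                   performance = as.vector(per), stringsAsFactors = FALSE)
  groups <- c(split(df, df$condition), list(overall = df))
  do.call(rbind, lapply(names(groups), function(g) {
    data.frame(condition = g, n = nrow(groups[[g]]),
               mean = mean(groups[[g]]$performance),
               sd = stats::sd(groups[[g]]$performance))
  }))
}

# chi-square test of the winner distribution across conditions; strategies
# nobody was assigned to carry no information and are dropped first
distribution_chisq <- function(distribution) {
  tab <- distribution[, colSums(distribution) > 0, drop = FALSE]
  if (nrow(tab) < 2L || ncol(tab) < 2L)
    return(list(statistic = c(`X-squared` = NA_real_), parameter = NA_integer_,
                p.value = NA_real_, method = "not applicable"))
  suppressWarnings(stats::chisq.test(tab))
}

#' Run the full study analysis
#'
#' Executes the complete pipeline on a trial table: exclusions, ln-time
#' preprocessing, MM-ML classification of every participant (with the
#' PCS grid search cached across participants), optional six-fold
#' cross-validated classification, the per-condition strategy
#' distributions with a chi-square test of their difference, adherence
#' and Fisher-z correlation tables, performance against the naive Bayes
#' benchmark, and the comparison of fitted P between conditions
#' (Wilcoxon rank-sum).
#'
#' @param trials trial table (see \code{\link{simulate_participant}} for
#'   the column schema).
#' @param tasks the \code{task_set}.
#' @param strategies candidate strategies for classification.
#' @param P_grid,lambda_grid PCS search grids.
#' @param constants a \code{pcs_constants} list.
#' @param crossval run the six-fold cross-validated classification too.
#' @param cv_folds,cv_seed cross-validation settings.
#' @param exclusions arguments passed to \code{\link{apply_exclusions}}.
#' @return list of class \code{study_report}; see Details.
#' @details The report contains \code{exclusion_log},
#'   \code{classification} (per-participant winner, fitted P and lambda,
#'   misfit flag, BICs), \code{distribution} (condition x strategy
#'   counts), \code{chisq} (the distribution test), \code{cv_*}
#'   analogues when \code{crossval = TRUE}, \code{adherence},
#'   \code{correlations}, \code{performance}, \code{P_by_condition}
#'   (means, SDs and the rank-sum test), and \code{alpha_note} on
#'   multiple-testing handling.
#' @export
run_study_report <- function(trials, tasks,
                             strategies = strategy_names(),
                             P_grid = seq(0, 5, by = 0.1),
                             lambda_grid = seq(0, 5, by = 0.1),
                             constants = pcs_constants(),
                             crossval = FALSE, cv_folds = 6L, cv_seed = 1L,
                             exclusions = list()) {
  excl <- do.call(apply_exclusions, c(list(trials = trials, tasks = tasks),
                                      exclusions))
  kept <- preprocess_times(excl$trials)
  cache <- if ("PCS_fitted" %in% strategies)
    pcs_grid_predictions(tasks, P_grid, constants) else NULL
  tabs <- prediction_tables(tasks, strategies, constants)
  parts <- split(kept, kept$participant)
  cls <- lapply(parts, classify, tasks = tasks, strategies = strategies,
                P_grid = P_grid, lambda_grid = lambda_grid,
                constants = constants, cache = cache, pred_tables = tabs)
  classification <- data.frame(
    participant = names(parts),
    condition = vapply(parts, function(d) d$condition[1], ""),
    winner = vapply(cls, `[[`, "", "winner"),
    P_star = vapply(cls, `[[`, 0, "P_star"),
    lambda_star = vapply(cls, `[[`, 0, "lambda_star"),
    misfit = vapply(cls, function(x) isTRUE(x$misfit$flag), NA),
    stringsAsFactors = FALSE, row.names = NULL)
  distribution <- table(condition = classification$condition,
                        strategy = factor(classification$winner,
                                          levels = strategies))
  chisq <- distribution_chisq(distribution)
  fitted_P <- stats::setNames(classification$P_star, classification$participant)
  adher <- adherence_table(kept, tasks, strategies, fitted_P, constants, cache)
  corr <- correlation_table(kept, tasks, strategies, fitted_P, constants, cache)
  perf <- performance_scores(kept, tasks)
  P_test <- if ("PCS_fitted" %in% strategies &&
                length(unique(classification$condition)) == 2L)
    suppressWarnings(stats::wilcox.test(P_star ~ condition, classification))
  else NULL
  P_by_condition <- do.call(rbind, lapply(
    split(classification, classification$condition), function(df)
      data.frame(condition = df$condition[1], n = nrow(df),
                 mean_P = mean(df$P_star), sd_P = stats::sd(df$P_star))))
  report <- list(exclusion_log = excl$log,
                 classification = classification,
                 distribution = distribution, chisq = chisq,
                 adherence = adher, correlations = corr,
                 performance = perf,
                 P_by_condition = P_by_condition, P_test = P_test,
                 strategies = strategies,
                 alpha_note = paste("alpha = .05;",
                                    "Bonferroni-corrected alpha for families",
                                    "of exploratory tests is .05 / #tests"))
  if (crossval) {
    cvs <- lapply(parts, crossval_classify, tasks = tasks,
                  strategies = strategies, folds = cv_folds, seed = cv_seed,
                  P_grid = P_grid, lambda_grid = lambda_grid,
                  constants = constants, cache = cache, pred_tables = tabs)
    report$cv_classification <- data.frame(
      participant = names(parts),
      condition = vapply(parts, function(d) d$condition[1], ""),
      winner = vapply(cvs, `[[`, "", "winner"),
      stringsAsFactors = FALSE, row.names = NULL)
    report$cv_distribution <- table(
      condition = report$cv_classification$condition,
      strategy = factor(report$cv_classification$winner, levels = strategies))
    report$cv_chisq <- distribution_chisq(report$cv_distribution)
  }
  structure(report, class = "study_report")
}

#' @export
print.study_report <- function(x, ...) {
  cat("Study report:", x$exclusion_log$participants_kept, "participants kept,",
      x$exclusion_log$trials_excluded_total, "RT trials censored\n\n")
  cat("Strategy distribution (BIC classification):\n")
  print(x$distribution)
  cat(sprintf("\nchi-square(%d) = %.2f, p = %.3f\n",
              x$chisq$parameter, unname(x$chisq$statistic), x$chisq$p.value))
  cat("\nMean fitted P by condition:\n")
  print(x$P_by_condition, row.names = FALSE)
  cat("\nPerformance vs. naive Bayes:\n")
  print(x$performance, row.names = FALSE)
  invisible(x)
}

#' Write a study report's tables to a directory
#'
#' All tables as CSV, plus a JSON summary of the headline quantities.
#'
#' @param report a \code{study_report}.
#' @param dir output directory (created if needed).
#' @return invisibly, the directory.
#' @export
write_study_report <- function(report, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  utils::write.csv(report$classification,
                   file.path(dir, "classification.csv"), row.names = FALSE)
  utils::write.csv(as.data.frame(report$distribution),
                   file.path(dir, "distribution.csv"), row.names = FALSE)
  utils::write.csv(report$adherence, file.path(dir, "adherence.csv"),
                   row.names = FALSE)
  utils::write.csv(report$correlations, file.path(dir, "correlations.csv"),
                   row.names = FALSE)
  utils::write.csv(report$performance, file.path(dir, "performance.csv"),
                   row.names = FALSE)
  summary <- list(
    participants_kept = report$exclusion_log$participants_kept,
    trials_censored = report$exclusion_log$trials_excluded_total,
    chisq_statistic = unname(report$chisq$statistic),
    chisq_p = report$chisq$p.value,
    mean_P = stats::setNames(report$P_by_condition$mean_P,
                             report$P_by_condition$condition),
    alpha_note = report$alpha_note)
  jsonlite::write_json(summary, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
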