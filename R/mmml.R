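#' Transform raw predictions into contrast weights
#'
#' Raw time and confidence predictions are only defined up to their
#' ordering and spacing, so they enter the likelihood as contrasts that
#' sum to zero and have a range of one: (x - mean(x)) / (max(x) - min(x)).
#' A constant input (e.g., the constant EIP time of EQW or WADD_c) yields
#' the all-zero vector. The transform is invariant under positive affine
#' rescaling of the raw predictions.
#'
#' @param x numeric vector of at least 2 raw predictions.
#' @return contrast vector of the same length.
#' @export
contrastify <- function(x) {
  stopifnot(is.numeric(x), length(x) >= 2L)
  rng <- max(x) - min(x)
  if (rng == 0) return(numeric(length(x)))
  (x - mean(x)) / rng
}

strategy_names <- function() c("EQW", "PCS_fitted", "PCS_fix", "TTB", "WADDc")

# ln-transform RTs and partial out a linear trial-order trend, per participant
derive_lnrt <- function(trials) {
  lnrt <- rep(NA_real_, nrow(trials))
  ok <- is.finite(trials$rt_ms) & trials$rt_ms > 0
  y <- log(trials$rt_ms[ok])
  if (sum(ok) >= 3L) {
    fit <- stats::lm.fit(cbind(1, trials$trial_index[ok]), y)
    lnrt[ok] <- fit$residuals + mean(y)
  } else lnrt[ok] <- y
  lnrt
}

# align participant trials with a strategy's prediction table by task id;
# prediction columns are prefixed "pred_"
align_trials <- function(trials, predictions) {
  idx <- match(trials$task_id, predictions$task_id)
  if (anyNA(idx))
    stop("participant trials reference task ids absent from the prediction table")
  if (is.null(trials$lnrt) && !is.null(trials$rt_ms))
    trials$lnrt <- derive_lnrt(trials)
  p <- predictions[idx, setdiff(names(predictions), "task_id"), drop = FALSE]
  names(p) <- paste0("pred_", names(p))
  cbind(trials, p)
}

# Gaussian measurement model: y ~ N(mu + beta * contrast, sigma^2), beta >= 0,
# ML sigma (divide by n). Zero-variance contrast or negative slope collapses
# to the intercept-only model with beta fixed at 0.
fit_gaussian_component <- function(y, contrast, sigma_floor = 1e-6) {
  use <- is.finite(y)
  y <- y[use]; x <- contrast[use]
  n <- length(y)
  if (n < 3L) stop("fewer than 3 usable trials for a Gaussian measure")
  beta <- 0
  if (stats::var(x) > 0) {
    b <- stats::cov(y, x) / stats::var(x)
    if (b > 0) beta <- b
  }
  mu <- mean(y) - beta * mean(x)
  resid <- y - mu - beta * x
  sigma <- max(sqrt(mean(resid^2)), sigma_floor)
  list(mu = mu, beta = beta, sigma = sigma,
       logL = sum(stats::dnorm(y, mu + beta * x, sigma, log = TRUE)),
       n = n)
}

gaussian_loglik <- function(y, contrast, par, sigma_floor = 1e-6) {
  use <- is.finite(y)
  sum(stats::dnorm(y[use], par$mu + par$beta * contrast[use],
                   max(par$sigma, sigma_floor), log = TRUE))
}

# Bernoulli choice log-likelihood. Deterministic strategies: constant error
# rate epsilon on non-random trials, p = .5 where random choice is predicted.
# PCS_fitted: logistic in the signed activation difference.
choice_loglik_epsilon <- function(match, random, epsilon) {
  n_match <- sum(!random & match)
  n_mis <- sum(!random & !match)
  ll <- sum(random) * log(0.5)
  if (n_match > 0) ll <- ll + n_match * log(1 - epsilon)
  if (n_mis > 0) ll <- ll + n_mis * log(epsilon)
  ll
}

choice_loglik_lambda <- function(signed_adiff, lambda) {
  # signed_adiff: activation difference in favor of the *observed* choice
  sum(stats::plogis(lambda * signed_adiff, log.p = TRUE))
}

#' Log-likelihood components of one strategy for one participant
#'
#' Evaluates (does not fit) the multiple-measure log-likelihood of a
#' participant's trials under a strategy's predictions at given parameter
#' values: Bernoulli choices, Gaussian preprocessed ln decision times
#' around the strategy's time contrast, and Gaussian confidences around
#' the confidence contrast.
#'
#' @param trials data.frame with columns \code{task_id}, \code{choice}
#'   ("A"/"B"), and, per measure used, \code{lnrt} (preprocessed ln RT;
#'   derived from \code{rt_ms}/\code{trial_index} when absent) and
#'   \code{confidence}. NAs are excluded trials.
#' @param predictions a \code{\link{strategy_predictions}} table.
#' @param par list with \code{epsilon} (deterministic strategies) or
#'   \code{lambda} (PCS_fitted), and per Gaussian measure a list
#'   \code{(mu, beta, sigma)} under \code{time} / \code{conf}.
#' @param measures subset of c("choice", "time", "confidence").
#' @return list of per-measure log-likelihoods, their total, and the
#'   observation count \code{n}.
#' @export
strategy_loglik <- function(trials, predictions, par,
                            measures = c("choice", "time", "confidence")) {
  measures <- match.arg(measures, several.ok = TRUE)
  d <- align_trials(trials, predictions)
  ll <- list(choice = 0, time = 0, confidence = 0)
  n <- 0L
  if ("choice" %in% measures) {
    if (!is.null(par$lambda)) {
      s <- ifelse(d$choice == "A", 1, -1) * d$pred_adiff
      ll$choice <- choice_loglik_lambda(s, par$lambda)
    } else {
      random <- d$pred_choice == "random"
      ll$choice <- choice_loglik_epsilon(d$choice == d$pred_choice, random, par$epsilon)
    }
    n <- n + sum(!is.na(d$choice))
  }
  if ("time" %in% measures) {
    ll$time <- gaussian_loglik(d$lnrt, d$pred_time_contrast, par$time)
    n <- n + sum(is.finite(d$lnrt))
  }
  if ("confidence" %in% measures) {
    ll$confidence <- gaussian_loglik(d$confidence, d$pred_conf_contrast, par$conf)
    n <- n + sum(is.finite(d$confidence))
  }
  list(choice = ll$choice, time = ll$time, confidence = ll$confidence,
       total = ll$choice + ll$time + ll$confidence, n = n)
}

mmml_param_count <- function(strategy, measures) {
  k <- 0L
  if ("choice" %in% measures)
    k <- k + if (strategy == "PCS_fitted") 3L else 1L
  k + 3L * sum(c("time", "confidence") %in% measures)
}

#' Fit one strategy to one participant by maximum likelihood
#'
#' Estimates the nuisance parameters of the MM-ML measurement model for a
#' fixed strategy prediction table: the choice error rate epsilon as the
#' observed error proportion on non-random trials (capped at .5), and the
#' Gaussian time and confidence models by least squares with the contrast
#' slope clamped at 0 if negative and ML (divide-by-n) sigma. For
#' PCS_fitted use \code{\link{grid_fit_pcs}}, which also searches P and
#' lambda.
#'
#' @inheritParams strategy_loglik
#' @param strategy name of a deterministic strategy ("TTB", "EQW",
#'   "WADDc", "PCS_fix").
#' @param sigma_floor lower bound for ML sigma estimates, guarding the
#'   noise-free limit.
#' @return object of class \code{mmml_fit}: strategy, fitted parameters,
#'   per-measure log-likelihoods, \code{k}, \code{n}, \code{BIC}.
#' @export
fit_strategy <- function(trials, predictions,
                         strategy = attr(predictions, "strategy"),
                         measures = c("choice", "time", "confidence"),
                         sigma_floor = 1e-6) {
  measures <- match.arg(measures, several.ok = TRUE)
  d <- align_trials(trials, predictions)
  par <- list()
  if ("choice" %in% measures) {
    random <- d$pred_choice == "random"
    mism <- sum(!random & (d$choice != d$pred_choice))
    n_det <- sum(!random)
    par$epsilon <- if (n_det == 0L) 0.5 else min(mism / n_det, 0.5)
  }
  if ("time" %in% measures) {
    if (is.null(d$lnrt)) stop("time measure requires lnrt or rt_ms")
    g <- fit_gaussian_component(d$lnrt, d$pred_time_contrast, sigma_floor)
    par$time <- g[c("mu", "beta", "sigma")]
  }
  if ("confidence" %in% measures)
    par$conf <- fit_gaussian_component(d$confidence, d$pred_conf_contrast,
                                       sigma_floor)[c("mu", "beta", "sigma")]
  ll <- strategy_loglik(trials, predictions, par, measures)
  k <- mmml_param_count(strategy, measures)
  structure(list(strategy = strategy, par = par, P = attr(predictions, "P"),
                 logL = ll, k = k, n = ll$n,
                 BIC = -2 * ll$total + k * log(ll$n),
                 predictions = predictions, measures = measures),
            class = "mmml_fit")
}

#' @export
print.mmml_fit <- function(x, ...) {
  cat(sprintf("MM-ML fit: %s  logL = %.2f (choice %.2f, time %.2f, conf %.2f)\n",
              x$strategy, x$logL$total, x$logL$choice, x$logL$time,
              x$logL$confidence))
  cat(sprintf("  k = %d, n = %d, BIC = %.2f\n", x$k, x$n, x$BIC))
  invisible(x)
}

#' Precompute PCS predictions over a grid of P values
#'
#' The network predictions depend on P but not on lambda, so a
#' classification run over many participants sharing one task set only
#' needs one network pass per (task, P) pair. The returned cache is a
#' named list of \code{\link{strategy_predictions}} tables.
#'
#' @param tasks a \code{task_set}.
#' @param P_grid numeric vector of P values.
#' @param constants a \code{pcs_constants} list.
#' @return named list mapping formatted P values to prediction tables.
#' @export
pcs_grid_predictions <- function(tasks, P_grid = seq(0, 5, by = 0.1),
                                 constants = pcs_constants()) {
  out <- lapply(P_grid, function(P)
    strategy_predictions(tasks, "PCS_fitted", P = P, constants = constants))
  names(out) <- format_P(P_grid)
  out
}

format_P <- function(P) sprintf("%.6g", P)

#' Grid-search fit of the PCS_fitted strategy
#'
#' Exhaustively searches the sensitivity parameter P and the determinism
#' parameter lambda (both over [0, 5] in steps of 0.1 by default) for the
#' combination maximizing the multiple-measure log-likelihood. The time
#' and confidence components depend on P only and are fit once per P;
#' the choice component is a logistic function of the signed activation
#' difference, vectorized over lambda. Exact likelihood ties break toward
#' the smallest P, then the smallest lambda.
#'
#' @inheritParams fit_strategy
#' @param tasks the \code{task_set} the participant responded to.
#' @param P_grid,lambda_grid search grids.
#' @param constants a \code{pcs_constants} list.
#' @param cache optional precomputed \code{\link{pcs_grid_predictions}};
#'   must cover \code{P_grid}.
#' @return an \code{mmml_fit} with additional elements \code{P_star} and
#'   \code{lambda_star}.
#' @export
grid_fit_pcs <- function(trials, tasks, P_grid = seq(0, 5, by = 0.1),
                         lambda_grid = seq(0, 5, by = 0.1),
                         constants = pcs_constants(), cache = NULL,
                         measures = c("choice", "time", "confidence"),
                         sigma_floor = 1e-6) {
  measures <- match.arg(measures, several.ok = TRUE)
  if (is.null(cache)) cache <- pcs_grid_predictions(tasks, P_grid, constants)
  keys <- format_P(P_grid)
  if (!all(keys %in% names(cache)))
    stop("prediction cache does not cover the requested P grid")
  if (is.null(trials$lnrt) && !is.null(trials$rt_ms))
    trials$lnrt <- derive_lnrt(trials)
  nP <- length(P_grid); nL <- length(lambda_grid)
  gauss_ll <- numeric(nP)
  choice_ll <- matrix(0, nP, nL)
  for (i in seq_len(nP)) {
    preds <- cache[[keys[i]]]
    d <- align_trials(trials, preds)
    if ("time" %in% measures)
      gauss_ll[i] <- gauss_ll[i] +
        fit_gaussian_component(d$lnrt, d$pred_time_contrast, sigma_floor)$logL
    if ("confidence" %in% measures)
      gauss_ll[i] <- gauss_ll[i] +
        fit_gaussian_component(d$confidence, d$pred_conf_contrast, sigma_floor)$logL
    if ("choice" %in% measures) {
      s <- ifelse(d$choice == "A", 1, -1) * d$pred_adiff
      choice_ll[i, ] <- colSums(stats::plogis(outer(s, lambda_grid), log.p = TRUE))
    }
  }
  total <- choice_ll + gauss_ll
  best <- which(total == max(total), arr.ind = TRUE)
  best <- best[order(best[, 1], best[, 2]), , drop = FALSE][1, ]
  P_star <- P_grid[best[1]]; lambda_star <- lambda_grid[best[2]]
  preds <- cache[[keys[best[1]]]]
  par <- list(lambda = lambda_star)
  d <- align_trials(trials, preds)
  if ("time" %in% measures)
    par$time <- fit_gaussian_component(d$lnrt, d$pred_time_contrast,
                                       sigma_floor)[c("mu", "beta", "sigma")]
  if ("confidence" %in% measures)
    par$conf <- fit_gaussian_component(d$confidence, d$pred_conf_contrast,
                                       sigma_floor)[c("mu", "beta", "sigma")]
  ll <- strategy_loglik(trials, preds, par, measures)
  k <- mmml_param_count("PCS_fitted", measures)
  structure(list(strategy = "PCS_fitted", par = par,
                 P = P_star, P_star = P_star, lambda_star = lambda_star,
                 logL = ll, k = k, n = ll$n,
                 BIC = -2 * ll$total + k * log(ll$n),
                 predictions = preds, measures = measures),
            class = "mmml_fit")
}

#' Classify a participant to a decision strategy by BIC
#'
#' Fits every candidate strategy with \code{\link{fit_strategy}} (or
#' \code{\link{grid_fit_pcs}} for PCS_fitted) and assigns the participant
#' to the strategy with the smallest BIC = -2 logL + k ln(n). BIC ties
#' break toward fewer parameters, then alphabetically. The winner's choice
#' component is screened against a saturated model
#' (\code{\link{saturated_misfit_test}}).
#'
#' @inheritParams grid_fit_pcs
#' @param strategies candidate strategy names.
#' @param pred_tables optional named list of precomputed
#'   \code{\link{strategy_predictions}} tables for the deterministic
#'   strategies; classification runs over many participants sharing one
#'   task set should compute these once.
#' @return object of class \code{classification_result}: list of fits,
#'   \code{winner}, \code{P_star}/\code{lambda_star} (NA unless
#'   PCS_fitted was fit), \code{misfit} (the saturated-model test on the
#'   winner, NULL when "choice" is not among the measures).
#' @export
classify <- function(trials, tasks,
                     strategies = strategy_names(),
                     P_grid = seq(0, 5, by = 0.1),
                     lambda_grid = seq(0, 5, by = 0.1),
                     constants = pcs_constants(), cache = NULL,
                     measures = c("choice", "time", "confidence"),
                     sigma_floor = 1e-6, pred_tables = NULL) {
  stopifnot(length(strategies) >= 2L)
  measures <- match.arg(measures, several.ok = TRUE)
  if (is.null(trials$lnrt) && !is.null(trials$rt_ms))
    trials$lnrt <- derive_lnrt(trials)
  fits <- lapply(strategies, function(s) {
    if (s == "PCS_fitted")
      grid_fit_pcs(trials, tasks, P_grid, lambda_grid, constants, cache,
                   measures, sigma_floor)
    else {
      preds <- if (!is.null(pred_tables[[s]])) pred_tables[[s]]
      else strategy_predictions(tasks, s, P = 1.9, constants = constants)
      fit_strategy(trials, preds, strategy = s, measures = measures,
                   sigma_floor = sigma_floor)
    }
  })
  names(fits) <- strategies
  bic <- vapply(fits, `[[`, 0, "BIC")
  k <- vapply(fits, `[[`, 0L, "k")
  ord <- order(bic, k, strategies)
  winner <- strategies[ord[1]]
  wf <- fits[[winner]]
  misfit <- if ("choice" %in% measures)
    saturated_misfit_test(trials, wf) else NULL
  structure(list(fits = fits, winner = winner,
                 P_star = if (!is.null(fits$PCS_fitted)) fits$PCS_fitted$P_star else NA_real_,
                 lambda_star = if (!is.null(fits$PCS_fitted)) fits$PCS_fitted$lambda_star else NA_real_,
                 BIC = bic, misfit = misfit),
            class = "classification_result")
}

#' @export
print.classification_result <- function(x, ...) {
  cat("MM-ML classification; winner:", x$winner, "\n")
  print(round(sort(x$BIC), 2))
  if (!is.null(x$misfit))
    cat(sprintf("saturated-model choice misfit: G2 = %.2f, df = %d, p = %.3f%s\n",
                x$misfit$G2, x$misfit$df, x$misfit$p,
                if (x$misfit$flag) "  *MISFIT*" else ""))
  invisible(x)
}

#' Saturated-model check of the winning strategy's choice fit
#'
#' Compares the winner's choice log-likelihood against a saturated model
#' with one free choice probability per distinct cue pattern (task), via
#' the likelihood-ratio statistic G2 = 2 (logL_sat - logL_winner) referred
#' to a chi-square distribution with (number of patterns - number of
#' choice parameters) degrees of freedom. Trials on which the strategy
#' predicts random choice are excluded, consistent with their treatment
#' in adherence scoring. A significant G2 (alpha = .05) flags that even
#' the best strategy misrepresents the participant's choice pattern.
#'
#' @inheritParams strategy_loglik
#' @param fit the winning \code{mmml_fit}.
#' @param alpha significance level of the chi-square test.
#' @return list with \code{G2}, \code{df}, \code{p}, \code{flag}.
#' @export
saturated_misfit_test <- function(trials, fit, alpha = 0.05) {
  d <- align_trials(trials, fit$predictions)
  nonrandom <- if (!is.null(fit$par$lambda)) d$pred_adiff != 0 else d$pred_choice != "random"
  d <- d[nonrandom, , drop = FALSE]
  if (nrow(d) == 0L)
    return(list(G2 = 0, df = 0L, p = 1, flag = FALSE))
  y <- as.integer(d$choice == "A")
  p_hat <- tapply(y, d$task_id, mean)
  n_g <- tapply(y, d$task_id, length)
  y_g <- tapply(y, d$task_id, sum)
  # per pattern: y log p + (n - y) log(1 - p), with 0 log 0 = 0
  logL_sat <- sum(ifelse(y_g > 0, y_g * log(p_hat), 0) +
                  ifelse(n_g - y_g > 0, (n_g - y_g) * log(1 - p_hat), 0))
  if (!is.null(fit$par$lambda)) {
    s <- ifelse(d$choice == "A", 1, -1) * d$pred_adiff
    logL_win <- choice_loglik_lambda(s, fit$par$lambda)
    k_choice <- 2L
  } else {
    logL_win <- choice_loglik_epsilon(d$choice == d$pred_choice,
                                      rep(FALSE, nrow(d)), fit$par$epsilon)
    k_choice <- 1L
  }
  G2 <- max(2 * (logL_sat - logL_win), 0)
  df <- max(length(p_hat) - k_choice, 1L)
  p <- stats::pchisq(G2, df, lower.tail = FALSE)
  list(G2 = G2, df = df, p = p, flag = p < alpha)
}

#' Cross-validated strategy classification
#'
#' Partitions a participant's trials into k folds (seeded), refits every
#' strategy's parameters — including the PCS grid search — on the
#' remaining folds, and accumulates the held-out log-likelihood of each
#' strategy. The winner is the strategy with the largest summed
#' out-of-sample log-likelihood; no BIC penalty is applied because no
#' parameter is fit to the held-out data.
#'
#' @inheritParams classify
#' @param folds number of folds (default 6).
#' @param seed integer seed for the fold assignment.
#' @return list of class \code{cv_result}: \code{oos_logL} per strategy,
#'   \code{winner}, \code{folds} (the fold assignment).
#' @export
crossval_classify <- function(trials, tasks,
                              strategies = strategy_names(),
                              folds = 6L, seed = 1L,
                              P_grid = seq(0, 5, by = 0.1),
                              lambda_grid = seq(0, 5, by = 0.1),
                              constants = pcs_constants(), cache = NULL,
                              measures = c("choice", "time", "confidence"),
                              sigma_floor = 1e-6, pred_tables = NULL) {
  n <- nrow(trials)
  if (n < 2L * folds) stop("need at least ", 2L * folds, " trials for ", folds, "-fold CV")
  measures <- match.arg(measures, several.ok = TRUE)
  if (is.null(trials$lnrt) && !is.null(trials$rt_ms))
    trials$lnrt <- derive_lnrt(trials)
  if (is.null(cache) && "PCS_fitted" %in% strategies)
    cache <- pcs_grid_predictions(tasks, P_grid, constants)
  fold_id <- local({
    set.seed(seed)
    sample(rep_len(seq_len(folds), n))
  })
  if (is.null(pred_tables)) {
    pred_tables <- lapply(strategies, function(s) {
      if (s == "PCS_fitted") NULL
      else strategy_predictions(tasks, s, P = 1.9, constants = constants)
    })
    names(pred_tables) <- strategies
  }
  oos <- stats::setNames(numeric(length(strategies)), strategies)
  for (f in seq_len(folds)) {
    train <- trials[fold_id != f, , drop = FALSE]
    test <- trials[fold_id == f, , drop = FALSE]
    for (s in strategies) {
      if (s == "PCS_fitted") {
        fit <- grid_fit_pcs(train, tasks, P_grid, lambda_grid, constants,
                            cache, measures, sigma_floor)
        preds <- fit$predictions
      } else {
        preds <- pred_tables[[s]]
        fit <- fit_strategy(train, preds, s, measures, sigma_floor)
      }
      par <- fit$par
      # held-out scoring: a vanishing smoothing floor (half a pseudo-mismatch
      # spread over the training trials) keeps the score finite when a
      # boundary estimate epsilon = 0 meets an unseen mismatch, without
      # distorting the noise-free limit
      if (!is.null(par$epsilon))
        par$epsilon <- min(max(par$epsilon, 0.5 / nrow(train)^2), 0.5)
      oos[s] <- oos[s] + strategy_loglik(test, preds, par, measures)$total
    }
  }
  winner <- strategies[order(-oos, strategies)[1]]
  structure(list(oos_logL = oos, winner = winner, folds = fold_id, seed = seed),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat("Cross-validated classification; winner:", x$winner, "\n")
  print(round(sort(x$oos_logL, decreasing = TRUE), 2))
  invisible(x)
}
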