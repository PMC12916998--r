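test_that("contrastify centers to zero sum and unit range", {
  expect_equal(contrastify(c(1, 2, 3)), c(-0.5, 0, 0.5))
  expect_identical(contrastify(rep(7, 10)), numeric(10))
  set.seed(2)
  for (i in 1:20) {
    x <- rnorm(60, sd = 10)
    cx <- contrastify(x)
    expect_lt(abs(sum(cx)), 1e-12)
    expect_equal(max(cx) - min(cx), 1, tolerance = 1e-12)
    # positive affine invariance
    expect_equal(contrastify(3.7 * x + 11), cx, tolerance = 1e-12)
  }
})

test_that("an error rate of .5 makes choices maximally uninformative", {
  tasks <- fixture_tasks()
  preds <- strategy_predictions(tasks, "TTB")
  trials <- noise_free_trials("TTB", tasks)
  ll <- strategy_loglik(trials, preds, list(epsilon = 0.5), measures = "choice")
  expect_equal(ll$choice, 60 * log(0.5))
  expect_equal(ll$total, ll$choice)
  # flipping every choice changes nothing at epsilon .5
  flipped <- trials
  flipped$choice <- ifelse(trials$choice == "A", "B", "A")
  expect_equal(strategy_loglik(flipped, preds, list(epsilon = 0.5),
                               measures = "choice")$choice, 60 * log(0.5))
})

test_that("a zero-variance contrast collapses to the intercept-only model", {
  tasks <- fixture_tasks()
  trials <- noise_free_trials("TTB", tasks)
  eqw <- strategy_predictions(tasks, "EQW")
  fit <- fit_strategy(trials, eqw)
  expect_identical(fit$par$time$beta, 0)
  # noise-free ln times are 8 + a zero-mean contrast, so the intercept is 8
  expect_equal(fit$par$time$mu, 8, tolerance = 1e-9)
})

test_that("log-likelihood components add up and BIC follows its formula", {
  expect_equal(-2 * (-100) + 7 * log(180), 236.3641, tolerance = 1e-4)
  tasks <- fixture_tasks()
  sim <- simulate_participant(recovery_spec("WADDc", seed = 5), tasks)
  for (s in c("TTB", "EQW", "WADDc", "PCS_fix")) {
    fit <- fit_strategy(sim$trials, strategy_predictions(tasks, s))
    expect_equal(fit$logL$total,
                 fit$logL$choice + fit$logL$time + fit$logL$confidence)
    expect_equal(fit$BIC, -2 * fit$logL$total + fit$k * log(fit$n))
    expect_identical(fit$k, 7L)
    expect_identical(fit$n, 180L)
  }
})

test_that("epsilon is the error proportion, capped at one half", {
  tasks <- fixture_tasks()
  preds <- strategy_predictions(tasks, "TTB")
  trials <- noise_free_trials("TTB", tasks)
  flip <- function(tr, k) {
    tr$choice[seq_len(k)] <- ifelse(tr$choice[seq_len(k)] == "A", "B", "A")
    tr
  }
  expect_equal(fit_strategy(flip(trials, 6), preds)$par$epsilon, 0.1)
  expect_equal(fit_strategy(flip(trials, 40), preds)$par$epsilon, 0.5)
})

test_that("Gaussian slopes are recovered from noisy agents", {
  tasks <- fixture_tasks()
  sim <- simulate_participant(recovery_spec("TTB", seed = 73), tasks)
  fit <- fit_strategy(sim$trials, strategy_predictions(tasks, "TTB"))
  expect_gt(fit$par$time$beta, 0.9)
  expect_lt(fit$par$time$beta, 1.1)
  expect_gt(fit$par$conf$beta, 0.9)
  expect_lt(fit$par$conf$beta, 1.1)
})

test_that("a noise-free TTB agent is best explained by TTB on every measure", {
  tasks <- fixture_tasks()
  trials <- noise_free_trials("TTB", tasks)
  fits <- lapply(c("TTB", "EQW", "WADDc", "PCS_fix"), function(s)
    fit_strategy(trials, strategy_predictions(tasks, s)))
  totals <- vapply(fits, function(f) f$logL$total, 0)
  expect_identical(which.max(totals), 1L)
  expect_true(all(totals[1] > totals[-1]))
})

test_that("the BIC penalty prefers the fixed PCS variant when fits tie", {
  tasks <- fixture_tasks()
  trials <- noise_free_trials("PCS_fix", tasks)
  cl <- classify(trials, tasks, cache = fixture_cache())
  # PCS_fitted can match PCS_fix at the P = 1.9 grid point but carries two
  # more parameters
  expect_identical(cl$winner, "PCS_fix")
  expect_lt(cl$BIC[["PCS_fix"]], cl$BIC[["PCS_fitted"]])
})

test_that("the grid search recovers generating PCS parameters", {
  tasks <- fixture_tasks()
  sim <- simulate_participant(recovery_spec("PCS_fitted", seed = 19,
                                            P = 2.0, lambda = 4), tasks)
  fit <- grid_fit_pcs(sim$trials, tasks, cache = fixture_cache())
  expect_lt(abs(fit$P_star - 2.0), 0.3 + 1e-9)
  expect_gt(fit$lambda_star, 1)
})

test_that("an indifferent agent is fitted with lambda at or near zero", {
  tasks <- fixture_tasks()
  sim <- simulate_participant(recovery_spec("PCS_fitted", seed = 23,
                                            P = 2.0, lambda = 0), tasks)
  fit <- grid_fit_pcs(sim$trials, tasks, cache = fixture_cache())
  expect_lte(fit$lambda_star, 1)
})

test_that("a restricted P grid piles fits onto the corner", {
  tasks <- fixture_tasks()
  corner <- vapply(1:6, function(i) {
    sim <- simulate_participant(recovery_spec("PCS_fitted", seed = 100 + i,
                                              P = 3.0, lambda = 4), tasks)
    grid_fit_pcs(sim$trials, tasks, P_grid = seq(1, 2, by = 0.1),
                 cache = fixture_cache())$P_star
  }, 0)
  expect_true(mean(corner == 2) >= 5 / 6)
})

test_that("the saturated model never fits worse and flags random choosers", {
  tasks <- fixture_tasks()
  trials <- noise_free_trials("TTB", tasks)
  preds <- strategy_predictions(tasks, "TTB")
  fit <- fit_strategy(trials, preds)
  mis <- saturated_misfit_test(trials, fit)
  expect_equal(mis$G2, 0)
  expect_false(mis$flag)

  set.seed(61)
  rnd <- trials
  rnd$choice <- sample(c("A", "B"), nrow(rnd), replace = TRUE)
  rfit <- fit_strategy(rnd, preds)
  rmis <- saturated_misfit_test(rnd, rfit)
  expect_gte(rmis$G2, 0)
  expect_true(rmis$flag)
})

test_that("cross-validation recovers a noise-free agent perfectly", {
  tasks <- fixture_tasks()
  trials <- noise_free_trials("TTB", tasks)
  cv <- crossval_classify(trials, tasks, seed = 9, cache = fixture_cache())
  expect_identical(cv$winner, "TTB")
  expect_identical(sort(as.integer(table(cv$folds))), rep(10L, 6))
})
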