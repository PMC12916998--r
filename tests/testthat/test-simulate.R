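test_that("generated task sets satisfy every construction constraint", {
  ts <- generate_task_set(60, seed = 7)
  expect_length(ts, 60)
  sigs <- character()
  for (t in ts) {
    expect_true(all(t$validities >= 0.60 & t$validities <= 0.94))
    expect_true(all(diff(t$validities) <= 0))
    expect_false(t$dominated)
    # brute-force dominance re-check
    d <- t$cue_matrix[, 1] - t$cue_matrix[, 2]
    expect_false((all(d >= 0) || all(d <= 0)) && any(d != 0))
    expect_false(all(d == 0))
    expect_false(naive_bayes(t)$superior == "tie")
    sigs <- c(sigs, paste(c(t$validities, t$cue_matrix), collapse = "|"))
  }
  expect_identical(anyDuplicated(sigs), 0L)
  # determinism
  again <- generate_task_set(60, seed = 7)
  expect_equal(as.data.frame(again), as.data.frame(ts))
  # custom ranges are respected
  narrow <- generate_task_set(10, validity_range = c(0.70, 0.75), seed = 2)
  for (t in narrow)
    expect_true(all(t$validities >= 0.70 & t$validities <= 0.75))
})

test_that("noise-free agents adhere perfectly and sit at their means", {
  tasks <- fixture_tasks()
  spec <- agent_spec("WADDc", "intuition", epsilon = 0, sigma_T = 0,
                     sigma_C = 0, seed = 4)
  sim <- simulate_participant(spec, tasks)
  preds <- strategy_predictions(tasks, "WADDc")
  d <- merge(sim$trials, preds, by.x = "task_id", by.y = "task_id")
  nonrandom <- d$choice.y != "random"
  expect_true(all(d$choice.x[nonrandom] == d$choice.y[nonrandom]))
  expect_equal(log(d$rt_ms), spec$mu_T + spec$beta_T * d$time_contrast)
  expect_equal(d$confidence,
               pmin(pmax(spec$mu_C + spec$beta_C * d$conf_contrast, 50), 100))
})

test_that("the deliberation shift reproduces the condition time ratio", {
  tasks <- fixture_tasks()
  lnrt <- function(cond, seeds) {
    unlist(lapply(seeds, function(s) {
      sim <- simulate_participant(agent_spec("WADDc", cond, seed = s), tasks)
      mean(log(sim$trials$rt_ms))
    }))
  }
  gap <- mean(lnrt("deliberation", 1:8)) - mean(lnrt("intuition", 1:8))
  # geometric-mean RT ratio close to 9241/5583
  expect_equal(exp(gap), 9241 / 5583, tolerance = 0.05)
})

test_that("logistic PCS agents adhere at the analytic mean rate", {
  tasks <- fixture_tasks()
  lambda <- 4
  preds <- fixture_cache()[[format_P_for_test(1.7)]]
  expected <- mean(plogis(lambda * abs(preds$adiff)))
  obs <- vapply(1:10, function(s) {
    sim <- simulate_participant(
      agent_spec("PCS_fitted", "intuition", lambda = lambda, P = 1.7, seed = s),
      tasks, preds = preds)
    d <- merge(sim$trials, preds, by = "task_id")
    mean(d$choice.x == d$choice.y)
  }, 0)
  se <- sqrt(expected * (1 - expected) / 600)
  expect_lt(abs(mean(obs) - expected), 4 * se)
})

test_that("studies are reproducible with exact mixture bookkeeping", {
  spec <- study_spec(n_intuition = 10, n_deliberation = 8,
                     mixture = c(WADDc = 0.5, TTB = 0.3, EQW = 0.2),
                     n_tasks = 12, seed = 77)
  study <- simulate_study(spec)
  expect_length(study$tasks, 12)
  expect_equal(nrow(study$trials), 18 * 12)
  expect_equal(sum(study$truth$condition == "intuition"), 10)
  expect_equal(sum(study$truth$condition == "deliberation"), 8)
  expect_equal(as.integer(table(study$truth$strategy)[c("WADDc", "TTB", "EQW")]),
               c(5L + 4L, 3L + 2L, 2L + 2L))
  # ground truth never leaks into the trial table
  expect_false(any(c("strategy", "epsilon", "lambda", "P") %in%
                   names(study$trials)))
  # bit-identical regeneration from the master seed
  again <- simulate_study(spec)
  expect_identical(study$trials, again$trials)
  expect_identical(study$truth, again$truth)
})

test_that("study data round-trip through plain-text files", {
  spec <- study_spec(n_intuition = 3, n_deliberation = 2,
                     mixture = c(TTB = 1), n_tasks = 8, seed = 5)
  study <- simulate_study(spec)
  dir <- withr::local_tempdir()
  write_study(study, dir)
  back <- read_study(dir)
  expect_equal(as.data.frame(back$tasks), as.data.frame(study$tasks))
  expect_equal(back$trials$choice, study$trials$choice)
  expect_equal(back$trials$rt_ms, study$trials$rt_ms, tolerance = 1e-12)
  expect_equal(back$truth$strategy, study$truth$strategy)
})

test_that("the full design size matches the two-condition study", {
  spec <- study_spec()
  expect_equal(spec$n_intuition + spec$n_deliberation, 128)
  expect_equal(spec$n_tasks, 60)
  expect_equal(sum(spec$mixture[c("PCS_fitted", "PCS_fix")]), 0.59)
  expect_equal(unname(spec$mixture["WADDc"]), 0.28)
})
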