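test_that("driver-cue weights are chance-corrected validities to the power P", {
  t1 <- example_tasks()[[1]]
  expect_equal(build_network(t1, P = 1)$w_v, c(.37, .37, .26, .10))
  expect_equal(build_network(t1, P = 0)$w_v, c(1, 1, 1, 1))
  expect_equal(build_network(t1, P = 2)$w_v, c(.1369, .1369, .0676, .0100))
  expect_error(build_network(t1, P = -0.1), "non-negative")

  w <- build_network(t1, P = 1.9)
  expect_equal(sign(unname(w$w_co)), sign(unname(t1$cue_matrix)))
  expect_lt(w$w_oo, 0)
})

test_that("weight ratios grow with P, separating compensatory regimes", {
  v1 <- 0.9; v2 <- 0.7
  Ps <- seq(0, 5, by = 0.5)
  ratio <- ((v1 - 0.5) / (v2 - 0.5))^Ps
  expect_true(all(diff(ratio) > 0))
  expect_equal(ratio[Ps == 0], 1)
})

test_that("the recursion matches an independent straight-line oracle", {
  tasks <- c(example_tasks(), list(
    generate_task_set(2, seed = 8)[[1]], generate_task_set(2, seed = 8)[[2]]))
  for (t in tasks) {
    for (P in c(0.5, 1.9, 3)) {
      got <- run_to_convergence(build_network(t, P))
      want <- oracle_pcs(t$validities, t$cue_matrix, P)
      expect_true(got$converged)
      expect_true(want$converged)
      expect_equal(unname(got$a_options["A"]), want$a_A, tolerance = 1e-10)
      expect_equal(unname(got$a_options["B"]), want$a_B, tolerance = 1e-10)
      expect_equal(got$a_cues, want$a_cues, tolerance = 1e-10)
      expect_identical(got$iterations, as.integer(want$iterations))
    }
  }
  # the fixed-variant prediction agrees with the oracle's preferred option
  t1 <- example_tasks()[[1]]
  want <- oracle_pcs(t1$validities, t1$cue_matrix, P = 1.9)
  expect_gt(want$a_A, want$a_B)
  expect_identical(pcs_predict(t1, P = 1.9)$choice, "A")
})

test_that("a symmetric network keeps both option activations identical", {
  # identical option columns cannot form a valid task, so build the
  # degenerate weights directly
  w <- structure(list(w_v = c(.4, .3, .2, .1)^1,
                      w_co = matrix(rep(c(1, -1, 1, -1) * 0.01, 2), 4, 2),
                      w_oo = -0.2),
                 class = "pcs_weights")
  res <- run_to_convergence(w)
  expect_identical(res$a_options[["A"]], res$a_options[["B"]])
})

test_that("mirroring a task swaps option activations exactly", {
  for (t in example_tasks()) {
    a <- pcs_predict(t, P = 1.9)
    b <- pcs_predict(mirror_task(t), P = 1.9)
    expect_identical(a$adiff, -b$adiff)
    expect_identical(a$confidence_raw, b$confidence_raw)
    expect_identical(a$time_raw, b$time_raw)
    expect_identical(b$choice, switch(a$choice, A = "B", B = "A", "random"))
  }
})

test_that("activations stay within bounds and networks converge across P", {
  tasks <- generate_task_set(12, seed = 21)
  consts <- pcs_constants()
  for (t in tasks) {
    for (P in c(0, 1, 2.5, 5)) {
      res <- run_to_convergence(build_network(t, P, consts), consts)
      expect_true(res$converged)
      expect_lte(res$iterations, consts$max_iterations)
      expect_true(all(c(res$a_options, res$a_cues) >= consts$a_min))
      expect_true(all(c(res$a_options, res$a_cues) <= consts$a_max))
    }
  }
})

test_that("the iteration-count convention is configurable", {
  t1 <- example_tasks()[[1]]
  first <- run_to_convergence(build_network(t1, 1.9),
                              pcs_constants(iteration_convention = "first_stable"))
  last <- run_to_convergence(build_network(t1, 1.9),
                             pcs_constants(iteration_convention = "window_end"))
  expect_identical(last$iterations - first$iterations,
                   pcs_constants()$stability_window - 1L)
})

test_that("choice_probability follows the logistic rule and is monotone", {
  expect_equal(choice_probability(0.7, 0), 0.5)
  expect_equal(choice_probability(0, 3.2), 0.5)
  expect_equal(choice_probability(1, 5), 1 / (1 + exp(-5)))
  d <- seq(0, 2, by = 0.25)
  expect_true(all(diff(choice_probability(d, 2)) > 0))
  l <- seq(0, 5, by = 0.5)
  expect_true(all(diff(vapply(l, choice_probability,
                              0, activation_diff = 0.8)) > 0))
  expect_error(choice_probability(-0.1, 1))
})
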