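tasks3 <- example_tasks()

test_that("TTB decides by the most valid discriminating cue", {
  got <- lapply(tasks3, ttb_predict)
  expect_equal(vapply(got, `[[`, "", "choice"), c("A", "B", "A"))
  expect_equal(vapply(got, `[[`, 0, "confidence_raw"), c(.87, .79, .74))
  # in all three examples the second cue discriminates: 2 cues examined
  expect_equal(vapply(got, `[[`, 0, "time_raw"), c(6, 6, 6))
  # a valid task always has a discriminating cue (identical columns are
  # rejected), so TTB never predicts random on constructible tasks
  for (t in generate_task_set(10, seed = 17))
    expect_true(ttb_predict(t)$choice %in% c("A", "B"))
})

test_that("EQW sums unweighted cue values", {
  got <- lapply(tasks3, eqw_predict)
  expect_equal(vapply(got, `[[`, "", "choice"), c("B", "A", "random"))
  expect_equal(vapply(got, `[[`, 0, "confidence_raw"), c(2, 2, 0))
  expect_true(all(vapply(got, `[[`, 0, "time_raw") == 15))
})

test_that("WADD_c weights cue values by chance-corrected validity", {
  got <- lapply(tasks3, waddc_predict)
  expect_equal(vapply(got, `[[`, "", "choice"), c("A", "A", "A"))
  expect_equal(vapply(got, `[[`, 0, "confidence_raw"), c(.02, .14, .12))
  expect_true(all(vapply(got, `[[`, 0, "time_raw") == 23))
  # score difference identity: 2 * sum (v - .5) d, d = (A - B)/2
  for (t in generate_task_set(10, seed = 3)) {
    d <- (t$cue_matrix[, 1] - t$cue_matrix[, 2]) / 2
    expect_equal(waddc_predict(t)$confidence_raw,
                 abs(2 * sum((t$validities - 0.5) * d)))
  }
})

test_that("EIP counts follow the fixed scheme", {
  expect_equal(eip_time("TTB", 2), 6)
  expect_equal(eip_time("TTB", 4), 12)
  expect_equal(eip_time("EQW"), 15)
  expect_equal(eip_time("WADDc"), 23)
  expect_error(eip_time("LEX"), "unknown")
})

test_that("naive Bayes multiplies validity likelihood ratios", {
  nb1 <- naive_bayes(tasks3[[1]])
  odds <- (.87 / .13) / ((.76 / .24) * (.60 / .40))
  expect_equal(nb1$posterior_A, odds / (1 + odds))
  # option A is Bayes-superior in all three printed examples
  expect_equal(vapply(tasks3, function(t) naive_bayes(t)$superior, ""),
               c("A", "A", "A"))
  # single discriminating cue favoring B
  tb <- make_task(c(.9, .8, .7, .6),
                  matrix(c(1, -1, 1, -1, 1, 1, 1, -1), 4, 2))
  expect_identical(naive_bayes(tb)$superior, "B")
  expect_equal(naive_bayes(tb)$posterior_A, 1 - 0.8)
})

test_that("every strategy obeys mirror symmetry on generated tasks", {
  preds <- list(TTB = ttb_predict, EQW = eqw_predict, WADDc = waddc_predict,
                PCS = function(t) pcs_predict(t, P = 1.9))
  for (t in generate_task_set(8, seed = 14)) {
    m <- mirror_task(t)
    for (f in preds) {
      a <- f(t); b <- f(m)
      expect_identical(b$choice, switch(a$choice, A = "B", B = "A", "random"))
      expect_equal(b$confidence_raw, a$confidence_raw)
      expect_equal(b$time_raw, a$time_raw)
    }
    nb_a <- naive_bayes(t); nb_b <- naive_bayes(m)
    expect_identical(nb_b$superior, switch(nb_a$superior, A = "B", B = "A", "tie"))
    expect_equal(nb_b$posterior_A, 1 - nb_a$posterior_A)
  }
})

test_that("confidence predictions live on their documented scales", {
  for (t in generate_task_set(15, seed = 31)) {
    ttb <- ttb_predict(t)
    if (ttb$choice != "random")
      expect_true(ttb$confidence_raw %in% t$validities)
    expect_true(eqw_predict(t)$confidence_raw %in% c(0, 2, 4, 6, 8))
  }
})

test_that("strategy_predictions assembles aligned tables with contrasts", {
  ts <- fixture_tasks()
  p <- strategy_predictions(ts, "TTB")
  expect_equal(nrow(p), 60)
  expect_equal(sum(p$time_contrast), 0, tolerance = 1e-12)
  expect_equal(max(p$time_contrast) - min(p$time_contrast), 1)
  # constant raw times give identically zero contrasts
  q <- strategy_predictions(ts, "EQW")
  expect_identical(q$time_contrast, numeric(60))
})
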