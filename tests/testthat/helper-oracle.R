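# Independent straight-line implementation of the interactive-activation
# recursion, written node by node without the package's matrix formulation.
# Serves as the oracle for the network dynamics.
oracle_pcs <- function(validities, cue_matrix, P,
                       decay = 0.05, a_min = -1, a_max = 1,
                       w_co_mag = 0.01, w_oo = -0.2,
                       thr = 1e-6, window = 10, max_it = 3000) {
  wv <- (validities - 0.5)^P
  wco <- cue_matrix * w_co_mag
  cue <- rep(0, 4); opt <- c(0, 0)
  stable <- 0; it <- 0
  upd <- function(a, input) {
    if (input >= 0) a * (1 - decay) + input * (a_max - a)
    else a * (1 - decay) + input * (a - a_min)
  }
  repeat {
    it <- it + 1
    new_cue <- numeric(4)
    for (i in 1:4) {
      input <- wv[i] * 1 + wco[i, 1] * opt[1] + wco[i, 2] * opt[2]
      new_cue[i] <- upd(cue[i], input)
    }
    new_opt <- numeric(2)
    for (o in 1:2) {
      input <- w_oo * opt[3 - o]
      for (i in 1:4) input <- input + wco[i, o] * cue[i]
      new_opt[o] <- upd(opt[o], input)
    }
    delta <- max(abs(c(new_cue - cue, new_opt - opt)))
    stable <- if (delta < thr) stable + 1 else 0
    cue <- new_cue; opt <- new_opt
    if (stable >= window) return(list(a_A = opt[1], a_B = opt[2], a_cues = cue,
                                      iterations = it - window + 1,
                                      converged = TRUE))
    if (it >= max_it) return(list(a_A = opt[1], a_B = opt[2], a_cues = cue,
                                  iterations = it, converged = FALSE))
  }
}

# a deterministic agent whose measures follow the strategy's contrasts
# exactly; used for noise-free limits
noise_free_trials <- function(strategy, tasks, P = 1.9, seed = 1,
                              coin_seed = seed) {
  preds <- strategy_predictions(tasks, strategy, P = P)
  set.seed(coin_seed)
  choice <- ifelse(preds$choice == "random",
                   sample(c("A", "B"), nrow(preds), replace = TRUE),
                   preds$choice)
  data.frame(participant = "nf", condition = "intuition",
             trial_index = seq_len(nrow(preds)), task_id = preds$task_id,
             choice = choice,
             rt_ms = exp(8 + preds$time_contrast),
             confidence = 75 + 10 * preds$conf_contrast,
             stringsAsFactors = FALSE)
}

# standard recovery-benchmark agent: unit contrast slopes, Gaussian noise
# sd 0.1 on both standardized measures, choice error rate epsilon
recovery_spec <- function(strategy, seed, epsilon = 0.05, sigma = 0.1,
                          P = NULL, lambda = 4) {
  agent_spec(strategy, "intuition", epsilon = epsilon, lambda = lambda,
             P = P, mu_T = 8.5, beta_T = 1, sigma_T = sigma,
             mu_C = 75, beta_C = 1, sigma_C = sigma, seed = seed)
}

# shared fixture task set + PCS grid cache, built once per test run
fixture_tasks <- local({
  val <- NULL
  function() {
    if (is.null(val)) val <<- generate_task_set(60, seed = 42)
    val
  }
})

format_P_for_test <- function(P) sprintf("%.6g", P)

fixture_cache <- local({
  val <- NULL
  function() {
    if (is.null(val)) val <<- pcs_grid_predictions(fixture_tasks())
    val
  }
})
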