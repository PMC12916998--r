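#' Network constants for the PCS decision model
#'
#' The interactive-activation network uses a small set of fixed constants:
#' activation decay, floor/ceiling, the magnitude of cue-option links, the
#' mutual inhibition between option nodes, and the stopping rule. Defaults
#' follow the published interactive-activation parameterization of this
#' model family; every value can be overridden.
#'
#' @param decay activation decay per iteration, in (0, 1).
#' @param a_min,a_max activation floor and ceiling (a_min < 0 < a_max).
#' @param w_co_mag magnitude of cue-option links; the sign of each link is
#'   the cue value (+1 excitatory, -1 inhibitory).
#' @param w_oo mutual inhibition between the two option nodes (negative).
#' @param stability_threshold maximal absolute per-node activation change
#'   counted as "stable".
#' @param stability_window number of consecutive stable iterations required
#'   for convergence.
#' @param max_iterations hard iteration cap.
#' @param iteration_convention \code{"first_stable"} (default) reports the
#'   first iteration of the stability window as the convergence time;
#'   \code{"window_end"} reports the last.
#' @return a list of class \code{pcs_constants}.
#' @export
pcs_constants <- function(decay = 0.05, a_min = -1, a_max = 1,
                          w_co_mag = 0.01, w_oo = -0.2,
                          stability_threshold = 1e-6, stability_window = 10L,
                          max_iterations = 3000L,
                          iteration_convention = c("first_stable", "window_end")) {
  iteration_convention <- match.arg(iteration_convention)
  stopifnot(decay > 0, decay < 1, a_min < 0, a_max > 0,
            w_co_mag > 0, w_oo < 0, stability_threshold > 0,
            stability_window >= 1, max_iterations >= stability_window)
  structure(list(decay = decay, a_min = a_min, a_max = a_max,
                 w_co_mag = w_co_mag, w_oo = w_oo,
                 stability_threshold = stability_threshold,
                 stability_window = as.integer(stability_window),
                 max_iterations = as.integer(max_iterations),
                 iteration_convention = iteration_convention),
            class = "pcs_constants")
}

#' Build the PCS network weights for a task
#'
#' The network has one driver node (clamped at activation 1), four cue
#' nodes and two option nodes. Driver-cue links carry the chance-corrected
#' validities raised to the sensitivity parameter P, (v_i - 0.5)^P; P < 1
#' compresses validity differences (more compensatory weighting), P > 1
#' amplifies them (more non-compensatory). Cue-option links are excitatory
#' or inhibitory according to the cue value; the two option nodes inhibit
#' each other. All links are bidirectional (symmetric).
#'
#' @param task a \code{pcs_task}.
#' @param P sensitivity parameter, >= 0.
#' @param constants a \code{pcs_constants} list.
#' @return list of class \code{pcs_weights} with \code{w_v} (4 driver-cue
#'   weights), \code{w_co} (4 x 2 cue-option weights) and \code{w_oo}.
#' @export
build_network <- function(task, P, constants = pcs_constants()) {
  stopifnot(inherits(task, "pcs_task"))
  if (!is.numeric(P) || length(P) != 1L || !is.finite(P) || P < 0)
    stop("P must be a single non-negative number")
  structure(list(w_v = (task$validities - 0.5)^P,
                 w_co = task$cue_matrix * constants$w_co_mag,
                 w_oo = constants$w_oo),
            class = "pcs_weights")
}

# full symmetric 7 x 7 weight matrix; node order: driver, cues 1-4, A, B
pcs_weight_matrix <- function(weights) {
  W <- matrix(0, 7L, 7L)
  W[1L, 2:5] <- weights$w_v
  W[2:5, 6:7] <- weights$w_co
  W[6L, 7L] <- weights$w_oo
  W + t(W)
}

#' Iterate the network to a stable state
#'
#' Synchronous interactive-activation updating. Every non-driver node
#' starts at 0; the driver is clamped at 1. Each iteration, every node
#' receives input equal to the weighted sum of its neighbours' activations
#' and is updated by
#' \deqn{a \leftarrow a(1 - decay) + input (a_{max} - a)}{a <- a(1-decay) + input (a_max - a)}
#' for non-negative input, and
#' \deqn{a \leftarrow a(1 - decay) + input (a - a_{min})}{a <- a(1-decay) + input (a - a_min)}
#' otherwise, which keeps activations within [a_min, a_max]. Iteration
#' stops once every node's change stays below the stability threshold for
#' a full stability window, or at the iteration cap.
#'
#' @param weights a \code{pcs_weights} object from \code{build_network}.
#' @param constants a \code{pcs_constants} list.
#' @return list of class \code{pcs_result}: \code{a_options} (named
#'   activations of A and B), \code{a_cues}, \code{iterations} (per the
#'   configured convention), \code{converged}.
#' @export
run_to_convergence <- function(weights, constants = pcs_constants()) {
  stopifnot(inherits(weights, "pcs_weights"))
  W <- pcs_weight_matrix(weights)
  decay <- constants$decay
  a_min <- constants$a_min
  a_max <- constants$a_max
  thr <- constants$stability_threshold
  win <- constants$stability_window
  a <- c(1, numeric(6L))
  stable <- 0L
  it <- 0L
  repeat {
    it <- it + 1L
    input <- as.vector(W %*% a)
    a_new <- ifelse(input >= 0,
                    a * (1 - decay) + input * (a_max - a),
                    a * (1 - decay) + input * (a - a_min))
    a_new[1L] <- 1
    if (any(!is.finite(a_new)))
      stop("non-finite activation; check network constants")
    stable <- if (max(abs(a_new - a)) < thr) stable + 1L else 0L
    a <- a_new
    if (stable >= win) { converged <- TRUE; break }
    if (it >= constants$max_iterations) { converged <- FALSE; break }
  }
  iterations <- if (converged && constants$iteration_convention == "first_stable")
    it - win + 1L else it
  structure(list(a_options = c(A = a[6L], B = a[7L]),
                 a_cues = a[2:5],
                 iterations = iterations,
                 converged = converged),
            class = "pcs_result")
}

#' Logistic choice probability
#'
#' Maps a non-negative activation advantage of the preferred option onto
#' the probability of choosing it: p = 1 / (1 + exp(-lambda * diff)).
#' lambda = 0 gives random choice; large lambda gives near-deterministic
#' choice.
#'
#' @param activation_diff activation of preferred minus non-preferred
#'   option, >= 0 (vectorized).
#' @param lambda determinism parameter, >= 0.
#' @return probabilities in [0.5, 1).
#' @export
choice_probability <- function(activation_diff, lambda) {
  stopifnot(all(activation_diff >= 0), lambda >= 0)
  stats::plogis(lambda * activation_diff)
}

#' PCS predictions for a single task
#'
#' Runs the network and derives the strategy prediction triple: the choice
#' is the option with the higher final activation, confidence is the
#' absolute activation difference between the option nodes, and time is
#' the number of iterations to convergence. Exact activation ties yield a
#' "random" choice prediction.
#'
#' @param task a \code{pcs_task}.
#' @param P sensitivity parameter (default 1.9, the fixed-variant value).
#' @param constants a \code{pcs_constants} list.
#' @return list with \code{choice} ("A", "B" or "random"),
#'   \code{confidence_raw}, \code{time_raw}, \code{adiff} (signed A - B
#'   activation difference), \code{converged}.
#' @export
pcs_predict <- function(task, P = 1.9, constants = pcs_constants()) {
  res <- run_to_convergence(build_network(task, P, constants), constants)
  if (!res$converged)
    warning("network did not converge for task ", task$id, " at P = ", P)
  adiff <- unname(res$a_options["A"] - res$a_options["B"])
  choice <- if (adiff > 0) "A" else if (adiff < 0) "B" else "random"
  list(choice = choice, confidence_raw = abs(adiff),
       time_raw = res$iterations, adiff = adiff, converged = res$converged)
}
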