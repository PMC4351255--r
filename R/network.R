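#' Create a tag-and-trace SARSA(lambda) network
#'
#' Builds the three-layer agent: instantaneous and transient (on/off)
#' sensory units, an association layer of regular (sigmoidal, memoryless)
#' and memory (transient-integrating) units, and a layer of Q-value units,
#' one per action.  Regular units and Q-value units carry a plastic bias
#' synapse (constant presynaptic activity 1); memory units receive neither a
#' bias nor instantaneous input, only the on/off transients.  Feedback
#' weights from Q-value units to association units are stored separately
#' from their feedforward partners, initialised from the same uniform
#' distribution, and updated by the same tag rule, so that feedforward and
#' feedback weights become proportional during learning rather than being
#' hard-shared.
#'
#' All randomness is drawn from streams derived from `seed`: one stream for
#' the weight initialisation and an independent one for action selection, so
#' that disabling exploration does not perturb anything else.
#'
#' @param arch an [architecture_spec()].
#' @param params a [learning_params()].
#' @param seed integer seed for the network's private random streams.
#' @return An object of class `augment_network` (handle with external state).
#' @examples
#' net <- augment_network(architecture_spec(n_inst = 4), seed = 1)
#' st <- agent_step(net, x = c(1, 0, 0, 0), reward = 0, terminal = FALSE)
#' st$action
#' @export
augment_network <- function(arch, params = learning_params(), seed = 1L) {
  stopifnot(inherits(arch, "augment_arch"), inherits(params, "augment_params"))
  ptr <- net_create(arch$n_inst, arch$n_regular, arch$n_memory, arch$n_q,
                    arch$init_low, arch$init_high,
                    params$beta, params$lambda, params$gamma, params$epsilon,
                    params$theta, as.integer(seed %% 2147483647))
  structure(list(ptr = ptr, arch = arch, seed = seed),
            class = "augment_network")
}

#' @export
print.augment_network <- function(x, ...) {
  p <- net_params(x$ptr)
  cat("attention-gated tag/trace SARSA(lambda) network\n")
  print(x$arch)
  cat(sprintf("  beta=%.3g lambda=%.3g gamma=%.3g epsilon=%.3g theta=%.3g\n",
              p$beta, p$lambda, p$gamma, p$epsilon, p$theta))
  invisible(x)
}

#' Advance the agent by one time step
#'
#' Performs the canonical per-step order: sensory transients are encoded,
#' synaptic traces updated, activities propagated forward; on a terminal
#' step the final reward-prediction error `delta = r - q_stored` is applied
#' to all tagged synapses and the trial state is cleared.  Otherwise an
#' action is selected by the Max-Boltzmann controller, the SARSA error
#' `delta = r + gamma * q_a(t) - q_a(t-1)` is applied using the tags laid
#' down through the previous action, and tags then decay (factor
#' `lambda * gamma`) and re-form, gated by feedback from the newly selected
#' action.
#'
#' @param net an [augment_network()].
#' @param x instantaneous sensory vector for this step.
#' @param reward reward received with this observation.
#' @param terminal logical; `TRUE` for the final step of a trial.
#' @param forced optionally force the action (0-based index), bypassing the
#'   controller; used for replay and analysis.
#' @return list with `action` (0-based, `NA` on terminal steps), `delta`
#'   (`NA` until a first action exists), `q`, `y_regular`, `y_memory`.
#' @export
agent_step <- function(net, x, reward = 0, terminal = FALSE, forced = NULL) {
  net_step_r(net$ptr, as.numeric(x), reward, isTRUE(terminal),
             if (is.null(forced)) -1L else as.integer(forced))
}

#' Reset the within-trial state
#'
#' Clears memory accumulators, activities, tags, traces and the stored
#' chosen Q-value; weights persist.  Called automatically when a terminal
#' step is processed.
#' @param net an [augment_network()].
#' @export
reset_trial <- function(net) {
  net_reset(net$ptr)
  invisible(net)
}

#' Inspect the full network state
#'
#' @param net an [augment_network()].
#' @return list with `weights` (six arrays: `V_regular`, `V_memory`,
#'   `W_regular`, `W_memory`, `FB_regular`, `FB_memory`; bias synapses are
#'   the last row of `V_regular` and `W_regular`), `tags` (congruent
#'   arrays), `trace` (the non-decaying within-trial synaptic traces onto
#'   memory units), activities, `q_stored` and the step counter `t`.
#' @export
network_state <- function(net) net_state(net$ptr)

#' @rdname network_state
#' @export
network_weights <- function(net) net_state(net$ptr)$weights

#' Overwrite weight arrays
#' @param net an [augment_network()].
#' @param value named list with any of the six weight arrays.
#' @export
set_network_weights <- function(net, value) {
  net_set_weights(net$ptr, value)
  invisible(net)
}

#' Set the learning parameters of an existing network
#'
#' `freeze_network()` is shorthand for `beta = 0, epsilon = 0`: learning and
#' exploration are disabled and behaviour becomes deterministic given the
#' task, which is how trained networks are evaluated and analysed.
#'
#' @param net an [augment_network()].
#' @param params a [learning_params()].
#' @export
set_network_params <- function(net, params) {
  stopifnot(inherits(params, "augment_params"))
  net_set_params(net$ptr, params$beta, params$lambda, params$gamma,
                 params$epsilon)
  invisible(net)
}

#' @rdname set_network_params
#' @export
freeze_network <- function(net) {
  p <- net_params(net$ptr)
  net_set_params(net$ptr, 0, p$lambda, p$gamma, 0)
  invisible(net)
}

#' @rdname set_network_params
#' @param beta,epsilon values to restore when unfreezing.
#' @export
unfreeze_network <- function(net, beta = 0.15, epsilon = 0.025) {
  p <- net_params(net$ptr)
  net_set_params(net$ptr, beta, p$lambda, p$gamma, epsilon)
  invisible(net)
}

#' Deep-copy a network
#' @param net an [augment_network()].
#' @export
clone_network <- function(net) {
  out <- net
  out$ptr <- net_clone(net$ptr)
  out
}

# ---------------------------------------------------------------------------
# pure functional pieces of the model, exposed for documentation and testing
# ---------------------------------------------------------------------------

#' Transient sensory encoding
#'
#' Every input feeds an on-unit reporting positive changes and an off-unit
#' reporting negative changes relative to the previous time step
#' (`x_on = [x(t) - x(t-1)]_+`, `x_off = [x(t-1) - x(t)]_+`).  At the start
#' of a trial the previous input is all-zero.
#'
#' @param x_now,x_prev instantaneous sensory vectors of equal length.
#' @return list with `x_inst`, `x_on`, `x_off`.
#' @examples
#' encode_sensory(c(1, 0), c(0, 0))$x_on
#' @export
encode_sensory <- function(x_now, x_prev) {
  if (length(x_now) != length(x_prev))
    stop("'x_now' and 'x_prev' must have the same length")
  list(x_inst = as.numeric(x_now),
       x_on = pmax(x_now - x_prev, 0),
       x_off = pmax(x_prev - x_now, 0))
}

#' Sigmoidal activation and its derivative
#'
#' `sigmoid(inp) = 1 / (1 + exp(theta - inp))`; the derivative is computed
#' from the activity as `y * (1 - y)`.
#' @param inp synaptic input.
#' @param theta sigmoid offset.
#' @export
sigmoid <- function(inp, theta = 2.5) 1 / (1 + exp(pmin(pmax(theta - inp, -500), 500)))

#' @rdname sigmoid
#' @param y activity value in (0, 1).
#' @export
sigmoid_deriv <- function(y) y * (1 - y)

#' SARSA reward-prediction error
#'
#' `delta = r + gamma * q_now - q_stored`; on a terminal transition the
#' Q-value of the terminal state is zero, so `delta = r - q_stored`.
#' @param r reward received.
#' @param q_now chosen Q-value at the current step.
#' @param q_stored chosen Q-value stored from the previous step.
#' @param gamma discount factor.
#' @param terminal logical terminal flag.
#' @export
compute_rpe <- function(r, q_now, q_stored, gamma, terminal = FALSE) {
  if (is.null(q_stored) || length(q_stored) == 0 || is.na(q_stored))
    stop("no stored Q-value: an action must have been taken before computing the RPE")
  if (isTRUE(terminal)) r - q_stored else r + gamma * q_now - q_stored
}

#' Max-Boltzmann action selection
#'
#' With probability `1 - epsilon` the greedy action (ties broken uniformly
#' at random); with probability `epsilon` a draw from the Boltzmann
#' distribution `P(k) proportional to exp(q_k)` (which may itself return the
#' greedy action).  Uses R's random number stream.
#'
#' @param q vector of Q-values.
#' @param epsilon exploration probability.
#' @return 0-based action index.
#' @export
select_action <- function(q, epsilon = 0.025) {
  stopifnot(all(is.finite(q)))
  if (stats::runif(1) >= epsilon) {
    best <- which(q == max(q))
    idx <- if (length(best) == 1L) best else best[sample.int(length(best), 1L)]
  } else {
    p <- exp(q - max(q))
    idx <- sample.int(length(q), 1L, prob = p / sum(p))
  }
  idx - 1L
}
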