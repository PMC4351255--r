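#' Finite-difference gradient check of the learning rule
#'
#' For `lambda = 0` (full tag decay, `alpha = 1`) the tag-and-trace update
#' is exactly one step of on-line gradient descent on the squared SARSA
#' prediction error of the sampled transition: every weight moves by
#' `beta * delta * dq_a(t-1)/dw`.  This oracle verifies that claim
#' numerically.  It replays a fixed episode (observations and forced
#' actions) on a frozen copy of the network, reads the tags present when
#' the transition's update is applied, and compares them against central
#' finite differences of the chosen Q-value with respect to every
#' feedforward weight.  Feedback weights are tied to the transpose of their
#' feedforward partners beforehand, since the derivation estimates the
#' feedforward weight by the feedback weight; with frozen weights the
#' trace-based approximation for synapses onto memory units is exact.
#'
#' @param episode list with `x` (matrix, one row per step, `n_inst`
#'   columns), `actions` (0-based, one per step) and `rewards` (one per
#'   step; reward delivered with the observation).
#' @param arch an [architecture_spec()].
#' @param params a [learning_params()]; `lambda` is forced to 0.
#' @param at step index `t` of the transition under scrutiny (the update
#'   applied at step `at` concerns the action taken at `at - 1`); defaults
#'   to the last step.
#' @param h finite-difference step.
#' @param seed seed for the random weight initialisation.
#' @return list with per-array maximum absolute discrepancies
#'   (`V_regular`, `V_memory`, `W_regular`, `W_memory`) and their overall
#'   maximum `max`.
#' @examples
#' ep <- list(x = rbind(c(1, 0), c(0, 1), c(0, 0)),
#'            actions = c(0, 1, 1), rewards = c(0, 0, 0.5))
#' gradient_check(ep, architecture_spec(n_inst = 2))$max
#' @export
gradient_check <- function(episode, arch, params = learning_params(),
                           at = NULL, h = 1e-5, seed = 1L) {
  params <- learning_params(beta = params$beta, lambda = 0,
                            gamma = params$gamma, epsilon = 0,
                            theta = params$theta)
  x <- as.matrix(episode$x)
  acts <- as.integer(episode$actions)
  rew <- as.numeric(episode$rewards)
  Tn <- nrow(x)
  stopifnot(length(acts) == Tn, length(rew) == Tn, Tn >= 2)
  if (is.null(at)) at <- Tn
  stopifnot(at >= 2, at <= Tn)

  net <- augment_network(arch, params, seed = seed)
  net_tie_feedback(net$ptr)
  w0 <- network_weights(net)

  # replay the prefix with learning disabled so weights stay frozen
  frozen <- clone_network(net)
  freeze_network(frozen)
  for (t in seq_len(at - 1))
    agent_step(frozen, x[t, ], rew[t], FALSE, forced = acts[t])
  tags <- network_state(frozen)$tags
  st <- agent_step(frozen, x[at, ], rew[at], FALSE, forced = acts[at])
  delta <- st$delta

  a_prev <- acts[at - 1] + 1L
  # chosen Q-value at step at-1 as a function of the weights, via replay
  q_of <- function(w) {
    probe <- clone_network(net)
    freeze_network(probe)
    set_network_weights(probe, w)
    for (t in seq_len(at - 1))
      agent_step(probe, x[t, ], rew[t], FALSE, forced = acts[t])
    network_state(probe)$q[a_prev]
  }

  arrays <- c("V_regular", "V_memory", "W_regular", "W_memory")
  disc <- sapply(arrays, function(nm) {
    tg <- tags[[nm]]
    grad <- array(0, dim(tg))
    for (idx in seq_along(tg)) {
      wp <- w0; wm <- w0
      wp[[nm]][idx] <- wp[[nm]][idx] + h
      wm[[nm]][idx] <- wm[[nm]][idx] - h
      grad[idx] <- (q_of(wp) - q_of(wm)) / (2 * h)
    }
    max(abs(params$beta * delta * (tg - grad)))
  })
  as.list(c(disc, max = max(disc)))
}

#' Random episodes for gradient checking
#'
#' Draws a short episode with uniform random observations in \[0, 1\],
#' random forced actions and random rewards, suitable for
#' [gradient_check()] on small networks.
#' @param n_steps episode length.
#' @param n_inst number of sensory inputs.
#' @param n_q number of actions.
#' @param seed RNG seed.
#' @export
random_episode <- function(n_steps = 3L, n_inst = 3L, n_q = 3L, seed = 1L) {
  set.seed(seed)
  list(x = matrix(stats::runif(n_steps * n_inst), nrow = n_steps),
       actions = sample(0:(n_q - 1L), n_steps, replace = TRUE),
       rewards = stats::runif(n_steps, 0, 0.5))
}
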