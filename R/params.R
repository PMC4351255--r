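#' Learning parameters
#'
#' Bundles the scalar constants of the learning scheme: the learning rate
#' `beta`, the SARSA trace-decay parameter `lambda`, the discount factor
#' `gamma`, the exploration rate `epsilon` of the Max-Boltzmann controller,
#' and the sigmoid offset `theta` of the association units.  The tag
#' persistence `alpha` is always derived as `1 - lambda * gamma`, which makes
#' the tag dynamics exactly equivalent to SARSA(lambda) eligibility traces
#' (tags decay by a factor `lambda * gamma` per time step).
#'
#' Defaults are the reference configuration used throughout the simulated
#' experiments: `beta = 0.15`, `lambda = 0.20`, `gamma = 0.90`,
#' `epsilon = 0.025`.  The sigmoid offset is not uniquely determined by the
#' model (bias weights can absorb any offset); the default `theta = 2.5`
#' keeps naive activities low, which stabilises early Q-value estimates.
#'
#' @param beta learning rate, > 0.
#' @param lambda eligibility/tag decay parameter in \[0, 1\].
#' @param gamma reward discount factor in \[0, 1\].
#' @param epsilon exploration probability in \[0, 1\].
#' @param theta sigmoid offset (activation units).
#' @return A list of class `augment_params` with fields `beta`, `lambda`,
#'   `gamma`, `alpha`, `epsilon`, `theta`.
#' @examples
#' p <- learning_params()
#' p$alpha  # 1 - 0.2 * 0.9 = 0.82
#' @export
learning_params <- function(beta = 0.15, lambda = 0.20, gamma = 0.90,
                            epsilon = 0.025, theta = 2.5) {
  stopifnot(is.numeric(beta), length(beta) == 1L, is.finite(beta))
  if (beta <= 0) stop("'beta' must be positive")
  if (lambda < 0 || lambda > 1) stop("'lambda' must lie in [0, 1]")
  if (gamma < 0 || gamma > 1) stop("'gamma' must lie in [0, 1]")
  if (epsilon < 0 || epsilon > 1) stop("'epsilon' must lie in [0, 1]")
  structure(
    list(beta = beta, lambda = lambda, gamma = gamma,
         alpha = 1 - lambda * gamma, epsilon = epsilon, theta = theta),
    class = "augment_params")
}

#' Network architecture specification
#'
#' Counts of units per layer and the bounds of the uniform weight
#' initialisation.  Each sensory input is represented by three units: one
#' instantaneous unit and an on/off pair of transient units, so a network
#' with `n_inst` inputs has `2 * n_inst` transient channels feeding the
#' memory units.  The reference architecture has 3 regular units, 4 memory
#' units and 3 Q-value units, with weights drawn uniformly from
#' \[-0.25, 0.25\].
#'
#' @param n_inst number of instantaneous sensory inputs (task dependent).
#' @param n_regular number of regular (instantaneous) association units.
#' @param n_memory number of integrating memory units.
#' @param n_q number of Q-value units (actions).
#' @param init_low,init_high bounds of the uniform weight initialisation.
#' @return A list of class `augment_arch`.
#' @export
architecture_spec <- function(n_inst, n_regular = 3L, n_memory = 4L,
                              n_q = 3L, init_low = -0.25, init_high = 0.25) {
  counts <- c(n_inst, n_regular, n_memory, n_q)
  if (any(counts < 1) || any(counts != as.integer(counts)))
    stop("unit counts must be positive integers")
  if (init_low >= init_high)
    stop("'init_low' must be smaller than 'init_high'")
  structure(
    list(n_inst = as.integer(n_inst), n_regular = as.integer(n_regular),
         n_memory = as.integer(n_memory), n_q = as.integer(n_q),
         init_low = init_low, init_high = init_high),
    class = "augment_arch")
}

#' @export
print.augment_params <- function(x, ...) {
  cat(sprintf(
    "learning parameters: beta=%.3g lambda=%.3g gamma=%.3g (alpha=%.3g) epsilon=%.3g theta=%.3g\n",
    x$beta, x$lambda, x$gamma, x$alpha, x$epsilon, x$theta))
  invisible(x)
}

#' @export
print.augment_arch <- function(x, ...) {
  cat(sprintf(
    "architecture: %d sensory inputs (+%d transient), %d regular, %d memory, %d Q units; init U[%g, %g]\n",
    x$n_inst, 2L * x$n_inst, x$n_regular, x$n_memory, x$n_q,
    x$init_low, x$init_high))
  invisible(x)
}

#' Derive per-network seeds from a master seed
#'
#' Fixed counter scheme: network `index` of a run with master seed `master`
#' always receives the same derived seed, so enlarging a population never
#' perturbs the random streams of earlier networks.
#' @param master master seed of the experiment.
#' @param index network counter (1-based).
#' @param stream sub-stream id (0 default; internal streams use fixed ids).
#' @export
derive_seed <- function(master, index, stream = 0L) {
  (as.double(master) * 1000003 + index * 97 + stream) %% 2147483647
}
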