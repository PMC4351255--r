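# shared builders for the test suite

tiny_arch <- function(n_inst = 2L, n_regular = 2L, n_memory = 2L, n_q = 3L) {
  architecture_spec(n_inst = n_inst, n_regular = n_regular,
                    n_memory = n_memory, n_q = n_q)
}

# a network with every weight array overwritten by a constant
const_net <- function(arch, value = 0, params = learning_params(), seed = 1) {
  net <- augment_network(arch, params, seed = seed)
  w <- network_weights(net)
  for (nm in names(w)) w[[nm]][] <- value
  set_network_weights(net, w)
  net
}

# drive a network through a fixed episode of observations and forced actions
play_episode <- function(net, x, actions, rewards,
                         terminal = c(rep(FALSE, nrow(x) - 1), TRUE)) {
  out <- vector("list", nrow(x))
  for (t in seq_len(nrow(x)))
    out[[t]] <- agent_step(net, x[t, ], rewards[t], terminal[t],
                           forced = if (terminal[t]) NULL else actions[t])
  out
}

# scripted optimal action sequence for one saccade trial type
saccade_optimal_actions <- function(type) {
  # type: 0 PL, 1 PR, 2 AL, 3 AR; respond toward (pro) / away from (anti) cue
  resp <- if (type %in% c(0, 3)) 0L else 2L
  c(1L, 1L, 1L, 1L, 1L, 1L, resp)
}

boot_median_se <- function(x, n = 500L) {
  stats::sd(replicate(n, stats::median(sample(x, replace = TRUE))))
}
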