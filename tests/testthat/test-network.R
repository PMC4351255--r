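test_that("transient encoding reports on/off changes and rejects mismatched lengths", {
  e <- encode_sensory(c(1, 0), c(0, 0))
  expect_equal(e$x_on, c(1, 0))
  expect_equal(e$x_off, c(0, 0))
  e <- encode_sensory(0.3, 0.8)
  expect_equal(e$x_on, 0)
  expect_equal(e$x_off, 0.5)
  e <- encode_sensory(0.7, 0.7)
  expect_equal(e$x_on, 0)
  expect_equal(e$x_off, 0)
  expect_error(encode_sensory(c(1, 2), 1), "same length")
})

test_that("sigmoid activation midpoint, derivative and saturation", {
  expect_equal(sigmoid(2.5, theta = 2.5), 0.5)
  expect_equal(sigmoid_deriv(0.5), 0.25)
  expect_equal(sigmoid(-1e6), 0)
  expect_equal(sigmoid(1e6), 1)
  expect_equal(sigmoid_deriv(sigmoid(-1e6)), 0)
})

test_that("forward pass of a zero-weight network gives baseline activities", {
  net <- const_net(tiny_arch(n_inst = 3), 0)
  st <- agent_step(net, c(1, 0.5, 0))
  expect_equal(st$y_regular, rep(1 / (1 + exp(2.5)), 2), tolerance = 1e-12)
  expect_equal(st$y_memory, rep(1 / (1 + exp(2.5)), 2), tolerance = 1e-12)
  expect_equal(st$q, rep(0, 3))
})

test_that("memory units integrate only transients: constant input is flat", {
  net <- augment_network(tiny_arch(n_inst = 2), seed = 3)
  x <- c(0.8, 0.4)
  agent_step(net, x, forced = 0)
  inp1 <- network_state(net)$inp_memory
  agent_step(net, x, forced = 0)
  agent_step(net, x, forced = 0)
  expect_equal(network_state(net)$inp_memory, inp1)
  expect_true(any(inp1 != 0))  # onset itself was integrated
})

test_that("two-step on/off stimulus accumulates both transient channels", {
  arch <- tiny_arch(n_inst = 2)
  net <- augment_network(arch, seed = 4)
  V <- network_weights(net)$V_memory  # rows: 2 on-channels then 2 off
  x <- c(0.6, 0.2)
  agent_step(net, x, forced = 0)       # onset
  agent_step(net, c(0, 0), forced = 0) # offset
  # hand-rolled trace of the accumulator: v_on . x + v_off . x
  expected <- drop(t(V[1:2, ]) %*% x + t(V[3:4, ]) %*% x)
  expect_equal(network_state(net)$inp_memory, expected, tolerance = 1e-12)
})

test_that("action selection is greedy without exploration and Boltzmann with", {
  set.seed(1)
  expect_true(all(replicate(20, select_action(c(0.1, 0.9, 0.2), 0)) == 1))
  # uniform tie-breaking
  draws <- replicate(6000, select_action(c(0.5, 0.5, 0.5), 0))
  expect_gt(min(table(factor(draws, levels = 0:2))), 6000 / 3 - 3 * sqrt(6000 * 2 / 9))
  # closed-form Boltzmann: q = (ln 2, 0, 0) gives P(action 0) = 1/2
  draws <- replicate(1e5, select_action(c(log(2), 0, 0), 1))
  p0 <- mean(draws == 0)
  expect_lt(abs(p0 - 0.5), 3 * sqrt(0.25 / 1e5))
})

test_that("engine exploration with equal Q-values is uniform", {
  net <- const_net(tiny_arch(n_inst = 2), 0,
                   params = learning_params(epsilon = 1), seed = 9)
  acts <- replicate(3000, {
    reset_trial(net)
    agent_step(net, c(1, 0))$action
  })
  p <- table(factor(acts, levels = 0:2)) / 3000
  expect_true(all(abs(p - 1 / 3) < 3 * sqrt(2 / 9 / 3000)))
})

test_that("SARSA reward-prediction error arithmetic and protocol guard", {
  expect_equal(compute_rpe(1.5, 0, 1.5, 0.9, terminal = TRUE), 0)
  expect_equal(compute_rpe(0, 1 / 0.9, 1, 0.9), 0)
  expect_equal(compute_rpe(0.2, 1.0, 0.5, 0.9), 0.6)
  expect_error(compute_rpe(1, 0, NA, 0.9), "stored Q-value")
})

test_that("engine RPE matches the SARSA definition step by step", {
  net <- augment_network(tiny_arch(n_inst = 2), seed = 5)
  s1 <- agent_step(net, c(1, 0), forced = 1)
  expect_true(is.na(s1$delta))  # no stored value yet, no update
  q1 <- s1$q[2]
  s2 <- agent_step(net, c(0, 1), reward = 0.2, forced = 0)
  expect_equal(s2$delta, 0.2 + 0.9 * s2$q[1] - q1, tolerance = 1e-12)
  q2 <- s2$q[1]
  s3 <- agent_step(net, c(0, 0), reward = 1.5, terminal = TRUE)
  expect_equal(s3$delta, 1.5 - q2, tolerance = 1e-12)
})

test_that("synaptic traces are additive and never decay within a trial", {
  net <- augment_network(tiny_arch(n_inst = 1), seed = 6)
  agent_step(net, 1, forced = 0)   # on event
  agent_step(net, 0, forced = 0)   # off event
  agent_step(net, 1, forced = 0)   # second on event
  tr <- network_state(net)$trace
  expect_equal(tr[1, ], rep(2, 2))  # on-channel saw two presentations
  expect_equal(tr[2, ], rep(1, 2))  # off-channel one
  reset_trial(net)
  agent_step(net, 0, forced = 0)
  agent_step(net, 0, forced = 0)
  expect_true(all(network_state(net)$trace == 0))
})

test_that("tags decay by exactly lambda * gamma and form one-hot by action", {
  net <- augment_network(tiny_arch(n_inst = 2), seed = 7)
  freeze_network(net)  # beta = 0: tags evolve without weight drift
  agent_step(net, c(1, 0), forced = 0)
  t1 <- network_state(net)$tags
  # only the selected column carries W-layer tag mass
  expect_true(all(t1$W_regular[, 2:3] == 0))
  expect_true(all(t1$W_memory[, 2:3] == 0))
  # silence the feedback of action 1 so that the next step adds no V-tag
  # mass anywhere: every tag without new contributions decays by lambda*gamma
  w <- network_weights(net)
  w$FB_regular[2, ] <- 0
  w$FB_memory[2, ] <- 0
  set_network_weights(net, w)
  agent_step(net, c(1, 0), forced = 1)
  t2 <- network_state(net)$tags
  expect_equal(t2$W_regular[, 1], 0.18 * t1$W_regular[, 1], tolerance = 1e-12)
  expect_equal(t2$W_memory[, 1], 0.18 * t1$W_memory[, 1], tolerance = 1e-12)
  expect_equal(t2$FB_regular[1, ], 0.18 * t1$FB_regular[1, ],
               tolerance = 1e-12)
  expect_equal(t2$FB_memory[1, ], 0.18 * t1$FB_memory[1, ], tolerance = 1e-12)
  expect_equal(t2$V_regular, 0.18 * t1$V_regular, tolerance = 1e-12)
  expect_equal(t2$V_memory, 0.18 * t1$V_memory, tolerance = 1e-12)
})

test_that("with full tag decay the W-tags equal the presynaptic activities", {
  net <- augment_network(tiny_arch(n_inst = 2),
                         params = learning_params(lambda = 0), seed = 8)
  freeze_network(net)  # alpha = 1 and no weight drift
  st <- agent_step(net, c(0.5, 1), forced = 2)
  tg <- network_state(net)$tags
  expect_equal(tg$W_regular[, 3], c(st$y_regular, 1), tolerance = 1e-12)
  expect_equal(tg$W_memory[, 3], st$y_memory, tolerance = 1e-12)
  expect_true(all(tg$W_regular[, 1:2] == 0))
})

test_that("zero feedback weight gates off tag formation on association inputs", {
  net <- augment_network(tiny_arch(n_inst = 2), seed = 10)
  w <- network_weights(net)
  w$FB_regular[1, 1] <- 0  # action 0 gives no feedback to regular unit 1
  set_network_weights(net, w)
  agent_step(net, c(1, 1), forced = 0)
  tg <- network_state(net)$tags
  expect_true(all(tg$V_regular[, 1] == 0))
  expect_false(all(tg$V_regular[, 2] == 0))
})

test_that("no plasticity without error or without tags", {
  net <- augment_network(tiny_arch(n_inst = 2), seed = 11)
  w0 <- network_weights(net)
  agent_step(net, c(1, 0), forced = 0)  # first step of trial: tags were zero
  expect_equal(network_weights(net), w0)
  # delta = 0: engineer r + gamma*q_now = q_stored via terminal with r = q
  q0 <- network_state(net)$q_stored
  agent_step(net, c(1, 0), reward = q0, terminal = TRUE)
  expect_equal(network_weights(net), w0, tolerance = 1e-12)
})

test_that("trial reset clears all dynamic state but keeps the weights", {
  net <- augment_network(tiny_arch(n_inst = 2), seed = 12)
  agent_step(net, c(1, 0), forced = 0)
  agent_step(net, c(0, 1), reward = 0.3, forced = 1)
  w_before <- network_weights(net)
  # terminal reward equal to the stored prediction: delta = 0, so the final
  # update leaves the weights untouched and only the reset acts
  agent_step(net, c(0, 0), reward = network_state(net)$q_stored,
             terminal = TRUE)
  st <- network_state(net)
  expect_equal(network_weights(net), w_before, tolerance = 1e-12)
  expect_true(all(st$inp_memory == 0))
  expect_true(all(st$trace == 0))
  for (tg in st$tags) expect_true(all(tg == 0))
  expect_true(is.na(st$q_stored))
  expect_equal(st$t, 0)
  expect_true(all(st$x_prev == 0))
  # naive activities reproduced after reset
  fresh <- augment_network(tiny_arch(n_inst = 2), seed = 12)
  set_network_weights(fresh, network_weights(net))
  expect_equal(agent_step(net, c(0.3, 0.3), forced = 0)$y_regular,
               agent_step(fresh, c(0.3, 0.3), forced = 0)$y_regular)
})

test_that("repeating an identical rewarded episode drives the final RPE to zero", {
  net <- augment_network(tiny_arch(n_inst = 2), seed = 13)
  x <- rbind(c(1, 0), c(0, 1), c(0, 0))
  deltas <- numeric(500)
  for (rep in 1:500) {
    agent_step(net, x[1, ], forced = 0)
    agent_step(net, x[2, ], forced = 1)
    deltas[rep] <- agent_step(net, x[3, ], reward = 1.5,
                              terminal = TRUE)$delta
  }
  expect_lt(abs(deltas[500]), 1e-3)
  expect_lt(abs(deltas[500]), abs(deltas[1]))
})
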