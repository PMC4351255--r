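test_that("saccade trials pay the shaping and final reward at the right steps", {
  env <- make_env("saccade", seed = 1)
  for (type in 0:3) {
    acts <- saccade_optimal_actions(type)
    s <- env_reset(env, spec = type)
    expect_equal(s$x, rep(0, 4))  # one step of empty screen
    rewards <- c()
    xs <- list(s$x)
    for (a in acts) {
      s <- env_step(env, a)
      rewards <- c(rewards, s$reward)
      xs <- c(xs, list(s$x))
    }
    expect_true(s$terminal)
    expect_equal(length(xs), 8)           # canonical 8-step trial
    expect_equal(sum(rewards == 0.2), 1)  # shaping reward exactly once
    expect_equal(max(rewards), 1.5)       # full reward on the correct choice
    expect_equal(sum(rewards), 1.7)
    info <- env_trial_info(env)
    expect_true(info$correct && info$fix_attained && info$reached_go)
  }
})

test_that("saccade rule: wrong direction, broken fixation and timeouts abort", {
  env <- make_env("saccade", seed = 2)
  # anti-trial with cue left: responding left is wrong
  env_reset(env, spec = 2)
  for (a in c(1, 1, 1, 1, 1, 1)) env_step(env, a)
  s <- env_step(env, 0)
  expect_true(s$terminal)
  expect_equal(s$reward, 0)
  expect_false(env_trial_info(env)$correct)
  # breaking fixation in the delay aborts with only the shaping reward
  env_reset(env, spec = 0)
  tot <- 0
  for (a in c(1, 1, 1, 1, 0)) { s <- env_step(env, a); tot <- tot + s$reward }
  expect_true(s$terminal)
  expect_equal(tot, 0.2)
  expect_true(env_trial_info(env)$reached_go == FALSE)
  # never fixating: terminal without reward after the 10-step window
  env_reset(env, spec = 0)
  n <- 0
  repeat {
    s <- env_step(env, 0)
    n <- n + 1
    if (s$terminal) break
  }
  expect_lte(n, 11)
  expect_equal(env_trial_info(env)$total_reward, 0)
  # waiting out the go phase forfeits the reward
  env_reset(env, spec = 0)
  for (a in rep(1, 14)) { s <- env_step(env, a); if (s$terminal) break }
  expect_true(s$terminal)
  expect_equal(env_trial_info(env)$total_reward, 0.2)
})

test_that("environments replay bit-exactly from a seed", {
  for (task in c("saccade", "category", "classification", "vibrotactile")) {
    env <- make_env(task, seed = 99)
    grab <- function() {
      env_reset(env, seed = 1234)
      obs <- list()
      repeat {
        s <- env_step(env, 1)
        obs <- c(obs, list(s))
        if (s$terminal) break
      }
      obs
    }
    expect_identical(grab(), grab())
  }
})

test_that("reward emission per trial is one shaping plus at most one final reward", {
  env <- make_env("saccade", seed = 5)
  net <- augment_network(architecture_spec(n_inst = 4), seed = 5)
  tot <- replicate(300, run_trial(net, env)["reward"])
  expect_true(all(tot %in% c(0, 0.2, 1.7)))
})

test_that("a one-step stimulus produces matching on and off transients", {
  env <- make_env("category", seed = 6)
  env_reset(env, spec = c(3, 7))
  xs <- list()
  for (a in c(1, 1, 1, 1)) xs <- c(xs, list(env_step(env, a)$x))
  cue <- xs[[3]][-1]   # tuned units during the cue step
  after <- xs[[4]][-1]
  # nearest preferred direction is within 9 deg + 5-deg noise of the cue
  expect_gt(max(cue), 0.5)
  expect_true(all(after == 0))
  on_ev <- encode_sensory(cue, rep(0, 20))
  off_ev <- encode_sensory(after, cue)
  expect_equal(on_ev$x_on, off_ev$x_off)
})

test_that("direction tuning and the category match rule", {
  expect_equal(max(direction_tuning(54)), 1)         # stimulus at a preferred direction
  expect_equal(which.max(direction_tuning(90)), 6)   # preferred 18*(6-1)=90
  expect_equal(category_of(0), category_of(5))       # 15 and 165 same side
  expect_false(category_of(0) == category_of(6))
  env <- make_env("category", seed = 7)
  # same category (15 and 75 deg): left response rewarded
  env_reset(env, spec = c(0, 2))
  for (a in rep(1, 6)) env_step(env, a)
  s <- env_step(env, 0)
  expect_equal(s$reward, 1.5)
  # different categories: right is correct
  env_reset(env, spec = c(0, 8))
  for (a in rep(1, 6)) env_step(env, a)
  s <- env_step(env, 2)
  expect_equal(s$reward, 1.5)
  # fixation mark stays on through the comparison phase
  env_reset(env, spec = c(0, 8))
  xs <- list()
  for (a in rep(1, 7)) xs <- c(xs, list(env_step(env, a)$x))
  expect_equal(xs[[6]][1], 1)  # cue-2 step, mark still on
})

test_that("classification reward follows the weighted-evidence formula", {
  expect_equal(reward_prob_red(c(2)), 10^0.9 / (1 + 10^0.9))
  expect_equal(reward_prob_red(c(0, 0, 0, 0)), 1)      # all red trumps
  expect_equal(reward_prob_red(c(0, 1, 3, 3)), 10^-1.8 / (1 + 10^-1.8))
  expect_equal(reward_prob_red(c(2, 3)), 0.5)          # paired weights cancel
  # empirical bait frequency matches the formula
  env <- make_env("classification", seed = 8)
  seqs <- c(2, 4, 5, 9)  # W = 0.9 + 0.7 - 0.7 - 0.3 = 0.6
  p_target <- reward_prob_red(seqs)
  n <- 4000
  hits <- 0
  for (i in seq_len(n)) {
    env_reset(env, spec = seqs)
    info <- env_trial_info(env)
    red_action <- if (info$extra2 == 1) 2L else 0L
    for (a in rep(1, 9)) env_step(env, a)
    s <- env_step(env, red_action)
    expect_true(s$terminal)
    hits <- hits + (s$reward == 1.5)
  }
  expect_lt(abs(hits / n - p_target), 3 * sqrt(p_target * (1 - p_target) / n))
})

test_that("balanced evidence counts either response as correct", {
  env <- make_env("classification", seed = 9)
  for (resp in c(0L, 2L)) {
    env_reset(env, spec = c(2, 3))  # +0.9 and -0.9
    for (a in rep(1, 7)) env_step(env, a)
    env_step(env, resp)
    expect_true(env_trial_info(env)$correct)
  }
})

test_that("frequency tuning midpoints and F2 sampling constraints", {
  r <- frequency_tuning(5.5)
  expect_equal(r[1], 0.5)   # increasing unit centred at the stimulus
  expect_equal(r[2], 0.5)   # decreasing partner
  inc <- seq(1, 19, 2)
  expect_true(all(frequency_tuning(50)[inc] >= frequency_tuning(5)[inc]))
  expect_true(all(frequency_tuning(50)[-inc] <= frequency_tuning(5)[-inc]))
  env <- make_env("vibrotactile", seed = 10)
  f <- t(replicate(400, {
    env_reset(env)
    unlist(env_trial_info(env)[c("extra1", "extra2")])
  }))
  expect_true(all(abs(f[, 2] - f[, 1]) >= 2))
  expect_true(all(f >= 5 & f <= 50))
  envf <- make_env("vibrotactile", seed = 11, mode = "fixed")
  f <- t(replicate(200, {
    env_reset(envf)
    unlist(env_trial_info(envf)[c("extra1", "extra2")])
  }))
  expect_true(all(f[, 1] == 30))
  expect_true(all(abs(f[, 2] - 30) >= 10))
  expect_true(all(f[, 2] %% 2.5 == 0))
})

test_that("vibrotactile comparison rule depends on the remembered frequency", {
  env <- make_env("vibrotactile", seed = 12)
  go_right <- function(f1, f2, resp) {
    env_reset(env, spec = c(f1, f2))
    for (a in rep(1, 6)) env_step(env, a)
    env_step(env, resp)$reward
  }
  expect_equal(go_right(20, 25, 2L), 1.5)  # F2 > F1: right
  expect_equal(go_right(30, 25, 0L), 1.5)  # same F2, opposite answer
  expect_equal(go_right(30, 25, 2L), 0)
})
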