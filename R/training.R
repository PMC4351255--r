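#' Run a single trial
#'
#' Couples the agent and the environment until the terminal step is
#' processed (including the final weight update against the terminal
#' transition).  With `log = TRUE` a per-step record of phase, action,
#' reward, reward-prediction error, Q-values and association activities is
#' returned, which is the substrate of all representation analyses.
#'
#' @param net an [augment_network()].
#' @param env an `augment_env` with matching input dimension.
#' @param spec optional trial specification (see [env_reset()]).
#' @param log logical; collect the per-step log.
#' @param forced optional integer vector of actions (0-based) forced for the
#'   leading steps of the trial (`-1` entries defer to the policy); only
#'   available with `log = TRUE`.
#' @param max_steps hard cap on environment steps; exceeding it signals an
#'   environment bug.
#' @return With `log = FALSE`, a named numeric vector with `trial_type`,
#'   `correct`, `reward`, `steps`, `fix`, `go`, `responded`, `extra1`,
#'   `extra2`.  With `log = TRUE`, a list with elements `log` (matrix) and
#'   `info`.
#' @export
run_trial <- function(net, env, spec = NULL, log = FALSE, forced = NULL,
                      max_steps = 100L) {
  spec <- if (is.null(spec)) numeric(0) else as.numeric(spec)
  if (!log) {
    if (!is.null(forced))
      stop("'forced' requires log = TRUE")
    out <- run_trial_cpp(net$ptr, env$ptr, spec, max_steps)
    names(out) <- c("trial_type", "correct", "reward", "steps", "fix", "go",
                    "responded", "extra1", "extra2")
    return(out)
  }
  run_trial_logged_cpp(net$ptr, env$ptr, spec,
                       if (is.null(forced)) integer(0) else as.integer(forced),
                       max_steps)
}

# rolling per-stratum accuracy windows ---------------------------------------

new_windows <- function(n_strata, width) {
  list(buf = matrix(0L, nrow = width, ncol = n_strata),
       pos = integer(n_strata), n = integer(n_strata),
       hits = integer(n_strata), width = width)
}

push_window <- function(w, stratum, hit) {
  i <- stratum
  p <- w$pos[i] + 1L
  if (p > w$width) p <- 1L
  if (w$n[i] == w$width) w$hits[i] <- w$hits[i] - w$buf[p, i]
  w$buf[p, i] <- hit
  w$hits[i] <- w$hits[i] + hit
  w$pos[i] <- p
  if (w$n[i] < w$width) w$n[i] <- w$n[i] + 1L
  w
}

windows_pass <- function(w, threshold) {
  all(w$n == w$width) && all(w$hits >= threshold * w$width)
}

#' Train one network to criterion
#'
#' Runs the trial loop for a single network on one task until its
#' convergence criterion is satisfied or `max_trials` is exhausted.  The
#' criteria mirror the simulated experiments:
#' \describe{
#'   \item{saccade}{at least 90% correct in the last 50 trials of each of
#'     the four trial types; then learning and exploration are frozen and a
#'     verification battery (20 trials per type, at least 90% each) must
#'     pass, otherwise training resumes.  Milestones are recorded: `fix`
#'     (fixation attained in 90 of 100 consecutive trials), `go` (fixation
#'     maintained until the go signal, same rule) and `task`.}
#'   \item{category}{at least 80% correct in the last 50 trials for each of
#'     the twelve cue-1 directions.}
#'   \item{vibrotactile, variable F1}{at least 80% in the last 50 trials of
#'     each of nine 5-Hz F1 bins, followed by a frozen psychometric battery
#'     (F1 of 20/30/40 Hz, F2 offsets +/-2..10 Hz, 20 repeats; at least 50%
#'     at 2 Hz and better than 75% elsewhere); on failure training resumes.}
#'   \item{vibrotactile, fixed F1}{at least 90% in the last 50 trials of
#'     each admissible comparison frequency (the 2.5-Hz grid at least
#'     10 Hz from the 30-Hz reference).}
#' }
#' Probabilistic classification uses the curriculum driver
#' [run_curriculum()] instead.
#'
#' @param task task name as in [make_env()].
#' @param seed per-network seed (derive from a master seed with one seed per
#'   network).
#' @param params a [learning_params()].
#' @param arch optional [architecture_spec()]; defaults to the reference
#'   layer sizes for the task's input dimension.
#' @param max_trials training budget in trials.
#' @param shaping logical; `FALSE` removes the intermediate shaping reward.
#' @param keep_net logical; return the trained network handle.
#' @param ... environment options forwarded to [make_env()].
#' @return list with `converged`, `trials` (criterion trial or `NA`),
#'   milestones (`fix`, `go`) for the saccade task, and optionally `net`,
#'   `env`.
#' @export
train_network <- function(task, seed = 1L, params = learning_params(),
                          arch = NULL, max_trials = 25000L, shaping = TRUE,
                          keep_net = FALSE, ...) {
  env <- make_env(task, seed = derive_seed(seed, 0L, 3L),
                  ri = if (shaping) 0.2 else 0, ...)
  n_inst <- env_n_inputs(env$ptr)
  if (is.null(arch)) arch <- architecture_spec(n_inst = n_inst)
  net <- augment_network(arch, params, seed = derive_seed(seed, 0L, 1L))

  cfg <- switch(task,
    saccade = list(n_strata = 4L, width = 50L, thr = 0.90),
    category = list(n_strata = 12L, width = 50L, thr = 0.80),
    vibrotactile = NULL,
    stop("use run_curriculum() for the classification task"))
  if (task == "vibrotactile") {
    opts <- list(...)
    fixed <- !is.null(opts$mode) && opts$mode == "fixed"
    # fixed mode: one 50-trial window per admissible comparison frequency
    cfg <- if (fixed) list(n_strata = 12L, width = 50L, thr = 0.90)
           else list(n_strata = 9L, width = 50L, thr = 0.80)
    cfg$fixed <- fixed
  }

  w <- new_windows(cfg$n_strata, cfg$width)
  # 100-trial milestone windows (saccade)
  fix_hist <- integer(100); go_hist <- integer(100)
  fix_sum <- 0L; go_sum <- 0L
  fix_trial <- NA_integer_; go_trial <- NA_integer_
  converged <- FALSE; conv_trial <- NA_integer_

  trial <- 0L
  while (trial < max_trials) {
    trial <- trial + 1L
    r <- run_trial_cpp(net$ptr, env$ptr, numeric(0), 100L)
    stratum <- as.integer(r[1]) + 1L
    w <- push_window(w, stratum, as.integer(r[2]))

    if (task == "saccade") {
      slot <- (trial - 1L) %% 100L + 1L
      fix_sum <- fix_sum - fix_hist[slot] + as.integer(r[5])
      fix_hist[slot] <- as.integer(r[5])
      go_sum <- go_sum - go_hist[slot] + as.integer(r[6])
      go_hist[slot] <- as.integer(r[6])
      if (is.na(fix_trial) && trial >= 100L && fix_sum >= 90L)
        fix_trial <- trial
      if (is.na(go_trial) && trial >= 100L && go_sum >= 90L)
        go_trial <- trial
    }

    if (windows_pass(w, cfg$thr)) {
      ok <- verify_network(task, net, env, cfg)
      if (ok) {
        converged <- TRUE
        conv_trial <- trial
        break
      }
    }
  }
  out <- list(converged = converged, trials = conv_trial, seed = seed,
              fix = fix_trial, go = go_trial, total_trials = trial)
  if (keep_net) {
    out$net <- net
    out$env <- env
  }
  out
}

# frozen verification battery; returns TRUE on pass and leaves the network
# unfrozen again on failure
verify_network <- function(task, net, env, cfg) {
  p <- net_params(net$ptr)
  freeze_network(net)
  on.exit(net_set_params(net$ptr, p$beta, p$lambda, p$gamma, p$epsilon))
  ok <- TRUE
  if (task == "saccade") {
    for (ty in 0:3) {
      hits <- 0L
      for (i in 1:20)
        hits <- hits + run_trial_cpp(net$ptr, env$ptr, ty, 100L)[2]
      if (hits < 18) { ok <- FALSE; break }
    }
  } else if (task == "vibrotactile" && !cfg$fixed) {
    ok <- vibro_battery_pass(net, env, repeats = 20L)
  }
  ok
}

# psychometric verification battery for the variable-F1 task
vibro_battery_pass <- function(net, env, repeats = 20L) {
  offsets <- c(-10, -8, -6, -4, -2, 2, 4, 6, 8, 10)
  for (f1 in c(20, 30, 40)) {
    for (off in offsets) {
      hits <- 0L
      for (i in seq_len(repeats))
        hits <- hits + run_trial_cpp(net$ptr, env$ptr, c(f1, f1 + off), 100L)[2]
      acc <- hits / repeats
      if (abs(off) <= 2) {
        if (acc < 0.5) return(FALSE)
      } else if (acc <= 0.75) return(FALSE)
    }
  }
  TRUE
}

#' Shaping curriculum for the probabilistic classification task
#'
#' Trains a single network through the eight difficulty levels, enlarging
#' the symbol set (trumps first, then pairs of decreasing absolute weight)
#' and then the sequence length, advancing whenever the success rate over
#' the level-specific window reaches 85%.  Success means choosing the
#' target with the higher reward probability (either side counts when the
#' probabilities are equal).  Weights persist across levels; the budget
#' caps the total number of trials over all levels.
#'
#' @param seed per-network seed.
#' @param params a [learning_params()].
#' @param max_total total trial budget across the eight levels.
#' @param keep_net logical; return the trained network handle.
#' @return list with `converged`, `trials` (total across levels, `NA` if not
#'   converged), `level_trials` (per level), and optionally `net`, `env`.
#' @export
run_curriculum <- function(seed = 1L, params = learning_params(),
                           max_total = 500000L, keep_net = FALSE) {
  levels <- curriculum_levels()
  env <- make_env("classification", seed = derive_seed(seed, 0L, 3L))
  net <- augment_network(architecture_spec(n_inst = env_n_inputs(env$ptr)),
                         params, seed = derive_seed(seed, 0L, 1L))
  total <- 0L
  level_trials <- integer(nrow(levels))
  converged <- FALSE
  for (lv in seq_len(nrow(levels))) {
    env_set_option(env$ptr, "n_symbols", levels$n_symbols[lv])
    env_set_option(env$ptr, "seq_len", levels$seq_len[lv])
    width <- levels$window[lv]
    w <- new_windows(1L, width)
    done <- FALSE
    while (total < max_total) {
      total <- total + 1L
      level_trials[lv] <- level_trials[lv] + 1L
      r <- run_trial_cpp(net$ptr, env$ptr, numeric(0), 100L)
      w <- push_window(w, 1L, as.integer(r[2]))
      if (windows_pass(w, 0.85)) { done <- TRUE; break }
    }
    if (!done) break
    if (lv == nrow(levels)) converged <- TRUE
  }
  out <- list(converged = converged,
              trials = if (converged) total else NA_integer_,
              level_trials = level_trials, seed = seed, total_trials = total)
  if (keep_net) { out$net <- net; out$env <- env }
  out
}

#' @rdname run_curriculum
#' @export
curriculum_levels <- function() {
  data.frame(level = 1:8,
             n_symbols = c(2L, 4L, 6L, 8L, 10L, 10L, 10L, 10L),
             seq_len = c(1L, 1L, 1L, 1L, 1L, 2L, 3L, 4L),
             window = c(1000L, 1500L, 2000L, 2500L, 3000L, 10000L, 10000L,
                        20000L))
}

#' Block training with a fixed comparison frequency per block
#'
#' Takes a network previously trained on the fixed-F1 task and continues
#' training in three blocks with F1 of 20, 30 and 40 Hz (random order of
#' the first two, 30 Hz always last).  Within a block the ten F2 offsets
#' (+/-2, 4, ..., 10 Hz) are each presented 150 times in random order.
#' Afterwards the network is frozen and the psychometric battery of
#' [psychometric_curves()] probes whether choices track F2 relative to the
#' final 30 Hz block rather than the nominal F1.
#'
#' @param net a trained [augment_network()] (learning still enabled).
#' @param env the `augment_env` used in training (vibrotactile).
#' @param reps presentations of each F2 offset per block.
#' @param seed seed for the block order and trial shuffling.
#' @return list with per-block training accuracies and the block order.
#' @export
block_training <- function(net, env, reps = 150L, seed = 1L) {
  set.seed(seed)
  order_f1 <- c(sample(c(20, 40)), 30)
  offsets <- c(-10, -8, -6, -4, -2, 2, 4, 6, 8, 10)
  block_acc <- numeric(length(order_f1))
  for (b in seq_along(order_f1)) {
    f1 <- order_f1[b]
    f2s <- sample(rep(f1 + offsets, reps))
    hits <- 0
    for (f2 in f2s)
      hits <- hits + run_trial_cpp(net$ptr, env$ptr, c(f1, f2), 100L)[2]
    block_acc[b] <- hits / length(f2s)
  }
  list(order = order_f1, accuracy = block_acc)
}

#' Train a population of independent networks
#'
#' Repeats [train_network()] (or [run_curriculum()] for the classification
#' task) over `n_networks` seeds derived from one master seed and summarises
#' convergence: the fraction of converged networks with a binomial
#' confidence interval, and the median trials-to-criterion over converged
#' networks.
#'
#' @param task task name; `"classification"` dispatches to the curriculum.
#' @param n_networks number of independently initialised networks.
#' @param seed master seed; network `i` uses `derive_seed(seed, i)`.
#' @param max_trials per-network budget (total budget for classification).
#' @param keep_nets logical; keep the trained network handles (memory heavy
#'   for large populations, but needed for representation analyses).
#' @param ... forwarded to [train_network()].
#' @return list of class `augment_experiment` with `networks` (data frame),
#'   `summary` and, if requested, `nets`.
#' @export
run_experiment <- function(task, n_networks = 100L, seed = 1L,
                           max_trials = 25000L, keep_nets = FALSE, ...) {
  rows <- vector("list", n_networks)
  nets <- if (keep_nets) vector("list", n_networks) else NULL
  for (i in seq_len(n_networks)) {
    si <- derive_seed(seed, i)
    res <- if (task == "classification") {
      run_curriculum(seed = si, max_total = max_trials, keep_net = keep_nets,
                     ...)
    } else {
      train_network(task, seed = si, max_trials = max_trials,
                    keep_net = keep_nets, ...)
    }
    rows[[i]] <- data.frame(
      network = i, seed = si, converged = res$converged,
      trials = ifelse(res$converged, res$trials, NA_integer_),
      fix = if (!is.null(res$fix)) res$fix else NA_integer_,
      go = if (!is.null(res$go)) res$go else NA_integer_)
    if (keep_nets) nets[[i]] <- res[c("net", "env")]
  }
  networks <- do.call(rbind, rows)
  conv <- networks$converged
  ci <- stats::binom.test(sum(conv), n_networks)$conf.int
  summary <- list(
    task = task, n_networks = n_networks,
    n_converged = sum(conv), fraction_converged = mean(conv),
    fraction_ci = as.numeric(ci),
    median_trials = stats::median(networks$trials[conv]),
    median_fix = stats::median(networks$fix[conv]),
    median_go = stats::median(networks$go[conv]))
  structure(list(networks = networks, summary = summary, nets = nets,
                 seed = seed),
            class = "augment_experiment")
}

#' @export
print.augment_experiment <- function(x, ...) {
  s <- x$summary
  cat(sprintf("experiment '%s': %d/%d networks converged (%.1f%%)\n",
              s$task, s$n_converged, s$n_networks,
              100 * s$fraction_converged))
  if (!is.na(s$median_trials))
    cat(sprintf("  median trials to criterion: %s\n",
                format(s$median_trials, big.mark = ",")))
  if (!is.null(s$median_fix) && !is.na(s$median_fix))
    cat(sprintf("  median fixation milestone: %s trials\n",
                format(s$median_fix, big.mark = ",")))
  invisible(x)
}

#' Parameter and network-size sweeps
#'
#' `sweep_parameters()` trains `n_networks` networks for every combination
#' of learning rate and tag-decay values and reports convergence fraction
#' and median trials.  `sweep_size()` scales the association layer
#' (regular and memory unit counts multiplied by `factors`), optionally
#' scaling `beta` and `lambda` jointly, as used to probe robustness of the
#' learning scheme to network size.
#'
#' @param task task name as in [make_env()].
#' @param beta_grid,lambda_grid numeric grids to sweep.
#' @param n_networks networks per grid cell.
#' @param seed master seed.
#' @param max_trials per-network budget.
#' @param ... forwarded to [train_network()].
#' @return data frame with one row per cell.
#' @export
sweep_parameters <- function(task, beta_grid = seq(0.05, 1, by = 0.05),
                             lambda_grid = seq(0, 0.9, by = 0.1),
                             n_networks = 10L, seed = 1L,
                             max_trials = 25000L, ...) {
  grid <- expand.grid(beta = beta_grid, lambda = lambda_grid)
  out <- vector("list", nrow(grid))
  for (g in seq_len(nrow(grid))) {
    p <- learning_params(beta = grid$beta[g], lambda = grid$lambda[g])
    res <- run_experiment(task, n_networks = n_networks,
                          seed = derive_seed(seed, g, 7L),
                          max_trials = max_trials, params = p, ...)
    out[[g]] <- data.frame(beta = grid$beta[g], lambda = grid$lambda[g],
                           fraction = res$summary$fraction_converged,
                           median_trials = res$summary$median_trials)
  }
  do.call(rbind, out)
}

#' @rdname sweep_parameters
#' @param factors association-layer scale factors (multiply the regular and
#'   memory unit counts).
#' @param scale_learning logical; also scale `beta` and `lambda` by
#'   `1/factor` (capped below at the smallest tested scaling of 1/8).
#' @export
sweep_size <- function(task, factors = c(1, 2, 4, 8), n_networks = 10L,
                       seed = 1L, max_trials = 25000L,
                       scale_learning = FALSE, ...) {
  out <- vector("list", length(factors))
  base <- learning_params()
  for (g in seq_along(factors)) {
    f <- factors[g]
    s <- if (scale_learning) max(1 / f, 1 / 8) else 1
    p <- learning_params(beta = base$beta * s, lambda = base$lambda * s)
    env0 <- make_env(task, seed = 0L)
    arch <- architecture_spec(n_inst = env_n_inputs(env0$ptr),
                              n_regular = 3L * f, n_memory = 4L * f)
    res <- run_experiment(task, n_networks = n_networks,
                          seed = derive_seed(seed, g, 11L),
                          max_trials = max_trials, params = p, arch = arch,
                          ...)
    out[[g]] <- data.frame(factor = f, beta = p$beta, lambda = p$lambda,
                           fraction = res$summary$fraction_converged,
                           median_trials = res$summary$median_trials)
  }
  do.call(rbind, out)
}
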