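#' Task environments
#'
#' Discrete-time generative environments for the four simulated experiments.
#' All tasks share the same trial skeleton and the same three-action
#' interface (0 = left, 1 = centre/hold, 2 = right): the agent first has to
#' acquire fixation (or hold the response key) within 10 steps, is then
#' shown the sample stimulus together with a small shaping reward `r_i`
#' (0.2 units by default), must hold through a two-step memory delay, and
#' finally responds during a go phase (at most 8 waiting steps).  A correct
#' response earns the full reward `r_f` (1.5 units); wrong responses, broken
#' fixation and timeouts terminate the trial without further reward.
#'
#' Tasks and their options (passed as `...`):
#' \describe{
#'   \item{`"saccade"`}{memory pro-/antisaccade.  4 inputs: black and white
#'     fixation marks (black = pro, white = anti) and left/right cues.
#'     `pro_only = TRUE` presents identical stimuli but always rewards the
#'     pro-saccade, making fixation colour irrelevant.}
#'   \item{`"category"`}{delayed match-to-category.  21 inputs: a fixation
#'     unit plus 20 units with circular Gaussian direction tuning
#'     (`tuning_sd = 12` deg).  Twelve motion directions spaced 30 deg
#'     apart are split into two categories of six; cue directions receive
#'     Gaussian noise (`noise_sd = 5` deg).  Respond left on a category
#'     match, right otherwise; the fixation mark stays on, cue-2 onset is
#'     the go signal.}
#'   \item{`"classification"`}{probabilistic weighted-symbol decision.
#'     45 inputs: fixation, four target units (side x colour) and 10
#'     symbols x 4 locations.  Symbols carry evidence weights
#'     (trump +/-Inf, then +/-0.9, 0.7, 0.5, 0.3); reward is assigned to
#'     the red target with probability `10^W / (1 + 10^W)` where `W` sums
#'     the sequence weights (a net trump excess forces its side).
#'     `n_symbols` and `seq_len` set the curriculum level.}
#'   \item{`"vibrotactile"`}{two-frequency comparison.  21 inputs: 20
#'     sigmoid frequency-tuned units (paired increasing/decreasing, centres
#'     5.5--49.5 Hz, steepness +/-5, additive rate noise sd
#'     `noise_sd = 0.075` truncated to \[0,1\]) and a binary skin-contact
#'     unit.  `mode = "variable"` draws F1 uniformly from 5--50 Hz and F2
#'     with at least 2 Hz separation; `mode = "fixed"` uses F1 = 30 Hz and
#'     F2 on a 2.5 Hz grid at least 10 Hz away.  Respond left if F2 < F1,
#'     right otherwise.}
#' }
#'
#' @param task one of `"saccade"`, `"category"`, `"classification"`,
#'   `"vibrotactile"`.
#' @param seed integer seed for the task's private random stream.
#' @param ri,rf shaping and final reward (units); `ri = 0` disables shaping.
#' @param ... task options, see Details.
#' @return An object of class `augment_env`.
#' @examples
#' env <- make_env("saccade", seed = 1)
#' s <- env_reset(env)          # empty screen
#' s <- env_step(env, 1)        # fixation mark appears
#' @export
make_env <- function(task = c("saccade", "category", "classification",
                              "vibrotactile"),
                     seed = 1L, ri = 0.2, rf = 1.5, ...) {
  task <- match.arg(task)
  ptr <- env_create(task, as.integer(seed %% 2147483647))
  env_set_option(ptr, "ri", ri)
  env_set_option(ptr, "rf", rf)
  opts <- list(...)
  for (k in names(opts)) {
    v <- opts[[k]]
    if (k == "mode") {
      v <- match(match.arg(v, c("variable", "fixed")), c("variable", "fixed"))
    }
    env_set_option(ptr, k, if (is.logical(v)) as.numeric(v) else as.numeric(v))
  }
  structure(list(ptr = ptr, task = task, seed = seed),
            class = "augment_env")
}

#' @export
print.augment_env <- function(x, ...) {
  cat(sprintf("task environment '%s' (%d sensory inputs)\n", x$task,
              env_n_inputs(x$ptr)))
  invisible(x)
}

#' Reset an environment to a fresh trial
#'
#' @param env an `augment_env`.
#' @param spec optional trial specification overriding the randomisation:
#'   saccade `c(type)` with type 0..3 = (pro/anti) x (left/right); category
#'   `c(cue1, cue2)` (0-based direction indices); classification an integer
#'   vector of symbol indices (0-based); vibrotactile `c(F1, F2)` in Hz.
#' @param seed optional reseed of the task stream before the trial.
#' @return list with the first observation: `x`, `reward`, `terminal`.
#' @export
env_reset <- function(env, spec = NULL, seed = NULL) {
  if (!is.null(seed)) env_reseed(env$ptr, as.integer(seed %% 2147483647))
  env_reset_r(env$ptr, if (is.null(spec)) numeric(0) else as.numeric(spec))
}

#' Advance an environment by one action
#' @param env an `augment_env`.
#' @param action integer in 0..2 (0 left, 1 centre/hold, 2 right).
#' @return list `x`, `reward`, `terminal`.
#' @export
env_step <- function(env, action) env_step_r(env$ptr, as.integer(action))

#' Trial metadata of the most recent trial
#' @param env an `augment_env`.
#' @return list with `trial_type`, `fix_attained`, `reached_go`,
#'   `responded`, `correct`, `total_reward` and task-specific extras
#'   (`extra1`/`extra2`: category cue indices, classification P(red),
#'   vibrotactile F1/F2).
#' @export
env_trial_info <- function(env) env_info(env$ptr)

#' Set an environment option on an existing environment
#' @param env an `augment_env`.
#' @param key option name (see [make_env()]).
#' @param value numeric value.
#' @export
env_option <- function(env, key, value) {
  env_set_option(env$ptr, key, as.numeric(value))
  invisible(env)
}

# ---------------------------------------------------------------------------
# tuning curves and task maths, exposed for analysis and tests
# ---------------------------------------------------------------------------

#' Circular Gaussian direction tuning
#'
#' Activity of the 20 direction-tuned units for a motion direction:
#' `exp(-d^2 / (2 sd^2))` with `d` the angular distance to the preferred
#' direction; preferred directions are spaced every 18 degrees.
#' @param angle stimulus direction in degrees.
#' @param sd tuning width in degrees.
#' @return numeric vector of 20 activities.
#' @export
direction_tuning <- function(angle, sd = 12) {
  pref <- 18 * (0:19)
  d <- abs(angle - pref) %% 360
  d <- pmin(d, 360 - d)
  exp(-d^2 / (2 * sd^2))
}

#' Motion directions and categories of the match-to-category task
#'
#' Twelve directions at 30-degree spacing starting at 15 degrees; the
#' category boundary runs along 0/180 degrees, so directions 15..165 form
#' one category and 195..345 the other.
#' @param idx 0-based direction index (0..11).
#' @export
category_direction <- function(idx) 15 + 30 * idx

#' @rdname category_direction
#' @export
category_of <- function(idx) ifelse(idx < 6, 0L, 1L)

#' Sigmoidal frequency tuning of the vibrotactile input layer
#'
#' Ten centre frequencies evenly spaced on 5.5--49.5 Hz, each represented by
#' an increasing and a decreasing sigmoid of steepness `+/-steep`.  Units are
#' interleaved (increasing, decreasing, ...).
#' @param f stimulus frequency in Hz.
#' @param steep tuning steepness.
#' @return numeric vector of 20 noise-free rates.
#' @export
frequency_tuning <- function(f, steep = 5) {
  centres <- seq(5.5, 49.5, length.out = 10)
  up <- 1 / (1 + exp(steep * (centres - f)))
  dn <- 1 / (1 + exp(-steep * (centres - f)))
  as.numeric(rbind(up, dn))
}

#' Symbol evidence weights of the classification task
#'
#' In presentation order used by the shaping curriculum: the red and green
#' trump symbols (+Inf/-Inf, they guarantee reward for their target), then
#' the finite pairs +/-0.9, +/-0.7, +/-0.5, +/-0.3.
#' @return numeric vector of length 10.
#' @export
symbol_weights <- function() {
  c(Inf, -Inf, 0.9, -0.9, 0.7, -0.7, 0.5, -0.5, 0.3, -0.3)
}

#' Probability that the red target is baited
#'
#' `P(red | s) = 10^W / (1 + 10^W)` where `W` sums the evidence weights of
#' the symbol sequence; an excess of red (green) trumps forces 1 (0), and
#' equal numbers of opposing trumps cancel.
#' @param symbols integer vector of 0-based symbol indices.
#' @export
reward_prob_red <- function(symbols) {
  w <- symbol_weights()
  trump <- sum(symbols == 0) - sum(symbols == 1)
  if (trump > 0) return(1)
  if (trump < 0) return(0)
  W <- sum(w[symbols[symbols >= 2] + 1])
  10^W / (1 + 10^W)
}
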