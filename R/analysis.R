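#' Association-layer activity over the saccade/antisaccade trial
#'
#' Runs a frozen network once on each of the four trial types and stacks
#' the association-layer activities (3 regular + 4 memory units) for the
#' eight time points of the canonical trial (empty screen, two fixation
#' steps, cue, two delay steps, go, saccade) into a single 32 x 7
#' observation matrix.  Freeze the network first; with exploration off the
#' trials are deterministic.
#'
#' @param net a trained, frozen [augment_network()].
#' @param env a saccade `augment_env`.
#' @return matrix with 32 rows (8 time points x 4 trial types; attributes
#'   `trial_type` and `time`) and 7 columns, plus a `q` attribute holding
#'   the corresponding 32 x 3 Q-value matrix.
#' @export
saccade_activity_matrix <- function(net, env) {
  rows <- vector("list", 4L)
  qrows <- vector("list", 4L)
  for (ty in 0:3) {
    tr <- run_trial(net, env, spec = ty, log = TRUE)
    lg <- tr$log
    if (nrow(lg) != 8L)
      stop("trial of type ", ty, " lasted ", nrow(lg),
           " steps; the activity matrix needs the canonical 8-step trial ",
           "(is the network trained and frozen?)")
    rows[[ty + 1L]] <- lg[, grep("^y_", colnames(lg)), drop = FALSE]
    qrows[[ty + 1L]] <- lg[, grep("^q_", colnames(lg)), drop = FALSE]
  }
  mat <- do.call(rbind, rows)
  structure(mat,
            trial_type = rep(0:3, each = 8L),
            time = rep(1:8, times = 4L),
            q = do.call(rbind, qrows))
}

#' Principal components of association-layer activity
#'
#' Centred PCA of an activity observation matrix (rows = time points x
#' trial types, columns = association units), as used to visualise the
#' learned representation.
#'
#' @param mat observation matrix, e.g. from [saccade_activity_matrix()].
#' @return list with `variance_explained` (fraction per component),
#'   `projection` (observations onto the first two components), `rotation`.
#' @export
pca_association <- function(mat) {
  if (all(apply(mat, 2, stats::var) < .Machine$double.eps))
    stop("activity matrix is constant; variance explained is undefined")
  p <- stats::prcomp(mat, center = TRUE, scale. = FALSE)
  ve <- p$sdev^2 / sum(p$sdev^2)
  list(variance_explained = ve,
       projection = p$x[, 1:2, drop = FALSE],
       rotation = p$rotation)
}

#' Representational similarity across trial types
#'
#' For one unit group (memory, regular or Q) and each time point, computes
#' the pairwise Euclidean distances between the activity vectors of the
#' four saccade trial types and marks the pair with the smallest distance
#' (ties split their unit of mass equally).  Averaging these incidence
#' matrices across networks shows which trial types are represented most
#' similarly at each stage of the trial.
#'
#' @param mats list of matrices from [saccade_activity_matrix()], one per
#'   network.
#' @param group `"memory"`, `"regular"` or `"q"`.
#' @return array `4 x 4 x 8` (trial type x trial type x time point); upper
#'   triangle holds the averaged incidence mass, each network contributing
#'   mass 1 per time point.
#' @export
similarity_matrices <- function(mats, group = c("memory", "regular", "q")) {
  group <- match.arg(group)
  out <- array(0, dim = c(4, 4, 8))
  for (m in mats) {
    act <- switch(group,
      memory = m[, grep("^y_mem_", colnames(m)), drop = FALSE],
      regular = m[, grep("^y_reg_", colnames(m)), drop = FALSE],
      q = attr(m, "q"))
    ty <- attr(m, "trial_type")
    tm <- attr(m, "time")
    for (s in 1:8) {
      v <- act[tm == s, , drop = FALSE][order(ty[tm == s]), , drop = FALSE]
      d <- as.matrix(stats::dist(v))
      diag(d) <- Inf
      mn <- min(d)
      hits <- which(d == mn & upper.tri(d), arr.ind = TRUE)
      for (h in seq_len(nrow(hits)))
        out[hits[h, 1], hits[h, 2], s] <-
          out[hits[h, 1], hits[h, 2], s] + 1 / nrow(hits)
    }
  }
  out / length(mats)
}

#' Delay-period direction tuning of memory units
#'
#' Measures memory-unit activity at the last delay step for each of the
#' twelve cue-1 directions (averaged over noise repeats) in a frozen
#' network trained on the match-to-category task.
#'
#' @param net a trained, frozen [augment_network()].
#' @param env a category `augment_env`.
#' @param repeats noise repeats to average per direction.
#' @return matrix `12 x n_memory` of mean delay activities.
#' @export
category_delay_tuning <- function(net, env, repeats = 10L) {
  n_mem <- net$arch$n_memory
  tune <- matrix(0, 12, n_mem)
  for (d in 0:11) {
    acc <- numeric(n_mem)
    for (r in seq_len(repeats)) {
      tr <- run_trial(net, env, spec = c(d, 0), log = TRUE,
                      forced = rep(1L, 6L))
      lg <- tr$log
      delay <- which(lg[, "phase"] == 3)
      acc <- acc + lg[max(delay), grep("^y_mem_", colnames(lg))]
    }
    tune[d + 1L, ] <- acc / repeats
  }
  tune
}

#' Preferred direction-change of category-trained memory units
#'
#' For every memory unit, finds the adjacent pair of cue directions (30
#' degrees apart) that elicits the largest absolute difference in delay
#' activity and reports whether that pair crosses the category boundary.
#' Units whose largest adjacent difference is below `floor` are discarded
#' as untuned.
#'
#' @param tunings list of matrices from [category_delay_tuning()], one per
#'   network.
#' @param floor minimal activity difference for a unit to count as tuned.
#' @return list with `pair_counts` (12 adjacent pairs, count of units
#'   preferring each), `boundary_fraction`, `n_units`.
#' @export
category_change_histogram <- function(tunings, floor = 1e-3) {
  # adjacent pairs (i, i+1 mod 12); pairs 6 (165->195) and 12 (345->15)
  # straddle the 0/180-degree boundary
  boundary_pairs <- c(6L, 12L)
  counts <- integer(12)
  n_units <- 0L
  for (tune in tunings) {
    for (u in seq_len(ncol(tune))) {
      diffs <- abs(tune[c(2:12, 1), u] - tune[, u])
      if (max(diffs) < floor) next
      counts[which.max(diffs)] <- counts[which.max(diffs)] + 1L
      n_units <- n_units + 1L
    }
  }
  list(pair_counts = counts,
       boundary_fraction = if (n_units > 0)
         sum(counts[boundary_pairs]) / n_units else NA_real_,
       n_units = n_units)
}

# ---------------------------------------------------------------------------
# probabilistic classification analyses
# ---------------------------------------------------------------------------

#' Enumerate symbol sequences and their reward log-likelihood ratios
#'
#' Enumerates all `10^4` ordered length-4 symbol sequences, computes the
#' probability that the red target is baited for each, and derives the
#' conditional probability for every prefix length by marginalising
#' uniformly over the unobserved symbols.  The log-likelihood ratio is
#' `log10(P(R|s_l) / (1 - P(R|s_l)))`; prefixes containing an unmatched
#' trump have infinite magnitude and are assigned to the extreme quintiles.
#'
#' @return list with `p_full` (vector of length 10000) and `prefixes`, a
#'   data frame with `length`, `prefix` (encoded), `p`, `loglr` and
#'   `quintile` (1..5 within each length).
#' @export
loglr_table <- function() {
  grid <- as.matrix(expand.grid(s1 = 0:9, s2 = 0:9, s3 = 0:9, s4 = 0:9))
  p_full <- apply(grid, 1, reward_prob_red)
  pref <- vector("list", 4L)
  for (l in 1:4) {
    key <- apply(grid[, seq_len(l), drop = FALSE], 1, paste, collapse = ".")
    p <- tapply(p_full, key, mean)
    loglr <- log10(p / (1 - p))
    # rank-based quintiles; +/-Inf sort to the extremes naturally
    qt <- ceiling(5 * rank(loglr, ties.method = "average") / length(loglr))
    qt <- pmin(pmax(qt, 1L), 5L)
    pref[[l]] <- data.frame(length = l, prefix = names(p), p = as.numeric(p),
                            loglr = as.numeric(loglr), quintile = qt,
                            row.names = NULL)
  }
  list(p_full = p_full, prefixes = do.call(rbind, pref))
}

#' Memory-unit activity by evidence quintile
#'
#' Samples random full-length trials from a frozen classification-trained
#' network, records memory-unit activity after each successive symbol, and
#' averages it within the log-likelihood-ratio quintile of the observed
#' prefix.  Per unit, the quintile order is flipped where needed so that
#' activity increases with the quintile (units integrate evidence for
#' either target), then averaged across units.
#'
#' @param net a trained, frozen [augment_network()].
#' @param env a classification `augment_env` (full task level).
#' @param n_trials number of sampled trials.
#' @param table optional precomputed [loglr_table()].
#' @return list with `mean_activity` (matrix length x quintile, averaged
#'   over aligned units) and `per_unit` (array unit x length x quintile).
#' @export
loglr_quintile_activity <- function(net, env, n_trials = 2000L,
                                    table = NULL) {
  if (is.null(table)) table <- loglr_table()
  pref <- table$prefixes
  qmap <- split(stats::setNames(pref$quintile, pref$prefix), pref$length)
  n_mem <- net$arch$n_memory
  sums <- array(0, c(n_mem, 4, 5))
  cnts <- array(0, c(4, 5))
  for (i in seq_len(n_trials)) {
    seq4 <- sample(0:9, 4, replace = TRUE)
    tr <- run_trial(net, env, spec = seq4, log = TRUE, forced = rep(1L, 3L))
    lg <- tr$log
    sym_rows <- which(lg[, "phase"] == 2)
    if (length(sym_rows) < 4) next  # aborted trial
    ycols <- grep("^y_mem_", colnames(lg))
    for (l in 1:4) {
      key <- paste(seq4[seq_len(l)], collapse = ".")
      qt <- qmap[[l]][[key]]
      sums[, l, qt] <- sums[, l, qt] + lg[sym_rows[l], ycols]
      cnts[l, qt] <- cnts[l, qt] + 1
    }
  }
  per_unit <- sweep(sums, c(2, 3), pmax(cnts, 1), "/")
  aligned <- per_unit
  for (u in seq_len(n_mem)) {
    if (per_unit[u, 4, 1] > per_unit[u, 4, 5])
      aligned[u, , ] <- per_unit[u, , 5:1]
  }
  list(mean_activity = apply(aligned, c(2, 3), mean), per_unit = per_unit,
       counts = cnts)
}

#' Correlation of learned symbol weights with the true evidence weights
#'
#' For each memory unit, averages the incoming on-channel synaptic weights
#' of every symbol over its four retinotopic locations and computes the
#' Spearman correlation with the true evidence weights (trumps rank at the
#' extremes).  Units with constant weight vectors have undefined
#' correlation and are recorded as 0.
#'
#' @param net a trained [augment_network()] on the classification task.
#' @return numeric vector of Spearman correlations, one per memory unit.
#' @export
symbol_weight_correlation <- function(net) {
  Vm <- network_weights(net)$V_memory
  n_inst <- net$arch$n_inst
  true_w <- symbol_weights()
  sapply(seq_len(ncol(Vm)), function(u) {
    avg <- sapply(0:9, function(s) {
      rows <- 5 + 10 * (0:3) + s + 1  # on-channel rows of symbol s
      mean(Vm[rows, u])
    })
    if (stats::sd(avg) < .Machine$double.eps) return(0)
    stats::cor(avg, true_w, method = "spearman")
  })
}

# ---------------------------------------------------------------------------
# vibrotactile analyses
# ---------------------------------------------------------------------------

# exact normal-equation OLS of each activity column on (1, F1, F2);
# rows with missing activities are dropped
ols_f1f2 <- function(acts, grid) {
  ok <- stats::complete.cases(acts)
  X <- cbind(1, grid$F1[ok], grid$F2[ok])
  solve(crossprod(X), crossprod(X, acts[ok, , drop = FALSE]))
}

#' Two-frequency regression of unit activity
#'
#' Evaluates a frozen network on every combination of the two vibration
#' frequencies on a 1-Hz grid (5..50 Hz) with noise-free tuning, samples
#' each unit's activity at the comparison step (F2 on screen), and fits
#' `activity = a1 * F1 + a2 * F2 + b` by ordinary least squares.  Memory
#' units with opposite signs of `a1` and `a2` encode the difference between
#' the stored and the current frequency.
#'
#' @param net a trained, frozen [augment_network()].
#' @param env a vibrotactile `augment_env`; sensory noise is switched off
#'   for the grid and restored afterwards.
#' @param freqs frequency grid (Hz).
#' @return data frame with one row per unit: `unit`, `group` (`regular`,
#'   `memory`, `q`), `a1`, `a2`, `b`; attribute `memory_cor` holds the
#'   Pearson correlation of (`a1`, `a2`) over memory units.
#' @export
f1f2_regression <- function(net, env, freqs = 5:50) {
  env_set_option(env$ptr, "noise_sd", 0)
  on.exit(env_set_option(env$ptr, "noise_sd", 0.075))
  grid <- expand.grid(F1 = freqs, F2 = freqs)
  n_reg <- net$arch$n_regular
  n_mem <- net$arch$n_memory
  n_q <- net$arch$n_q
  acts <- matrix(0, nrow(grid), n_reg + n_mem + n_q)
  for (i in seq_len(nrow(grid))) {
    # hold through the comparison onset so that every grid point reaches the
    # F2 step; activities depend on the observations only
    tr <- run_trial(net, env, spec = c(grid$F1[i], grid$F2[i]), log = TRUE,
                    forced = rep(1L, 7L))
    lg <- tr$log
    row <- which(lg[, "phase"] == 4)[1]
    acts[i, ] <- c(lg[row, grep("^y_reg_", colnames(lg))],
                   lg[row, grep("^y_mem_", colnames(lg))],
                   lg[row, grep("^q_", colnames(lg))])
  }
  coef <- ols_f1f2(acts, grid)
  out <- data.frame(
    unit = seq_len(ncol(acts)),
    group = rep(c("regular", "memory", "q"), c(n_reg, n_mem, n_q)),
    a1 = coef[2, ], a2 = coef[3, ], b = coef[1, ])
  mem <- out$group == "memory"
  attr(out, "memory_cor") <- stats::cor(out$a1[mem], out$a2[mem])
  out
}

#' Psychometric curves of a frozen network
#'
#' Presents each (F1, F2) comparison repeatedly with sensory noise on,
#' records the proportion of "F2 > F1" choices, and fits a two-parameter
#' logistic curve per F1.  For networks trained with a variable F1 the
#' fitted location tracks F1; after block training with a fixed 30-Hz
#' reference the locations collapse onto 30 Hz.
#'
#' @param net a trained, frozen [augment_network()].
#' @param env a vibrotactile `augment_env`.
#' `p_higher` is the proportion of "F2 higher" choices among trials on
#' which the network expressed a choice; `response_rate` records how often
#' it responded at all (trained networks respond on essentially every
#' trial, but block-trained networks probed with an unfamiliar reference
#' frequency sometimes withhold their response until the window closes).
#'
#' @param f1s reference frequencies (Hz).
#' @param offsets F2 offsets relative to F1 (Hz).
#' @param repeats presentations per comparison.
#' @return list with `responses` (data frame F1, F2, `p_higher`,
#'   `response_rate`) and `fits`: one logistic fit per F1 (`location`,
#'   `slope`, `degenerate`) plus a pooled fit over all comparisons
#'   (`F1 = NA`).  A fit is flagged degenerate when the choices contain no
#'   intermediate proportions (all 0/1); its location is then the empirical
#'   step threshold (or `NA` when the choices never switch) and the slope
#'   is `NA`.  The pooled fit is the relevant summary for block-trained
#'   networks, whose choices depend on F2 alone.
#' @export
psychometric_curves <- function(net, env, f1s = c(20, 30, 40),
                                offsets = c(-10, -8, -6, -4, -2, 2, 4, 6,
                                            8, 10),
                                repeats = 100L) {
  rows <- list()
  for (f1 in f1s) {
    f2s <- f1 + offsets
    nright <- integer(length(f2s))
    nresp <- integer(length(f2s))
    for (j in seq_along(f2s)) {
      for (k in seq_len(repeats)) {
        r <- run_trial(net, env, spec = c(f1, f2s[j]))
        if (r["responded"] == 1) {
          nresp[j] <- nresp[j] + 1L
          # "responded F2 > F1" = right choice
          right <- (r["correct"] == 1) == (f2s[j] > f1)
          nright[j] <- nright[j] + as.integer(right)
        }
      }
    }
    rows[[as.character(f1)]] <- data.frame(
      F1 = f1, F2 = f2s,
      p_higher = ifelse(nresp > 0, nright / nresp, NA_real_),
      response_rate = nresp / repeats, n_right = nright, n_resp = nresp)
  }
  responses <- do.call(rbind, c(rows, make.row.names = FALSE))
  logi_fit <- function(d, f1val) {
    d <- d[d$n_resp > 0, ]
    if (nrow(d) < 2)
      return(data.frame(F1 = f1val, location = NA_real_, slope = NA_real_,
                        degenerate = TRUE, row.names = NULL))
    degenerate <- all(d$n_right == 0 | d$n_right == d$n_resp)
    if (degenerate) {
      # all-or-none choices: the slope is unidentified; report the
      # empirical step threshold as the location when one exists
      lo <- d$F2[d$p_higher <= 0.5]
      hi <- d$F2[d$p_higher > 0.5]
      loc <- if (length(lo) && length(hi) && max(lo) < min(hi))
        (max(lo) + min(hi)) / 2 else NA_real_
      return(data.frame(F1 = f1val, location = loc, slope = NA_real_,
                        degenerate = TRUE, row.names = NULL))
    }
    fit <- suppressWarnings(
      stats::glm(cbind(n_right, n_resp - n_right) ~ F2, data = d,
                 family = stats::binomial()))
    b <- stats::coef(fit)
    data.frame(F1 = f1val, location = -b[1] / b[2], slope = b[2],
               degenerate = FALSE, row.names = NULL)
  }
  fits <- do.call(rbind, c(lapply(f1s, function(f1)
    logi_fit(responses[responses$F1 == f1, ], f1)), make.row.names = FALSE))
  pooled <- logi_fit(responses, NA_real_)
  list(responses = responses[, c("F1", "F2", "p_higher", "response_rate")],
       fits = rbind(fits, pooled))
}
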