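test_that("PCA of association activity: variance fractions and rank bound", {
  set.seed(1)
  mat <- matrix(rnorm(32 * 7), 32, 7)
  p <- pca_association(mat)
  expect_equal(sum(p$variance_explained), 1)
  expect_lte(sum(p$variance_explained > 1e-12), 7)
  expect_equal(dim(p$projection), c(32L, 2L))
  expect_error(pca_association(matrix(1, 10, 3)), "constant")
})

test_that("similarity matrices mark closest trial types and conserve mass", {
  # synthetic activity: types 1 and 2 identical for memory units at all steps
  mat <- matrix(rnorm(32 * 7, sd = 3), 32, 7)
  colnames(mat) <- c(paste0("y_reg_", 1:3), paste0("y_mem_", 1:4))
  ty <- rep(0:3, each = 8)
  tm <- rep(1:8, times = 4)
  mat[ty == 1, 4:7] <- mat[ty == 0, 4:7]
  m <- structure(mat, trial_type = ty, time = tm,
                 q = matrix(rnorm(32 * 3), 32, 3))
  sim <- similarity_matrices(list(m, m), "memory")
  expect_equal(sim[1, 2, ], rep(1, 8))  # the identical pair wins every step
  expect_equal(apply(sim, 3, sum), rep(1, 8))
  # exact ties split their mass
  mat2 <- matrix(0, 32, 7)
  colnames(mat2) <- colnames(mat)
  mat2[, 4] <- c(0, 0, 1, 1)[ty + 1]  # types (0,1) and (2,3) pair up exactly
  m2 <- structure(mat2, trial_type = ty, time = tm, q = attr(m, "q"))
  sim2 <- similarity_matrices(list(m2), "memory")
  expect_equal(sim2[1, 2, 1], 0.5)
  expect_equal(sim2[3, 4, 1], 0.5)
})

test_that("category change histogram finds boundary-crossing steps and drops flat units", {
  # a perfect category cell: step function across the 0/180-deg boundary
  step_unit <- c(rep(1, 6), rep(0, 6))
  flat_unit <- rep(0.4, 12)
  # asymmetric graded profile whose largest adjacent change (pair 2 -> 3)
  # does not cross the boundary
  graded <- c(0, 0.9, 2, 2.2, 2.3, 2.35, 2.3, 2.2, 2, 1.5, 1, 0.5)
  tune <- cbind(step_unit, flat_unit, graded)
  h <- category_change_histogram(list(tune))
  expect_equal(h$n_units, 2L)  # the flat unit is excluded
  expect_equal(sum(h$pair_counts), 2L)
  expect_equal(sum(h$pair_counts[c(6, 12)]), 1L)  # the step cell is at a boundary
  expect_equal(h$boundary_fraction, 0.5)
})

test_that("evidence enumeration: marginals obey the law of total probability", {
  tab <- loglr_table()
  expect_equal(length(tab$p_full), 10000L)
  pref <- tab$prefixes
  # the empty-sequence marginal is 1/2 by the +/- pairing of the weights
  expect_equal(mean(pref$p[pref$length == 1]), 0.5, tolerance = 1e-12)
  # P(R | s_l) equals the mean of P(R | s_{l+1}) over the ten next symbols
  set.seed(2)
  for (k in 1:20) {
    l <- sample(1:3, 1)
    row <- pref[pref$length == l, ][sample(sum(pref$length == l), 1), ]
    nxt <- pref[pref$length == l + 1 &
                  startsWith(pref$prefix, paste0(row$prefix, ".")), ]
    expect_equal(nrow(nxt), 10L)
    expect_equal(mean(nxt$p), row$p, tolerance = 1e-12)
  }
  # trump-dominated prefixes land in the extreme quintiles
  expect_equal(pref$quintile[pref$length == 4 &
                               pref$prefix == "0.0.0.0"], 5L)
  expect_equal(pref$quintile[pref$length == 4 &
                               pref$prefix == "1.1.1.1"], 1L)
  # the +/- pairing makes the evidence antisymmetric under colour swap
  swap <- function(s) {
    v <- as.integer(strsplit(s, ".", fixed = TRUE)[[1]])
    paste(ifelse(v %% 2 == 0, v + 1L, v - 1L), collapse = ".")
  }
  l4 <- pref[pref$length == 4, ]
  idx <- sample(nrow(l4), 50)
  mirrored <- l4$loglr[match(vapply(l4$prefix[idx], swap, ""), l4$prefix)]
  expect_equal(mirrored, -l4$loglr[idx])
})

test_that("symbol-weight correlations recover monotone, inverted and flat units", {
  net <- augment_network(architecture_spec(n_inst = 45, n_memory = 3),
                         seed = 1)
  w <- network_weights(net)
  true_w <- symbol_weights()
  ranks <- rank(true_w)
  for (s in 0:9) {
    rows <- 5 + 10 * (0:3) + s + 1
    w$V_memory[rows, 1] <- ranks[s + 1]        # monotone transform
    w$V_memory[rows, 2] <- -ranks[s + 1]       # sign flipped
    w$V_memory[rows, 3] <- 1                   # constant
  }
  set_network_weights(net, w)
  rho <- symbol_weight_correlation(net)
  expect_equal(rho, c(1, -1, 0))
})

test_that("the two-frequency OLS recovers planted coefficients exactly", {
  grid <- expand.grid(F1 = 5:50, F2 = 5:50)
  acts <- cbind(0.01 * grid$F1 - 0.02 * grid$F2 + 0.3,
                -0.005 * (grid$F1 - grid$F2))
  coef <- augmentrl:::ols_f1f2(acts, grid)
  expect_lt(max(abs(coef[2, ] - c(0.01, -0.005))), 1e-9)
  expect_lt(max(abs(coef[3, ] - c(-0.02, 0.005))), 1e-9)
  expect_lt(max(abs(coef[1, ] - c(0.3, 0))), 1e-9)
})

test_that("trained-network regression and psychometrics behave sensibly", {
  r <- train_network("vibrotactile", seed = derive_seed(404, 1),
                     keep_net = TRUE)
  expect_true(r$converged)
  freeze_network(r$net)
  f <- f1f2_regression(r$net, r$env)
  expect_equal(nrow(f), 10L)
  # regular units have no access to the remembered F1
  expect_lt(max(abs(f$a1[f$group == "regular"])),
            max(abs(f$a2[f$group == "regular"])))
  pc <- psychometric_curves(r$net, r$env, repeats = 30)
  resp <- pc$responses
  for (f1 in c(20, 30, 40)) {
    d <- resp[resp$F1 == f1, ]
    expect_gte(d$p_higher[d$F2 == f1 + 10], d$p_higher[d$F2 == f1 + 2])
    expect_lte(d$p_higher[d$F2 == f1 - 10], d$p_higher[d$F2 == f1 - 2])
  }
  loc30 <- pc$fits$location[which(pc$fits$F1 == 30)]
  expect_false(pc$fits$degenerate[which(pc$fits$F1 == 30)])
  expect_lt(abs(loc30 - 30), 4)
})
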