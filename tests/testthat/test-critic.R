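test_that("min-max normalisation respects the risk direction", {
  B <- matrix(c(0, 2, 4, 8), 2, 2, byrow = TRUE)
  S <- normalize_indicator(B, "proportional")
  expect_equal(S[1, 1], 0)          # matrix minimum
  expect_equal(S[1, 2], 0.25)       # (2 - 0) / (8 - 0)
  expect_equal(S[2, 2], 1)
  Si <- normalize_indicator(B, "inverse")
  expect_equal(Si[2, 2], 0)         # matrix maximum maps to 0
  expect_equal(Si[1, 1], 1)
  expect_equal(S + Si, matrix(1, 2, 2))
  expect_error(normalize_indicator(matrix(3, 2, 2), "proportional"),
               "degenerate")
})

test_that("dispersion is the sample standard deviation over all entries", {
  expect_equal(indicator_dispersion(matrix(0.5, 3, 3)), 0)
  expect_equal(indicator_dispersion(matrix(c(0, 1), 1, 2)),
               sqrt((0.25 + 0.25) / 1))
  expect_equal(indicator_dispersion(matrix(c(0, 0.5, 1, 0.5), 2, 2)),
               sqrt(0.5 / 3))
})

test_that("conflict measures follow 1 - Pearson correlation", {
  S1 <- matrix(c(0, 0.2, 0.7, 1), 2, 2)
  cm <- conflict_measures(list(a = S1, b = S1))
  expect_equal(unname(cm$conflict), c(0, 0))
  cm2 <- conflict_measures(list(a = S1, b = 1 - S1))
  expect_equal(cm2$r[1, 2], -1)
  expect_equal(unname(cm2$conflict), c(2, 2))
  # three indicators vs explicit-loop recomputation
  set.seed(3)
  mats <- replicate(3, matrix(runif(4), 2, 2), simplify = FALSE)
  S <- lapply(mats, normalize_indicator, direction = "proportional")
  cm3 <- conflict_measures(S)
  orc <- oracle_critic(mats, rep("proportional", 3))
  expect_equal(unname(cm3$conflict), orc$R, tolerance = 1e-12)
  expect_error(conflict_measures(list(S1, matrix(0.5, 2, 2))), "degenerate")
})

test_that("objective weights divide information content", {
  expect_equal(critic_objective_weights(c(1, 3), c(1, 1)), c(0.25, 0.75))
  expect_equal(critic_objective_weights(c(2, 2), c(0.5, 0.5)), c(0.5, 0.5))
  w <- critic_objective_weights(c(0, 1, 2), c(1, 1, 1))
  expect_equal(w[1], 0)             # zero dispersion carries no weight
  expect_equal(sum(w), 1)
  expect_error(critic_objective_weights(c(0, 0), c(1, 1)), "no information")
})

test_that("the correlation function is the weighted sum of normalised values", {
  S1 <- matrix(0.2, 2, 2); S2 <- matrix(0.6, 2, 2)
  L <- correlation_function(list(S1, S2), c(0.5, 0.5))
  expect_equal(L, matrix(0.4, 2, 2))
  expect_equal(correlation_function(list(matrix(1, 2, 2), matrix(1, 2, 2)),
                                    c(0.3, 0.7)),
               matrix(1, 2, 2))
  expect_error(correlation_function(list(S1), c(0.5, 0.5)), "one weight")
  expect_error(correlation_function(list(S1, S2), c(0.4, 0.4)), "sum to 1")
})

test_that("full CRITIC agrees with the explicit-loop oracle to 1e-12", {
  set.seed(9)
  for (rep in 1:10) {
    ind <- generate_synthetic_indicators(h = 6, seed = 100 + rep)
    cw <- critic_weights(ind)
    orc <- oracle_critic(ind$matrices, unname(ind$directions))
    expect_equal(unname(cw$weights), orc$w, tolerance = 1e-12)
    expect_equal(unname(cw$L), unname(orc$L), tolerance = 1e-12)
  }
})

test_that("CRITIC is invariant to affine rescaling of raw data and equivariant under relabelling", {
  ind <- generate_synthetic_indicators(h = 5, seed = 21)
  base <- critic_weights(ind)
  scaled <- ind
  scaled$matrices[[2]] <- 3.7 * scaled$matrices[[2]] + 11
  scaled$matrices[[4]] <- 0.01 * scaled$matrices[[4]]
  cw2 <- critic_weights(scaled)
  expect_equal(cw2$weights, base$weights, tolerance = 1e-12)
  expect_equal(cw2$L, base$L, tolerance = 1e-12)
  perm <- sample(5)
  permuted <- indicator_data(lapply(ind$matrices, function(B) B[perm, perm]),
                             unname(ind$directions))
  cwp <- critic_weights(permuted)
  expect_equal(cwp$weights, base$weights, tolerance = 1e-12)
  expect_equal(unname(cwp$L), unname(base$L[perm, perm]), tolerance = 1e-12)
})

test_that("degenerate indicators are dropped with a warning and weight 0", {
  ind <- generate_synthetic_indicators(h = 5, seed = 33)
  ind$matrices$personnel_flow[] <- 2.5
  expect_warning(cw <- critic_weights(ind), "personnel_flow")
  expect_equal(unname(cw$weights["personnel_flow"]), 0)
  expect_equal(sum(cw$weights), 1, tolerance = 1e-12)
  expect_equal(cw$dropped, "personnel_flow")
  # fewer than two usable indicators is an error
  two <- indicator_data(list(a = matrix(1, 3, 3),
                             b = matrix(runif(9), 3, 3)))
  expect_warning(expect_error(critic_weights(two), "at least two"))
})

test_that("diagonal exclusion is available and changes only the statistics' support", {
  ind <- generate_synthetic_indicators(h = 5, seed = 12)
  cw <- critic_weights(ind, include_diag = FALSE)
  expect_true(all(is.na(diag(cw$L))))
  off <- cw$L[row(cw$L) != col(cw$L)]
  expect_true(all(off >= 0 & off <= 1))
  expect_equal(sum(cw$weights), 1, tolerance = 1e-12)
})
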