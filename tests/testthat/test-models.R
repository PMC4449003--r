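test_that("Prelec weighting has its fixed points and reductions", {
  p <- seq(0.01, 1, by = 0.01)
  # alpha = 1 collapses variant I to the identity
  expect_equal(prelec_weight(p, alpha = 1), p, tolerance = 1e-12)
  # p = 1/e is a fixed point of variant I for any alpha
  for (a in c(0.3, 0.65, 1, 2))
    expect_equal(prelec_weight(exp(-1), alpha = a), exp(-1), tolerance = 1e-12)
  # variant II with beta_w = 1 equals variant I
  expect_equal(prelec_weight(p, 0.6, beta_w = 1, variant = "II"),
               prelec_weight(p, 0.6, variant = "I"), tolerance = 1e-15)
  # boundary conventions and monotonicity
  expect_equal(prelec_weight(0, 0.5), 0)
  expect_equal(prelec_weight(1, 0.5), 1)
  w <- prelec_weight(p, 0.5, beta_w = 1.4, variant = "II")
  expect_true(all(diff(w) > 0))
  expect_error(prelec_weight(0.5, alpha = -1), "alpha")
  expect_error(prelec_weight(1.2, alpha = 1), "0, 1")
})

test_that("power utility obeys u(0) = 0 and simple closed forms", {
  expect_equal(power_utility(0, 0.37), 0)
  x <- c(0, 1, 2.5, 7)
  expect_equal(power_utility(x, 1), x)
  expect_equal(power_utility(4, 0.5), 2)
  expect_error(power_utility(4, 0), "mu")
  expect_error(power_utility(-1, 1), ">= 0")
})

test_that("rank-dependent utility reduces to EV and matches the hand oracle", {
  dists <- list(
    enumerate_walk(walk_spec(2, 3, 3, 0.4)),
    enumerate_walk(walk_spec(1, 2, 5, 0.7)),
    outcome_dist(c(0, 8), c(0.6, 0.4))
  )
  for (d in dists) {
    expect_equal(rdu_value(d, mu = 1, alpha = 1), compute_stats(d)$ev,
                 tolerance = 1e-10)
    expect_equal(rdu_value(d, 1, 1, beta_w = 1, variant = "II"),
                 compute_stats(d)$ev, tolerance = 1e-10)
    # against the independent scalar oracle at curved parameters
    expect_equal(rdu_value(d, 0.8, 0.5), hand_rdu(d$support, d$probs, 0.8, 0.5),
                 tolerance = 1e-12)
    expect_equal(rdu_value(d, 1.2, 0.7, 1.5, "II"),
                 hand_rdu(d$support, d$probs, 1.2, 0.7, 1.5), tolerance = 1e-12)
  }
  # hand-derived two-outcome case: V = w(0.4) * 8 with Prelec-I alpha = 0.5
  d <- outcome_dist(c(0, 8), c(0.6, 0.4))
  expect_equal(rdu_value(d, 1, 0.5), exp(-sqrt(-log(0.4))) * 8, tolerance = 1e-12)
  # storage order of the input distribution is irrelevant (ranking is internal)
  d2 <- outcome_dist(c(8, 0), c(0.4, 0.6))
  expect_equal(rdu_value(d2, 0.9, 0.6), rdu_value(d, 0.9, 0.6))
})

test_that("option values follow the model equations and their reductions", {
  dA <- enumerate_walk(walk_spec(2, 3, 3, 0.4))
  dB <- enumerate_walk(walk_spec(2, 3, 5, 0.25))
  ftF <- trial_features(dA, dB, frame = "foraging", days = 3)
  ftC <- trial_features(dA, dB, frame = "casino", days = 3)
  sA <- compute_stats(dA)

  # arithmetic of the homeostatic value (EV + xi * p_starve)
  expect_equal(option_value(7, c(beta = 1, xi = -2), ftF, "A"),
               sA$ev - 2 * sA$p_starve)
  # xi = 0 nests the EV-only model
  expect_equal(option_value(7, c(beta = 1, xi = 0), ftF, "A"),
               option_value(1, c(beta = 1), ftF, "A"))
  # frame-specific weights act only in their own frame
  pars10 <- c(beta = 1, xi_foraging = -4, xi_casino = -1)
  expect_equal(option_value(10, pars10, ftF, "A"), sA$ev - 4 * sA$p_starve)
  expect_equal(option_value(10, pars10, ftC, "A"), sA$ev - 1 * sA$p_starve)
  # equal frame weights reproduce the common-weight model exactly
  pars_eq <- c(beta = 1, xi_foraging = -2.5, xi_casino = -2.5)
  for (ft in list(ftF, ftC)) {
    expect_equal(option_value(10, pars_eq, ft, "A"),
                 option_value(7, c(beta = 1, xi = -2.5), ft, "A"),
                 tolerance = 1e-12)
  }
  # equal day weights reproduce it too
  pars12 <- c(beta = 1, xi_d1 = -2.5, xi_d2 = -2.5, xi_d3 = -2.5)
  expect_equal(option_value(12, pars12, ftF, "B"),
               option_value(7, c(beta = 1, xi = -2.5), ftF, "B"),
               tolerance = 1e-12)
  # moment models are the stated linear combinations
  sB <- compute_stats(dB)
  expect_equal(option_value(4, c(beta = 1, rho = 0.2, lambda = -0.5), ftF, "B"),
               sB$ev + 0.2 * sB$var - 0.5 * sB$skw)
  expect_equal(option_value(11, c(beta = 1), ftF, "A"), sA$p_starve)
  expect_error(option_value(7, c(beta = 1), ftF, "A"), "xi")
})

test_that("softmax choice rule is symmetric, calibrated and noise-limited", {
  expect_equal(choice_prob(2, 2, 1), 0.5)
  expect_equal(choice_prob(1.7, 0.7, 1), 1 / (1 + exp(-1)))
  v1 <- c(-1, 0, 2.3)
  v2 <- c(1.2, 0, -4)
  expect_equal(choice_prob(v1, v2, 0.8) + choice_prob(v2, v1, 0.8),
               rep(1, 3), tolerance = 1e-12)
  expect_equal(choice_prob(5, 1, 1e6), 0.5, tolerance = 1e-5)
  expect_true(all(diff(choice_prob(seq(-3, 3, 0.5), 0, 1)) > 0))
  expect_error(choice_prob(1, 0, beta = 0), "beta")
})

test_that("the model registry matches the documented parameterisation", {
  tab <- model_table()
  expect_equal(nrow(tab), 12)
  expect_equal(tab$k, c(1, 2, 2, 3, 3, 4, 2, 3, 4, 3, 1, 4))
  expect_equal(tab$family[1:4], rep("moments", 4))
  expect_equal(tab$family[5:6], rep("rank_dependent", 2))
  expect_equal(tab$family[7:10], rep("homeostatic", 4))
  expect_identical(model_spec("EV+pstarve")$model_id, 7L)
  expect_error(model_spec(13), "1..12")
})
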