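test_that("log-group Bayes factors sum per-participant differences", {
  tab <- rbind(c(10, 5, 12), c(20, 13, 19))
  colnames(tab) <- c("1", "7", "9")
  lgbf <- log_group_bayes_factors(tab, "1")
  expect_equal(unname(lgbf["1"]), 0)
  expect_equal(unname(lgbf["7"]), (5 - 10) + (13 - 20))  # -12
  # invariant to per-participant constants added to every model
  shifted <- tab + c(100, -3)
  expect_equal(log_group_bayes_factors(shifted, "1"), lgbf)
})

test_that("BMS is symmetric under equal evidence and conserves counts", {
  K <- 5
  le <- matrix(-100, nrow = 22, ncol = K)
  res <- bms_random_effects(le, prior_alpha = 1, seed = 3, n_samples = 2e5)
  expect_equal(sum(res$alpha), K + 22, tolerance = 1e-6)
  expect_equal(unname(res$model_posterior_mean), rep(1 / K, K), tolerance = 1e-8)
  mc3 <- 3 * sqrt((1 / K) * (1 - 1 / K) / 2e5)
  expect_true(all(abs(res$exceedance - 1 / K) < mc3 + 1e-3))
  expect_equal(sum(res$exceedance), 1)
})

test_that("uniform dominance forces the winner's exceedance", {
  le <- matrix(-150, nrow = 22, ncol = 4)
  le[, 3] <- le[, 3] + 20  # model 3 better by 20 nats for everyone
  res <- bms_random_effects(le, seed = 5, n_samples = 2e5)
  expect_gte(res$exceedance[3], 0.999)
  expect_equal(sum(res$alpha), 4 + 22, tolerance = 1e-6)
})

test_that("single-participant BMS ranks models like raw log evidence", {
  le <- matrix(c(-10, -12, -9.5, -14), nrow = 1)
  res <- bms_random_effects(le, seed = 7, n_samples = 1e5)
  expect_equal(order(res$exceedance, decreasing = TRUE),
               order(le[1, ], decreasing = TRUE))
})

test_that("exceedance is equivariant under model relabeling", {
  set.seed(8)
  le <- matrix(rnorm(22 * 4, -100, 3), 22, 4)
  perm <- c(3, 1, 4, 2)
  r1 <- bms_random_effects(le, seed = 9, n_samples = 2e5)
  r2 <- bms_random_effects(le[, perm], seed = 9, n_samples = 2e5)
  expect_lt(max(abs(unname(r2$exceedance) - unname(r1$exceedance[perm]))), 0.01)
  expect_equal(unname(r2$alpha), unname(r1$alpha[perm]), tolerance = 1e-6)
})

test_that("two-model exceedance matches the Beta tail cross-check", {
  set.seed(10)
  le <- matrix(rnorm(22 * 2, -100, 2), 22, 2)
  res <- bms_random_effects(le, seed = 11, n_samples = 5e5)
  exact <- 1 - pbeta(0.5, res$alpha[1], res$alpha[2])
  expect_equal(unname(res$exceedance[1]), unname(exact), tolerance = 5e-3)
})

test_that("family BMS equalizes prior mass and respects symmetry and dominance", {
  # symmetric case: equal-size families, identical evidences
  le_sym <- matrix(-100, nrow = 10, ncol = 6)
  fams_sym <- c("a", "a", "a", "b", "b", "b")
  res_sym <- family_bms(le_sym, fams_sym, seed = 13, n_samples = 2e5)
  expect_equal(unname(res_sym$alpha_prior), rep(1 / 3, 6))
  expect_lt(max(abs(unname(res_sym$family_exceedance) - 0.5)), 5e-3)
  expect_equal(sum(res_sym$family_exceedance), 1)
  # unequal family sizes: prior mass per family is equalized
  fams <- c("a", "a", "a", "a", "b", "b")
  le <- matrix(-100, nrow = 10, ncol = 6)
  le[, 1] <- le[, 1] + 5  # keep the evidence informative
  res <- family_bms(le, fams, seed = 15, n_samples = 2e4)
  expect_equal(unname(res$alpha_prior), c(rep(1 / 4, 4), rep(1 / 2, 2)))
  expect_equal(sum(res$family_exceedance), 1)
  # all participants favor a family-b member by 10 nats
  le2 <- matrix(-100, nrow = 10, ncol = 6)
  le2[, 5] <- le2[, 5] + 10
  res2 <- family_bms(le2, fams, seed = 14, n_samples = 2e5)
  expect_gt(res2$family_exceedance[["b"]], 0.99)
  expect_error(family_bms(le2, fams[1:3], seed = 1), "every model")
})

test_that("singleton families reproduce model-level exceedance under relabeling", {
  # family labels sort differently than the model columns, so this guards
  # the group-to-column mapping
  set.seed(12)
  le <- matrix(rnorm(8 * 2, -50, 2), 8, 2)
  colnames(le) <- c("1", "7")
  fams <- c("moments", "homeostatic")  # alphabetical order flips the columns
  b <- bms_random_effects(le, seed = 21, n_samples = 2e5)
  f <- family_bms(le, fams, seed = 21, n_samples = 2e5)
  expect_lt(abs(f$family_exceedance[["moments"]] - b$exceedance[["1"]]), 0.01)
  expect_lt(abs(f$family_exceedance[["homeostatic"]] - b$exceedance[["7"]]), 0.01)
})

test_that("fixed- and random-effects agree on a uniformly dominant model", {
  le <- matrix(-150, nrow = 22, ncol = 4)
  le[, 2] <- le[, 2] + 8
  ic <- -le  # BIC-scale evidence is minus the criterion
  lgbf <- log_group_bayes_factors(ic, 1)
  res <- bms_random_effects(le, seed = 15, n_samples = 1e5)
  expect_equal(unname(which.min(lgbf)), unname(which.max(res$exceedance)))
  # consistency: group IC difference equals summed log-evidence difference
  expect_equal(unname(lgbf[2]), -sum(le[, 2] - le[, 1]))
})

test_that("the sign test reproduces exact binomial tail probabilities", {
  st <- sign_test(rep(-1, 22))
  expect_equal(st$p_value, 2 * 0.5^22, tolerance = 1e-12)
  st <- sign_test(c(rep(-1, 11), rep(1, 11)))
  expect_equal(st$p_value, 1)
  # 17 of 22 negative: doubled upper tail of Binomial(22, 1/2)
  st <- sign_test(c(rep(-1, 17), rep(1, 5)))
  expect_equal(st$p_value, 2 * sum(choose(22, 17:22)) / 2^22, tolerance = 1e-12)
  # ties at the null are dropped
  st <- sign_test(c(rep(-1, 5), 0, 0))
  expect_equal(st$n_used, 5)
  expect_equal(st$n_dropped, 2)
  expect_error(sign_test(c(0, 0)), "undefined")
})
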