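make_indifferent_trials <- function(n = 10) {
  # both options identical, so every model is at chance
  data.frame(participant_id = 1, frame = rep(c("casino", "foraging"), length.out = n),
             block = 1L, trial_index = seq_len(n) - 1L, pair_id = seq_len(n),
             x0 = 2, n = 2, gA = 3, pA = 0.4, gB = 3, pB = 0.4,
             choice = rep(c("A", "B"), length.out = n), rt_ms = 500)
}

test_that("likelihood is the coin-flip value at indifference and is additive", {
  tr <- make_indifferent_trials(12)
  expect_equal(negative_log_likelihood(1, c(beta = 0.7), tr), 12 * log(2),
               tolerance = 1e-12)
  tr2 <- quick_trials(7, c(beta = 0.5, xi = -3), pairs = small_gamble_set(5))
  nll1 <- negative_log_likelihood(7, c(beta = 0.5, xi = -3), tr2)
  nll2 <- negative_log_likelihood(7, c(beta = 0.5, xi = -3), rbind(tr2, tr2))
  expect_equal(nll2, 2 * nll1, tolerance = 1e-10)
})

test_that("missed trials are excluded and all-missed data errors", {
  tr <- make_indifferent_trials(10)
  tr$choice[1:3] <- "missed"
  expect_equal(negative_log_likelihood(1, c(beta = 1), tr), 7 * log(2))
  tr$choice <- "missed"
  expect_error(negative_log_likelihood(1, c(beta = 1), tr), "non-missed")
})

test_that("the likelihood separates the true parameter sign at scale", {
  pairs <- generate_gamble_set(gamble_config(n_per_combo = 60), seed = 21)
  tr <- quick_trials(7, c(beta = 1, xi = -3), pairs = pairs, seed = 77)
  expect_equal(nrow(tr), 480 * 2 * 60 / 120)  # 240 pairs x 2 frames
  nll_true <- negative_log_likelihood(7, c(beta = 1, xi = -3), tr)
  nll_flip <- negative_log_likelihood(7, c(beta = 1, xi = 3), tr)
  expect_lt(nll_true, nll_flip - 50)
})

test_that("fitting descends from the seed and populates the result", {
  tr <- quick_trials(7, c(beta = 0.5, xi = -3), pairs = small_gamble_set(30))
  fr <- fit_participant(7, tr, participant_id = "s1")
  seed_nll <- negative_log_likelihood(7, c(beta = 0.5, xi = 0.5), tr)
  expect_lte(fr$negll, seed_nll)
  expect_true(fr$converged)
  expect_equal(fr$n_trials, nrow(tr))
  expect_named(fr$params, c("beta", "xi"))
  expect_equal(fr$bic, fr$negll + 0.5 * 2 * log(fr$n_trials))
  expect_equal(fr$aic, fr$negll + 2)
  expect_true(fr$params[["beta"]] > 0)
  expect_lt(fr$params[["xi"]], 0)
})

test_that("information criteria use the half-scale convention", {
  ic <- information_criteria(100, k = 2, n = 960)
  expect_equal(ic[["bic"]], 100 + log(960))
  expect_equal(ic[["aic"]], 102)
  ic0 <- information_criteria(50, k = 0, n = 100)
  expect_equal(unname(ic0), c(50, 50))
  expect_equal(information_criteria(100, 3, 10)[["aic"]], 103)
  expect_error(information_criteria(1, -1, 10), "k")
})

test_that("nested models never fit worse than their special cases", {
  tr <- quick_trials(7, c(beta = 0.5, xi = -2.5), pairs = small_gamble_set(40),
                     seed = 31)
  ct <- compile_trials(tr)
  nll <- sapply(c(1, 2, 3, 4, 7, 8, 9, 10, 12), function(m)
    fit_participant(m, ct)$negll)
  names(nll) <- c("m1", "m2", "m3", "m4", "m7", "m8", "m9", "m10", "m12")
  tol <- 0.05  # optimizer slack
  expect_lte(nll[["m2"]], nll[["m1"]] + tol)
  expect_lte(nll[["m3"]], nll[["m1"]] + tol)
  expect_lte(nll[["m7"]], nll[["m1"]] + tol)
  expect_lte(nll[["m4"]], nll[["m2"]] + tol)
  expect_lte(nll[["m8"]], nll[["m7"]] + tol)
  expect_lte(nll[["m9"]], nll[["m8"]] + tol)
  expect_lte(nll[["m10"]], nll[["m7"]] + tol)
  expect_lte(nll[["m12"]], nll[["m7"]] + tol)
})

test_that("refits from perturbed seeds land on the same likelihood", {
  tr <- quick_trials(7, c(beta = 0.5, xi = -3), pairs = small_gamble_set(30),
                     seed = 41)
  ct <- compile_trials(tr)
  base <- fit_participant(7, ct)
  set.seed(99)
  for (i in 1:5) {
    opts <- fit_options(pos_seed = 0.5 + stats::runif(1, -0.3, 1.5))
    fr <- fit_participant(7, ct, options = opts)
    expect_lt(abs(fr$negll - base$negll), 0.1)
  }
})

test_that("cohort fitting returns a complete summary and evidence table", {
  pairs <- small_gamble_set(25)
  tr <- rbind(
    quick_trials(7, c(beta = 0.5, xi = -3), pairs, seed = 1),
    transform(quick_trials(7, c(beta = 0.6, xi = -2), pairs, seed = 2),
              participant_id = 2)
  )
  fit <- fit_cohort(tr, models = c(1, 7))
  expect_equal(nrow(fit$summary), 4)
  expect_true(all(fit$summary$converged))
  tab <- evidence_table(fit, "BIC")
  expect_equal(dim(tab), c(2, 2))
  expect_equal(tab["1", "7"],
               fit$summary$bic[fit$summary$participant_id == 1 &
                                 fit$summary$model_id == 7])
  xs <- fitted_params(fit, 7, "xi")
  expect_length(xs, 2)
  expect_true(all(xs < 0))
  aic_tab <- evidence_table(fit, "AIC")
  expect_true(all(aic_tab != tab))
})
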