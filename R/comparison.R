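#' Fixed-effects log-group Bayes factors
#'
#' For each model, subtracts the reference model's information criterion per
#' participant and sums the differences over the group. With the half-scale
#' criteria used here (see [information_criteria()]) these sums are log-group
#' Bayes factors; smaller (more negative) values indicate more evidence for
#' the model relative to the reference.
#'
#' @param table Participants-by-models matrix of BIC or AIC values, e.g. from
#'   [evidence_table()].
#' @param reference Column name or index of the reference model.
#' @return Named numeric vector of log-group Bayes factors; the reference
#'   maps to 0.
#' @export
log_group_bayes_factors <- function(table, reference) {
  if (!is.matrix(table)) stop("`table` must be a matrix", call. = FALSE)
  if (is.character(reference)) {
    if (!reference %in% colnames(table))
      stop("reference model '", reference, "' not in table", call. = FALSE)
    ref <- table[, reference]
  } else {
    ref <- table[, reference]
  }
  colSums(table - ref)
}

# log-space row normalisation: exp(x) / rowSums(exp(x)) without overflow
.softmax_rows <- function(x) {
  mx <- apply(x, 1, max)
  e <- exp(x - mx)
  e / rowSums(e)
}

# Dirichlet argmax frequencies by chunked Monte-Carlo sampling; `group` maps
# columns to groups whose sampled frequencies are summed before the argmax
.dirichlet_exceedance <- function(alpha, n_samples, group = NULL, chunk = 1e5) {
  K <- length(alpha)
  gl <- if (is.null(group)) factor(seq_len(K)) else factor(group)
  G <- nlevels(gl)
  counts <- numeric(G)
  done <- 0
  while (done < n_samples) {
    s <- min(chunk, n_samples - done)
    draws <- matrix(stats::rgamma(s * K, shape = rep(alpha, each = s)), s, K)
    if (!is.null(group)) {
      # columns are in model order, groups in factor-level order: always
      # remap, even when every group is a singleton
      agg <- matrix(0, s, G)
      for (g in seq_len(G))
        agg[, g] <- rowSums(draws[, gl == levels(gl)[g], drop = FALSE])
      draws <- agg
    }
    winner <- max.col(draws, ties.method = "first")
    counts <- counts + tabulate(winner, nbins = G)
    done <- done + s
  }
  stats::setNames(counts / n_samples, levels(gl))
}

#' Random-effects Bayesian model selection
#'
#' Treats the model identity as a random effect across participants: the
#' population frequencies of the models follow a Dirichlet distribution whose
#' posterior is approximated by the standard variational scheme. Iteratively,
#' each participant's posterior model assignment is proportional to
#' `exp(log evidence + digamma(alpha_m) - digamma(sum(alpha)))`, and the
#' Dirichlet counts are updated to the prior plus the summed assignments,
#' until the counts change by less than `tol`. Exceedance probabilities (the
#' posterior probability that a model is the most frequent in the population)
#' are estimated by sampling the Dirichlet posterior and counting arg-max
#' frequencies.
#'
#' @param log_evidence Participants-by-models matrix of log model evidences
#'   (use `-BIC` with the half-scale convention of [information_criteria()]).
#' @param prior_alpha Dirichlet prior counts: a single value or one per model
#'   (default 1, uniform).
#' @param seed Integer seed for the exceedance sampler.
#' @param n_samples Number of Dirichlet draws for the exceedance estimate.
#' @param tol Convergence tolerance on the change in `alpha`.
#' @param max_iter Iteration cap; exceeding it is an error.
#' @return An object of class `bms_result`: `alpha`, `alpha_prior`,
#'   `model_posterior_mean`, `exceedance`, `assignments` (participant-level
#'   posterior model probabilities), `n_iter`, `n_samples`, `seed`, and
#'   (for [family_bms()]) `family` and `family_exceedance`.
#' @export
bms_random_effects <- function(log_evidence, prior_alpha = 1, seed = 1,
                               n_samples = 1e6, tol = 1e-6, max_iter = 10000) {
  if (!is.matrix(log_evidence) || any(!is.finite(log_evidence)))
    stop("`log_evidence` must be a finite matrix", call. = FALSE)
  N <- nrow(log_evidence)
  K <- ncol(log_evidence)
  if (length(prior_alpha) == 1L) prior_alpha <- rep(prior_alpha, K)
  if (length(prior_alpha) != K || any(prior_alpha <= 0))
    stop("`prior_alpha` must be positive, length 1 or one per model", call. = FALSE)

  alpha <- prior_alpha + N / K
  g <- NULL
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    lw <- sweep(log_evidence, 2, digamma(alpha) - digamma(sum(alpha)), "+")
    g <- .softmax_rows(lw)
    alpha_new <- prior_alpha + colSums(g)
    delta <- max(abs(alpha_new - alpha))
    alpha <- alpha_new
    if (delta < tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged)
    stop("BMS did not converge after ", max_iter, " iterations; ",
         "last alpha residual ", signif(delta, 3), call. = FALSE)

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  xp <- .dirichlet_exceedance(alpha, n_samples)
  nm <- colnames(log_evidence)
  if (!is.null(nm)) {
    names(alpha) <- nm
    names(xp) <- nm
    colnames(g) <- nm
  }
  structure(list(
    alpha = alpha, alpha_prior = prior_alpha,
    model_posterior_mean = alpha / sum(alpha),
    exceedance = xp, assignments = g,
    n_iter = it, n_samples = n_samples, seed = seed,
    family = NULL, family_exceedance = NULL
  ), class = "bms_result")
}

#' @export
print.bms_result <- function(x, ...) {
  cat("<bms_result>\n")
  tab <- data.frame(alpha = signif(x$alpha, 5),
                    posterior_mean = signif(x$model_posterior_mean, 4),
                    exceedance = signif(x$exceedance, 4))
  print(tab)
  if (!is.null(x$family_exceedance)) {
    cat("family exceedance:\n")
    print(signif(x$family_exceedance, 4))
  }
  invisible(x)
}

#' Family-level Bayesian model selection
#'
#' Runs [bms_random_effects()] with the prior mass equalized across model
#' families (each family receives total prior mass 1, split equally among its
#' members) and estimates, for each family, the posterior probability that
#' its summed population frequency exceeds every other family's.
#'
#' @param log_evidence Participants-by-models matrix of log evidences.
#' @param partition Family label per model (character or factor, length =
#'   number of columns).
#' @param seed,n_samples,tol,max_iter Passed to [bms_random_effects()].
#' @return A `bms_result` with `family` and `family_exceedance` filled in.
#' @export
family_bms <- function(log_evidence, partition, seed = 1, n_samples = 1e6,
                       tol = 1e-6, max_iter = 10000) {
  if (length(partition) != ncol(log_evidence))
    stop("`partition` must label every model (column)", call. = FALSE)
  fam <- factor(partition)
  sizes <- table(fam)
  if (any(sizes == 0)) stop("empty family in `partition`", call. = FALSE)
  prior <- 1 / as.numeric(sizes[fam])
  res <- bms_random_effects(log_evidence, prior_alpha = prior, seed = seed,
                            n_samples = n_samples, tol = tol, max_iter = max_iter)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed + 1L)
  res$family <- fam
  res$family_exceedance <- .dirichlet_exceedance(res$alpha, n_samples, group = fam)
  res
}

#' Exact sign test
#'
#' Exact two-sided binomial test that the median of `values` is
#' `null_median`: ties at the null are dropped and the count of values above
#' it is referred to a Binomial(n, 1/2) distribution.
#'
#' @param values Numeric vector (e.g. per-participant parameter estimates).
#'   For a paired comparison pass the per-participant differences.
#' @param null_median Hypothesized median (default 0).
#' @return A list of class `sign_test`: `n_positive`, `n_negative`, `n_used`,
#'   `n_dropped`, `p_value`.
#' @examples
#' sign_test(c(-3, -2.5, -1, -4, -0.2, 0.3))
#' @export
sign_test <- function(values, null_median = 0) {
  values <- values[!is.na(values)]
  d <- values - null_median
  dropped <- sum(d == 0)
  d <- d[d != 0]
  if (length(d) == 0L)
    stop("all values equal the null median; sign test undefined", call. = FALSE)
  k <- sum(d > 0)
  n <- length(d)
  p <- stats::binom.test(k, n, p = 0.5)$p.value
  structure(list(n_positive = k, n_negative = n - k, n_used = n,
                 n_dropped = dropped, p_value = p),
            class = "sign_test")
}

#' @export
print.sign_test <- function(x, ...) {
  cat(sprintf("<sign_test> %d positive / %d negative of %d (dropped %d ties), exact p = %.4g\n",
              x$n_positive, x$n_negative, x$n_used, x$n_dropped, x$p_value))
  invisible(x)
}
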