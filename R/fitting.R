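#' Optimizer settings for participant-level fits
#'
#' @param clip Choice-probability clipping bound, see
#'   [negative_log_likelihood()].
#' @param reltol Relative function tolerance of the simplex search.
#' @param maxit_per_param Evaluation budget: `maxit = maxit_per_param * k`.
#' @param pos_seed Raw-scale starting value of the positive-seed branch
#'   (all parameters).
#' @param neg_seed Raw-scale starting value of the unconstrained parameters
#'   in the negative-seed branch (positivity-constrained parameters keep
#'   `pos_seed`).
#' @param restarts Maximum number of simplex restarts from the incumbent
#'   optimum (guards against premature simplex collapse).
#' @param restart_tol Improvement (nats) below which restarting stops.
#' @return A list of class `fit_options`.
#' @export
fit_options <- function(clip = 1e-10, reltol = 1e-6, maxit_per_param = 2000L,
                        pos_seed = 0.5, neg_seed = -0.5, restarts = 3L,
                        restart_tol = 0.01) {
  structure(list(clip = clip, reltol = reltol,
                 maxit_per_param = as.integer(maxit_per_param),
                 pos_seed = pos_seed, neg_seed = neg_seed,
                 restarts = as.integer(restarts), restart_tol = restart_tol),
            class = "fit_options")
}

# raw <-> unconstrained optimizer scale; positive parameters live on log scale
.to_theta <- function(raw, positive) ifelse(positive, log(raw), raw)
.to_raw <- function(theta, positive) ifelse(positive, exp(theta), theta)

#' Fit one participant by maximum likelihood
#'
#' Minimizes the negative log-likelihood with a Nelder-Mead simplex search
#' (Brent line search for one-parameter models). Positivity-constrained
#' parameters are optimized on the log scale. The optimizer is first started
#' from positive seed values for every raw parameter; if that run does not
#' converge, a second run starts the unconstrained parameters from negative
#' seeds, and the better of any converged result is kept. If neither branch
#' converges the best values found are returned with `converged = FALSE`.
#'
#' @param model A [model_spec()] or id/name.
#' @param trials Trial data frame or [compile_trials()] object for one
#'   participant.
#' @param options A [fit_options()] list.
#' @param participant_id Identifier copied into the result.
#' @return A list of class `fit_result`: `participant_id`, `model_id`,
#'   `params` (named estimates on the raw scale), `negll`, `n_trials`,
#'   `bic`, `aic`, `converged`, `seed_branch`.
#' @export
fit_participant <- function(model, trials, options = fit_options(),
                            participant_id = NA) {
  m <- if (inherits(model, "model_spec")) model else model_spec(model)
  ct <- compile_trials(trials)
  k <- length(m$params)
  pos <- m$positive

  fn <- function(theta) {
    raw <- .to_raw(theta, pos)
    if (any(!is.finite(raw))) return(1e10)
    names(raw) <- m$params
    nll <- negative_log_likelihood(m, raw, ct, clip = options$clip)
    if (!is.finite(nll)) 1e10 else nll
  }

  run <- function(raw0) {
    theta0 <- .to_theta(raw0, pos)
    if (k == 1L) {
      res <- stats::optim(theta0, fn, method = "Brent", lower = -25, upper = 25)
      return(list(theta = res$par, value = res$value,
                  converged = res$convergence == 0 && is.finite(res$value) &&
                    res$value < 1e10))
    }
    # simplex restarts from the incumbent guard against premature collapse
    # on ridge-shaped likelihoods (e.g. correlated skewness / p_starve terms)
    res <- stats::optim(theta0, fn, method = "Nelder-Mead",
                        control = list(reltol = options$reltol,
                                       maxit = options$maxit_per_param * k))
    for (r in seq_len(options$restarts)) {
      res2 <- stats::optim(res$par, fn, method = "Nelder-Mead",
                           control = list(reltol = options$reltol,
                                          maxit = options$maxit_per_param * k))
      improved <- res$value - res2$value
      if (res2$value <= res$value) res <- res2
      if (improved < options$restart_tol) break
    }
    list(theta = res$par, value = res$value,
         converged = res$convergence == 0 && is.finite(res$value) &&
           res$value < 1e10)
  }

  pos_run <- run(rep(options$pos_seed, k))
  branch <- "positive"
  best <- pos_run
  if (!pos_run$converged) {
    raw0 <- ifelse(pos, options$pos_seed, options$neg_seed)
    neg_run <- run(raw0)
    if (neg_run$converged || neg_run$value < best$value) {
      best <- neg_run
      branch <- "negative"
    }
  }

  raw <- .to_raw(best$theta, pos)
  names(raw) <- m$params
  ic <- information_criteria(best$value, k, ct$n_trials)
  structure(list(
    participant_id = participant_id, model_id = m$model_id,
    params = raw, negll = best$value, n_trials = ct$n_trials,
    bic = ic[["bic"]], aic = ic[["aic"]],
    converged = best$converged, seed_branch = branch
  ), class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("<fit_result> participant %s, model %d: negLL = %.3f (BIC %.3f, AIC %.3f)%s\n",
              as.character(x$participant_id), x$model_id, x$negll, x$bic, x$aic,
              if (x$converged) "" else "  [NOT CONVERGED]"))
  cat("  ", paste(sprintf("%s = %.4g", names(x$params), x$params), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' Information criteria, half-scale convention
#'
#' `BIC = -ln(L) + 0.5 k ln(n)` and `AIC = -ln(L) + k`: the criteria are on
#' the scale of the negative log-likelihood itself (half the conventional
#' `-2 ln(L)` scale), so `-BIC` is directly a Laplace-style approximation of
#' the log model evidence.
#'
#' @param negll Negative log-likelihood in nats.
#' @param k Number of free parameters.
#' @param n Number of data points (the participant's non-missed trials).
#' @return Named numeric vector `c(bic = ..., aic = ...)`.
#' @examples
#' information_criteria(100, k = 2, n = 960)
#' @export
information_criteria <- function(negll, k, n) {
  if (k < 0 || n < 1) stop("`k` must be >= 0 and `n` >= 1", call. = FALSE)
  c(bic = negll + 0.5 * k * log(n), aic = negll + k)
}

#' Fit a set of models to every participant in a dataset
#'
#' @param trials Trial data frame for the whole cohort (column
#'   `participant_id` splits it).
#' @param models Vector of model ids/names to fit (default: the nine core
#'   models plus the frame-specific Model 10).
#' @param options A [fit_options()] list.
#' @return An object of class `cohort_fit`: a list with `summary` (data frame,
#'   one row per participant x model: `participant_id`, `model_id`, `k`,
#'   `n_trials`, `negll`, `bic`, `aic`, `converged`, `seed_branch`) and
#'   `params` (long data frame: `participant_id`, `model_id`, `param`,
#'   `value`).
#' @export
fit_cohort <- function(trials, models = 1:10, options = fit_options()) {
  ids <- unique(trials$participant_id)
  specs <- lapply(models, model_spec)
  sum_rows <- list()
  par_rows <- list()
  for (pid in ids) {
    ct <- compile_trials(trials[trials$participant_id == pid, , drop = FALSE])
    for (m in specs) {
      fr <- fit_participant(m, ct, options, participant_id = pid)
      sum_rows[[length(sum_rows) + 1L]] <- data.frame(
        participant_id = pid, model_id = m$model_id, k = length(m$params),
        n_trials = fr$n_trials, negll = fr$negll, bic = fr$bic, aic = fr$aic,
        converged = fr$converged, seed_branch = fr$seed_branch
      )
      par_rows[[length(par_rows) + 1L]] <- data.frame(
        participant_id = pid, model_id = m$model_id,
        param = names(fr$params), value = unname(fr$params)
      )
    }
  }
  structure(list(summary = do.call(rbind, sum_rows),
                 params = do.call(rbind, par_rows)),
            class = "cohort_fit")
}

#' @export
print.cohort_fit <- function(x, ...) {
  cat(sprintf("<cohort_fit> %d participants x %d models\n",
              length(unique(x$summary$participant_id)),
              length(unique(x$summary$model_id))))
  agg <- stats::aggregate(bic ~ model_id, data = x$summary, FUN = sum)
  names(agg)[2] <- "group_bic"
  print(agg, row.names = FALSE)
  invisible(x)
}

#' Extract one fitted parameter across participants
#'
#' @param fit A [fit_cohort()] result.
#' @param model Model id.
#' @param param Parameter name.
#' @return Named numeric vector of per-participant estimates.
#' @export
fitted_params <- function(fit, model, param) {
  stopifnot(inherits(fit, "cohort_fit"))
  sel <- fit$params[fit$params$model_id == model & fit$params$param == param, ]
  if (nrow(sel) == 0L)
    stop("no fitted values for model ", model, ", parameter '", param, "'",
         call. = FALSE)
  stats::setNames(sel$value, sel$participant_id)
}

#' Participants-by-models matrix of information criteria
#'
#' @param fit A [fit_cohort()] result.
#' @param ic `"BIC"` or `"AIC"`.
#' @return Numeric matrix, rows = participants, columns = model ids.
#' @export
evidence_table <- function(fit, ic = c("BIC", "AIC")) {
  stopifnot(inherits(fit, "cohort_fit"))
  ic <- match.arg(ic)
  col <- if (ic == "BIC") "bic" else "aic"
  s <- fit$summary
  ids <- unique(s$participant_id)
  mods <- sort(unique(s$model_id))
  out <- matrix(NA_real_, length(ids), length(mods),
                dimnames = list(as.character(ids), as.character(mods)))
  for (i in seq_len(nrow(s)))
    out[as.character(s$participant_id[i]), as.character(s$model_id[i])] <- s[[col]][i]
  if (any(!is.finite(out))) stop("evidence table has non-finite entries", call. = FALSE)
  out
}

#' Write cohort fit results to CSV
#'
#' @param fit A [fit_cohort()] result.
#' @param dir Output directory (created if needed).
#' @return Paths of the two CSV files, invisibly.
#' @export
write_cohort_fit <- function(fit, dir) {
  stopifnot(inherits(fit, "cohort_fit"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p1 <- file.path(dir, "fit_summary.csv")
  p2 <- file.path(dir, "fit_params.csv")
  utils::write.csv(fit$summary, p1, row.names = FALSE)
  utils::write.csv(fit$params, p2, row.names = FALSE)
  invisible(c(p1, p2))
}
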