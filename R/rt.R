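#' Linear mixed-effects analysis of reaction times
#'
#' Fits `log(RT) ~ aev * aps + (1 + aev * aps | participant)` by maximum
#' likelihood, where `aev` and `aps` are each trial's absolute
#' between-option differences in expected value and starvation probability.
#' The significance of each fixed effect is assessed by a likelihood-ratio
#' test against the model with that single fixed term removed (random-effect
#' structure unchanged). If the full random-effects covariance is singular or
#' fails to converge, the random structure is reduced stepwise
#' (`(1 + aev + aps | participant)`, then `(1 | participant)`) with a warning.
#'
#' @param trials Trial data frame with positive `rt_ms` on all non-missed
#'   trials. Reaction times must be on the millisecond (response-time) scale;
#'   the log transform is applied internally.
#' @return A list of class `rt_model_result`: `estimates`, `std_errors` and
#'   `t_values` (named by `aev`, `aps`, `aev:aps`), `loglik_full`, `lrt` (data frame
#'   with `term`, `chisq`, `df`, `p_value`, `loglik_reduced`), `re_structure`,
#'   and the fitted `model` (a `lmerMod`).
#' @export
fit_rt_model <- function(trials) {
  keep <- trials$choice %in% c("A", "B")
  tr <- trials[keep, , drop = FALSE]
  if (nrow(tr) == 0L) stop("no non-missed trials", call. = FALSE)
  if (any(!is.finite(tr$rt_ms) | tr$rt_ms <= 0))
    stop("all non-missed trials must have positive rt_ms", call. = FALSE)
  d <- trial_difficulty(tr)
  dat <- data.frame(log_rt = log(tr$rt_ms), aev = d$aev, aps = d$aps,
                    participant = factor(tr$participant_id))

  res <- c("(1 + aev * aps | participant)",
           "(1 + aev + aps | participant)",
           "(1 | participant)")
  fit_with <- function(fixed, re) {
    f <- stats::as.formula(paste("log_rt ~", fixed, "+", re))
    lme4::lmer(f, data = dat, REML = FALSE,
               control = lme4::lmerControl(calc.derivs = FALSE))
  }
  full <- NULL
  used <- NULL
  for (re in res) {
    fit <- tryCatch(suppressWarnings(fit_with("aev + aps + aev:aps", re)),
                    error = function(e) NULL)
    if (!is.null(fit) && !lme4::isSingular(fit, tol = 1e-5)) {
      full <- fit
      used <- re
      break
    }
    if (!is.null(fit) && is.null(full)) {
      full <- fit  # keep a singular fit as last resort
      used <- re
    }
  }
  if (is.null(full)) stop("mixed model could not be fitted", call. = FALSE)
  if (used != res[1])
    warning("random-effects structure reduced to ", used, call. = FALSE)

  reduced_fixed <- c(aev = "aps + aev:aps",
                     aps = "aev + aev:aps",
                     `aev:aps` = "aev + aps")
  ll_full <- as.numeric(stats::logLik(full))
  lrt <- do.call(rbind, lapply(names(reduced_fixed), function(term) {
    red <- suppressWarnings(fit_with(reduced_fixed[[term]], used))
    ll_red <- as.numeric(stats::logLik(red))
    stat <- max(0, 2 * (ll_full - ll_red))
    data.frame(term = term, chisq = stat, df = 1L,
               p_value = stats::pchisq(stat, df = 1, lower.tail = FALSE),
               loglik_reduced = ll_red)
  }))

  cf <- summary(full)$coefficients
  sel <- c("aev", "aps", "aev:aps")
  structure(list(
    estimates = stats::setNames(cf[sel, "Estimate"], sel),
    std_errors = stats::setNames(cf[sel, "Std. Error"], sel),
    t_values = stats::setNames(cf[sel, "t value"], sel),
    loglik_full = ll_full,
    lrt = lrt,
    re_structure = used,
    model = full
  ), class = "rt_model_result")
}

#' @export
print.rt_model_result <- function(x, ...) {
  cat("<rt_model_result> log(RT) ~ aev * aps +", x$re_structure, "\n")
  tab <- data.frame(estimate = signif(x$estimates, 4),
                    t = signif(x$t_values, 4),
                    lrt_chisq = signif(x$lrt$chisq, 4),
                    lrt_p = signif(x$lrt$p_value, 4))
  print(tab)
  invisible(x)
}
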