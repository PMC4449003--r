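#' The model registry
#'
#' Twelve choice models, in three families plus two supplementary variants.
#' Family 1 (moments): option value is a linear combination of statistical
#' moments of the endpoint distribution (EV, Var, Skw) with free weights.
#' Family 2 (rank-dependent utility): value is a decision-weighted sum of
#' power utilities, with Prelec one- or two-parameter probability weighting.
#' Family 3 (homeostatic): the moment combinations are extended with a free
#' weight on the starvation probability p_starve. Model 10 splits the
#' p_starve weight by task frame, Model 11 drops EV altogether, and Model 12
#' splits the p_starve weight by the number of foraging days.
#'
#' All models share the softmax decision-noise parameter `beta`. Parameters
#' `beta`, `mu`, `alpha` and `beta_w` are constrained positive (optimized on
#' the log scale); the linear weights (`rho`, `lambda`, `xi` and variants)
#' are unconstrained.
#'
#' @param model Model id in 1..12, or its name (e.g. `"EV+pstarve"`).
#' @return A list of class `model_spec` with fields `model_id`, `name`,
#'   `family`, `params` (ordered free-parameter names) and `positive`
#'   (logical mask of positivity-constrained parameters).
#' @examples
#' model_spec(7)
#' model_spec("EV+pstarve")
#' @export
model_spec <- function(model) {
  reg <- .model_registry()
  if (is.character(model)) {
    hit <- which(vapply(reg, function(m) identical(m$name, model), logical(1)))
    if (length(hit) != 1L)
      stop("unknown model name '", model, "'; see model_table()", call. = FALSE)
    return(reg[[hit]])
  }
  if (!is.numeric(model) || length(model) != 1L || !(model %in% 1:12))
    stop("`model` must be an id in 1..12 or a registered name", call. = FALSE)
  reg[[model]]
}

.model_registry <- function() {
  mk <- function(id, name, family, params, positive) {
    structure(list(model_id = id, name = name, family = family,
                   params = params, positive = positive),
              class = "model_spec")
  }
  list(
    mk(1L, "EV", "moments", "beta", TRUE),
    mk(2L, "EV+Var", "moments", c("beta", "rho"), c(TRUE, FALSE)),
    mk(3L, "EV+Skw", "moments", c("beta", "lambda"), c(TRUE, FALSE)),
    mk(4L, "EV+Var+Skw", "moments", c("beta", "rho", "lambda"), c(TRUE, FALSE, FALSE)),
    mk(5L, "Prelec-I", "rank_dependent", c("beta", "mu", "alpha"), c(TRUE, TRUE, TRUE)),
    mk(6L, "Prelec-II", "rank_dependent", c("beta", "mu", "alpha", "beta_w"),
       c(TRUE, TRUE, TRUE, TRUE)),
    mk(7L, "EV+pstarve", "homeostatic", c("beta", "xi"), c(TRUE, FALSE)),
    mk(8L, "EV+Var+pstarve", "homeostatic", c("beta", "rho", "xi"),
       c(TRUE, FALSE, FALSE)),
    mk(9L, "EV+Var+Skw+pstarve", "homeostatic", c("beta", "rho", "lambda", "xi"),
       c(TRUE, FALSE, FALSE, FALSE)),
    mk(10L, "EV+frame-pstarve", "homeostatic", c("beta", "xi_foraging", "xi_casino"),
       c(TRUE, FALSE, FALSE)),
    mk(11L, "pstarve", "supplementary", "beta", TRUE),
    mk(12L, "EV+day-pstarve", "supplementary", c("beta", "xi_d1", "xi_d2", "xi_d3"),
       c(TRUE, FALSE, FALSE, FALSE))
  )
}

#' @export
print.model_spec <- function(x, ...) {
  cat(sprintf("<model_spec> Model %d: %s (family: %s)\n  free parameters: %s\n",
              x$model_id, x$name, x$family, paste(x$params, collapse = ", ")))
  invisible(x)
}

#' Overview table of all registered models
#'
#' @return A data frame with one row per model: id, name, family, the free
#'   parameters, and the parameter count.
#' @export
model_table <- function() {
  reg <- .model_registry()
  data.frame(
    model_id = vapply(reg, `[[`, integer(1), "model_id"),
    name = vapply(reg, `[[`, character(1), "name"),
    family = vapply(reg, `[[`, character(1), "family"),
    params = vapply(reg, function(m) paste(m$params, collapse = ","), character(1)),
    k = vapply(reg, function(m) length(m$params), integer(1))
  )
}

#' Power utility over non-negative outcomes
#'
#' `u(x) = x^mu` with `u(0) = 0`, the utility function of the rank-dependent
#' models.
#'
#' @param x Outcome value(s), >= 0.
#' @param mu Positive exponent.
#' @return Utilities, same length as `x`.
#' @export
power_utility <- function(x, mu) {
  if (!is.numeric(mu) || length(mu) != 1L || !is.finite(mu) || mu <= 0)
    stop("`mu` must be a single positive number", call. = FALSE)
  if (any(x < 0)) stop("outcomes must be >= 0", call. = FALSE)
  x^mu
}

#' Prelec probability weighting
#'
#' One-parameter (variant `"I"`) and two-parameter (variant `"II"`) Prelec
#' weighting: `w(p) = exp(-beta_w * (-log(p))^alpha)`, with `beta_w = 1` for
#' variant I. By convention `w(0) = 0`; `w(1) = 1` holds exactly.
#'
#' @param p Probabilities in \[0, 1\] (0 allowed by the `w(0) = 0` convention).
#' @param alpha Positive curvature parameter.
#' @param beta_w Positive elevation parameter (variant II; must be 1-like
#'   behaviour is obtained with `beta_w = 1`).
#' @param variant `"I"` or `"II"`.
#' @return Weights in \[0, 1\], same length as `p`.
#' @export
prelec_weight <- function(p, alpha, beta_w = 1, variant = c("I", "II")) {
  variant <- match.arg(variant)
  if (!is.finite(alpha) || alpha <= 0)
    stop("`alpha` must be positive", call. = FALSE)
  if (variant == "I") beta_w <- 1
  if (!is.finite(beta_w) || beta_w <= 0)
    stop("`beta_w` must be positive", call. = FALSE)
  if (any(p < 0 | p > 1)) stop("`p` must lie in [0, 1]", call. = FALSE)
  w <- ifelse(p == 0, 0, exp(-beta_w * (-log(p))^alpha))
  # exp(-beta_w * 0^alpha) is exactly 1 at p = 1
  w
}

#' Rank-dependent utility of an outcome distribution
#'
#' Values an option as the decision-weighted sum of power utilities of its
#' outcomes. Outcomes are ranked internally from best to worst; the decision
#' weight of the best outcome is `w` of its probability, and each subsequent
#' weight is the successive difference of `w` applied to the cumulative
#' probability of outcomes at least as good. The weights sum to 1.
#'
#' @param dist An [outcome_dist()].
#' @param mu Positive utility exponent, see [power_utility()].
#' @param alpha,beta_w,variant Weighting parameters, see [prelec_weight()].
#' @return The option's value (a single number).
#' @examples
#' d <- enumerate_walk(walk_spec(2, 2, 3, 0.4))
#' rdu_value(d, mu = 1, alpha = 1)   # equals compute_stats(d)$ev
#' @export
rdu_value <- function(dist, mu, alpha, beta_w = 1, variant = c("I", "II")) {
  variant <- match.arg(variant)
  if (!inherits(dist, "outcome_dist"))
    stop("`dist` must be an outcome_dist", call. = FALSE)
  ord <- order(dist$support, decreasing = TRUE)
  x <- dist$support[ord]
  pr <- dist$probs[ord]
  cum <- pmin(cumsum(pr), 1)
  w <- prelec_weight(cum, alpha, beta_w, variant)
  pi_j <- diff(c(0, w))
  sum(pi_j * power_utility(x, mu))
}

#' Features of one trial, for model evaluation
#'
#' Bundles both options' endpoint distributions and moments with the frame
#' and day-count indicators a model may use.
#'
#' @param distA,distB [outcome_dist()] objects for options A and B.
#' @param frame `"foraging"` or `"casino"`.
#' @param days Day count of the trial's gambles (1, 2 or 3).
#' @return A list of class `trial_features`.
#' @export
trial_features <- function(distA, distB, frame = c("casino", "foraging"), days) {
  frame <- match.arg(frame)
  if (!days %in% 1:3) stop("`days` must be 1, 2 or 3", call. = FALSE)
  structure(list(
    A = list(stats = compute_stats(distA), dist = distA),
    B = list(stats = compute_stats(distB), dist = distB),
    f = as.integer(frame == "foraging"),
    d1 = as.integer(days == 1), d2 = as.integer(days == 2),
    d3 = as.integer(days == 3)
  ), class = "trial_features")
}

#' Value of one option under a model
#'
#' Evaluates the model's value equation for one option of a trial.
#'
#' @param model A [model_spec()], or an id/name accepted by it.
#' @param params Named numeric vector with the model's free parameters
#'   (the softmax `beta` may be present; it is ignored here).
#' @param feat A [trial_features()] object.
#' @param option `"A"` or `"B"`.
#' @return The option value `V` (a single number).
#' @examples
#' dA <- enumerate_walk(walk_spec(2, 3, 3, 0.4))
#' dB <- enumerate_walk(walk_spec(2, 3, 4, 0.3))
#' ft <- trial_features(dA, dB, frame = "foraging", days = 3)
#' option_value(7, c(beta = 1, xi = -2), ft, "A")
#' @export
option_value <- function(model, params, feat, option = c("A", "B")) {
  option <- match.arg(option)
  m <- if (inherits(model, "model_spec")) model else model_spec(model)
  if (!inherits(feat, "trial_features"))
    stop("`feat` must be a trial_features object", call. = FALSE)
  o <- feat[[option]]
  s <- o$stats
  pget <- function(nm) {
    if (!nm %in% names(params))
      stop("model '", m$name, "' needs parameter '", nm, "'", call. = FALSE)
    unname(params[[nm]])
  }
  switch(as.character(m$model_id),
    "1" = s$ev,
    "2" = s$ev + pget("rho") * s$var,
    "3" = s$ev + pget("lambda") * s$skw,
    "4" = s$ev + pget("rho") * s$var + pget("lambda") * s$skw,
    "5" = rdu_value(o$dist, pget("mu"), pget("alpha"), 1, "I"),
    "6" = rdu_value(o$dist, pget("mu"), pget("alpha"), pget("beta_w"), "II"),
    "7" = s$ev + pget("xi") * s$p_starve,
    "8" = s$ev + pget("rho") * s$var + pget("xi") * s$p_starve,
    "9" = s$ev + pget("rho") * s$var + pget("lambda") * s$skw +
          pget("xi") * s$p_starve,
    "10" = s$ev + (feat$f * pget("xi_foraging") +
                   (1 - feat$f) * pget("xi_casino")) * s$p_starve,
    "11" = s$p_starve,
    "12" = s$ev + (feat$d1 * pget("xi_d1") + feat$d2 * pget("xi_d2") +
                   feat$d3 * pget("xi_d3")) * s$p_starve,
    stop("unknown model id ", m$model_id, call. = FALSE)
  )
}

#' Softmax choice probability
#'
#' Probability of choosing option 1 given the two option values:
#' `P = 1 / (1 + exp(-(V1 - V2) / beta))`. `beta` is the decision noise;
#' larger `beta` pulls choices toward indifference.
#'
#' @param V1,V2 Option values (vectorized).
#' @param beta Positive decision-noise parameter.
#' @return Choice probabilities in (0, 1).
#' @examples
#' choice_prob(1, 0, beta = 1)   # 0.731...
#' @export
choice_prob <- function(V1, V2, beta) {
  if (!is.numeric(beta) || length(beta) != 1L || !is.finite(beta) || beta <= 0)
    stop("`beta` must be a single positive number", call. = FALSE)
  stats::plogis((V1 - V2) / beta)
}
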