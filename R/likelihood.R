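#' Compile trials for fast likelihood evaluation
#'
#' Precomputes everything the likelihood needs that does not depend on the
#' parameters: per-trial moment features, frame and day indicators, and the
#' ranked outcome/cumulative-probability matrices the rank-dependent models
#' use. Missed trials are excluded from the likelihood here.
#'
#' @param trials Trial data frame with columns `participant_id`, `frame`,
#'   `block`, `trial_index`, `pair_id`, `x0`, `n`, `gA`, `pA`, `gB`, `pB`,
#'   `choice` (values `"A"`, `"B"` or `"missed"`) and `rt_ms`.
#' @return An object of class `compiled_trials`.
#' @export
compile_trials <- function(trials) {
  if (inherits(trials, "compiled_trials")) return(trials)
  req <- c("frame", "pair_id", "x0", "n", "gA", "pA", "gB", "pB", "choice")
  if (!all(req %in% names(trials)))
    stop("`trials` must have columns ", paste(req, collapse = ", "), call. = FALSE)
  keep <- trials$choice %in% c("A", "B")
  if (!any(keep)) stop("no non-missed trials to fit", call. = FALSE)
  tr <- trials[keep, , drop = FALSE]

  key <- paste(tr$x0, tr$n, tr$gA, tr$pA, tr$gB, tr$pB, sep = "|")
  ukey <- unique(key)
  pidx <- match(key, ukey)
  first <- match(ukey, key)
  upairs <- data.frame(pair_id = seq_along(ukey),
                       x0 = tr$x0[first], n = tr$n[first],
                       gA = tr$gA[first], pA = tr$pA[first],
                       gB = tr$gB[first], pB = tr$pB[first])
  gf <- gamble_features(upairs)

  # ranked outcome / cumulative-probability matrices (best outcome first),
  # zero-probability padding keeps a rectangular layout without affecting
  # the decision weights
  rank_mats <- function(dists) {
    jmax <- max(vapply(dists, function(d) length(d$support), integer(1)))
    X <- matrix(0, length(dists), jmax)
    CUM <- matrix(1, length(dists), jmax)
    for (i in seq_along(dists)) {
      ord <- order(dists[[i]]$support, decreasing = TRUE)
      x <- dists[[i]]$support[ord]
      cm <- pmin(cumsum(dists[[i]]$probs[ord]), 1)
      j <- length(x)
      X[i, seq_len(j)] <- x
      CUM[i, seq_len(j)] <- cm
      if (j < jmax) CUM[i, (j + 1):jmax] <- cm[j]
    }
    list(X = X, CUM = CUM)
  }

  structure(list(
    n_trials = nrow(tr),
    choiceA = tr$choice == "A",
    f = as.numeric(tr$frame == "foraging"),
    d1 = as.numeric(tr$n == 1), d2 = as.numeric(tr$n == 2),
    d3 = as.numeric(tr$n == 3),
    pair_index = pidx,
    pair_features = gf$features,
    rduA = rank_mats(gf$dists$A),
    rduB = rank_mats(gf$dists$B)
  ), class = "compiled_trials")
}

# option values for both options, per trial, under any registered model
.model_values <- function(m, params, ct) {
  pf <- ct$pair_features
  ix <- ct$pair_index
  pget <- function(nm) unname(params[[nm]])
  lin <- function(rho = 0, lambda = 0) {
    list(VA = (pf$evA + rho * pf$varA + lambda * pf$skwA)[ix],
         VB = (pf$evB + rho * pf$varB + lambda * pf$skwB)[ix],
         psA = pf$psA[ix], psB = pf$psB[ix])
  }
  id <- m$model_id
  if (id %in% c(5L, 6L)) {
    mu <- pget("mu"); alpha <- pget("alpha")
    bw <- if (id == 6L) pget("beta_w") else 1
    val <- function(rm) {
      W <- exp(-bw * (-log(rm$CUM))^alpha)
      PI <- W - cbind(0, W[, -ncol(W), drop = FALSE])
      rowSums(PI * rm$X^mu)
    }
    return(list(VA = val(ct$rduA)[ix], VB = val(ct$rduB)[ix]))
  }
  if (id == 1L) { v <- lin(); return(list(VA = v$VA, VB = v$VB)) }
  if (id == 2L) { v <- lin(rho = pget("rho")); return(list(VA = v$VA, VB = v$VB)) }
  if (id == 3L) { v <- lin(lambda = pget("lambda")); return(list(VA = v$VA, VB = v$VB)) }
  if (id == 4L) { v <- lin(rho = pget("rho"), lambda = pget("lambda"))
                  return(list(VA = v$VA, VB = v$VB)) }
  if (id == 7L) { v <- lin()
                  xi <- pget("xi")
                  return(list(VA = v$VA + xi * v$psA, VB = v$VB + xi * v$psB)) }
  if (id == 8L) { v <- lin(rho = pget("rho"))
                  xi <- pget("xi")
                  return(list(VA = v$VA + xi * v$psA, VB = v$VB + xi * v$psB)) }
  if (id == 9L) { v <- lin(rho = pget("rho"), lambda = pget("lambda"))
                  xi <- pget("xi")
                  return(list(VA = v$VA + xi * v$psA, VB = v$VB + xi * v$psB)) }
  if (id == 10L) { v <- lin()
                   xi <- ct$f * pget("xi_foraging") + (1 - ct$f) * pget("xi_casino")
                   return(list(VA = v$VA + xi * v$psA, VB = v$VB + xi * v$psB)) }
  if (id == 11L) { return(list(VA = pf$psA[ix], VB = pf$psB[ix])) }
  if (id == 12L) { v <- lin()
                   xi <- ct$d1 * pget("xi_d1") + ct$d2 * pget("xi_d2") +
                         ct$d3 * pget("xi_d3")
                   return(list(VA = v$VA + xi * v$psA, VB = v$VB + xi * v$psB)) }
  stop("unknown model id ", id, call. = FALSE)
}

#' Negative log-likelihood of a model on a participant's trials
#'
#' Sums `-log P(observed choice)` over all non-missed trials, with the choice
#' probability from [choice_prob()]. Probabilities are clipped to
#' `[clip, 1 - clip]` before taking logs so near-deterministic parameter
#' regions keep a finite likelihood.
#'
#' @param model A [model_spec()] or id/name.
#' @param params Named numeric vector including `beta` and the model's other
#'   free parameters.
#' @param trials Trial data frame, or a [compile_trials()] object (compiling
#'   once and reusing it is much faster inside optimization loops).
#' @param clip Clipping bound for the choice probabilities.
#' @return The negative log-likelihood in nats (a single non-negative number).
#' @export
negative_log_likelihood <- function(model, params, trials, clip = 1e-10) {
  m <- if (inherits(model, "model_spec")) model else model_spec(model)
  ct <- compile_trials(trials)
  need <- setdiff(m$params, names(params))
  if (length(need))
    stop("missing parameter(s) for model '", m$name, "': ",
         paste(need, collapse = ", "), call. = FALSE)
  beta <- unname(params[["beta"]])
  if (!is.finite(beta) || beta <= 0) return(Inf)
  v <- .model_values(m, params, ct)
  dv <- (v$VA - v$VB) / beta
  pA <- stats::plogis(dv)
  p_obs <- ifelse(ct$choiceA, pA, 1 - pA)
  p_obs <- pmin(pmax(p_obs, clip), 1 - clip)
  -sum(log(p_obs))
}
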