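#' Specify a foraging gamble as a random walk
#'
#' A foraging option is a random walk on the non-negative integers with an
#' absorbing boundary at zero ("starvation"). The walker starts at energy
#' `x0` and takes `n` steps ("days"). On each day it either forages
#' successfully, with probability `p`, gaining `g` points net of the sure
#' daily cost of one point (a step of `+(g - 1)`), or unsuccessfully, with
#' probability `1 - p`, paying only the cost (a step of `-1`). A walk that
#' touches zero stops there.
#'
#' @param x0 Initial energy (integer, >= 1).
#' @param n Number of days/steps (integer, >= 1).
#' @param g Gross gain on a successful day (integer, >= 2, so the net
#'   right-step `g - 1` is at least 1).
#' @param p Per-day success probability, strictly inside (0, 1).
#'
#' @return An object of class `walk_spec`.
#' @examples
#' walk_spec(x0 = 2, n = 3, g = 3, p = 0.4)
#' @export
walk_spec <- function(x0, n, g, p) {
  if (length(x0) != 1L || !is.finite(x0) || x0 < 1 || x0 != round(x0))
    stop("`x0` must be a single integer >= 1", call. = FALSE)
  if (length(n) != 1L || !is.finite(n) || n < 1 || n != round(n))
    stop("`n` must be a single integer >= 1", call. = FALSE)
  if (length(g) != 1L || !is.finite(g) || g < 2 || g != round(g))
    stop("`g` must be a single integer >= 2", call. = FALSE)
  if (length(p) != 1L || !is.finite(p) || p <= 0 || p >= 1)
    stop("`p` must be a single probability strictly inside (0, 1)", call. = FALSE)
  structure(
    list(x0 = as.integer(x0), n = as.integer(n), g = as.integer(g), p = as.numeric(p)),
    class = "walk_spec"
  )
}

#' @export
print.walk_spec <- function(x, ...) {
  cat(sprintf("<walk_spec> x0 = %d, n = %d, g = %d, p = %.3f\n", x$x0, x$n, x$g, x$p))
  invisible(x)
}

#' Exact endpoint distribution of an absorbed random walk
#'
#' Computes the exact probability distribution of the walker's energy after
#' `n` days, with absorption at zero: any visit to zero terminates the walk
#' and contributes its mass to the endpoint value 0. Probabilities are
#' obtained by exact forward propagation of the state distribution, which is
#' equivalent to summing, over all root-to-leaf paths of the step tree, the
#' product of the step probabilities along each path.
#'
#' @param spec A [walk_spec()].
#'
#' @return An object of class `outcome_dist`: a list with
#'   `support` (strictly increasing integer endpoint values, including 0 when
#'   reachable), `probs` (matching probabilities summing to 1), and
#'   `p_starve` (the mass at 0; 0 if 0 is unreachable).
#' @examples
#' enumerate_walk(walk_spec(2, 3, 3, 0.4))
#' @export
enumerate_walk <- function(spec) {
  if (!inherits(spec, "walk_spec")) spec <- do.call(walk_spec, as.list(spec))
  p <- spec$p
  q <- 1 - p
  step_up <- spec$g - 1L
  # state distribution over energy; absorbed mass accumulates at 0
  states <- spec$x0
  mass <- 1
  for (i in seq_len(spec$n)) {
    alive <- states > 0L
    up <- states[alive] + step_up
    down <- states[alive] - 1L
    new_states <- c(states[!alive], up, down)
    new_mass <- c(mass[!alive], mass[alive] * p, mass[alive] * q)
    agg <- rowsum(new_mass, group = new_states)
    states <- as.integer(rownames(agg))
    mass <- as.numeric(agg)
  }
  ord <- order(states)
  states <- states[ord]
  mass <- mass[ord]
  outcome_dist(support = states, probs = mass)
}

#' Construct an endpoint outcome distribution
#'
#' @param support Endpoint values (non-negative, strictly increasing after
#'   sorting; duplicates are not allowed).
#' @param probs Matching probabilities; must be non-negative and sum to 1
#'   within 1e-12.
#'
#' @return An `outcome_dist` object with fields `support`, `probs` and
#'   `p_starve` (the probability at value 0, or 0 when absent).
#' @export
outcome_dist <- function(support, probs) {
  if (length(support) != length(probs))
    stop("`support` and `probs` must have equal length", call. = FALSE)
  ord <- order(support)
  support <- support[ord]
  probs <- probs[ord]
  if (any(duplicated(support)))
    stop("`support` values must be distinct", call. = FALSE)
  if (any(support < 0))
    stop("`support` values must be >= 0", call. = FALSE)
  if (any(probs < 0))
    stop("`probs` must be non-negative", call. = FALSE)
  if (abs(sum(probs) - 1) > 1e-12)
    stop("`probs` must sum to 1 within 1e-12", call. = FALSE)
  p_starve <- if (support[1] == 0) probs[1] else 0
  structure(
    list(support = as.numeric(support), probs = as.numeric(probs),
         p_starve = as.numeric(p_starve)),
    class = "outcome_dist"
  )
}

#' @export
print.outcome_dist <- function(x, ...) {
  cat("<outcome_dist>\n")
  print(data.frame(outcome = x$support, prob = signif(x$probs, 6)), row.names = FALSE)
  cat(sprintf("p_starve = %.6g\n", x$p_starve))
  invisible(x)
}

#' Statistical moments of an outcome distribution
#'
#' Expected value, variance, standardized skewness and starvation probability
#' of an endpoint distribution. Skewness is the third central moment divided
#' by the 3/2 power of the variance; it is defined as 0 for a degenerate
#' (zero-variance) distribution.
#'
#' @param dist An [outcome_dist()] (or a [walk_spec()], which is enumerated
#'   first).
#'
#' @return A list of class `gamble_stats` with fields `ev`, `var`, `skw`,
#'   `p_starve`.
#' @examples
#' compute_stats(enumerate_walk(walk_spec(2, 3, 3, 0.4)))
#' @export
compute_stats <- function(dist) {
  if (inherits(dist, "walk_spec")) dist <- enumerate_walk(dist)
  if (!inherits(dist, "outcome_dist"))
    stop("`dist` must be an outcome_dist or walk_spec", call. = FALSE)
  x <- dist$support
  pr <- dist$probs
  ev <- sum(x * pr)
  v <- sum(pr * (x - ev)^2)
  skw <- if (v > 0) sum(pr * (x - ev)^3) / v^1.5 else 0
  structure(list(ev = ev, var = v, skw = skw, p_starve = dist$p_starve),
            class = "gamble_stats")
}

#' @export
print.gamble_stats <- function(x, ...) {
  cat(sprintf("<gamble_stats> EV = %.4g, Var = %.4g, Skw = %.4g, p_starve = %.4g\n",
              x$ev, x$var, x$skw, x$p_starve))
  invisible(x)
}

#' Export an outcome distribution as JSON
#'
#' @param dist An [outcome_dist()].
#' @param path Optional file path; when `NULL` the JSON string is returned.
#' @return The JSON string, invisibly when written to `path`.
#' @export
outcome_dist_json <- function(dist, path = NULL) {
  stopifnot(inherits(dist, "outcome_dist"))
  js <- jsonlite::toJSON(list(support = dist$support, probs = dist$probs,
                              p_starve = dist$p_starve),
                         auto_unbox = FALSE, digits = NA)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}
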