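#' Settings for the gamble-set generator
#'
#' The task's gamble list pairs two foraging options that share the trial's
#' initial energy `x0` and horizon `n` (one energy bar and one day count per
#' trial). The default settings reproduce the structure of the study design:
#' 120 pairs for each of the four (x0, n) combinations (1,1), (1,2), (2,2),
#' (2,3), gross gains drawn uniformly from 2..6, and per-option success
#' probabilities drawn uniformly on [0.008, 0.9] and rounded to three
#' decimals. Every generated option has strictly positive starvation
#' probability.
#'
#' @param combos Data frame with integer columns `x0`, `n`: the initial
#'   state / day-count combinations.
#' @param n_per_combo Number of gamble pairs per combination.
#' @param gains Integer vector of admissible gross gains.
#' @param p_range Length-2 numeric range for success probabilities.
#' @param p_digits Decimals the probabilities are rounded to.
#'
#' @return A list of class `gamble_config`.
#' @export
gamble_config <- function(combos = data.frame(x0 = c(1L, 1L, 2L, 2L),
                                              n  = c(1L, 2L, 2L, 3L)),
                          n_per_combo = 120L,
                          gains = 2:6,
                          p_range = c(0.008, 0.9),
                          p_digits = 3L) {
  if (!is.data.frame(combos) || !all(c("x0", "n") %in% names(combos)) ||
      nrow(combos) == 0L)
    stop("`combos` must be a non-empty data frame with columns x0, n", call. = FALSE)
  if (n_per_combo < 1L) stop("`n_per_combo` must be >= 1", call. = FALSE)
  if (length(gains) == 0L || any(gains < 2))
    stop("`gains` must be a non-empty set of integers >= 2", call. = FALSE)
  if (length(p_range) != 2L || p_range[1] <= 0 || p_range[2] >= 1 ||
      p_range[1] > p_range[2])
    stop("`p_range` must be an increasing range inside (0, 1)", call. = FALSE)
  structure(list(combos = combos, n_per_combo = as.integer(n_per_combo),
                 gains = as.integer(gains), p_range = as.numeric(p_range),
                 p_digits = as.integer(p_digits)),
            class = "gamble_config")
}

#' Generate a structured set of binary gamble pairs
#'
#' Draws gamble pairs under a [gamble_config()]. Options within a pair share
#' (x0, n); gains and probabilities are drawn independently per option, and a
#' pair is redrawn when either option's starvation probability leaves (0, 1)
#' or the two options are identical.
#'
#' @param config A [gamble_config()].
#' @param seed Integer seed; the generated set is reproducible under it.
#'
#' @return A data frame with columns `pair_id`, `x0`, `n`, `gA`, `pA`,
#'   `gB`, `pB`, one row per gamble pair.
#' @examples
#' pairs <- generate_gamble_set(gamble_config(n_per_combo = 5), seed = 1)
#' @export
generate_gamble_set <- function(config = gamble_config(), seed) {
  if (!inherits(config, "gamble_config")) stop("`config` must be a gamble_config", call. = FALSE)
  if (missing(seed)) stop("`seed` is required for reproducibility", call. = FALSE)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  draw_p <- function() {
    pr <- round(stats::runif(1, config$p_range[1], config$p_range[2]), config$p_digits)
    min(max(pr, config$p_range[1]), config$p_range[2])
  }
  rows <- vector("list", nrow(config$combos) * config$n_per_combo)
  k <- 0L
  for (ci in seq_len(nrow(config$combos))) {
    x0 <- as.integer(config$combos$x0[ci])
    n <- as.integer(config$combos$n[ci])
    for (i in seq_len(config$n_per_combo)) {
      repeat {
        gA <- sample(config$gains, 1L)
        gB <- sample(config$gains, 1L)
        pA <- draw_p()
        pB <- draw_p()
        if (gA == gB && pA == pB) next
        psA <- enumerate_walk(walk_spec(x0, n, gA, pA))$p_starve
        psB <- enumerate_walk(walk_spec(x0, n, gB, pB))$p_starve
        if (psA > 0 && psA < 1 && psB > 0 && psB < 1) break
      }
      k <- k + 1L
      rows[[k]] <- data.frame(x0 = x0, n = n, gA = gA, pA = pA, gB = gB, pB = pB)
    }
  }
  out <- do.call(rbind, rows)
  out <- cbind(pair_id = seq_len(nrow(out)), out)
  rownames(out) <- NULL
  out
}

#' Derived decision variables for a set of gamble pairs
#'
#' Enumerates each option's endpoint distribution and attaches the moments
#' and starvation probability (`evA`, `varA`, `skwA`, `psA`, and likewise
#' for B) plus day indicators `d1`, `d2`, `d3`. Distributions are returned
#' alongside for rank-dependent models.
#'
#' @param pairs Data frame as returned by [generate_gamble_set()].
#'
#' @return A list with `features` (data frame, one row per pair) and
#'   `dists` (list with per-pair `A` and `B` [outcome_dist()] objects).
#' @export
gamble_features <- function(pairs) {
  req <- c("pair_id", "x0", "n", "gA", "pA", "gB", "pB")
  if (!all(req %in% names(pairs)))
    stop("`pairs` must have columns ", paste(req, collapse = ", "), call. = FALSE)
  nP <- nrow(pairs)
  distA <- vector("list", nP)
  distB <- vector("list", nP)
  statA <- matrix(0, nP, 4)
  statB <- matrix(0, nP, 4)
  for (i in seq_len(nP)) {
    dA <- enumerate_walk(walk_spec(pairs$x0[i], pairs$n[i], pairs$gA[i], pairs$pA[i]))
    dB <- enumerate_walk(walk_spec(pairs$x0[i], pairs$n[i], pairs$gB[i], pairs$pB[i]))
    sA <- compute_stats(dA)
    sB <- compute_stats(dB)
    distA[[i]] <- dA
    distB[[i]] <- dB
    statA[i, ] <- c(sA$ev, sA$var, sA$skw, sA$p_starve)
    statB[i, ] <- c(sB$ev, sB$var, sB$skw, sB$p_starve)
  }
  feats <- data.frame(
    pair_id = pairs$pair_id,
    x0 = pairs$x0, n = pairs$n,
    evA = statA[, 1], varA = statA[, 2], skwA = statA[, 3], psA = statA[, 4],
    evB = statB[, 1], varB = statB[, 2], skwB = statB[, 3], psB = statB[, 4],
    d1 = as.integer(pairs$n == 1), d2 = as.integer(pairs$n == 2),
    d3 = as.integer(pairs$n == 3)
  )
  list(features = feats, dists = list(A = distA, B = distB))
}

#' Write / read a gamble set as CSV
#'
#' @param pairs Gamble-pair data frame.
#' @param path File path.
#' @return `read_gamble_set` returns the gamble-pair data frame.
#' @export
write_gamble_set <- function(pairs, path) {
  utils::write.csv(pairs, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_gamble_set
#' @export
read_gamble_set <- function(path) {
  out <- utils::read.csv(path)
  req <- c("pair_id", "x0", "n", "gA", "pA", "gB", "pB")
  if (!all(req %in% names(out)))
    stop("gamble CSV must have columns ", paste(req, collapse = ", "), call. = FALSE)
  out
}

# save/restore the RNG state so seeded generators do not disturb the caller's
# random stream
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  invisible(NULL)
}
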