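# Independent oracles and small fixtures, kept deliberately naive.

# brute-force endpoint distribution: enumerate all 2^n success/failure
# sequences; once absorbed the state stays at zero while the remaining step
# probabilities keep multiplying, so the 2^n sequences partition the
# probability space exactly and aggregate to the absorbed-walk distribution
brute_force_walk <- function(x0, n, g, p) {
  endpoints <- numeric(2^n)
  masses <- numeric(2^n)
  for (code in 0:(2^n - 1)) {
    steps <- as.integer(intToBits(code))[seq_len(n)]  # 1 = success
    pos <- x0
    prob <- 1
    for (s in steps) {
      prob <- prob * if (s == 1) p else (1 - p)
      if (pos > 0) pos <- if (s == 1) pos + (g - 1) else pos - 1
      if (pos <= 0) pos <- 0
    }
    endpoints[code + 1] <- pos
    masses[code + 1] <- prob
  }
  agg <- tapply(masses, endpoints, sum)
  list(support = as.numeric(names(agg)), probs = as.numeric(agg))
}

# hand evaluation of rank-dependent utility (best-ranked-first), independent
# of the package's matrix implementation
hand_rdu <- function(support, probs, mu, alpha, beta_w = 1) {
  ord <- order(support, decreasing = TRUE)
  x <- support[ord]
  pr <- probs[ord]
  v <- 0
  cum_prev <- 0
  w <- function(p) if (p == 0) 0 else exp(-beta_w * (-log(p))^alpha)
  for (j in seq_along(x)) {
    cum <- min(cum_prev + pr[j], 1)
    v <- v + (w(cum) - w(cum_prev)) * x[j]^mu
    cum_prev <- cum
  }
  v
}

# small reusable gamble set (deterministic)
small_gamble_set <- function(n_per_combo = 10, seed = 101) {
  generate_gamble_set(gamble_config(n_per_combo = n_per_combo), seed = seed)
}

# quick single-agent dataset without RTs
quick_trials <- function(model_id, params, pairs = small_gamble_set(),
                         seed = 11, missed_rate = 0) {
  ag <- agent_spec(model_id, params, participant_id = 1L, seed = seed)
  simulate_agent(ag, pairs, missed_rate = missed_rate)
}
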