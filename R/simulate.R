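#' Specify a synthetic decision-making agent
#'
#' @param model_id Generating model id (1..12).
#' @param params Named numeric vector of generating parameters (must include
#'   `beta` and the model's other free parameters).
#' @param participant_id Identifier written into the generated trials.
#' @param seed Integer seed for the agent's choice (and missed-trial) noise.
#' @return A list of class `agent_spec`.
#' @export
agent_spec <- function(model_id, params, participant_id = 1L, seed = 1L) {
  m <- model_spec(model_id)
  need <- setdiff(m$params, names(params))
  if (length(need))
    stop("agent for model '", m$name, "' needs parameter(s): ",
         paste(need, collapse = ", "), call. = FALSE)
  if (params[["beta"]] <= 0) stop("`beta` must be positive", call. = FALSE)
  structure(list(model_id = m$model_id, params = params,
                 participant_id = participant_id, seed = as.integer(seed)),
            class = "agent_spec")
}

# skeleton of one session: casino blocks precede foraging blocks; each
# frame presents the full pair list split into two blocks
.session_skeleton <- function(pairs, frames = c("casino", "foraging")) {
  nP <- nrow(pairs)
  half <- ceiling(nP / 2)
  block <- rep(c(1L, 2L), c(half, nP - half))
  rows <- lapply(frames, function(fr) {
    data.frame(frame = fr, block = block,
               pair_id = pairs$pair_id,
               x0 = pairs$x0, n = pairs$n,
               gA = pairs$gA, pA = pairs$pA, gB = pairs$gB, pB = pairs$pB)
  })
  out <- do.call(rbind, rows)
  out$trial_index <- seq_len(nrow(out)) - 1L
  out
}

#' Simulate one agent's choices over a gamble set
#'
#' Presents every gamble pair in each frame (casino blocks first), computes
#' the generating model's option values and draws each choice from the
#' softmax probability. A small fraction of trials is marked missed
#' (missing completely at random).
#'
#' @param agent An [agent_spec()].
#' @param pairs Gamble-pair data frame from [generate_gamble_set()].
#' @param frames Frames to present, in order.
#' @param missed_rate Probability that a trial is missed (default 2/960, the
#'   study's average).
#' @return Trial data frame (one row per trial) with `choice` in
#'   `"A"`/`"B"`/`"missed"` and `rt_ms = NA` (see [simulate_rts()]).
#' @export
simulate_agent <- function(agent, pairs, frames = c("casino", "foraging"),
                           missed_rate = 2 / 960) {
  stopifnot(inherits(agent, "agent_spec"))
  if (nrow(pairs) == 0L) stop("`pairs` must be non-empty", call. = FALSE)
  tr <- .session_skeleton(pairs, frames)
  tr <- cbind(participant_id = agent$participant_id, tr)
  tr$choice <- "A"  # placeholder so the trials compile
  tr$rt_ms <- NA_real_
  ct <- compile_trials(tr)
  m <- model_spec(agent$model_id)
  v <- .model_values(m, agent$params, ct)
  pA <- choice_prob(v$VA, v$VB, agent$params[["beta"]])

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(agent$seed)
  tr$choice <- ifelse(stats::runif(nrow(tr)) < pA, "A", "B")
  if (missed_rate > 0) {
    miss <- stats::runif(nrow(tr)) < missed_rate
    tr$choice[miss] <- "missed"
  }
  tr[c("participant_id", "frame", "block", "trial_index", "pair_id",
       "x0", "n", "gA", "pA", "gB", "pB", "choice", "rt_ms")]
}

#' Reaction-time generator settings
#'
#' Log reaction times follow the linear mixed structure the RT analysis
#' assumes: fixed effects of the absolute between-option differences in EV
#' and p_starve and their interaction, participant-level random intercepts
#' and slopes, and Gaussian residual noise, all on the log-millisecond scale.
#' The defaults give median RTs near 1.1 s, faster responses for easier
#' (larger-difference) trials, and a slowing interaction, mirroring the
#' qualitative pattern the analysis is designed to detect.
#'
#' @param fixed Fixed effects `c(intercept, ev, pstarve, interaction)` on
#'   log-ms scale.
#' @param ranef_sd Participant random-effect SDs for the same four terms.
#' @param resid_sd Residual SD (> 0).
#' @return A list of class `rt_generator_spec`.
#' @export
rt_generator_spec <- function(fixed = c(intercept = 7.0, ev = -0.05,
                                        pstarve = -0.30, interaction = 0.20),
                              ranef_sd = c(intercept = 0.15, ev = 0.02,
                                           pstarve = 0.10, interaction = 0.05),
                              resid_sd = 0.30) {
  if (length(fixed) != 4L || length(ranef_sd) != 4L)
    stop("`fixed` and `ranef_sd` must have length 4", call. = FALSE)
  if (resid_sd <= 0) stop("`resid_sd` must be positive", call. = FALSE)
  structure(list(fixed = fixed, ranef_sd = ranef_sd, resid_sd = resid_sd),
            class = "rt_generator_spec")
}

#' Add model-driven reaction times to a dataset
#'
#' Fills `rt_ms` on all non-missed trials from the log-normal mixed model of
#' [rt_generator_spec()], using each trial's absolute between-option
#' differences in EV and starvation probability as predictors.
#'
#' @param trials Trial data frame (cohort-level; `participant_id` defines the
#'   random-effect grouping).
#' @param spec An [rt_generator_spec()].
#' @param seed Integer seed.
#' @return The trial data frame with `rt_ms` filled on non-missed trials.
#' @export
simulate_rts <- function(trials, spec = rt_generator_spec(), seed = 1L) {
  stopifnot(inherits(spec, "rt_generator_spec"))
  preds <- trial_difficulty(trials)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  ids <- unique(trials$participant_id)
  b <- matrix(stats::rnorm(length(ids) * 4, 0, rep(spec$ranef_sd, each = length(ids))),
              length(ids), 4, dimnames = list(as.character(ids), NULL))
  ri <- match(as.character(trials$participant_id), rownames(b))
  X <- cbind(1, preds$aev, preds$aps, preds$aev * preds$aps)
  mu <- X %*% spec$fixed + rowSums(X * b[ri, , drop = FALSE])
  log_rt <- mu + stats::rnorm(nrow(trials), 0, spec$resid_sd)
  trials$rt_ms <- ifelse(trials$choice == "missed", NA_real_, exp(log_rt))
  trials
}

#' Per-trial difficulty predictors
#'
#' Absolute between-option differences in expected value (`aev`) and
#' starvation probability (`aps`) for every trial.
#'
#' @param trials Trial data frame.
#' @return Data frame with columns `aev`, `aps` aligned with `trials` rows.
#' @export
trial_difficulty <- function(trials) {
  key <- paste(trials$x0, trials$n, trials$gA, trials$pA, trials$gB, trials$pB,
               sep = "|")
  ukey <- unique(key)
  first <- match(ukey, key)
  upairs <- data.frame(pair_id = seq_along(ukey),
                       x0 = trials$x0[first], n = trials$n[first],
                       gA = trials$gA[first], pA = trials$pA[first],
                       gB = trials$gB[first], pB = trials$pB[first])
  pf <- gamble_features(upairs)$features
  ix <- match(key, ukey)
  data.frame(aev = abs(pf$evA - pf$evB)[ix], aps = abs(pf$psA - pf$psB)[ix])
}

#' Simulate a complete synthetic cohort
#'
#' Generates a shared gamble set, draws per-agent generating parameters from
#' the stated population distribution, simulates every agent's choices
#' (casino frame first) and reaction times, and records the ground truth.
#' The default mirrors the study shape: 22 agents, 480 pairs presented in two
#' frames (960 trials each), generated by the frame-specific homeostatic
#' model with beta = 0.5 and p_starve weights around -3 (foraging) and -1.5
#' (casino).
#'
#' Positivity-constrained parameters (`beta`, `mu`, `alpha`, `beta_w`) are
#' drawn log-normally with median `param_means` and log-scale SD `param_sds`;
#' unconstrained weights are drawn normally.
#'
#' @param n_agents Number of agents.
#' @param model_id Generating model id.
#' @param param_means Named vector of population medians/means of the
#'   generating parameters.
#' @param param_sds Named vector of population SDs (log-scale for positive
#'   parameters); 0 gives identical agents.
#' @param config [gamble_config()] for the shared gamble set.
#' @param seed Integer master seed (gamble set, parameter draws, per-agent
#'   choice seeds and RTs all derive from it).
#' @param rt_spec [rt_generator_spec()] for the reaction times, or `NULL` to
#'   leave `rt_ms` empty.
#' @param missed_rate Per-trial missed probability.
#' @return A list of class `cohort_sim`: `trials` (all agents),
#'   `agents` (ground-truth data frame: one row per agent with its
#'   generating parameters), `pairs`, `rt_spec`, `seed`.
#' @export
simulate_cohort <- function(n_agents = 22L,
                            model_id = 10L,
                            param_means = c(beta = 0.5, xi_foraging = -3,
                                            xi_casino = -1.5),
                            param_sds = c(beta = 0.25, xi_foraging = 0.75,
                                          xi_casino = 0.5),
                            config = gamble_config(),
                            seed = 1L,
                            rt_spec = rt_generator_spec(),
                            missed_rate = 2 / 960) {
  if (n_agents < 1L) stop("`n_agents` must be >= 1", call. = FALSE)
  m <- model_spec(model_id)
  need <- setdiff(m$params, names(param_means))
  if (length(need))
    stop("`param_means` must cover: ", paste(m$params, collapse = ", "),
         call. = FALSE)
  if (!all(m$params %in% names(param_sds)))
    stop("`param_sds` must cover: ", paste(m$params, collapse = ", "),
         call. = FALSE)

  pairs <- generate_gamble_set(config, seed = seed)

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed + 1L)
  draws <- matrix(NA_real_, n_agents, length(m$params),
                  dimnames = list(NULL, m$params))
  for (j in seq_along(m$params)) {
    nm <- m$params[j]
    if (m$positive[j]) {
      draws[, j] <- exp(stats::rnorm(n_agents, log(param_means[[nm]]),
                                     param_sds[[nm]]))
    } else {
      draws[, j] <- stats::rnorm(n_agents, param_means[[nm]], param_sds[[nm]])
    }
  }
  agent_seeds <- sample.int(.Machine$integer.max - 1L, n_agents)

  trials <- vector("list", n_agents)
  for (i in seq_len(n_agents)) {
    ag <- agent_spec(m$model_id, stats::setNames(draws[i, ], m$params),
                     participant_id = i, seed = agent_seeds[i])
    trials[[i]] <- simulate_agent(ag, pairs, missed_rate = missed_rate)
  }
  trials <- do.call(rbind, trials)
  if (!is.null(rt_spec)) trials <- simulate_rts(trials, rt_spec, seed = seed + 2L)

  agents <- data.frame(participant_id = seq_len(n_agents),
                       model_id = m$model_id, seed = agent_seeds)
  agents <- cbind(agents, as.data.frame(draws))
  structure(list(trials = trials, agents = agents, pairs = pairs,
                 rt_spec = rt_spec, seed = seed),
            class = "cohort_sim")
}

#' @export
print.cohort_sim <- function(x, ...) {
  cat(sprintf("<cohort_sim> %d agents x %d trials (model %d), %d gamble pairs\n",
              nrow(x$agents), nrow(x$trials) / nrow(x$agents),
              x$agents$model_id[1], nrow(x$pairs)))
  invisible(x)
}
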