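.dataset_columns <- c("participant_id", "frame", "block", "trial_index",
                      "pair_id", "x0", "n", "gA", "pA", "gB", "pB",
                      "choice", "rt_ms")

#' Load a trial-level dataset
#'
#' Reads and validates trial records. The CSV schema is the one written by
#' [write_dataset()] (columns `participant_id`, `frame`, `block`,
#' `trial_index`, `pair_id`, `x0`, `n`, `gA`, `pA`, `gB`, `pB`, `choice`,
#' `rt_ms`). Malformed rows are reported with their row numbers. MATLAB
#' files are not parsed directly; export the deposited data to this CSV
#' schema first (the internal layout of such files is not standardized, so a
#' field mapping would be required in any case).
#'
#' @param path File path.
#' @param format `"csv"` (supported) or `"mat"` (not parsed; see above).
#' @return Validated trial data frame. The number of distinct participants is
#'   attached as attribute `"n_participants"` and reported via `message()`.
#' @export
load_dataset <- function(path, format = c("csv", "mat")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "mat")
    stop("MAT files are not parsed directly; convert the file to the ",
         "documented CSV schema (see ?write_dataset) with a field mapping ",
         "of your choice", call. = FALSE)
  tr <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(.dataset_columns, names(tr))
  if (length(miss))
    stop("dataset is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  bad_frame <- which(!tr$frame %in% c("foraging", "casino"))
  bad_choice <- which(!tr$choice %in% c("A", "B", "missed"))
  bad_rt <- which(tr$choice %in% c("A", "B") &
                    (!is.finite(tr$rt_ms) | tr$rt_ms <= 0))
  probs <- c(
    if (length(bad_frame)) paste0("invalid frame at row(s) ",
                                  paste(utils::head(bad_frame, 10), collapse = ", ")),
    if (length(bad_choice)) paste0("invalid choice at row(s) ",
                                   paste(utils::head(bad_choice, 10), collapse = ", ")),
    if (length(bad_rt)) paste0("non-positive rt_ms on non-missed trial at row(s) ",
                               paste(utils::head(bad_rt, 10), collapse = ", "))
  )
  if (length(probs)) stop(paste(probs, collapse = "; "), call. = FALSE)
  n_part <- length(unique(tr$participant_id))
  message(sprintf("loaded %d trials from %d participants", nrow(tr), n_part))
  attr(tr, "n_participants") <- n_part
  tr
}

#' Write a trial-level dataset as CSV
#'
#' @param trials Trial data frame (see [load_dataset()] for the schema).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(trials, path) {
  miss <- setdiff(.dataset_columns, names(trials))
  if (length(miss))
    stop("dataset is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  utils::write.csv(trials[.dataset_columns], path, row.names = FALSE)
  invisible(path)
}

#' Compare fitted models at the group level
#'
#' Convenience wrapper running the fixed-effects log-group Bayes factors, the
#' random-effects model-level BMS, and the family-level BMS on a cohort fit.
#'
#' @param fit A [fit_cohort()] result.
#' @param ic `"BIC"` or `"AIC"`; log evidence is taken as minus the criterion.
#' @param reference Reference model (column) for the log-group Bayes factors;
#'   default the first fitted model.
#' @param seed,n_samples Passed to the BMS samplers.
#' @return A list of class `model_comparison`: `ic`, `log_group_bayes_factors`,
#'   `bms` (model-level [bms_random_effects()] result), `family_bms`
#'   (family-level result), `families` (label per fitted model).
#' @export
compare_models <- function(fit, ic = c("BIC", "AIC"), reference = 1L,
                           seed = 1L, n_samples = 1e6) {
  ic <- match.arg(ic)
  tab <- evidence_table(fit, ic)
  fams <- vapply(as.integer(colnames(tab)),
                 function(id) model_spec(id)$family, character(1))
  lgbf <- log_group_bayes_factors(tab, reference)
  le <- -tab
  bms <- bms_random_effects(le, prior_alpha = 1, seed = seed,
                            n_samples = n_samples)
  fbms <- family_bms(le, fams, seed = seed, n_samples = n_samples)
  structure(list(ic = ic, log_group_bayes_factors = lgbf, bms = bms,
                 family_bms = fbms, families = stats::setNames(fams, colnames(tab))),
            class = "model_comparison")
}

#' @export
print.model_comparison <- function(x, ...) {
  cat("<model_comparison> based on", x$ic, "\n")
  tab <- data.frame(model = names(x$log_group_bayes_factors),
                    family = unname(x$families),
                    log_group_BF = round(unname(x$log_group_bayes_factors), 1),
                    exceedance = signif(unname(x$bms$exceedance), 4))
  print(tab, row.names = FALSE)
  cat("family exceedance:\n")
  print(signif(x$family_bms$family_exceedance, 4))
  invisible(x)
}

#' Pipeline configuration
#'
#' Bundles every setting of a full synthetic-cohort analysis run. Every
#' stochastic stage draws its seed deterministically from the single `seed`
#' here.
#'
#' @param n_agents,model_id,param_means,param_sds,missed_rate Cohort settings,
#'   see [simulate_cohort()].
#' @param gamble A [gamble_config()].
#' @param fit_models Model ids to fit.
#' @param fit A [fit_options()] list.
#' @param ic `"BIC"` or `"AIC"`.
#' @param bms_samples Dirichlet draws for exceedance estimates.
#' @param rt_spec [rt_generator_spec()] or `NULL` to skip RTs (and the RT
#'   analysis stage).
#' @param dataset_path Optional path to an existing dataset CSV; when given,
#'   the generate/simulate stages are skipped and the file is loaded instead.
#' @param seed Master seed.
#' @param out_dir Output directory.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(n_agents = 22L, model_id = 10L,
                            param_means = c(beta = 0.5, xi_foraging = -3,
                                            xi_casino = -1.5),
                            param_sds = c(beta = 0.25, xi_foraging = 0.75,
                                          xi_casino = 0.5),
                            missed_rate = 2 / 960,
                            gamble = gamble_config(),
                            fit_models = 1:10,
                            fit = fit_options(),
                            ic = c("BIC", "AIC"),
                            bms_samples = 1e6,
                            rt_spec = rt_generator_spec(),
                            dataset_path = NULL,
                            seed = 1L,
                            out_dir = tempfile("foragefit_run_")) {
  ic <- match.arg(ic)
  structure(list(n_agents = n_agents, model_id = model_id,
                 param_means = param_means, param_sds = param_sds,
                 missed_rate = missed_rate, gamble = gamble,
                 fit_models = fit_models, fit = fit, ic = ic,
                 bms_samples = bms_samples, rt_spec = rt_spec,
                 dataset_path = dataset_path, seed = as.integer(seed),
                 out_dir = out_dir),
            class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Executes generate/simulate (or load) -> fit -> compare -> RT analysis,
#' writing each stage's outputs to `config$out_dir` as it completes
#' (`dataset.csv`, `ground_truth.json`, `fit_summary.csv`, `fit_params.csv`,
#' `comparison.json`, `rt.json`) plus a provenance `manifest.json` with the
#' seed, package version and a hash of the configuration. A failed stage
#' leaves the earlier stages' files in place so a rerun can start from the
#' written dataset.
#'
#' @param config A [pipeline_config()].
#' @return A list of class `pipeline_report` with elements `trials`,
#'   `ground_truth` (NULL for loaded data), `fit`, `comparison`, `rt`
#'   (NULL when RTs are absent), `paths`, `config_hash`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list()

  cfg_json <- jsonlite::serializeJSON(config[setdiff(names(config), "out_dir")])
  cfg_file <- file.path(config$out_dir, "config.json")
  writeLines(as.character(cfg_json), cfg_file)
  config_hash <- unname(tools::md5sum(cfg_file))
  paths$config <- cfg_file

  ground_truth <- NULL
  if (is.null(config$dataset_path)) {
    sim <- simulate_cohort(n_agents = config$n_agents,
                           model_id = config$model_id,
                           param_means = config$param_means,
                           param_sds = config$param_sds,
                           config = config$gamble,
                           seed = config$seed,
                           rt_spec = config$rt_spec,
                           missed_rate = config$missed_rate)
    trials <- sim$trials
    ground_truth <- sim$agents
    paths$ground_truth <- file.path(config$out_dir, "ground_truth.json")
    jsonlite::write_json(ground_truth, paths$ground_truth, digits = NA)
  } else {
    trials <- load_dataset(config$dataset_path)
  }
  paths$dataset <- file.path(config$out_dir, "dataset.csv")
  write_dataset(trials, paths$dataset)

  fit <- fit_cohort(trials, models = config$fit_models, options = config$fit)
  paths$fit <- write_cohort_fit(fit, config$out_dir)

  comp <- compare_models(fit, ic = config$ic, seed = config$seed,
                         n_samples = config$bms_samples)
  paths$comparison <- file.path(config$out_dir, "comparison.json")
  jsonlite::write_json(list(
    ic = comp$ic,
    log_group_bayes_factors = as.list(comp$log_group_bayes_factors),
    alpha = as.list(comp$bms$alpha),
    exceedance = as.list(comp$bms$exceedance),
    family_exceedance = as.list(comp$family_bms$family_exceedance)
  ), paths$comparison, auto_unbox = TRUE, digits = NA)

  rt <- NULL
  if (any(trials$choice %in% c("A", "B") & is.finite(trials$rt_ms))) {
    rt <- fit_rt_model(trials)
    paths$rt <- file.path(config$out_dir, "rt.json")
    jsonlite::write_json(list(
      estimates = as.list(rt$estimates),
      t_values = as.list(rt$t_values),
      lrt = rt$lrt,
      re_structure = rt$re_structure
    ), paths$rt, auto_unbox = TRUE, digits = NA)
  }

  manifest <- list(
    package = "foragefit",
    version = as.character(utils::packageVersion("foragefit")),
    seed = config$seed,
    config_hash = config_hash,
    files = lapply(paths, as.character)
  )
  paths$manifest <- file.path(config$out_dir, "manifest.json")
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE)

  structure(list(trials = trials, ground_truth = ground_truth, fit = fit,
                 comparison = comp, rt = rt, paths = paths,
                 config_hash = config_hash),
            class = "pipeline_report")
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("<pipeline_report>\n")
  print(x$comparison)
  if (!is.null(x$rt)) print(x$rt)
  cat("outputs:", dirname(x$paths$dataset), "\n")
  invisible(x)
}
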