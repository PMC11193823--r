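TRIAL_COLUMNS <- c("subject_id", "group", "trial", "pair", "choice",
                   "optimal", "reward", "rt_ms")

#' Write a trial table to CSV
#'
#' Single tabular interchange format of the package: header row, UTF-8,
#' "." decimal; `rt_ms` may be empty.
#'
#' @param table a trial table.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_trial_table <- function(table, path) {
  if (!"rt_ms" %in% names(table)) table$rt_ms <- NA_real_
  write.csv(table[, TRIAL_COLUMNS], path, row.names = FALSE, quote = FALSE,
            na = "")
  invisible(path)
}

#' Read and validate a trial table from CSV
#'
#' Checks column presence, legal reward values, and uniqueness plus
#' chronological contiguity of `(subject_id, trial)`; errors name the
#' offending row. A header-only file yields an empty, valid table.
#'
#' @param path CSV file path.
#' @return validated trial table data.frame.
#' @export
read_trial_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  tab <- read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(setdiff(TRIAL_COLUMNS, "rt_ms"), names(tab))
  if (length(missing)) stop("missing column(s): ", paste(missing, collapse = ", "))
  if (!"rt_ms" %in% names(tab)) tab$rt_ms <- NA_real_
  if (nrow(tab) == 0L) return(tab[, TRIAL_COLUMNS])
  bad <- which(!tab$reward %in% c(0L, 1L))
  if (length(bad)) stop("illegal reward value in row ", bad[1])
  key <- paste(tab$subject_id, tab$trial)
  dup <- which(duplicated(key))
  if (length(dup)) stop("duplicate (subject_id, trial) in row ", dup[1])
  for (id in unique(tab$subject_id)) {
    rows <- which(tab$subject_id == id)
    if (is.unsorted(tab$trial[rows], strictly = TRUE)) {
      stop("trials of subject ", id, " are not in chronological order (row ",
           rows[which(diff(tab$trial[rows]) <= 0)[1] + 1L], ")")
    }
  }
  bad_opt <- which(tab$optimal != as.integer(tab$choice %% 2L == 1L))
  if (length(bad_opt)) {
    stop("optimal flag inconsistent with choice in row ", bad_opt[1])
  }
  tab[, TRIAL_COLUMNS]
}

#' Persist posterior draws as long CSV plus a JSON sidecar
#'
#' The group-level draws (and optionally the subject-level draws) are
#' written in long format (`chain`, `iteration`, `parameter`, `value`); a
#' `<path>.meta.json` sidecar records model, priors, sampler configuration,
#' and the diagnostics summary.
#'
#' @param draws an `rl_posterior`.
#' @param path CSV output path.
#' @param include_subjects also write the subject-level draws (parameter
#'   names `u_<par>.<subject_id>`).
#' @return `path`, invisibly.
#' @export
write_posterior_draws <- function(draws, path, include_subjects = FALSE) {
  stopifnot(inherits(draws, "rl_posterior"))
  d <- dim(draws$hyper)
  long <- data.frame(
    chain = rep(rep(seq_len(d[2]), each = d[1]), d[3]),
    iteration = rep(seq_len(d[1]), d[2] * d[3]),
    parameter = rep(dimnames(draws$hyper)[[3]], each = d[1] * d[2]),
    value = as.vector(draws$hyper)
  )
  if (include_subjects) {
    ds <- dim(draws$subj)
    per_chain <- ds[1] / d[2]
    sub_long <- data.frame(
      chain = rep(rep(seq_len(d[2]), each = per_chain), ds[2] * ds[3]),
      iteration = rep(seq_len(per_chain), d[2] * ds[2] * ds[3]),
      parameter = rep(paste0("u_", rep(dimnames(draws$subj)[[3]], each = ds[2]),
                             ".", rep(dimnames(draws$subj)[[2]], ds[3])),
                      each = ds[1]),
      value = as.vector(draws$subj)
    )
    long <- rbind(long, sub_long)
  }
  write.csv(long, path, row.names = FALSE, quote = FALSE)
  meta <- list(
    model_id = draws$model_id,
    response_convention = draws$response_convention,
    priors = unclass(draws$priors),
    config = unclass(draws$config),
    subjects = draws$subjects,
    groups = draws$group,
    accept_rate = draws$accept_rate,
    converged = draws$converged,
    diagnostics = draws$diagnostics
  )
  jsonlite::write_json(meta, paste0(path, ".meta.json"), auto_unbox = TRUE,
                       digits = NA, dataframe = "rows", pretty = TRUE)
  invisible(path)
}

#' Read posterior draws written by [write_posterior_draws()]
#'
#' Reconstructs the group-level draw array and metadata (subject-level
#' draws, if present, are returned in long form).
#'
#' @param path CSV path given to [write_posterior_draws()].
#' @return list with `hyper` (iterations x chains x quantities), `subjects`
#'   (long data.frame or `NULL`) and `meta`.
#' @export
read_posterior_draws <- function(path) {
  long <- read.csv(path, stringsAsFactors = FALSE)
  meta <- jsonlite::fromJSON(paste0(path, ".meta.json"))
  is_sub <- grepl("^u_.*\\.", long$parameter)
  hyper_long <- long[!is_sub, ]
  params <- unique(hyper_long$parameter)
  n_chain <- max(hyper_long$chain)
  n_iter <- max(hyper_long$iteration)
  hyper <- array(NA_real_, c(n_iter, n_chain, length(params)),
                 dimnames = list(NULL, NULL, params))
  for (p in params) {
    rows <- hyper_long[hyper_long$parameter == p, ]
    hyper[cbind(rows$iteration, rows$chain, match(p, params))] <- rows$value
  }
  list(hyper = hyper,
       subjects = if (any(is_sub)) long[is_sub, ] else NULL,
       meta = meta)
}

RUN_CONFIG_KEYS <- c("out_dir", "scenario", "design", "sampler", "seeds", "rope")

validate_run_config <- function(config) {
  if (is.character(config)) config <- jsonlite::fromJSON(config)
  unknown <- setdiff(names(config), RUN_CONFIG_KEYS)
  if (length(unknown)) stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  if (is.null(config$out_dir)) stop("config requires out_dir")
  if (is.null(config$scenario)) stop("config requires a scenario block")
  for (s in c("simulate", "fit", "evaluate")) {
    if (is.null(config$seeds[[s]])) stop("config requires an explicit seeds$", s)
  }
  config$scenario$preset <- config$scenario$preset %||% "inverted_u"
  config$scenario$model_id <- config$scenario$model_id %||% "SWo"
  config$scenario$n_subjects <- config$scenario$n_subjects %||% 141L
  config$design <- config$design %||% list(trials_per_pair = 40L)
  config$sampler <- config$sampler %||% list(scale = "test")
  config$rope <- config$rope %||% c(-0.1, 0.1)
  config
}

log_line <- function(stage, ...) {
  message(format(Sys.time(), "%Y-%m-%dT%H:%M:%S"), " [", stage, "] ", ...)
}

#' Run the full pipeline: simulate, fit, evaluate, hypotheses
#'
#' Thin driver tying the package's stages together: simulates a synthetic
#' cohort from a scenario, fits the hierarchical model, evaluates it
#' (model accuracy, posterior predictive check, PSIS-LOO), and computes the
#' posterior hypothesis statistics; all artifacts are written under
#' `config$out_dir` (trial table and truth CSVs, posterior draws CSV with
#' JSON sidecar, evaluation and hypothesis JSON reports).
#'
#' @param config a list (or path to a JSON file) with keys `out_dir`,
#'   `scenario` (`preset`, `model_id`, `n_subjects`), optional `design`
#'   (`trials_per_pair`), optional `sampler` (fields of
#'   [sampler_config()]), `seeds` (`simulate`, `fit`, `evaluate`; all
#'   required) and optional `rope`. Unknown keys are rejected before any
#'   computation.
#' @return named list of artifact paths, invisibly.
#' @export
run_pipeline <- function(config) {
  config <- validate_run_config(config)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  path <- function(f) file.path(config$out_dir, f)

  log_line("simulate", "building design and cohort (seed ", config$seeds$simulate, ")")
  design <- default_design(config$design$trials_per_pair %||% 40L)
  scenario <- make_scenario(config$scenario$preset,
                            model_id = config$scenario$model_id,
                            n_subjects = config$scenario$n_subjects)
  cohort <- draw_cohort(scenario, seed = config$seeds$simulate)
  table <- simulate_cohort(cohort, design, seed = config$seeds$simulate + 1L)
  write.csv(as.data.frame(cohort), path("cohort_truth.csv"), row.names = FALSE)
  write_trial_table(table, path("trials.csv"))

  log_line("fit", "sampling the hierarchical posterior (seed ", config$seeds$fit, ")")
  cfg <- do.call(sampler_config, c(config$sampler, list(seed = config$seeds$fit)))
  t0 <- Sys.time()
  draws <- sample_posterior(table, config$scenario$model_id, config = cfg)
  log_line("fit", "done in ", round(as.numeric(Sys.time() - t0, units = "secs"), 1),
           " s; max split R-hat ",
           round(max(draws$diagnostics$rhat, na.rm = TRUE), 3))
  write_posterior_draws(draws, path("posterior_draws.csv"))
  means <- subject_posterior_means(draws)
  write.csv(means, path("subject_posterior_means.csv"), row.names = FALSE)

  log_line("evaluate", "model accuracy, predictive check, PSIS-LOO (seed ",
           config$seeds$evaluate, ")")
  acc <- model_accuracy(table, means, config$scenario$model_id)
  ppc <- posterior_predictive(table, means, config$scenario$model_id, design,
                              repeats = 20L, seed = config$seeds$evaluate)
  loo <- psis_loo(pointwise_loglik(draws, table,
                                   thin = max(1L, floor(dim(draws$subj)[1] / 500))))
  jsonlite::write_json(
    list(model_accuracy = acc,
         looic = loo$looic, elpd_loo = loo$elpd_loo, loo_se = loo$se,
         n_bad_pareto_k = loo$n_bad_k,
         observed_optimal_curve = as.numeric(ppc$observed_curve),
         simulated_optimal_curve = as.numeric(ppc$sim_curve)),
    path("evaluation.json"), auto_unbox = TRUE, digits = NA, pretty = TRUE)

  log_line("hypotheses", "pattern fractions, contrasts, trend regression")
  hypothesis_report(draws, rope = config$rope, path = path("hypotheses.json"))

  log_line("done", "artifacts in ", config$out_dir)
  invisible(list(
    trials = path("trials.csv"),
    truth = path("cohort_truth.csv"),
    draws = path("posterior_draws.csv"),
    subject_means = path("subject_posterior_means.csv"),
    evaluation = path("evaluation.json"),
    hypotheses = path("hypotheses.json")
  ))
}
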