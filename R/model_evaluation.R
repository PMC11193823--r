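# align a subject-parameter table (subject_id + constrained parameter
# columns) with the subjects of a dataset; returns a parameter matrix
subject_par_matrix <- function(dataset, subject_params, spec) {
  info <- dataset_subjects(dataset)
  missing <- setdiff(info$ids, subject_params$subject_id)
  if (length(missing)) {
    stop("parameters missing for subject(s): ", paste(missing, collapse = ", "))
  }
  rows <- match(info$ids, subject_params$subject_id)
  as.matrix(subject_params[rows, spec$name, drop = FALSE])
}

#' Model accuracy: mean likelihood of observed choices
#'
#' The mean, over all trials of the dataset, of the probability the model
#' assigns to the observed choice at the given subject-level parameters
#' (canonically the subject posterior means).
#'
#' @param dataset trial table.
#' @param subject_params data.frame with `subject_id` and one column per
#'   constrained model parameter (e.g. from [subject_posterior_means()] or
#'   an `rl_cohort`).
#' @param model_id model identifier.
#' @param response_convention see [param_spec()].
#' @return mean model likelihood in `(0, 1)`.
#' @export
model_accuracy <- function(dataset, subject_params, model_id,
                           response_convention = NULL) {
  spec <- param_spec(model_id, response_convention)
  pars <- subject_par_matrix(dataset, subject_params, spec)
  ix <- cohort_index(dataset)
  ll <- cohort_trial_logp_cpp(ix$start, ix$len, ix$pair, ix$chosen, ix$other,
                              ix$reward, pars, attr(spec, "family"))
  mean(exp(ll))
}

# rebuild a schedule from a subject's observed pair sequence (stimulus
# positions are irrelevant to the models; better stimulus shown left)
schedule_from_trials <- function(trials) {
  data.frame(trial = seq_len(nrow(trials)), pair_id = trials$pair,
             left_stimulus = 2L * trials$pair - 1L,
             right_stimulus = 2L * trials$pair)
}

#' Posterior predictive choice simulation
#'
#' Re-simulates choices at given subject-level parameters, both on each
#' subject's observed task structure (pair sequence) and on fresh
#' randomized schedules. Simulation is repeated `repeats` times because
#' choices are drawn against uniform random thresholds; per-trial
#' optimal-choice likelihoods are averaged over repeats. In addition the
#' deterministic model likelihood of the optimal choice on the observed
#' data (given the observed history) is returned.
#'
#' @param dataset trial table the parameters were fitted on.
#' @param subject_params data.frame with `subject_id` and constrained
#'   parameter columns.
#' @param model_id model identifier.
#' @param design the task design (for fresh schedules and feedback).
#' @param repeats number of simulation repeats (default 20).
#' @param response_convention see [param_spec()].
#' @param seed optional integer; output is deterministic given it.
#' @return list with `observed_curve` (per within-pair trial index: mean
#'   model likelihood of the optimal choice on observed data),
#'   `sim_structure_curve` and `sim_curve` (mean simulated optimal-choice
#'   rates, averaged over repeats, on the observed structure and on fresh
#'   schedules), and `sim_tables` (`repeats` simulated trial tables on
#'   fresh schedules).
#' @export
posterior_predictive <- function(dataset, subject_params, model_id,
                                 design = default_design(), repeats = 20L,
                                 response_convention = NULL, seed = NULL) {
  if (repeats < 1L) stop("repeats must be at least 1")
  spec <- param_spec(model_id, response_convention)
  pars <- subject_par_matrix(dataset, subject_params, spec)
  info <- dataset_subjects(dataset)
  ix <- cohort_index(dataset)

  # deterministic likelihood of the optimal choice on observed data
  ll <- cohort_trial_logp_cpp(ix$start, ix$len, ix$pair, ix$chosen, ix$other,
                              ix$reward, pars, attr(spec, "family"))
  p_chosen <- exp(ll)
  is_opt <- ix$chosen %% 2L == 1L
  p_opt <- ifelse(is_opt, p_chosen, 1 - p_chosen)
  pair_trial <- stats::ave(seq_along(ix$pair),
                           dataset$subject_id, ix$pair, FUN = seq_along)
  observed_curve <- tapply(p_opt, pair_trial, mean)

  with_seed(seed, {
    acc_struct <- numeric(0); acc_fresh <- numeric(0)
    pt_struct <- integer(0); pt_fresh <- integer(0)
    sim_tables <- vector("list", repeats)
    for (r in seq_len(repeats)) {
      per_subj <- lapply(seq_along(info$ids), function(i) {
        rows <- dataset[dataset$subject_id == info$ids[i], ]
        prm <- setNames(pars[i, ], spec$name)
        s1 <- simulate_choices(prm, schedule_from_trials(rows), design, model_id,
                               response_convention)
        s2 <- simulate_choices(prm, build_schedule(design), design, model_id,
                               response_convention)
        s1$p_chosen <- NULL
        s2$p_chosen <- NULL
        list(struct = cbind(subject_id = info$ids[i], s1),
             fresh = cbind(subject_id = info$ids[i], group = info$group[i], s2))
      })
      struct <- do.call(rbind, lapply(per_subj, `[[`, "struct"))
      fresh <- do.call(rbind, lapply(per_subj, `[[`, "fresh"))
      acc_struct <- c(acc_struct, struct$optimal)
      pt_struct <- c(pt_struct, stats::ave(seq_len(nrow(struct)), struct$subject_id,
                                           struct$pair, FUN = seq_along))
      acc_fresh <- c(acc_fresh, fresh$optimal)
      pt_fresh <- c(pt_fresh, stats::ave(seq_len(nrow(fresh)), fresh$subject_id,
                                         fresh$pair, FUN = seq_along))
      rownames(fresh) <- NULL
      sim_tables[[r]] <- fresh
    }
    list(
      observed_curve = observed_curve,
      sim_structure_curve = tapply(acc_struct, pt_struct, mean),
      sim_curve = tapply(acc_fresh, pt_fresh, mean),
      sim_tables = sim_tables
    )
  })
}

#' Draw-wise, trial-wise log-likelihood matrix
#'
#' For each retained subject-level posterior draw, the log probability the
#' model assigns to every observed choice; the input to [psis_loo()]. Row
#' sums equal the per-draw total log-likelihood.
#'
#' @param draws an `rl_posterior` fitted to `dataset`.
#' @param dataset the trial table the posterior was fitted on.
#' @param thin keep every k-th retained draw (rows).
#' @return matrix, draws x trials, of log choice probabilities.
#' @export
pointwise_loglik <- function(draws, dataset, thin = 1L) {
  stopifnot(inherits(draws, "rl_posterior"))
  info <- dataset_subjects(dataset)
  if (!identical(info$ids, draws$subjects)) {
    stop("dataset subjects do not match the posterior's subjects")
  }
  spec <- draws$spec
  ix <- cohort_index(dataset)
  family <- attr(spec, "family")
  rows <- seq(1L, dim(draws$subj)[1], by = thin)
  out <- matrix(NA_real_, length(rows), length(ix$pair))
  for (s in seq_along(rows)) {
    u <- matrix(draws$subj[rows[s], , ], ncol = nrow(spec))
    out[s, ] <- cohort_trial_logp_cpp(ix$start, ix$len, ix$pair, ix$chosen,
                                      ix$other, ix$reward,
                                      constrain_pars(u, spec), family)
  }
  out
}

# generalized Pareto fit (Zhang & Stephens 2009 style) to exceedances x > 0
gpd_fit <- function(x) {
  x <- sort(x)
  n <- length(x)
  m <- 30L + floor(sqrt(n))
  jj <- seq_len(m)
  xstar <- x[max(1L, floor(n / 4 + 0.5))]
  if (xstar <= 0) xstar <- min(x[x > 0])
  theta <- 1 / x[n] + (1 - sqrt(m / (jj - 0.5))) / (3 * xstar)
  k_of <- vapply(theta, function(b) -mean(log1p(-b * x)), numeric(1))
  l_theta <- n * (log(theta / k_of) + k_of - 1)
  w <- exp(l_theta - max(l_theta))
  w <- w / sum(w)
  theta_hat <- sum(theta * w)
  k <- -mean(log1p(-theta_hat * x))
  sigma <- k / theta_hat
  k <- (k * n + 5) / (n + 10)  # weak prior toward k = 0.5 stabilizes small tails
  list(k = k, sigma = sigma)
}

qgpd <- function(p, k, sigma) {
  if (abs(k) < 1e-12) return(-sigma * log(1 - p))
  sigma * ((1 - p)^(-k) - 1) / k
}

# Pareto-smooth one vector of log importance ratios; returns log weights
# (unnormalized) and the tail shape estimate
psis_smooth <- function(lr, tail_frac = 0.2) {
  s <- length(lr)
  lr <- lr - max(lr)
  tail_len <- ceiling(tail_frac * s)
  if (tail_len < 5L || s < 25L) {
    return(list(lw = lr, k = NA_real_))
  }
  ord <- order(lr)
  tail_idx <- ord[(s - tail_len + 1L):s]
  cutoff_log <- lr[ord[s - tail_len]]
  cutoff <- exp(cutoff_log)
  exceed <- exp(lr[tail_idx]) - cutoff
  # degenerate tails (ties, zero spread) cannot support a Pareto fit
  if (max(exceed) <= 0 || length(unique(exceed)) < 5L) {
    return(list(lw = lr, k = NA_real_))
  }
  fit <- gpd_fit(exceed)
  if (!is.finite(fit$k) || !is.finite(fit$sigma) || fit$sigma <= 0) {
    return(list(lw = lr, k = NA_real_))
  }
  q <- qgpd((seq_len(tail_len) - 0.5) / tail_len, fit$k, fit$sigma)
  smoothed <- log(cutoff + q)
  smoothed <- pmin(smoothed, 0)  # truncate at the raw maximum ratio
  lw <- lr
  lw[tail_idx[order(exp(lr[tail_idx]))]] <- sort(smoothed)
  list(lw = lw, k = fit$k)
}

log_sum_exp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

#' PSIS leave-one-out cross-validation
#'
#' Pareto-smoothed importance-sampling estimate of the expected log
#' pointwise predictive density. Importance ratios of each observation (the
#' reciprocal likelihoods) have their largest 20 percent replaced by
#' expected order statistics of a generalized Pareto distribution fitted to
#' that tail; observations with tail shape `k > 0.7` are flagged.
#'
#' @param loglik_matrix draws x observations matrix of log likelihoods
#'   (e.g. from [pointwise_loglik()]).
#' @return list of class `rl_loo`: `elpd_loo`, `se`, `looic`
#'   (`= -2 * elpd_loo`), `pointwise` (per-observation elpd), `pareto_k`,
#'   `n_bad_k` (observations with `k > 0.7`).
#' @export
psis_loo <- function(loglik_matrix) {
  ll <- as.matrix(loglik_matrix)
  if (!all(is.finite(ll))) stop("log-likelihood matrix must be finite")
  n <- ncol(ll); s <- nrow(ll)
  if (n < 1L || s < 1L) stop("at least one draw and one observation required")
  pointwise <- numeric(n)
  pareto_k <- numeric(n)
  for (i in seq_len(n)) {
    sm <- psis_smooth(-ll[, i])
    lw <- sm$lw
    pointwise[i] <- log_sum_exp(lw + ll[, i]) - log_sum_exp(lw)
    pareto_k[i] <- sm$k
  }
  elpd <- sum(pointwise)
  se <- sqrt(n * var(pointwise))
  n_bad <- sum(pareto_k > 0.7, na.rm = TRUE)
  if (n_bad > 0) {
    warning(n_bad, " observation(s) with Pareto k > 0.7; LOO estimate may be unstable")
  }
  structure(list(elpd_loo = elpd, se = se, looic = -2 * elpd,
                 pointwise = pointwise, pareto_k = pareto_k, n_bad_k = n_bad),
            class = "rl_loo")
}

#' @export
print.rl_loo <- function(x, ...) {
  cat("PSIS-LOO: elpd =", round(x$elpd_loo, 1), " looic =", round(x$looic, 1),
      " se =", round(x$se, 1), "\n")
  if (x$n_bad_k > 0) cat(x$n_bad_k, "observation(s) with Pareto k > 0.7\n")
  invisible(x)
}

#' LOOIC comparison table
#'
#' @param fits named list of `rl_loo` objects.
#' @return data.frame sorted by LOOIC (lower is better out-of-sample
#'   prediction).
#' @export
looic_table <- function(fits) {
  out <- data.frame(
    model = names(fits),
    elpd_loo = vapply(fits, function(f) f$elpd_loo, numeric(1)),
    looic = vapply(fits, function(f) f$looic, numeric(1)),
    se = vapply(fits, function(f) f$se, numeric(1))
  )
  out <- out[order(out$looic), ]
  rownames(out) <- NULL
  out
}

#' Parameter recovery study
#'
#' Simulates fresh choice data for every agent of a truth table at its true
#' parameters, refits the model, and reports the Spearman rank correlation
#' between fitted and generative values per parameter (on the unconstrained
#' scale).
#'
#' @param model_id model identifier.
#' @param truth an `rl_cohort` (or data.frame with `subject_id`, `group`,
#'   `u_<par>` and `<par>` columns).
#' @param design task design for the simulated sessions.
#' @param fit_method `"mle"` (per-subject maximum likelihood; default) or
#'   `"hierarchical"` (posterior means from [sample_posterior()]).
#' @param seed integer seed for simulation, fitting starts and sampling.
#' @param response_convention see [param_spec()].
#' @param config sampler configuration for the hierarchical method.
#' @return list of class `rl_recovery`: `per_parameter` (data.frame with
#'   `parameter`, `rho`), `mean_rho`, `fitted` (the per-subject estimates),
#'   `fit_method`. A constant true parameter yields `NA` for that
#'   parameter's correlation.
#' @export
parameter_recovery <- function(model_id, truth, design = default_design(),
                               fit_method = c("mle", "hierarchical"),
                               seed = 1L, response_convention = NULL,
                               config = sampler_config("test")) {
  fit_method <- match.arg(fit_method)
  spec <- param_spec(model_id, response_convention)
  if (nrow(truth) < 2L) stop("recovery needs at least two agents")
  u_cols <- paste0("u_", spec$name)
  stopifnot(all(u_cols %in% names(truth)))

  scenario <- attr(truth, "scenario")
  if (is.null(scenario)) {
    scenario <- make_scenario("null", model_id = model_id,
                              n_subjects = nrow(truth),
                              response_convention = response_convention)
  }
  cohort <- truth
  attr(cohort, "scenario") <- scenario
  class(cohort) <- c("rl_cohort", "data.frame")
  table <- simulate_cohort(cohort, design, seed = seed, rt = FALSE)

  if (fit_method == "mle") {
    est <- t(vapply(truth$subject_id, function(id) {
      fit <- fit_mle(table[table$subject_id == id, ], model_id,
                     response_convention, seed = seed + id)
      fit$unconstrained
    }, numeric(nrow(spec))))
    fitted <- data.frame(subject_id = truth$subject_id)
    for (k in seq_len(nrow(spec))) fitted[[u_cols[k]]] <- est[, k]
  } else {
    cfg <- config
    cfg$seed <- as.integer(seed)
    draws <- sample_posterior(table, model_id, config = cfg,
                              response_convention = response_convention)
    fitted <- subject_posterior_means(draws)
  }

  per_par <- data.frame(parameter = spec$name, rho = NA_real_)
  for (k in seq_len(nrow(spec))) {
    tv <- truth[[u_cols[k]]]
    fv <- fitted[[u_cols[k]]][match(truth$subject_id, fitted$subject_id)]
    if (length(unique(tv)) < 2L) next  # constant truth: correlation undefined
    per_par$rho[k] <- suppressWarnings(cor(tv, fv, method = "spearman"))
  }
  structure(list(per_parameter = per_par,
                 mean_rho = mean(per_par$rho, na.rm = TRUE),
                 fitted = fitted, fit_method = fit_method),
            class = "rl_recovery")
}

#' @export
print.rl_recovery <- function(x, ...) {
  cat("Parameter recovery (", x$fit_method, "): mean rank correlation ",
      round(x$mean_rho, 3), "\n", sep = "")
  print(x$per_parameter, row.names = FALSE)
  invisible(x)
}
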