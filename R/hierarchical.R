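#' Prior configuration for the hierarchical group model
#'
#' Two variants are supported. Under `wide` priors the group-level mean of
#' each parameter has a `Normal(0, 100)` prior and the group spread a
#' `Uniform(0, 100)` prior; under `narrow` priors these become
#' `Normal(0, 1)` and a half-`Normal(0, 0.2)` (the positive half-line is
#' forced for a spread). The per-group offsets keep a `Normal(0, 3)` prior
#' in both variants. All normal distributions are parameterized by their
#' standard deviation.
#'
#' @param variant `"wide"` (SWo-style) or `"narrow"` (SSo-style).
#' @return a list of class `rl_priors` with elements `variant`, `mu_sd`,
#'   `sigma_prior` (`"uniform"` with `sigma_upper`, or `"half_normal"` with
#'   `sigma_sd`) and `delta_sd`.
#' @export
prior_config <- function(variant = c("wide", "narrow")) {
  variant <- match.arg(variant)
  out <- if (variant == "wide") {
    list(variant = variant, mu_sd = 100, sigma_prior = "uniform",
         sigma_upper = 100, sigma_sd = NA_real_, delta_sd = 3)
  } else {
    list(variant = variant, mu_sd = 1, sigma_prior = "half_normal",
         sigma_upper = Inf, sigma_sd = 0.2, delta_sd = 3)
  }
  structure(out, class = "rl_priors")
}

# prior variant implied by a model id (SWo wide, SSo narrow; extended
# models default to narrow, mirroring common toolkit defaults)
default_priors <- function(model_id) {
  prior_config(if (identical(model_id, "SWo")) "wide" else "narrow")
}

log_prior_sigma <- function(sigma, priors) {
  if (any(sigma <= 0)) return(-Inf)
  if (priors$sigma_prior == "uniform") {
    if (any(sigma > priors$sigma_upper)) return(-Inf)
    sum(-log(priors$sigma_upper) + 0 * sigma)
  } else {
    sum(log(2) + dnorm(sigma, 0, priors$sigma_sd, log = TRUE))
  }
}

log_prior_hyper <- function(mu0, delta, sigma, priors) {
  # delta is n_par x 5 with the baseline column fixed at 0 (not a free term)
  sum(dnorm(mu0, 0, priors$mu_sd, log = TRUE)) +
    sum(dnorm(delta[, -1, drop = FALSE], 0, priors$delta_sd, log = TRUE)) +
    log_prior_sigma(sigma, priors)
}

#' Sampler configuration
#'
#' The `paper` preset mirrors the published sampling scheme: eight chains
#' with 10,000 warm-up and 10,000 retained iterations each (80,000 retained
#' group-level draws). The `test` preset (4 chains, 500/500) is the default
#' for continuous testing. `target_accept` and `max_tree_depth` are carried
#' as metadata describing the tree-sampler configuration of the original
#' scheme; the package's blocked Metropolis-within-Gibbs sampler has no
#' analogous knobs.
#'
#' @param scale `"test"` or `"paper"`; individual fields override the preset.
#' @param n_chains,n_warmup,n_sampling MCMC bookkeeping.
#' @param target_accept,max_tree_depth metadata (see above).
#' @param seed integer seed; every chain derives its stream from it.
#' @param thin_subjects keep every k-th subject-level draw (group-level
#'   draws are never thinned).
#' @return a list of class `rl_sampler_config`.
#' @export
sampler_config <- function(scale = c("test", "paper"), n_chains = NULL,
                           n_warmup = NULL, n_sampling = NULL,
                           target_accept = 0.99, max_tree_depth = 15,
                           seed = 1L, thin_subjects = 1L) {
  scale <- match.arg(scale)
  preset <- if (scale == "paper") {
    list(n_chains = 8L, n_warmup = 10000L, n_sampling = 10000L)
  } else {
    list(n_chains = 4L, n_warmup = 500L, n_sampling = 500L)
  }
  out <- list(
    scale = scale,
    n_chains = as.integer(n_chains %||% preset$n_chains),
    n_warmup = as.integer(n_warmup %||% preset$n_warmup),
    n_sampling = as.integer(n_sampling %||% preset$n_sampling),
    target_accept = target_accept, max_tree_depth = max_tree_depth,
    seed = as.integer(seed), thin_subjects = as.integer(thin_subjects)
  )
  structure(out, class = "rl_sampler_config")
}

#' Number of retained group-level draws implied by a sampler configuration
#'
#' @param config an `rl_sampler_config`.
#' @return `n_chains * n_sampling` (80,000 for the `paper` preset).
#' @export
retained_draws <- function(config) {
  stopifnot(inherits(config, "rl_sampler_config"))
  config$n_chains * config$n_sampling
}

# subjects/groups of a trial table, in order of first appearance
dataset_subjects <- function(dataset) {
  ids <- unique(dataset$subject_id)
  if (is.null(dataset$group)) stop("dataset must carry a group column")
  grp <- dataset$group[match(ids, dataset$subject_id)]
  if (!all(grp %in% EFFICACY_GROUPS)) stop("group labels must be in {0,25,50,75,100}")
  list(ids = ids, group = as.integer(grp), gi = match(grp, EFFICACY_GROUPS))
}

#' Log joint density of the hierarchical model
#'
#' Sum of the hyperpriors, the subject-level normal densities on the
#' unconstrained scales, and the per-subject choice log-likelihoods at the
#' transformed parameters. This is the exact target of
#' [sample_posterior()].
#'
#' @param dataset trial table (may be empty: prior-only evaluation).
#' @param group_state list with `mu0` (named vector), `delta` (parameter x
#'   5-group matrix, baseline column zero) and `sigma` (named vector).
#' @param subject_unconstrained matrix, one row per subject in order of
#'   first appearance in `dataset`, one column per parameter.
#' @param priors an `rl_priors` object.
#' @param model_id model identifier.
#' @param response_convention see [param_spec()].
#' @return scalar log density (`-Inf` if any spread is nonpositive).
#' @export
log_joint <- function(dataset, group_state, subject_unconstrained, priors,
                      model_id, response_convention = NULL) {
  spec <- param_spec(model_id, response_convention)
  P <- nrow(spec)
  mu0 <- group_state$mu0[spec$name]
  sigma <- group_state$sigma[spec$name]
  delta <- group_state$delta[spec$name, , drop = FALSE]
  if (ncol(delta) != 5L) stop("delta must have one column per efficacy group")
  if (any(delta[, 1] != 0)) stop("the baseline group's offsets must be 0")
  lp <- log_prior_hyper(mu0, delta, sigma, priors)
  if (!is.finite(lp)) return(lp)
  if (is.null(dataset) || nrow(dataset) == 0L) return(lp)
  info <- dataset_subjects(dataset)
  X <- matrix(subject_unconstrained, ncol = P)
  if (nrow(X) != length(info$ids)) stop("subject_unconstrained has the wrong number of rows")
  M <- t(delta[, info$gi, drop = FALSE] + mu0)
  lp <- lp + sum(dnorm(X, M, rep(sigma, each = nrow(X)), log = TRUE))
  con <- constrain_pars(X, spec)
  lp + sum(cohort_loglik(dataset, con, model_id, response_convention))
}

#' Sample the hierarchical posterior
#'
#' Blocked MCMC targeting [log_joint()]: conjugate Gibbs updates for the
#' group-level means and offsets, stepping-out slice sampling for the group
#' spreads, and per-subject adaptive random-walk Metropolis updates of the
#' subject parameter vectors (proposal scales adapt during warm-up only, so
#' the retained chain is a valid Markov chain with the posterior as its
#' invariant distribution). Chains run sequentially with seeds derived from
#' `config$seed`; results are deterministic given the configuration.
#'
#' @param dataset trial table with `subject_id`, `group`, `trial`, `pair`,
#'   `choice`, `reward` columns.
#' @param model_id model identifier.
#' @param priors an `rl_priors` (default: wide for SWo, narrow otherwise).
#' @param config an `rl_sampler_config` (default: `test` preset).
#' @param response_convention see [param_spec()].
#' @return an object of class `rl_posterior` holding the retained
#'   group-level draws (`hyper`: iterations x chains x quantities, with
#'   names `mu_<par>`, `delta_<par>_<group>`, `sigma_<par>`), the retained
#'   subject-level draws (`subj`: iterations x subjects x parameters,
#'   chains stacked, unconstrained scale), per-quantity convergence
#'   diagnostics, and metadata. If any group-level split R-hat exceeds 1.1
#'   the `converged` flag is set to `FALSE` and a warning is issued.
#' @export
sample_posterior <- function(dataset, model_id = "SWo", priors = NULL,
                             config = sampler_config("test"),
                             response_convention = NULL) {
  priors <- priors %||% default_priors(model_id)
  stopifnot(inherits(priors, "rl_priors"), inherits(config, "rl_sampler_config"))
  spec <- param_spec(model_id, response_convention)
  P <- nrow(spec)
  family <- attr(spec, "family")
  if (is.null(dataset) || nrow(dataset) == 0L) {
    # prior-only sampling: no subjects, hyperparameters follow their priors
    info <- list(ids = integer(0), group = integer(0), gi = integer(0))
    ll_of <- function(X) numeric(0)
  } else {
    info <- dataset_subjects(dataset)
    ix <- cohort_index(dataset)
    stopifnot(identical(ix$subjects, info$ids))
    ll_of <- function(X) {
      cohort_logp_cpp(ix$start, ix$len, ix$pair, ix$chosen, ix$other, ix$reward,
                      constrain_pars(X, spec), family)
    }
  }
  n <- length(info$ids)
  groups_present <- sort(unique(info$gi))
  n_iter <- config$n_warmup + config$n_sampling
  keep_sub <- seq(1L, config$n_sampling, by = config$thin_subjects)

  hyper_names <- c(paste0("mu_", spec$name),
                   as.vector(t(outer(spec$name, EFFICACY_GROUPS[-1],
                                     function(p, g) paste0("delta_", p, "_", g)))),
                   paste0("sigma_", spec$name))
  K <- length(hyper_names)
  hyper <- array(NA_real_, c(config$n_sampling, config$n_chains, K),
                 dimnames = list(NULL, NULL, hyper_names))
  subj <- array(NA_real_,
                c(length(keep_sub) * config$n_chains, n, P),
                dimnames = list(NULL, info$ids, spec$name))
  accept <- numeric(config$n_chains)

  # fixed design matrix of the group-mean block: intercept + offsets 25..100
  Z <- matrix(0, n, 5)
  Z[, 1] <- 1
  for (g in 2:5) Z[, g] <- as.numeric(info$gi == g)
  ZtZ <- crossprod(Z)
  prior_prec_md <- diag(c(1 / priors$mu_sd^2, rep(1 / priors$delta_sd^2, 4)))

  for (chain in seq_len(config$n_chains)) {
    with_seed(config$seed + (chain - 1L), {
      X <- matrix(rnorm(n * P, 0, 0.5), n, P)
      mu0 <- rep(0, P)
      delta <- matrix(0, P, 5)
      sigma <- rep(0.5, P)
      prop_sd <- matrix(0.5, n, P)   # per-(subject, parameter) step sizes
      step_loc <- matrix(0.3, P, 5)  # translation-move step sizes
      step_sig <- rep(0.3, P)        # scale-move step sizes (log scale)
      ll_cur <- ll_of(X)
      acc_n <- 0; acc_d <- 0
      sub_row <- 0L

      for (it in seq_len(n_iter)) {
       for (sweep in 1:2) {  # two full kernel sweeps per recorded iteration
        ## subject parameters: component-wise adaptive random-walk MH
        ## (independent across subjects, so acceptance is vectorized)
        M <- t(delta[, info$gi, drop = FALSE] + mu0)
        for (p in seq_len(P)) {
          Xs <- X
          Xs[, p] <- X[, p] + rnorm(n) * prop_sd[, p]
          ll_star <- ll_of(Xs)
          lp_cur <- dnorm(X[, p], M[, p], sigma[p], log = TRUE)
          lp_star <- dnorm(Xs[, p], M[, p], sigma[p], log = TRUE)
          take <- log(runif(n)) < (ll_star + lp_star) - (ll_cur + lp_cur)
          X[take, p] <- Xs[take, p]
          ll_cur[take] <- ll_star[take]
          if (it <= config$n_warmup) {
            gain <- pmin(0.5, 2 / sqrt(it))
            prop_sd[, p] <- prop_sd[, p] * exp(gain * (as.numeric(take) - 0.44))
            prop_sd[, p] <- pmin(pmax(prop_sd[, p], 1e-3), 10)
          } else {
            acc_n <- acc_n + sum(take); acc_d <- acc_d + n
          }
        }

        ## joint conjugate Gibbs draw of (mu0, delta) per parameter:
        ## removes the mean/offset anticorrelation that stalls scalar Gibbs
        for (p in seq_len(P)) {
          A <- ZtZ / sigma[p]^2 + prior_prec_md
          b <- crossprod(Z, X[, p]) / sigma[p]^2
          U <- chol(A)
          m <- backsolve(U, backsolve(U, b, transpose = TRUE))
          md <- m + backsolve(U, rnorm(5))
          mu0[p] <- md[1]
          delta[p, 2:5] <- md[2:5]
        }

        ## group spreads: stepping-out slice sampler
        for (p in seq_len(P)) {
          m_p <- mu0[p] + delta[p, info$gi]
          target <- function(s) {
            if (s <= 0) return(-Inf)
            if (priors$sigma_prior == "uniform" && s > priors$sigma_upper) return(-Inf)
            pr <- if (priors$sigma_prior == "uniform") -log(priors$sigma_upper)
                  else log(2) + dnorm(s, 0, priors$sigma_sd, log = TRUE)
            pr + sum(dnorm(X[, p], m_p, s, log = TRUE))
          }
          sigma[p] <- slice_sample_1d(sigma[p], target, w = 0.3)
        }

        ## interweaved translation moves: shift a group-level mean together
        ## with its subjects' parameters (residuals fixed), so group-level
        ## quantities are not tied to the subjects' slow local walks
        for (p in seq_len(P)) {
          for (g in 1:5) {
            s <- rnorm(1) * step_loc[p, g]
            Xs <- X
            if (g == 1L) {
              idx <- rep(TRUE, n)
              d_hyper <- dnorm(mu0[p] + s, 0, priors$mu_sd, log = TRUE) -
                dnorm(mu0[p], 0, priors$mu_sd, log = TRUE)
            } else {
              idx <- info$gi == g
              d_hyper <- dnorm(delta[p, g] + s, 0, priors$delta_sd, log = TRUE) -
                dnorm(delta[p, g], 0, priors$delta_sd, log = TRUE)
            }
            Xs[idx, p] <- X[idx, p] + s
            ll_star <- ll_of(Xs)
            ok <- log(runif(1)) < d_hyper + sum(ll_star[idx] - ll_cur[idx])
            if (ok) {
              X <- Xs
              ll_cur[idx] <- ll_star[idx]
              if (g == 1L) mu0[p] <- mu0[p] + s else delta[p, g] <- delta[p, g] + s
            }
            if (it <= config$n_warmup) {
              gain <- pmin(0.5, 2 / sqrt(it))
              step_loc[p, g] <- min(max(step_loc[p, g] * exp(gain * (ok - 0.44)), 1e-3), 10)
            }
          }
        }

        ## interweaved scale move: rescale a parameter's residuals with its
        ## group spread (non-centered step against the funnel geometry)
        for (p in seq_len(P)) {
          m_p <- mu0[p] + delta[p, info$gi]
          f <- exp(rnorm(1) * step_sig[p])
          s_new <- sigma[p] * f
          ok <- FALSE
          if (!(priors$sigma_prior == "uniform" && s_new > priors$sigma_upper)) {
            Xs <- X
            Xs[, p] <- m_p + (X[, p] - m_p) * f
            ll_star <- ll_of(Xs)
            pr_new <- if (priors$sigma_prior == "uniform") -log(priors$sigma_upper)
                      else log(2) + dnorm(s_new, 0, priors$sigma_sd, log = TRUE)
            pr_old <- if (priors$sigma_prior == "uniform") -log(priors$sigma_upper)
                      else log(2) + dnorm(sigma[p], 0, priors$sigma_sd, log = TRUE)
            # log-scale proposal on sigma: Jacobian contributes log(s_new/sigma)
            log_a <- pr_new - pr_old + log(s_new / sigma[p]) +
              sum(ll_star - ll_cur)
            ok <- log(runif(1)) < log_a
            if (ok) {
              X <- Xs
              ll_cur <- ll_star
              sigma[p] <- s_new
            }
          }
          if (it <= config$n_warmup) {
            gain <- pmin(0.5, 2 / sqrt(it))
            step_sig[p] <- min(max(step_sig[p] * exp(gain * (ok - 0.44)), 1e-3), 3)
          }
        }
       }  # end sweeps

        if (it > config$n_warmup) {
          s <- it - config$n_warmup
          hyper[s, chain, ] <- c(mu0, as.vector(t(delta[, -1, drop = FALSE])), sigma)
          if (s %in% keep_sub) {
            sub_row <- sub_row + 1L
            subj[(chain - 1L) * length(keep_sub) + sub_row, , ] <- X
          }
        }
      }
      accept[chain] <- acc_n / max(acc_d, 1)
    })
  }

  diag <- diagnostics_from_array(hyper)
  converged <- all(is.na(diag$rhat) | diag$rhat < 1.1)
  if (!converged) {
    warning("split R-hat exceeds 1.1 for: ",
            paste(diag$quantity[which(diag$rhat >= 1.1)], collapse = ", "))
  }
  structure(
    list(hyper = hyper, subj = subj, model_id = model_id,
         response_convention = response_convention, spec = spec,
         priors = priors, config = config,
         subjects = info$ids, group = info$group,
         accept_rate = accept, diagnostics = diag, converged = converged),
    class = "rl_posterior"
  )
}

#' @export
print.rl_posterior <- function(x, ...) {
  cat("Hierarchical posterior:", x$model_id, "/", x$priors$variant, "priors /",
      dim(x$hyper)[2], "chains x", dim(x$hyper)[1], "retained iterations\n")
  cat(length(x$subjects), "subjects; mean subject-block acceptance",
      round(mean(x$accept_rate), 3), "\n")
  cat("max split R-hat:", round(max(x$diagnostics$rhat, na.rm = TRUE), 4),
      if (x$converged) "(converged)" else "(NOT converged)", "\n")
  invisible(x)
}

# univariate stepping-out slice sampler (Neal 2003), support s > 0
slice_sample_1d <- function(x0, log_f, w = 0.3, max_steps = 50L) {
  f0 <- log_f(x0)
  z <- f0 + log(runif(1))  # log-scaled slice height
  u <- runif(1)
  L <- x0 - u * w
  R <- L + w
  k <- max_steps
  while (k > 0 && L > 0 && log_f(L) > z) { L <- L - w; k <- k - 1 }
  L <- max(L, 1e-12)
  k <- max_steps
  while (k > 0 && log_f(R) > z) { R <- R + w; k <- k - 1 }
  repeat {
    x1 <- runif(1, L, R)
    if (log_f(x1) > z) return(x1)
    if (x1 < x0) L <- x1 else R <- x1
    if (R - L < 1e-12) return(x0)
  }
}

# flatten hyper array into a draws x quantity matrix (chains stacked)
hyper_matrix <- function(draws) {
  stopifnot(inherits(draws, "rl_posterior"))
  d <- dim(draws$hyper)
  out <- matrix(aperm(draws$hyper, c(1, 2, 3)), d[1] * d[2], d[3])
  colnames(out) <- dimnames(draws$hyper)[[3]]
  out
}

#' Per-subject posterior means
#'
#' Arithmetic means of the retained subject-level draws on the
#' unconstrained scale, together with two constrained-scale summaries: the
#' mean of the transformed draws (`<par>`) and the transform of the
#' unconstrained mean (`<par>_of_mean`). The unconstrained means are the
#' canonical per-subject markers used by downstream group analyses.
#'
#' @param draws an `rl_posterior`.
#' @return data.frame with `subject_id`, `group`, `u_<par>`, `<par>` and
#'   `<par>_of_mean` columns.
#' @export
subject_posterior_means <- function(draws) {
  stopifnot(inherits(draws, "rl_posterior"))
  if (dim(draws$subj)[1] < 1) stop("no retained subject-level draws")
  spec <- draws$spec
  u_mean <- apply(draws$subj, c(2, 3), mean)
  con_mean <- u_mean
  for (k in seq_len(nrow(spec))) {
    m <- draws$subj[, , k]
    m <- matrix(m, ncol = length(draws$subjects))
    tr <- switch(spec$transform[k],
                 logit = plogis(m),
                 log = exp(m),
                 scaled_logit = spec$lo[k] + (spec$hi[k] - spec$lo[k]) * plogis(m))
    con_mean[, k] <- colMeans(tr)
  }
  con_of_mean <- constrain_pars(u_mean, spec)
  out <- data.frame(subject_id = draws$subjects, group = draws$group)
  for (k in seq_len(nrow(spec))) out[[paste0("u_", spec$name[k])]] <- u_mean[, k]
  for (k in seq_len(nrow(spec))) out[[spec$name[k]]] <- con_mean[, k]
  for (k in seq_len(nrow(spec))) out[[paste0(spec$name[k], "_of_mean")]] <- con_of_mean[, k]
  out
}

#' Maximum-likelihood fit of one subject
#'
#' Multi-start bounded quasi-Newton optimization of [sequence_loglik()] on
#' the unconstrained scale; the fast point-estimation path used for
#' recovery studies and tests.
#'
#' @param trials one subject's trial rows.
#' @param model_id model identifier.
#' @param response_convention see [param_spec()].
#' @param n_starts number of optimization starts (one at the origin, the
#'   rest drawn `Normal(0, 1.5)`).
#' @param seed optional integer controlling the random starts.
#' @return list with `params` (constrained), `unconstrained`, `loglik` and
#'   `n_starts`.
#' @export
fit_mle <- function(trials, model_id, response_convention = NULL,
                    n_starts = 5L, seed = NULL) {
  if (is.null(trials) || nrow(trials) < 1L) stop("at least one trial is required")
  spec <- param_spec(model_id, response_convention)
  P <- nrow(spec)
  trials$subject_id <- NULL
  ix <- cohort_index(trials)
  family <- attr(spec, "family")
  negll <- function(x) {
    -cohort_logp_cpp(ix$start, ix$len, ix$pair, ix$chosen, ix$other, ix$reward,
                     matrix(constrain_pars(x, spec), nrow = 1), family)
  }
  with_seed(seed, {
    starts <- rbind(rep(0, P),
                    if (n_starts > 1) matrix(rnorm((n_starts - 1) * P, 0, 1.5),
                                             n_starts - 1, P))
    best <- NULL
    for (i in seq_len(nrow(starts))) {
      fit <- tryCatch(
        optim(starts[i, ], negll, method = "L-BFGS-B", lower = -8, upper = 8),
        error = function(e) NULL
      )
      if (!is.null(fit) && (is.null(best) || fit$value < best$value)) best <- fit
    }
    if (is.null(best)) stop("optimization failed from every start")
    u <- setNames(best$par, spec$name)
    list(params = constrain_pars(u, spec), unconstrained = u,
         loglik = -best$value, n_starts = n_starts)
  })
}

# split R-hat and ESS from an iterations x chains x quantities array
diagnostics_from_array <- function(a) {
  stopifnot(length(dim(a)) == 3)
  qn <- dimnames(a)[[3]] %||% paste0("q", seq_len(dim(a)[3]))
  n_chain <- dim(a)[2]
  rhat <- vapply(seq_len(dim(a)[3]), function(k) split_rhat(a[, , k, drop = TRUE]),
                 numeric(1))
  ess <- vapply(seq_len(dim(a)[3]), function(k) {
    m <- matrix(a[, , k], ncol = n_chain)
    sum(vapply(seq_len(n_chain), function(ch) {
      unname(coda::effectiveSize(coda::mcmc(m[, ch])))
    }, numeric(1)))
  }, numeric(1))
  data.frame(quantity = qn, rhat = rhat, ess = ess)
}

# split R-hat (chains halved, pooled-vs-within variance ratio)
split_rhat <- function(x) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (ncol(x) < 2 && n < 4) return(NA_real_)
  half <- floor(n / 2)
  halves <- do.call(cbind, lapply(seq_len(ncol(x)), function(j) {
    cbind(x[seq_len(half), j], x[(n - half + 1):n, j])
  }))
  m <- ncol(halves); n2 <- nrow(halves)
  means <- colMeans(halves)
  vars <- apply(halves, 2, var)
  W <- mean(vars)
  B <- n2 * var(means)
  if (W == 0) return(ifelse(B == 0, 1, Inf))
  sqrt(((n2 - 1) / n2 * W + B / n2) / W)
}

#' Convergence diagnostics of posterior draws
#'
#' Split R-hat (each chain halved before computing the pooled/within
#' variance ratio) and effective sample size per group-level quantity.
#'
#' @param draws an `rl_posterior`, or a 3-D array (iterations x chains x
#'   quantities).
#' @return data.frame with `quantity`, `rhat`, `ess`. With a single chain,
#'   `rhat` is `NA` and a warning is issued.
#' @export
convergence_diagnostics <- function(draws) {
  a <- if (inherits(draws, "rl_posterior")) draws$hyper else draws
  stopifnot(length(dim(a)) == 3)
  if (dim(a)[2] < 2) {
    warning("split R-hat requires at least two chains; reporting ESS only")
    out <- diagnostics_from_array(a)
    out$rhat <- NA_real_
    return(out)
  }
  diagnostics_from_array(a)
}
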