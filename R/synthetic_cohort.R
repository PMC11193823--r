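#' Scenario presets for synthetic cohorts
#'
#' A scenario fixes, for every model parameter, a baseline group-level mean
#' on the unconstrained scale, per-group offsets for the five purported
#' treatment-efficacy groups (0/25/50/75/100 percent), and a subject-level
#' spread. Presets operationalize the competing hypotheses about the effect
#' of expected treatment efficacy on the gain learning rate:
#' \describe{
#'   \item{null}{all group offsets zero.}
#'   \item{monotonic}{offsets on the effect parameter strictly increasing
#'     with purported efficacy.}
#'   \item{inverted_u}{offsets peaked at the 50 percent (maximum
#'     uncertainty) group and declining toward 0 and 100.}
#'   \item{custom}{offsets supplied by the caller via `deltas`.}
#' }
#' Default magnitudes put the peak offset at 0.8 on the logit scale with a
#' subject spread of 0.4, comparable to the large pairwise contrasts the
#' hierarchy is meant to detect; both are configurable.
#'
#' @param preset one of `"null"`, `"monotonic"`, `"inverted_u"`, `"custom"`.
#' @param model_id model identifier (the effect parameter is `a_gain`, or
#'   `alpha` for the RLf-CK model).
#' @param n_subjects cohort size.
#' @param effect_size peak offset magnitude on the unconstrained scale.
#' @param sigma subject-level spread(s); a single value or a named vector
#'   per parameter.
#' @param mu0 optional named vector of baseline means on the unconstrained
#'   scale; defaults to the unconstrained [default_params()].
#' @param deltas for `preset = "custom"`: a named list mapping parameter
#'   names to length-5 offset vectors (groups 0, 25, 50, 75, 100); the
#'   baseline offset must be 0.
#' @param response_convention see [param_spec()].
#' @return an object of class `rl_scenario`.
#' @export
make_scenario <- function(preset = c("null", "monotonic", "inverted_u", "custom"),
                          model_id = "SWo", n_subjects = 141L,
                          effect_size = 0.8, sigma = 0.4, mu0 = NULL,
                          deltas = NULL, response_convention = NULL) {
  preset <- match.arg(preset)
  spec <- param_spec(model_id, response_convention)
  if (n_subjects < 1L) stop("n_subjects must be positive")
  base <- unconstrain_pars(default_params(model_id, response_convention), spec)
  if (!is.null(mu0)) base[names(mu0)] <- mu0
  if (length(sigma) == 1L) sigma <- setNames(rep(sigma, nrow(spec)), spec$name)
  if (any(sigma[spec$name] <= 0)) stop("sigma must be positive")
  effect_par <- if (model_id == "RLfCK") "alpha" else "a_gain"
  delta <- matrix(0, nrow = nrow(spec), ncol = 5,
                  dimnames = list(spec$name, as.character(EFFICACY_GROUPS)))
  if (preset == "monotonic") {
    delta[effect_par, ] <- effect_size * c(0, 0.25, 0.5, 0.75, 1)
  } else if (preset == "inverted_u") {
    delta[effect_par, ] <- effect_size * c(0, 0.5, 1, 0.5, 0)
  } else if (preset == "custom") {
    if (is.null(deltas)) stop("preset 'custom' requires deltas")
    for (nm in names(deltas)) {
      if (!nm %in% spec$name) stop("unknown parameter in deltas: ", nm)
      d <- deltas[[nm]]
      if (length(d) != 5L) stop("deltas[['", nm, "']] must have length 5")
      if (d[1] != 0) stop("the baseline group's offset must be 0")
      delta[nm, ] <- d
    }
  }
  structure(
    list(model_id = model_id, response_convention = response_convention,
         n_subjects = as.integer(n_subjects), preset = preset,
         mu0 = base, sigma = sigma[spec$name], delta = delta, spec = spec),
    class = "rl_scenario"
  )
}

EFFICACY_GROUPS <- c(0L, 25L, 50L, 75L, 100L)

#' @export
print.rl_scenario <- function(x, ...) {
  cat("Synthetic cohort scenario:", x$preset, "/", x$model_id, "/",
      x$n_subjects, "subjects\n")
  cat("baseline means (unconstrained):\n")
  print(round(x$mu0, 3))
  cat("group offsets:\n")
  print(round(x$delta, 3))
  invisible(x)
}

#' Draw a cohort of subjects from a scenario
#'
#' Group labels are assigned i.i.d. uniformly over the five efficacy groups
#' (group sizes may be unbalanced, as under online randomization); each
#' subject's unconstrained parameters are drawn
#' `Normal(mu0 + delta[group], sigma)` and mapped through the model's
#' transforms.
#'
#' @param scenario an `rl_scenario` from [make_scenario()].
#' @param seed optional integer for reproducibility.
#' @return data.frame of class `rl_cohort` with `subject_id`, `group`, one
#'   `u_<name>` column per unconstrained parameter and one `<name>` column
#'   per constrained parameter; the scenario is attached as an attribute.
#' @export
draw_cohort <- function(scenario, seed = NULL) {
  stopifnot(inherits(scenario, "rl_scenario"))
  spec <- scenario$spec
  with_seed(seed, {
    n <- scenario$n_subjects
    group <- sample(EFFICACY_GROUPS, n, replace = TRUE)
    gi <- match(group, EFFICACY_GROUPS)
    u <- sapply(seq_len(nrow(spec)), function(k) {
      rnorm(n, scenario$mu0[k] + scenario$delta[k, gi], scenario$sigma[k])
    })
    u <- matrix(u, nrow = n, dimnames = list(NULL, spec$name))
    con <- constrain_pars(u, spec)
    out <- data.frame(subject_id = seq_len(n), group = group)
    for (k in spec$name) out[[paste0("u_", k)]] <- u[, k]
    for (k in spec$name) out[[k]] <- con[, k]
    attr(out, "scenario") <- scenario
    class(out) <- c("rl_cohort", "data.frame")
    out
  })
}

#' Simulate a full trial table for a cohort
#'
#' Builds a fresh randomized schedule per subject and simulates the
#' subject's choices and feedback with [simulate_choices()] at the
#' subject's true parameters. Optional reaction times are drawn from a
#' log-normal (median about 600 ms) capped at the response window; they are
#' metadata only and carry no model content.
#'
#' @param cohort an `rl_cohort` from [draw_cohort()].
#' @param design an `rl_task_design` (default [default_design()]).
#' @param seed optional integer; the whole table is deterministic given it.
#' @param rt if `TRUE`, add a simulated `rt_ms` column.
#' @return a trial table: data.frame with columns `subject_id`, `group`,
#'   `trial`, `pair`, `choice`, `optimal`, `reward`, `rt_ms`.
#' @export
simulate_cohort <- function(cohort, design = default_design(), seed = NULL, rt = TRUE) {
  stopifnot(inherits(cohort, "rl_cohort"))
  if (nrow(cohort) < 1L) stop("empty cohort")
  scenario <- attr(cohort, "scenario")
  spec <- scenario$spec
  with_seed(seed, {
    tabs <- lapply(seq_len(nrow(cohort)), function(i) {
      sched <- build_schedule(design)
      params <- unlist(cohort[i, spec$name])
      sim <- simulate_choices(params, sched, design, scenario$model_id,
                              scenario$response_convention)
      sim$p_chosen <- NULL
      cbind(subject_id = cohort$subject_id[i], group = cohort$group[i], sim)
    })
    out <- do.call(rbind, tabs)
    out$rt_ms <- if (rt) {
      pmin(round(rlnorm(nrow(out), log(600), 0.3)), design$response_window_ms)
    } else {
      NA_real_
    }
    rownames(out) <- NULL
    out
  })
}
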