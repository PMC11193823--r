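#' Per-draw group-level means of a parameter
#'
#' For each retained draw, the group-level mean of parameter `theta` in
#' efficacy group `j` is `mu_theta0 + delta_theta_j`; the baseline column
#' (group 0) is `mu_theta0` itself.
#'
#' @param draws an `rl_posterior`.
#' @param theta parameter name (e.g. `"a_gain"`).
#' @return numeric matrix, retained draws x 5 groups (columns `"0"`,
#'   `"25"`, `"50"`, `"75"`, `"100"`).
#' @export
group_level_mean_draws <- function(draws, theta) {
  h <- hyper_matrix(draws)
  mu_col <- paste0("mu_", theta)
  if (!mu_col %in% colnames(h)) stop("unknown parameter: ", theta)
  out <- cbind(
    h[, mu_col],
    h[, mu_col] + h[, paste0("delta_", theta, "_", EFFICACY_GROUPS[-1]), drop = FALSE]
  )
  colnames(out) <- as.character(EFFICACY_GROUPS)
  out
}

#' Strict inequality patterns over group-level means
#'
#' Presets encode the two hypotheses about the shape of the
#' treatment-efficacy effect, over all five groups or over the reduced set
#' obtained by omitting the 25 and 75 percent conditions:
#' `monotonic5` (0 < 25 < 50 < 75 < 100), `invU5` (0 < 25 < 50 > 75 > 100),
#' `monotonic3` (0 < 50 < 100) and `invU3` (0 < 50 > 100). All
#' inequalities are strict; ties fail the pattern.
#'
#' @param preset one of `"monotonic5"`, `"invU5"`, `"monotonic3"`,
#'   `"invU3"`, or `"custom"`.
#' @param groups for `"custom"`: ordered group labels (at least 3).
#' @param signs for `"custom"`: comparison directions between consecutive
#'   groups, each `"<"` or `">"` (length `length(groups) - 1`).
#' @return a list of class `rl_pattern` with `groups` and `signs`.
#' @export
pattern_spec <- function(preset = c("monotonic5", "invU5", "monotonic3", "invU3",
                                    "custom"),
                         groups = NULL, signs = NULL) {
  preset <- match.arg(preset)
  spec <- switch(preset,
    monotonic5 = list(groups = EFFICACY_GROUPS, signs = rep("<", 4)),
    invU5 = list(groups = EFFICACY_GROUPS, signs = c("<", "<", ">", ">")),
    monotonic3 = list(groups = c(0L, 50L, 100L), signs = c("<", "<")),
    invU3 = list(groups = c(0L, 50L, 100L), signs = c("<", ">")),
    custom = {
      if (is.null(groups) || is.null(signs)) stop("custom patterns need groups and signs")
      list(groups = as.integer(groups), signs = signs)
    }
  )
  if (length(spec$groups) < 3L) stop("a pattern must cover at least 3 groups")
  if (length(spec$signs) != length(spec$groups) - 1L) {
    stop("signs must have one entry per consecutive group pair")
  }
  if (!all(spec$signs %in% c("<", ">"))) stop("signs must be '<' or '>'")
  structure(c(spec, list(preset = preset)), class = "rl_pattern")
}

#' Fraction of posterior draws matching an inequality pattern
#'
#' Counts the retained draws in which the group-level means satisfy every
#' strict inequality of the pattern and divides by the number of draws.
#'
#' @param mu_draws draws x groups matrix from [group_level_mean_draws()]
#'   (columns named by group label).
#' @param pattern an `rl_pattern` from [pattern_spec()].
#' @return fraction in `[0, 1]`.
#' @export
pattern_fraction <- function(mu_draws, pattern) {
  stopifnot(inherits(pattern, "rl_pattern"))
  labs <- as.character(pattern$groups)
  if (!all(labs %in% colnames(mu_draws))) {
    stop("mu_draws lacks column(s): ",
         paste(setdiff(labs, colnames(mu_draws)), collapse = ", "))
  }
  ok <- rep(TRUE, nrow(mu_draws))
  for (i in seq_along(pattern$signs)) {
    a <- mu_draws[, labs[i]]
    b <- mu_draws[, labs[i + 1]]
    ok <- ok & if (pattern$signs[i] == "<") a < b else a > b
  }
  mean(ok)
}

#' All four preset pattern fractions of a parameter
#'
#' @param draws an `rl_posterior`.
#' @param theta parameter name.
#' @return named numeric vector (`monotonic5`, `invU5`, `monotonic3`,
#'   `invU3`), each a fraction of retained draws.
#' @export
pattern_fractions <- function(draws, theta) {
  mu <- group_level_mean_draws(draws, theta)
  presets <- c("monotonic5", "invU5", "monotonic3", "invU3")
  vapply(presets, function(p) pattern_fraction(mu, pattern_spec(p)), numeric(1))
}

#' Posterior contrast summary (pd, ps, ROPE)
#'
#' Summarizes the posterior of a difference `d = draws_j - draws_k`:
#' posterior mean, equal-tailed 95 percent credible interval, probability
#' of direction `pd = max(P(d > 0), P(d < 0))`, practical significance
#' `ps` (posterior mass beyond the ROPE boundary in the direction of the
#' median), and the percentage of draws inside the ROPE.
#'
#' @param draws_j,draws_k equal-length draw vectors (or `draws_k = 0` to
#'   summarize `draws_j` itself).
#' @param rope region of practical equivalence, default `c(-0.1, 0.1)`.
#' @return one-row data.frame with `mean`, `ci_lower`, `ci_upper`, `pd`,
#'   `ps`, `pct_rope`. For an all-zero difference, `pd` is `NA` with a
#'   warning (neither direction has any mass).
#' @export
contrast_summary <- function(draws_j, draws_k = 0, rope = c(-0.1, 0.1)) {
  if (length(draws_j) == 0L) stop("empty draws")
  if (length(draws_k) > 1L && length(draws_k) != length(draws_j)) {
    stop("draw vectors must have equal length")
  }
  d <- draws_j - draws_k
  ci <- unname(quantile(d, c(0.025, 0.975), type = 7))
  p_pos <- mean(d > 0)
  p_neg <- mean(d < 0)
  pd <- max(p_pos, p_neg)
  if (p_pos == 0 && p_neg == 0) {
    warning("degenerate all-zero difference: pd undefined")
    pd <- NA_real_
  }
  med <- median(d)
  ps <- if (med > 0) mean(d > rope[2]) else if (med < 0) mean(d < rope[1]) else {
    max(mean(d > rope[2]), mean(d < rope[1]))
  }
  data.frame(mean = mean(d), ci_lower = ci[1], ci_upper = ci[2],
             pd = pd, ps = ps,
             pct_rope = 100 * mean(d >= rope[1] & d <= rope[2]))
}

#' Pairwise group contrasts of a parameter's group-level means
#'
#' All ten pairwise contrasts between the five efficacy groups, each
#' summarized with [contrast_summary()] on the group-level mean draws.
#'
#' @param draws an `rl_posterior`.
#' @param theta parameter name.
#' @param rope region of practical equivalence.
#' @return data.frame with one row per contrast (`contrast` column, e.g.
#'   `"0-25"`) and the [contrast_summary()] fields.
#' @export
contrast_table <- function(draws, theta, rope = c(-0.1, 0.1)) {
  mu <- group_level_mean_draws(draws, theta)
  combos <- utils::combn(as.character(EFFICACY_GROUPS), 2)
  out <- do.call(rbind, lapply(seq_len(ncol(combos)), function(i) {
    j <- combos[1, i]; k <- combos[2, i]
    cbind(contrast = paste0(j, "-", k),
          contrast_summary(mu[, j], mu[, k], rope))
  }))
  rownames(out) <- NULL
  out
}

#' Linear plus quadratic trend regression over efficacy groups
#'
#' Ordinary least squares of a per-subject statistic on the centered
#' numerical efficacy value (groups 0..100 mapped to -50..50) and its
#' square, comparing the linear-only with the full model.
#'
#' @param y per-subject values (e.g. unconstrained posterior means).
#' @param group_percent per-subject group labels in `{0,25,50,75,100}`.
#' @return list with `b_linear`, `b_quadratic` (full-model coefficients),
#'   `r2_linear`, `r2_full`, `delta_r2`, and the fitted models.
#' @export
quadratic_trend <- function(y, group_percent) {
  stopifnot(length(y) == length(group_percent))
  if (length(unique(group_percent)) < 3L) {
    stop("at least 3 distinct group values are required for a quadratic term")
  }
  x <- group_percent - 50
  if (var(y) == 0) {
    return(list(b_linear = 0, b_quadratic = 0, r2_linear = 0, r2_full = 0,
                delta_r2 = 0, fit_linear = NULL, fit_full = NULL))
  }
  x2 <- x^2
  fit1 <- lm(y ~ x)
  fit2 <- lm(y ~ x + x2)
  r2 <- function(f) summary(f)$r.squared
  list(b_linear = unname(coef(fit2)["x"]),
       b_quadratic = unname(coef(fit2)["x2"]),
       r2_linear = r2(fit1), r2_full = r2(fit2),
       delta_r2 = r2(fit2) - r2(fit1),
       fit_linear = fit1, fit_full = fit2)
}

#' BIC-based Bayes factor
#'
#' Approximate Bayes factor from two BIC values. The default orientation is
#' the conventional `BF10 = exp((BIC_null - BIC_alt) / 2)`, so that values
#' above 1 favor the alternative; `orientation = "printed"` exposes the
#' reversed sign sometimes seen in reports.
#'
#' @param bic_null,bic_alt finite BIC values of the null (intercept-only)
#'   and alternative models.
#' @param orientation `"conventional"` or `"printed"`.
#' @return the Bayes factor.
#' @export
bic_bayes_factor <- function(bic_null, bic_alt,
                             orientation = c("conventional", "printed")) {
  orientation <- match.arg(orientation)
  if (!is.finite(bic_null) || !is.finite(bic_alt)) stop("BIC values must be finite")
  if (orientation == "conventional") {
    exp((bic_null - bic_alt) / 2)
  } else {
    exp((bic_alt - bic_null) / 2)
  }
}

#' Hypothesis report over all parameters of a fit
#'
#' Emits, as a JSON-ready list (optionally written to a file), the four
#' preset pattern fractions, the ten pairwise group contrasts, and the
#' linear/quadratic trend regression of the unconstrained subject posterior
#' means, for every model parameter.
#'
#' @param draws an `rl_posterior`.
#' @param rope region of practical equivalence for the contrasts.
#' @param path optional JSON output path.
#' @return the report list, invisibly if written.
#' @export
hypothesis_report <- function(draws, rope = c(-0.1, 0.1), path = NULL) {
  stopifnot(inherits(draws, "rl_posterior"))
  means <- subject_posterior_means(draws)
  report <- lapply(draws$spec$name, function(par) {
    trend <- quadratic_trend(means[[paste0("u_", par)]], means$group)
    list(
      pattern_fractions = as.list(pattern_fractions(draws, par)),
      contrasts = contrast_table(draws, par, rope),
      trend = trend[c("b_linear", "b_quadratic", "r2_linear", "r2_full", "delta_r2")]
    )
  })
  names(report) <- draws$spec$name
  report <- list(model_id = draws$model_id, priors = draws$priors$variant,
                 rope = rope, parameters = report)
  if (is.null(path)) return(report)
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", pretty = TRUE)
  invisible(report)
}
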