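# a minimal hand-built posterior object with known group-level draws
fake_posterior <- function(mu0, deltas, n = 50, sigma = 0.3) {
  spec <- param_spec("SWo")
  hyper_names <- c(paste0("mu_", spec$name),
                   as.vector(t(outer(spec$name, c(25, 50, 75, 100),
                                     function(p, g) paste0("delta_", p, "_", g)))),
                   paste0("sigma_", spec$name))
  hyper <- array(0, c(n, 2, length(hyper_names)),
                 dimnames = list(NULL, NULL, hyper_names))
  hyper[, , "mu_a_gain"] <- mu0
  for (g in c(25, 50, 75, 100)) {
    hyper[, , paste0("delta_a_gain_", g)] <- deltas[[as.character(g)]]
  }
  hyper[, , paste0("sigma_", spec$name)] <- sigma
  structure(list(hyper = hyper, spec = spec, model_id = "SWo",
                 priors = prior_config("wide")),
            class = "rl_posterior")
}

test_that("group-level mean draws are mu0 plus the group offset", {
  fp <- fake_posterior(mu0 = 0.5,
                       deltas = list(`25` = 0.1, `50` = 0.2, `75` = 0.3, `100` = 0.4))
  mu <- group_level_mean_draws(fp, "a_gain")
  expect_equal(dim(mu), c(100, 5))
  expect_true(all(mu[, "0"] == 0.5))
  expect_true(all(mu[, "75"] == 0.8))
  # shifting every offset by a constant shifts the four non-baseline columns
  fp2 <- fake_posterior(0.5, list(`25` = 1.1, `50` = 1.2, `75` = 1.3, `100` = 1.4))
  mu2 <- group_level_mean_draws(fp2, "a_gain")
  expect_equal(mu2[, -1], mu[, -1] + 1)
  expect_equal(mu2[, 1], mu[, 1])
  expect_error(group_level_mean_draws(fp, "gamma"), "unknown")
})

test_that("pattern fractions match brute-force counting on explicit draws", {
  groups <- as.character(c(0, 25, 50, 75, 100))
  rows <- rbind(
    c(1, 2, 3, 4, 5),    # monotonic
    c(1, 2, 5, 4, 3),    # inverted-U
    c(1, 2, 5, 4, 4.5),  # peaked at 50 but 75 < 100: invU5 fails, invU3 holds
    c(5, 4, 3, 2, 1),    # decreasing
    c(1, 1, 2, 3, 4),    # tie at the first step: strictness fails monotonic5
    c(0, 1, 4, 2, 1),    # inverted-U
    c(2, 3, 4, 5, 6),    # monotonic
    c(1, 3, 2, 4, 5),    # neither
    c(-3, -2, -1, 0, 1), # monotonic
    c(-1, 0, 1, 0, -1)   # inverted-U
  )
  colnames(rows) <- groups
  # brute-force row-by-row count
  mono5 <- mean(apply(rows, 1, function(r) all(diff(r) > 0)))
  invu5 <- mean(apply(rows, 1, function(r) {
    r[1] < r[2] && r[2] < r[3] && r[3] > r[4] && r[4] > r[5]
  }))
  expect_equal(pattern_fraction(rows, pattern_spec("monotonic5")), mono5)
  expect_equal(pattern_fraction(rows, pattern_spec("invU5")), invu5)
  expect_equal(pattern_fraction(rows, pattern_spec("monotonic3")), 5 / 10)
  expect_equal(pattern_fraction(rows, pattern_spec("invU3")), 4 / 10)
  # degenerate certainty cases
  asc <- matrix(rep(1:5, each = 3), 3, dimnames = list(NULL, groups))
  expect_equal(pattern_fraction(asc, pattern_spec("monotonic5")), 1)
  expect_equal(pattern_fraction(asc, pattern_spec("invU5")), 0)
  peak <- matrix(rep(c(1, 2, 9, 4, 3), each = 3), 3, dimnames = list(NULL, groups))
  expect_equal(pattern_fraction(peak, pattern_spec("invU5")), 1)
  expect_error(pattern_fraction(rows[, 1:3], pattern_spec("invU5")), "lacks")
})

test_that("the two five-group patterns are mutually exclusive per draw", {
  set.seed(81)
  draws <- matrix(rnorm(5000), 1000, 5,
                  dimnames = list(NULL, as.character(c(0, 25, 50, 75, 100))))
  f_mono <- pattern_fraction(draws, pattern_spec("monotonic5"))
  f_invu <- pattern_fraction(draws, pattern_spec("invU5"))
  expect_lte(f_mono + f_invu, 1)
  # row-shift invariance
  shifted <- draws + rnorm(1000)
  expect_equal(pattern_fraction(shifted, pattern_spec("invU5")), f_invu)
})

test_that("contrast summaries equal direct counting on explicit values", {
  d <- c(-0.30, -0.25, -0.18, -0.12, -0.11, -0.09, -0.05, 0.00, 0.02, 0.04,
         0.06, 0.08, 0.11, 0.13, 0.18, 0.22, 0.30, 0.41, 0.55, 0.70)
  cs <- contrast_summary(d, 0)
  expect_equal(cs$mean, mean(d))
  expect_equal(cs$pd, max(mean(d > 0), mean(d < 0)))
  expect_equal(cs$pct_rope, 100 * sum(d >= -0.1 & d <= 0.1) / 20)
  expect_equal(cs$ps, mean(d > 0.1))  # median is positive
  expect_equal(c(cs$ci_lower, cs$ci_upper),
               unname(quantile(d, c(0.025, 0.975))))
  # identical vectors: zero difference, all mass in the ROPE
  same <- rnorm(50)
  cs0 <- suppressWarnings(contrast_summary(same, same))
  expect_equal(cs0$mean, 0)
  expect_equal(cs0$pct_rope, 100)
  expect_true(is.na(cs0$pd))
  # unit point mass: maximal direction and practical significance
  cs1 <- contrast_summary(rep(1, 30), 0)
  expect_equal(cs1$pd, 1)
  expect_equal(cs1$ps, 1)
  expect_equal(cs1$pct_rope, 0)
  expect_error(contrast_summary(numeric(0)), "empty")
})

test_that("pct_rope and its complement always total 100", {
  set.seed(82)
  for (i in 1:5) {
    d <- rnorm(200, sd = runif(1, 0.01, 2))
    cs <- contrast_summary(d, 0)
    outside <- 100 * mean(d < -0.1 | d > 0.1)
    expect_equal(cs$pct_rope + outside, 100)
  }
})

test_that("the contrast table covers the ten group pairs", {
  fp <- fake_posterior(0.2, list(`25` = 0.1, `50` = 0.4, `75` = 0.15, `100` = 0.05))
  tab <- contrast_table(fp, "a_gain")
  expect_equal(nrow(tab), 10)
  expect_setequal(tab$contrast,
                  c("0-25", "0-50", "0-75", "0-100", "25-50", "25-75",
                    "25-100", "50-75", "50-100", "75-100"))
  expect_true(all(tab$pd >= 0.5 & tab$pd <= 1))
})

test_that("the quadratic trend regression matches the normal equations", {
  group <- rep(c(0, 25, 50, 75, 100), each = 3)
  x <- group - 50
  set.seed(83)
  y <- 0.3 + 0.004 * x - 0.0002 * x^2 + rnorm(15, 0, 0.05)
  tr <- quadratic_trend(y, group)
  # closed-form normal equations oracle
  X <- cbind(1, x, x^2)
  beta_hat <- solve(t(X) %*% X, t(X) %*% y)
  expect_equal(tr$b_linear, beta_hat[2], tolerance = 1e-10)
  expect_equal(tr$b_quadratic, beta_hat[3], tolerance = 1e-10)
  # exact polynomial: perfect fit, coefficients recovered
  y0 <- 1 + 0.02 * x - 0.001 * x^2
  tr0 <- suppressWarnings(quadratic_trend(y0, group))  # exact fit: lm warns
  expect_equal(tr0$r2_full, 1, tolerance = 1e-10)
  expect_equal(tr0$b_linear, 0.02, tolerance = 1e-10)
  expect_equal(tr0$b_quadratic, -0.001, tolerance = 1e-10)
  # degenerate inputs
  trc <- quadratic_trend(rep(2, 15), group)
  expect_equal(trc$b_linear, 0)
  expect_equal(trc$r2_full, 0)
  expect_error(quadratic_trend(y[1:6], rep(c(0, 50), each = 3)), "distinct")
})

test_that("BIC Bayes factors follow the conventional orientation", {
  expect_equal(bic_bayes_factor(10, 10), 1)
  expect_equal(bic_bayes_factor(12, 10), exp(1))
  expect_equal(bic_bayes_factor(10, 12, orientation = "printed"), exp(1))
  expect_gt(bic_bayes_factor(100, 90), bic_bayes_factor(100, 95))
  expect_error(bic_bayes_factor(Inf, 1), "finite")
})
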