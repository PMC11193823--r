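make_group_state <- function(spec, mu0, sigma, delta = NULL) {
  P <- length(mu0)
  d <- delta %||% matrix(0, P, 5)
  rownames(d) <- names(mu0)
  list(mu0 = mu0, sigma = sigma, delta = d)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("log_joint equals an independently coded density on a tiny case", {
  spec <- param_spec("SWo")
  mu0 <- c(a_gain = 0.2, a_loss = -1, beta = -1.5)
  sigma <- c(a_gain = 0.7, a_loss = 0.5, beta = 0.4)
  delta <- matrix(0, 3, 5, dimnames = list(names(mu0), NULL))
  delta[, 3] <- c(0.5, -0.2, 0.1)
  gs <- make_group_state(spec, mu0, sigma, delta)
  x <- matrix(c(0.3, -0.8, -1.2), 1, 3)
  trials <- data.frame(subject_id = 1, group = 50, trial = 1:2, pair = c(1, 1),
                       choice = c(1, 2), reward = c(1, 0))
  priors <- prior_config("wide")
  got <- log_joint(trials, gs, x, priors, "SWo")
  # hand-rolled: hyperpriors + subject normals + forward-recursion likelihood
  lp_hyper <- sum(dnorm(mu0, 0, 100, log = TRUE)) +
    sum(dnorm(delta[, 2:5], 0, 3, log = TRUE)) + 3 * (-log(100))
  m <- mu0 + delta[, 3]
  lp_subj <- sum(dnorm(x[1, ], m, sigma, log = TRUE))
  con <- constrain_pars(x[1, ], spec)
  lp_lik <- oracle_seq_logprob("SWo", con, c(1, 1), c(1, 2), c(2, 1), c(1, 0))
  expect_equal(got, lp_hyper + lp_subj + lp_lik, tolerance = 1e-8)
})

test_that("log_joint is prior-only on empty data and additive over subjects", {
  spec <- param_spec("SWo")
  gs <- make_group_state(spec, c(a_gain = 0, a_loss = 0, beta = 0),
                         c(a_gain = 1, a_loss = 1, beta = 1))
  priors <- prior_config("narrow")
  prior_val <- log_joint(NULL, gs, matrix(numeric(0), 0, 3), priors, "SWo")
  expect_true(is.finite(prior_val))

  sch <- toy_schedule(6, seed = 9)
  t1 <- cbind(subject_id = 1, group = 0, toy_trials(sch, rep(1, 6)))
  t2 <- cbind(subject_id = 2, group = 50, toy_trials(sch, rep(0, 6)))
  x1 <- matrix(rnorm(3), 1); x2 <- matrix(rnorm(3), 1)
  j1 <- log_joint(t1, gs, x1, priors, "SWo")
  j2 <- log_joint(t2, gs, x2, priors, "SWo")
  joint <- log_joint(rbind(t1, t2), gs, rbind(x1, x2), priors, "SWo")
  expect_equal(joint, j1 + j2 - prior_val, tolerance = 1e-10)
  # invariant to subject ordering
  flipped <- log_joint(rbind(t2, t1), gs, rbind(x2, x1), priors, "SWo")
  expect_equal(joint, flipped, tolerance = 1e-10)
  # nonpositive spread is rejected
  bad <- make_group_state(spec, gs$mu0, c(a_gain = -1, a_loss = 1, beta = 1))
  expect_equal(log_joint(t1, bad, x1, priors, "SWo"), -Inf)
})

test_that("the paper-scale configuration retains exactly 80,000 group-level draws", {
  cfg <- sampler_config("paper")
  expect_equal(cfg$n_chains, 8L)
  expect_equal(cfg$n_warmup, 10000L)
  expect_equal(retained_draws(cfg), 80000L)
  expect_equal(cfg$target_accept, 0.99)
  expect_equal(cfg$max_tree_depth, 15)
})

test_that("prior-only sampling reproduces the closed-form prior moments", {
  cfg <- sampler_config("test", n_chains = 2, n_warmup = 100, n_sampling = 800,
                        seed = 9)
  dr <- suppressWarnings(
    sample_posterior(NULL, "SSo", priors = prior_config("narrow"), config = cfg)
  )
  mu <- as.vector(dr$hyper[, , "mu_a_gain"])
  expect_equal(mean(mu), 0, tolerance = 0.1)
  expect_equal(sd(mu), 1, tolerance = 0.1)
  sg <- as.vector(dr$hyper[, , "sigma_beta"])
  expect_equal(mean(sg), 0.2 * sqrt(2 / pi), tolerance = 0.02)
  de <- as.vector(dr$hyper[, , "delta_a_loss_75"])
  expect_equal(sd(de), 3, tolerance = 0.3)
})

test_that("posterior sampling is deterministic given the seed", {
  dat <- tiny_cohort(n = 4, seed = 51)$table
  cfg <- sampler_config("test", n_chains = 2, n_warmup = 60, n_sampling = 40,
                        seed = 77)
  d1 <- suppressWarnings(sample_posterior(dat, "SWo", config = cfg))
  d2 <- suppressWarnings(sample_posterior(dat, "SWo", config = cfg))
  expect_identical(d1$hyper, d2$hyper)
  expect_identical(d1$subj, d2$subj)
  expect_equal(dim(d1$hyper)[1] * dim(d1$hyper)[2], retained_draws(cfg))
})

test_that("subject posterior means behave under transforms and degeneracy", {
  dat <- tiny_cohort(n = 4, seed = 51)$table
  cfg <- sampler_config("test", n_chains = 2, n_warmup = 60, n_sampling = 40,
                        seed = 78)
  dr <- suppressWarnings(sample_posterior(dat, "SWo", config = cfg))
  sm <- subject_posterior_means(dr)
  expect_equal(nrow(sm), 4)
  # transform of the unconstrained mean and mean of transforms both in bounds
  expect_true(all(sm$a_gain > 0 & sm$a_gain < 1))
  expect_true(all(sm$a_gain_of_mean > 0 & sm$a_gain_of_mean < 1))
  # constant draws: both constrained summaries coincide at the transform
  dg <- dr
  dg$subj[] <- 0
  smc <- subject_posterior_means(dg)
  expect_equal(smc$u_a_gain, rep(0, 4))
  expect_equal(smc$a_gain, rep(0.5, 4))
  expect_equal(smc$a_gain_of_mean, rep(0.5, 4))
  # monotone transform preserves subject ordering
  expect_equal(order(sm$u_beta), order(sm$beta_of_mean))
})

test_that("maximum likelihood recovers generating values from long sessions", {
  # decision noise keeps all three parameters identifiable here; at much
  # smaller inverse gain the choices are near-deterministic and the gain
  # rate's likelihood is flat between the truth and 1
  p <- c(a_gain = 0.8, a_loss = 0.1, beta = 0.3)
  big <- task_design(c(0.8, 0.7, 0.6), trials_per_pair = 1700)
  sim <- simulate_choices(p, build_schedule(big, seed = 61), big, "SWo", seed = 62)
  fit <- fit_mle(sim, "SWo", seed = 63)
  expect_equal(unname(fit$params), unname(p), tolerance = 0.1)
  # optimality holds even in the near-deterministic regime
  p0 <- c(a_gain = 0.8, a_loss = 0.1, beta = 0.1)
  sim0 <- simulate_choices(p0, build_schedule(big, seed = 64), big, "SWo", seed = 65)
  fit0 <- fit_mle(sim0, "SWo", seed = 66)
  expect_gte(fit0$loglik, sequence_loglik(sim0, p0, "SWo"))
  expect_gte(fit$loglik, sequence_loglik(sim, p, "SWo"))
})

test_that("degenerate maximum-likelihood inputs are tolerated", {
  one <- data.frame(trial = 1, pair = 1, choice = 1, reward = 1)
  fit <- fit_mle(one, "SWo", seed = 64)
  expect_true(all(is.finite(fit$unconstrained)))
  expect_true(all(fit$params > param_spec("SWo")$lo))
  expect_error(fit_mle(one[0, ], "SWo"), "trial")
})

test_that("split R-hat separates stationary from shifted chains", {
  set.seed(71)
  iid <- array(rnorm(4000), c(1000, 4, 1), dimnames = list(NULL, NULL, "x"))
  d <- convergence_diagnostics(iid)
  expect_equal(d$rhat, 1, tolerance = 0.01)
  expect_lte(d$ess, 4000 * 1.5)
  shifted <- iid
  shifted[, 2, 1] <- shifted[, 2, 1] + 5
  expect_gt(convergence_diagnostics(shifted)$rhat, 1.1)
  expect_warning(convergence_diagnostics(iid[, 1, , drop = FALSE]), "chain")
})
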