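test_that("the dual-rate update applies the correct rate to each error sign", {
  expect_equal(dual_rate_update(0.5, 1, a_gain = 0.3, a_loss = 0.1), 0.65)
  expect_equal(dual_rate_update(0.5, 0, a_gain = 0.3, a_loss = 0.1), 0.45)
  expect_equal(dual_rate_update(1, 1, 0.3, 0.1), 1)  # zero prediction error
  expect_error(dual_rate_update(1.5, 1, 0.3, 0.1))
})

test_that("forgetting decays all values toward zero", {
  expect_equal(forget_decay(0.8, 0.25), 0.6)
  q <- runif(6)
  expect_equal(forget_decay(q, 0), q)
  expect_equal(forget_decay(q, 1), rep(0, 6))
})

test_that("the choice kernel tracks recent choices toward 1 and 0", {
  expect_equal(ck_update(c(0, 0), 1, 0.5), c(0.5, 0))
  ck <- c(0.3, 0.6)
  expect_equal(ck_update(ck, 2, 0), ck)
  # repeated choice: chosen kernel strictly increases, other's decreases
  for (i in 1:10) {
    new <- ck_update(ck, 1, 0.4)
    expect_gt(new[1], ck[1]); expect_lt(new[2], ck[2])
    ck <- new
  }
  expect_true(all(ck >= 0 & ck <= 1))
})

test_that("response rules give the textbook probabilities", {
  expect_equal(choice_prob_inverse_gain(0.4, 0.4, 2), 0.5)
  expect_equal(choice_prob_inverse_gain(0.7, 0.7, 0), 0.5)  # tie beats clamping
  expect_equal(choice_prob_inverse_gain(1, 0, 1), 1 / (1 + exp(-1)))
  expect_equal(choice_prob_inverse_gain(1, 0, 1e9), 0.5, tolerance = 1e-6)
  expect_equal(choice_prob_noisy(1, 0, 2, xi = 1), 0.5)
  expect_equal(choice_prob_noisy(1, 0, 2, xi = 0), 1 / (1 + exp(-2)))
  expect_equal(choice_prob_noisy(0.3, 0.3, 5, xi = 0.4), 0.5)
  xi <- 0.3
  expect_true(all(choice_prob_noisy(c(1, 0), c(0, 1), 20, xi)
                  <= 1 - xi / 2 + 1e-12))
  expect_equal(choice_prob_ck(0.2, 0.2, 0.5, 0.5, 0, 0), 0.5)
  expect_equal(choice_prob_ck(1, 0, 0.4, 0.4, 2, 3), 1 / (1 + exp(-2)))
  expect_equal(choice_prob_ck(0.5, 0.5, 1, 0, 2, -5), 1 / (1 + exp(5)))
})

test_that("reduced response rules collapse onto the plain softmax", {
  q <- cbind(runif(20), runif(20))
  expect_equal(choice_prob_noisy(q[, 1], q[, 2], 3, xi = 0),
               plogis((q[, 1] - q[, 2]) * 3))
  expect_equal(choice_prob_ck(q[, 1], q[, 2], runif(20), runif(20), 3, tau = 0),
               plogis((q[, 1] - q[, 2]) * 3))
})

test_that("inverse-gain and inverse-temperature conventions agree at beta_temp = 1/beta_gain", {
  sch <- toy_schedule(30, seed = 5)
  take_a <- rbinom(30, 1, 0.5)
  trials <- toy_trials(sch, take_a)
  for (bg in c(0.1, 0.5, 2)) {
    ll_gain <- sequence_loglik(trials, c(a_gain = 0.4, a_loss = 0.2, beta = bg), "SWo")
    ll_temp <- sequence_loglik(trials, c(a_gain = 0.4, a_loss = 0.2, beta = 1 / bg),
                               "SWo", response_convention = "inverse_temperature")
    expect_equal(ll_gain, ll_temp, tolerance = 1e-12)
  }
})

test_that("one equal-value trial has log-likelihood log(0.5)", {
  trials <- data.frame(trial = 1, pair = 1, choice = 1, reward = 1)
  for (m in c("SWo", "ES", "RLfCK")) {
    p <- default_params(m)
    if (m == "ES") p["xi"] <- 0.2
    expect_equal(sequence_loglik(trials, p, m), log(0.5), tolerance = 1e-12)
  }
})

test_that("the likelihood is additive over independent pairs (no forgetting)", {
  sch1 <- list(pair = rep(1L, 6), a = rep(1L, 6), b = rep(2L, 6),
               reward = c(1, 0, 1, 1, 0, 1))
  sch2 <- list(pair = rep(2L, 5), a = rep(3L, 5), b = rep(4L, 5),
               reward = c(0, 1, 1, 0, 1))
  t1 <- toy_trials(sch1, c(1, 1, 0, 1, 0, 1))
  t2 <- toy_trials(sch2, c(0, 1, 1, 1, 0))
  both <- rbind(t1, t2)
  both$trial <- seq_len(nrow(both))
  p <- c(a_gain = 0.5, a_loss = 0.2, beta = 0.3)
  expect_equal(sequence_loglik(both, p, "SWo"),
               sequence_loglik(t1, p, "SWo") + sequence_loglik(t2, p, "SWo"),
               tolerance = 1e-12)
})

test_that("likelihood input contracts are enforced", {
  trials <- data.frame(trial = c(2, 1), pair = c(1, 1), choice = c(1, 2),
                       reward = c(1, 0))
  p <- default_params("SWo")
  expect_error(sequence_loglik(trials, p, "SWo"), "chronological")
  bad <- data.frame(trial = 1, pair = 1, choice = 5, reward = 1)
  expect_error(sequence_loglik(bad, p, "SWo"), "pair")
  expect_error(sequence_loglik(toy_trials(toy_schedule(3, 1), c(1, 1, 1)),
                               c(a_gain = 2, a_loss = 0.1, beta = 0.2), "SWo"),
               "bounds")
})

test_that("enumerated choice-sequence probabilities sum to 1 and match the oracle", {
  T <- 8L
  seqs <- all_choice_sequences(T)
  for (m in c("SWo", "ES", "RLfCK")) {
    for (rep in 1:3) {
      set.seed(1000 + rep)
      params <- random_params(m)
      sch <- toy_schedule(T, seed = 50 + rep)
      lls <- apply(seqs, 1, function(take_a) {
        sequence_loglik(toy_trials(sch, take_a), params, m)
      })
      oracle <- apply(seqs, 1, function(take_a) {
        tt <- toy_trials(sch, take_a)
        oracle_seq_logprob(m, params, tt$pair, tt$choice,
                           ifelse(tt$choice %% 2 == 1, tt$choice + 1L, tt$choice - 1L),
                           tt$reward)
      })
      expect_equal(sum(exp(lls)), 1, tolerance = 1e-10)
      expect_equal(lls, oracle, tolerance = 1e-10)
    }
  }
})

test_that("simulation is deterministic, tie-breaks fairly, and learns when it should", {
  d <- default_design()
  s <- build_schedule(d, seed = 3)
  p <- default_params("SWo")
  sim1 <- simulate_choices(p, s, d, "SWo", seed = 11)
  sim2 <- simulate_choices(p, s, d, "SWo", seed = 11)
  expect_identical(sim1, sim2)
  # zero learning rates: values never move, every trial is an exact tie
  frozen <- c(a_gain = 0, a_loss = 0, beta = 0.2)
  big <- task_design(0.8, trials_per_pair = 5000)
  simf <- simulate_choices(frozen, build_schedule(big, seed = 4), big, "SWo",
                           seed = 12)
  expect_true(all(simf$p_chosen == 0.5))
  expect_equal(mean(simf$optimal), 0.5, tolerance = 0.02)
  # learners beat chance: 200 seeded agents, one-sided binomial at 0.001
  set.seed(13)
  learn <- c(a_gain = 0.3, a_loss = 0.1, beta = 0.2)
  opt <- vapply(1:200, function(i) {
    mean(simulate_choices(learn, build_schedule(d), d, "SWo")$optimal)
  }, numeric(1))
  n_trials <- 200 * 120
  k <- round(mean(opt) * n_trials)
  expect_lt(binom.test(k, n_trials, 0.5, alternative = "greater")$p.value, 0.001)
})
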