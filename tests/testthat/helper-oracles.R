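# Independent oracles, coded directly from the model equations and kept
# separate from the package's computation paths.

# Probability of one fixed choice sequence under fixed per-trial feedback.
# pair/chosen/other are integer vectors (stimuli 1..6, pair 1..3); reward[t]
# is received whatever is chosen (feedback fixed by trial, so the choice
# sequence is the only source of randomness and probabilities sum to 1).
oracle_seq_logprob <- function(model_id, params, pair, chosen, other, reward) {
  q <- rep(0, 6)
  ck <- rep(0, 6)
  seen <- rep(FALSE, 3)
  lp <- 0
  for (t in seq_along(chosen)) {
    c <- chosen[t]; o <- other[t]; r <- reward[t]
    p_c <- if (model_id %in% c("SWo", "SSo")) {
      if (q[c] == q[o]) 0.5 else {
        b <- max(params[["beta"]], 1e-6)
        exp(q[c] / b) / (exp(q[c] / b) + exp(q[o] / b))
      }
    } else if (model_id == "ES") {
      ps <- exp(q[c] * params[["beta"]]) /
        (exp(q[c] * params[["beta"]]) + exp(q[o] * params[["beta"]]))
      (1 - params[["xi"]]) * ps + params[["xi"]] / 2
    } else {
      lc <- q[c] * params[["beta"]] + ck[c] * params[["tau"]]
      lo <- q[o] * params[["beta"]] + ck[o] * params[["tau"]]
      exp(lc) / (exp(lc) + exp(lo))
    }
    lp <- lp + log(p_c)
    if (model_id == "ES" && !seen[pair[t]]) {
      q[c] <- params[["q0"]]
      seen[pair[t]] <- TRUE
    }
    pe <- r - q[c]
    lr <- if (model_id == "RLfCK") params[["alpha"]] else {
      if (pe > 0) params[["a_gain"]] else params[["a_loss"]]
    }
    q[c] <- q[c] + lr * pe
    if (model_id %in% c("ES", "RLfCK")) q <- (1 - params[["phi"]]) * q
    if (model_id == "RLfCK") {
      ck[c] <- ck[c] + params[["a_ck"]] * (1 - ck[c])
      ck[o] <- ck[o] + params[["a_ck"]] * (0 - ck[o])
    }
  }
  lp
}

# random in-bounds parameters for a model (interior, away from edges)
random_params <- function(model_id) {
  sp <- param_spec(model_id)
  u <- rnorm(nrow(sp), 0, 1.2)
  constrain_pars(u, sp)
}

# a short fixed schedule: pair/chosen-slot layout for enumeration tests;
# returns pair, option A, option B, fixed reward sequence
toy_schedule <- function(T, seed) {
  set.seed(seed)
  pair <- sample(1:3, T, replace = TRUE)
  list(pair = pair, a = 2L * pair - 1L, b = 2L * pair,
       reward = sample(0:1, T, replace = TRUE))
}

# every binary choice sequence of length T as a matrix of 0/1 (choose a?)
all_choice_sequences <- function(T) {
  as.matrix(expand.grid(rep(list(0:1), T)))
}

# build a single-subject trial table for a fixed choice sequence
toy_trials <- function(sch, take_a) {
  choice <- ifelse(take_a == 1, sch$a, sch$b)
  data.frame(trial = seq_along(sch$pair), pair = sch$pair,
             choice = choice, reward = sch$reward)
}

# small synthetic cohort + table, shared by slower tests
tiny_cohort <- function(n = 8, preset = "null", seed = 42) {
  sc <- make_scenario(preset, n_subjects = n)
  co <- draw_cohort(sc, seed = seed)
  list(cohort = co, table = simulate_cohort(co, seed = seed + 1, rt = FALSE))
}
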