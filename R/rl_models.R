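#' Dual-rate Rescorla-Wagner update
#'
#' Updates an expected value with separate learning rates for positive
#' (gain) and negative (loss) reward prediction errors:
#' `q' = q + a_gain * (r - q)` if `r > q`, `q' = q + a_loss * (r - q)` if
#' `r < q`, and `q' = q` when the prediction error is zero.
#'
#' @param q current expected value in `[0, 1]`.
#' @param r reward, 0 or 1.
#' @param a_gain,a_loss learning rates in `[0, 1]`.
#' @return updated value, guaranteed to stay in `[0, 1]`.
#' @export
dual_rate_update <- function(q, r, a_gain, a_loss) {
  stopifnot(all(q >= 0 & q <= 1), all(r %in% c(0, 1)),
            all(a_gain >= 0 & a_gain <= 1), all(a_loss >= 0 & a_loss <= 1))
  pe <- r - q
  q + ifelse(pe > 0, a_gain, a_loss) * pe
}

#' Forgetting decay of stimulus values
#'
#' Decays every expected value toward the initial value 0:
#' `q <- q + phi * (0 - q) = (1 - phi) * q`, applied to all stimuli.
#'
#' @param q_vector numeric vector of values in `[0, 1]`.
#' @param phi forgetting rate in `[0, 1]`.
#' @return decayed values.
#' @export
forget_decay <- function(q_vector, phi) {
  stopifnot(length(phi) == 1, phi >= 0, phi <= 1)
  (1 - phi) * q_vector
}

#' Choice-kernel update of a presented pair
#'
#' The chosen option's kernel value moves toward 1, the unchosen one's
#' toward 0, both with rate `a_ck`.
#'
#' @param ck_pair numeric length-2 vector of kernel values in `[0, 1]`.
#' @param chosen_index 1 or 2, the chosen element of `ck_pair`.
#' @param a_ck choice learning rate in `[0, 1]`.
#' @return updated length-2 kernel vector.
#' @export
ck_update <- function(ck_pair, chosen_index, a_ck) {
  stopifnot(length(ck_pair) == 2, all(ck_pair >= 0 & ck_pair <= 1),
            chosen_index %in% c(1, 2), a_ck >= 0, a_ck <= 1)
  target <- c(0, 0)
  target[chosen_index] <- 1
  ck_pair + a_ck * (target - ck_pair)
}

#' Inverse-gain softmax choice probability
#'
#' Probability of choosing option A when Q-values are *divided* by the
#' inverse gain `beta` before the softmax. Larger `beta` means more random
#' choice. `beta` below `1e-6` is clamped; when `qA == qB` the probability
#' is exactly 0.5 for any `beta`, returned before any division.
#'
#' @param qA,qB expected values of the two options.
#' @param beta inverse gain, nonnegative.
#' @return probability of choosing A.
#' @export
choice_prob_inverse_gain <- function(qA, qB, beta) {
  stopifnot(all(beta >= 0))
  b <- pmax(beta, 1e-6)
  ifelse(qA == qB, 0.5, plogis((qA - qB) / b))
}

#' Softmax choice probability with irreducible noise
#'
#' The ES response rule: a mixture of an inverse-temperature softmax
#' (Q-values multiplied by `beta`) and uniform random choice with weight
#' `xi`, so the returned probability lies in `[xi/2, 1 - xi/2]`.
#'
#' @param qA,qB expected values of the two options.
#' @param beta inverse temperature in `[0, 20]`.
#' @param xi irreducible-noise weight in `[0, 1]`.
#' @return probability of choosing A.
#' @export
choice_prob_noisy <- function(qA, qB, beta, xi) {
  stopifnot(all(beta >= 0 & beta <= 20), all(xi >= 0 & xi <= 1))
  (1 - xi) * plogis((qA - qB) * beta) + xi / 2
}

#' Softmax choice probability with a choice kernel
#'
#' The RLf-CK response rule: logits are `Q * beta + CK * tau`, combining
#' value evidence with a perseveration trace.
#'
#' @param qA,qB expected values of the two options.
#' @param ckA,ckB choice-kernel values of the two options, in `[0, 1]`.
#' @param beta inverse temperature in `[0, 20]`.
#' @param tau choice inverse temperature in `[-5, 5]`.
#' @return probability of choosing A.
#' @export
choice_prob_ck <- function(qA, qB, ckA, ckB, beta, tau) {
  stopifnot(all(beta >= 0 & beta <= 20), all(tau >= -5 & tau <= 5),
            all(ckA >= 0 & ckA <= 1), all(ckB >= 0 & ckB <= 1))
  plogis((qA * beta + ckA * tau) - (qB * beta + ckB * tau))
}

# the partner of a chosen stimulus within its pair (stimuli 2p-1, 2p)
pair_partner <- function(pair, choice) {
  better <- 2L * pair - 1L
  worse <- 2L * pair
  if (any(choice != better & choice != worse)) {
    stop("choice does not belong to its pair for trial row(s) ",
         paste(which(choice != better & choice != worse), collapse = ", "))
  }
  ifelse(choice == better, worse, better)
}

# validate and index one-or-many-subject trial rows for the C++ kernels
cohort_index <- function(trials) {
  req <- c("pair", "choice", "reward")
  missing <- setdiff(req, names(trials))
  if (length(missing)) stop("missing column(s): ", paste(missing, collapse = ", "))
  if (!all(trials$reward %in% c(0L, 1L))) stop("reward must be 0 or 1")
  if (is.null(trials$subject_id)) trials$subject_id <- 1L
  ord_sub <- unique(trials$subject_id)
  idx <- match(trials$subject_id, ord_sub)
  if (is.unsorted(idx)) stop("each subject's trials must be contiguous")
  if (!is.null(trials$trial)) {
    for (s in ord_sub) {
      tr <- trials$trial[trials$subject_id == s]
      if (is.unsorted(tr, strictly = TRUE)) {
        stop("trials of subject ", s, " are not in chronological order")
      }
    }
  }
  len <- as.integer(table(idx)[as.character(seq_along(ord_sub))])
  start <- cumsum(c(0L, len[-length(len)]))
  list(
    subjects = ord_sub,
    start = as.integer(start), len = len,
    pair = as.integer(trials$pair),
    chosen = as.integer(trials$choice),
    other = as.integer(pair_partner(as.integer(trials$pair), as.integer(trials$choice))),
    reward = as.integer(trials$reward)
  )
}

#' Sequence log-likelihood of observed choices
#'
#' Runs the model's state evolution over one subject's chronologically
#' ordered trials and sums the log probability assigned to each observed
#' choice. Trials must carry `pair`, `choice` (stimulus id) and `reward`
#' columns; the partner stimulus is implied by the pair.
#'
#' @param trials one subject's trial rows (a `TrialTable` subset).
#' @param params named constrained parameter vector for the model.
#' @param model_id one of `"SWo"`, `"SSo"`, `"ES"`, `"RLfCK"`.
#' @param response_convention see [param_spec()].
#' @param pointwise if `TRUE`, return the per-trial log probabilities
#'   instead of their sum.
#' @return scalar log-likelihood (or per-trial vector).
#' @export
sequence_loglik <- function(trials, params, model_id, response_convention = NULL,
                            pointwise = FALSE) {
  spec <- param_spec(model_id, response_convention)
  params <- canonical_params(params, spec)
  ix <- cohort_index(trials)
  if (length(ix$subjects) != 1L) stop("sequence_loglik expects a single subject")
  ll <- cohort_trial_logp_cpp(ix$start, ix$len, ix$pair, ix$chosen, ix$other,
                              ix$reward, matrix(params, nrow = 1), attr(spec, "family"))
  if (pointwise) ll else sum(ll)
}

# per-subject summed log-likelihoods for a whole cohort; par_matrix has one
# row per subject in the order subjects appear in `trials`
cohort_loglik <- function(trials, par_matrix, model_id, response_convention = NULL) {
  spec <- param_spec(model_id, response_convention)
  ix <- cohort_index(trials)
  stopifnot(nrow(par_matrix) == length(ix$subjects), ncol(par_matrix) == nrow(spec))
  ll <- cohort_logp_cpp(ix$start, ix$len, ix$pair, ix$chosen, ix$other, ix$reward,
                        par_matrix, attr(spec, "family"))
  names(ll) <- ix$subjects
  ll
}

# in-R state machine mirroring the C++ per-trial operation order; used by
# the choice simulator (which needs RNG interleaved with the updates)
rl_step_machine <- function(params, family) {
  q <- rep(0, 6)
  ck <- rep(0, 6)
  seen <- rep(FALSE, 3)
  prob <- function(c, o) {
    switch(family,
      choice_prob_inverse_gain(q[c], q[o], params[["beta"]]),
      plogis((q[c] - q[o]) * params[["beta"]]),
      choice_prob_noisy(q[c], q[o], params[["beta"]], params[["xi"]]),
      choice_prob_ck(q[c], q[o], ck[c], ck[o], params[["beta"]], params[["tau"]])
    )
  }
  update <- function(c, o, r, pair) {
    if (family == 3L && !seen[pair]) {
      q[c] <<- params[["q0"]]
      seen[pair] <<- TRUE
    }
    pe <- r - q[c]
    lr <- if (family == 4L) params[["alpha"]] else if (pe > 0) params[["a_gain"]] else params[["a_loss"]]
    q[c] <<- q[c] + lr * pe
    if (family >= 3L) q <<- (1 - params[["phi"]]) * q
    if (family == 4L) {
      ck[c] <<- ck[c] + params[["a_ck"]] * (1 - ck[c])
      ck[o] <<- ck[o] + params[["a_ck"]] * (0 - ck[o])
    }
  }
  list(prob = prob, update = update)
}

#' Simulate choices and feedback of one agent on a schedule
#'
#' Per trial, the model's choice probability is computed from the current
#' state; the choice falls to option A when the probability exceeds a
#' uniform random threshold, and an exact probability tie (both options at
#' 0.5) is resolved by a fair coin. Feedback is then drawn from the pair's
#' reward contingency and the agent's state is updated exactly as in
#' [sequence_loglik()].
#'
#' @param params named constrained parameter vector.
#' @param schedule a schedule from [build_schedule()].
#' @param design the `rl_task_design` the schedule was built from.
#' @param model_id model identifier.
#' @param response_convention see [param_spec()].
#' @param seed optional integer for a deterministic trajectory.
#' @return data.frame with columns `trial`, `pair`, `choice`, `optimal`,
#'   `reward` and `p_chosen` (the model probability of the realized choice).
#' @export
simulate_choices <- function(params, schedule, design, model_id,
                             response_convention = NULL, seed = NULL) {
  spec <- param_spec(model_id, response_convention)
  params <- canonical_params(params, spec)
  family <- attr(spec, "family")
  with_seed(seed, {
    n <- nrow(schedule)
    machine <- rl_step_machine(params, family)
    choice <- integer(n); reward <- integer(n); optimal <- integer(n); p_chosen <- numeric(n)
    for (t in seq_len(n)) {
      a <- schedule$left_stimulus[t]
      b <- schedule$right_stimulus[t]
      pa <- machine$prob(a, b)
      pb <- 1 - pa
      ch <- if (pa == pb) {
        if (runif(1) < 0.5) a else b   # exact tie: fair coin
      } else {
        if (runif(1) < pa) a else b
      }
      pair <- design$pairs[schedule$pair_id[t], ]
      r <- sample_feedback(pair, ch)
      choice[t] <- ch
      reward[t] <- r
      optimal[t] <- as.integer(ch == pair$stim_better)
      p_chosen[t] <- if (ch == a) pa else pb
      machine$update(ch, if (ch == a) b else a, r, schedule$pair_id[t])
    }
    data.frame(trial = schedule$trial, pair = schedule$pair_id,
               choice = choice, optimal = optimal, reward = reward,
               p_chosen = p_chosen)
  })
}
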