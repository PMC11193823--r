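#' Default probabilistic reinforcement-learning task design
#'
#' The task presents three fixed pairs of stimuli with reward contingencies
#' 80:20, 70:30 and 60:40 for the better vs. worse stimulus, 40 trials per
#' pair (120 trials in total). Choosing a stimulus is rewarded with its
#' reward probability; the worse stimulus of a pair is rewarded exactly with
#' one minus the better stimulus's probability. Stimulus identities are
#' opaque integer labels 1..6; by convention pair `p` holds stimuli
#' `2p - 1` (better) and `2p` (worse).
#'
#' @param trials_per_pair number of trials per pair (default 40); must be
#'   even so left/right positions can be balanced exactly.
#' @return an object of class `rl_task_design`: a list with a `pairs`
#'   data.frame (`pair_id`, `stim_better`, `stim_worse`, `p_reward_better`),
#'   `trials_per_pair`, and timing metadata (`response_window_ms`,
#'   `feedback_ms`; carried but never simulated).
#' @export
default_design <- function(trials_per_pair = 40L) {
  task_design(p_reward_better = c(0.8, 0.7, 0.6), trials_per_pair = trials_per_pair)
}

#' Construct a task design
#'
#' @param p_reward_better reward probabilities of the better stimulus of each
#'   pair, each in (0.5, 1]. The worse stimulus is rewarded with
#'   `1 - p_reward_better`.
#' @param trials_per_pair trials per pair (even positive integer).
#' @param response_window_ms,feedback_ms timing metadata in milliseconds.
#' @return an `rl_task_design` object; see [default_design()].
#' @export
task_design <- function(p_reward_better, trials_per_pair = 40L,
                        response_window_ms = 1700L, feedback_ms = 1000L) {
  n_pairs <- length(p_reward_better)
  if (n_pairs < 1L) stop("at least one pair is required")
  if (any(p_reward_better <= 0.5 | p_reward_better > 1)) {
    stop("p_reward_better must lie in (0.5, 1]")
  }
  trials_per_pair <- as.integer(trials_per_pair)
  if (trials_per_pair < 1L) stop("trials_per_pair must be positive")
  pairs <- data.frame(
    pair_id = seq_len(n_pairs),
    stim_better = 2L * seq_len(n_pairs) - 1L,
    stim_worse = 2L * seq_len(n_pairs),
    p_reward_better = as.numeric(p_reward_better)
  )
  structure(
    list(pairs = pairs, trials_per_pair = trials_per_pair,
         response_window_ms = as.integer(response_window_ms),
         feedback_ms = as.integer(feedback_ms)),
    class = "rl_task_design"
  )
}

#' @export
print.rl_task_design <- function(x, ...) {
  cat("Probabilistic RL task design:", nrow(x$pairs), "pairs x",
      x$trials_per_pair, "trials =", total_trials(x), "trials\n")
  print(x$pairs, row.names = FALSE)
  invisible(x)
}

#' Total number of scheduled trials of a design
#'
#' @param design an `rl_task_design`.
#' @return integer, pairs times trials per pair (120 for the default design).
#' @export
total_trials <- function(design) {
  stopifnot(inherits(design, "rl_task_design"))
  nrow(design$pairs) * design$trials_per_pair
}

#' Build a randomized, position-balanced trial schedule
#'
#' Each pair appears exactly `trials_per_pair` times; within a pair, each
#' stimulus is shown on the left on exactly half of its trials. The trial
#' order is a uniform random permutation of all (pair, position) slots.
#'
#' @param design an `rl_task_design`.
#' @param seed optional integer; if given, the schedule is a deterministic
#'   function of it (the caller's RNG state is left untouched).
#' @return data.frame with columns `trial`, `pair_id`, `left_stimulus`,
#'   `right_stimulus`.
#' @export
build_schedule <- function(design, seed = NULL) {
  stopifnot(inherits(design, "rl_task_design"))
  if (design$trials_per_pair %% 2L != 0L) {
    stop("trials_per_pair must be even for an exact left/right position balance")
  }
  with_seed(seed, {
    half <- design$trials_per_pair / 2L
    rows <- do.call(rbind, lapply(seq_len(nrow(design$pairs)), function(i) {
      p <- design$pairs[i, ]
      better_left <- sample(rep(c(TRUE, FALSE), each = half))
      data.frame(
        pair_id = p$pair_id,
        left_stimulus = ifelse(better_left, p$stim_better, p$stim_worse),
        right_stimulus = ifelse(better_left, p$stim_worse, p$stim_better)
      )
    }))
    rows <- rows[sample.int(nrow(rows)), , drop = FALSE]
    rows <- cbind(trial = seq_len(nrow(rows)), rows)
    rownames(rows) <- NULL
    rows
  })
}

#' Sample probabilistic feedback for a chosen stimulus
#'
#' Bernoulli reward with the pair's reward probability for the chosen
#' stimulus: `p_reward_better` if the better stimulus was chosen, otherwise
#' `1 - p_reward_better`.
#'
#' @param pair one row of `design$pairs` (or a list with `stim_better`,
#'   `stim_worse`, `p_reward_better`).
#' @param chosen_stimulus stimulus id; must belong to the pair.
#' @param n number of independent draws.
#' @return integer vector of rewards in `{0, 1}` of length `n`.
#' @export
sample_feedback <- function(pair, chosen_stimulus, n = 1L) {
  p <- reward_probability(pair, chosen_stimulus)
  as.integer(runif(n) < p)
}

reward_probability <- function(pair, chosen_stimulus) {
  if (chosen_stimulus == pair$stim_better) {
    pair$p_reward_better
  } else if (chosen_stimulus == pair$stim_worse) {
    1 - pair$p_reward_better
  } else {
    stop("stimulus ", chosen_stimulus, " does not belong to pair ", pair$pair_id)
  }
}

#' Bernoulli entropy of a reward probability
#'
#' Shannon entropy (in bits) of a Bernoulli reward with probability `p`;
#' maximal at `p = 0.5`, the point of maximum reward uncertainty.
#'
#' @param p probability in `[0, 1]`.
#' @return entropy in bits.
#' @export
bernoulli_entropy <- function(p) {
  stopifnot(all(p >= 0 & p <= 1))
  term <- function(q) ifelse(q == 0, 0, -q * log2(q))
  term(p) + term(1 - p)
}

#' Serialize a task design to JSON
#'
#' @param design an `rl_task_design`.
#' @param path optional file path; if `NULL` the JSON string is returned.
#' @return the JSON string, invisibly if written to a file.
#' @export
design_to_json <- function(design, path = NULL) {
  stopifnot(inherits(design, "rl_task_design"))
  doc <- list(
    pairs = design$pairs[, c("pair_id", "p_reward_better")],
    trials_per_pair = design$trials_per_pair,
    response_window_ms = design$response_window_ms,
    feedback_ms = design$feedback_ms
  )
  json <- jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (is.null(path)) return(json)
  writeLines(json, path)
  invisible(json)
}

#' Read a task design from JSON
#'
#' @param path file path or JSON string produced by [design_to_json()].
#' @return an `rl_task_design`.
#' @export
design_from_json <- function(path) {
  doc <- jsonlite::fromJSON(path)
  ord <- order(doc$pairs$pair_id)
  task_design(
    p_reward_better = doc$pairs$p_reward_better[ord],
    trials_per_pair = doc$trials_per_pair,
    response_window_ms = doc$response_window_ms %||% 1700L,
    feedback_ms = doc$feedback_ms %||% 1000L
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate expr under a temporary RNG seed; NULL seed uses the current stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}
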