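#' Stay probability of a choice sequence
#'
#' The probability that three consecutive choices within a stimulus pair
#' are equal, given that the two preceding choices were equal: over all
#' overlapping windows of three consecutive same-pair trials whose first
#' two choices agree, the fraction whose third choice agrees as well.
#' Windows never span pairs; non-responses (`NA` choices) break windows.
#'
#' @param x either a subject's trial rows (data.frame with `pair` and
#'   `choice`, in chronological order) or a list of per-pair choice
#'   vectors.
#' @return the stay probability, or `NA` if no eligible window exists.
#' @export
stay_probability <- function(x) {
  seqs <- if (is.data.frame(x)) {
    split(x$choice, x$pair)
  } else if (is.list(x)) {
    x
  } else {
    list(x)
  }
  eligible <- 0L
  stays <- 0L
  for (ch in seqs) {
    n <- length(ch)
    if (n < 3L) next
    for (t in seq_len(n - 2L)) {
      w <- ch[t:(t + 2L)]
      if (anyNA(w)) next
      if (w[1] == w[2]) {
        eligible <- eligible + 1L
        if (w[3] == w[1]) stays <- stays + 1L
      }
    }
  }
  if (eligible == 0L) NA_real_ else stays / eligible
}

#' Per-subject aggregate behavioral measures
#'
#' The four conventional summaries of task performance: rate of optimal
#' choices, rate of collected reward, mean reaction time over responded
#' trials (if reaction times are present), and the stay probability, plus
#' the response count used by the exclusion rule. Non-responses (`NA`
#' choices) are excluded from all rate denominators.
#'
#' @param table a trial table.
#' @return data.frame with one row per subject: `subject_id`, `group`,
#'   `response_count`, `optimal_rate`, `reward_rate`, `mean_rt_ms`,
#'   `stay_prob`.
#' @export
aggregate_behavior <- function(table) {
  if (is.null(table) || nrow(table) == 0L) stop("empty trial table")
  ids <- unique(table$subject_id)
  out <- do.call(rbind, lapply(ids, function(id) {
    rows <- table[table$subject_id == id, ]
    resp <- rows[!is.na(rows$choice), ]
    if (nrow(resp) == 0L) stop("subject ", id, " has no responded trials")
    data.frame(
      subject_id = id,
      group = if (!is.null(rows$group)) rows$group[1] else NA_integer_,
      response_count = nrow(resp),
      optimal_rate = mean(resp$optimal),
      reward_rate = mean(resp$reward),
      mean_rt_ms = if (!is.null(resp$rt_ms)) mean(resp$rt_ms, na.rm = TRUE) else NA_real_,
      stay_prob = stay_probability(rows)
    )
  }))
  rownames(out) <- NULL
  out
}

#' Cumulative-mean curves of a behavioral measure
#'
#' For each subject and pair, the running mean of a trial-level measure
#' from the pair's first trial to the given within-pair trial index, plus
#' cross-subject mean and standard-error bands per pair.
#'
#' @param table a trial table.
#' @param measure name of a numeric trial column (e.g. `"optimal"`,
#'   `"reward"`, `"rt_ms"`).
#' @return list with `individual` (subject_id, pair, pair_trial, value,
#'   cum_mean) and `summary` (pair, pair_trial, mean, se, n).
#' @export
cumulative_curves <- function(table, measure = "optimal") {
  if (!measure %in% names(table)) stop("unknown measure: ", measure)
  if (!is.numeric(table[[measure]])) stop("measure must be numeric")
  parts <- split(table, list(table$subject_id, table$pair), drop = TRUE)
  indiv <- do.call(rbind, lapply(parts, function(rows) {
    rows <- rows[order(rows$trial), ]
    v <- rows[[measure]]
    data.frame(subject_id = rows$subject_id[1], pair = rows$pair[1],
               pair_trial = seq_along(v), value = v,
               cum_mean = cumsum(v) / seq_along(v))
  }))
  rownames(indiv) <- NULL
  agg <- do.call(rbind, lapply(split(indiv, list(indiv$pair, indiv$pair_trial),
                                     drop = TRUE), function(g) {
    data.frame(pair = g$pair[1], pair_trial = g$pair_trial[1],
               mean = mean(g$cum_mean),
               se = if (nrow(g) > 1) sd(g$cum_mean) / sqrt(nrow(g)) else NA_real_,
               n = nrow(g))
  }))
  agg <- agg[order(agg$pair, agg$pair_trial), ]
  rownames(agg) <- NULL
  list(individual = indiv, summary = agg)
}

#' Sliding-window correlation of a subject statistic with behavior
#'
#' Moves a window of `window` trials in steps of `step` across the task
#' (the first window, reported at its last trial index, covers trials 1 to
#' `window`) and correlates, across subjects, a per-subject statistic with
#' each subject's windowed mean of a behavioral measure. The 95 percent
#' band is the uncorrected Fisher-z interval.
#'
#' @param table a trial table.
#' @param statistic data.frame with `subject_id` and `value` columns (one
#'   row per subject), or a vector named by subject id.
#' @param measure trial column to average within windows.
#' @param window window length in trials (default 20).
#' @param step step size in trials (default 1).
#' @return data.frame with `window_end`, `r`, `ci_lower`, `ci_upper`, `n`;
#'   `r` is `NA` where either variable has zero variance.
#' @export
sliding_window_correlation <- function(table, statistic, measure = "optimal",
                                       window = 20L, step = 1L) {
  if (!measure %in% names(table)) stop("unknown measure: ", measure)
  if (!is.data.frame(statistic)) {
    statistic <- data.frame(subject_id = as.integer(names(statistic)),
                            value = as.numeric(statistic))
  }
  ids <- unique(table$subject_id)
  if (!all(ids %in% statistic$subject_id)) {
    stop("statistic must be defined for every subject")
  }
  stat <- statistic$value[match(ids, statistic$subject_id)]
  per_subj <- lapply(ids, function(id) {
    rows <- table[table$subject_id == id, ]
    rows[[measure]][order(rows$trial)]
  })
  n_trials <- unique(vapply(per_subj, length, integer(1)))
  if (length(n_trials) != 1L) stop("subjects differ in trial counts")
  if (n_trials < window) stop("fewer trials than the window length")
  ends <- seq(window, n_trials, by = step)
  out <- do.call(rbind, lapply(ends, function(e) {
    wm <- vapply(per_subj, function(v) mean(v[(e - window + 1L):e]), numeric(1))
    if (sd(wm) == 0 || sd(stat) == 0) {
      return(data.frame(window_end = e, r = NA_real_, ci_lower = NA_real_,
                        ci_upper = NA_real_, n = length(ids)))
    }
    r <- cor(stat, wm)
    z <- atanh(r)
    se <- 1 / sqrt(length(ids) - 3)
    data.frame(window_end = e, r = r,
               ci_lower = tanh(z - 1.959964 * se),
               ci_upper = tanh(z + 1.959964 * se), n = length(ids))
  }))
  rownames(out) <- NULL
  out
}

#' Low-response participant exclusion
#'
#' Excludes subjects whose response count falls below the sample mean minus
#' three sample standard deviations of the response counts (all subjects
#' enter the mean/sd computation).
#'
#' @param table a trial table (non-responses as `NA` choices).
#' @return vector of retained subject ids.
#' @export
exclusion_filter <- function(table) {
  beh <- aggregate_behavior(table)
  if (nrow(beh) < 2L) stop("the exclusion rule needs at least two subjects")
  threshold <- mean(beh$response_count) - 3 * sd(beh$response_count)
  beh$subject_id[beh$response_count >= threshold]
}
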