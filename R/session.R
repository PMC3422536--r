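#' Configuration for one simulated behavioural session
#'
#' A session presents a fixed quota of signal and no-signal (non-correction)
#' trials, drawn with equal probability until each quota is filled. After an
#' error, correction trials — identical repeats of the erroneous trial — are
#' appended until a correct response is given (when enabled); correction
#' trials do not count towards the quotas.
#'
#' @param stimuli A [stimulus_set()].
#' @param n_signal_trials,n_nosignal_trials Non-correction trial quotas
#'   (default 50 + 50, the conventional session minimum).
#' @param use_correction_trials Repeat erroneous trials until correct?
#' @param centre_reward_prob Probability that a trial is flagged as having
#'   received water at the centre spout; such trials are excluded from every
#'   analysis. Default 0.
#' @param seed Optional integer seed applied at the start of the session.
#' @param max_trials Safety cap on the total number of trials (including
#'   corrections); default `40 * (n_signal_trials + n_nosignal_trials)`.
#'   Degenerate observers that cannot answer a correction trial correctly
#'   otherwise never terminate.
#' @return An object of class `session_config`.
#' @export
session_config <- function(stimuli, n_signal_trials = 50L,
                           n_nosignal_trials = 50L,
                           use_correction_trials = TRUE,
                           centre_reward_prob = 0, seed = NULL,
                           max_trials = NULL) {
  stopifnot(inherits(stimuli, "stimulus_set"),
            n_signal_trials > 0, n_nosignal_trials > 0,
            centre_reward_prob >= 0, centre_reward_prob <= 1)
  if (is.null(max_trials))
    max_trials <- 40L * (n_signal_trials + n_nosignal_trials)
  structure(list(stimuli = stimuli,
                 n_signal_trials = as.integer(n_signal_trials),
                 n_nosignal_trials = as.integer(n_nosignal_trials),
                 use_correction_trials = isTRUE(use_correction_trials),
                 centre_reward_prob = centre_reward_prob,
                 seed = seed,
                 max_trials = as.integer(max_trials)),
            class = "session_config")
}

#' Simulate one behavioural session
#'
#' Runs the SDT observer through a session trial by trial. On trial i the
#' criterion is
#' `optimal_criterion(stimuli) + criterion_bias + s1*sign(resp[i-1]) +
#' s2*sign(resp[i-2])` with `sign(yes) = +1`, `sign(no) = -1` (0 while no
#' history exists). With probability `guess_rate` the response is a fair
#' coin; otherwise the response is "yes" iff the internal value exceeds the
#' criterion. History shifts are updated by every response, including those
#' on correction and guess trials.
#'
#' @param config A [session_config()].
#' @param params An [observer_params()].
#' @param history Optional character vector of the responses preceding the
#'   session, most recent first (e.g. `c("yes", "no")` means trial i-1 was
#'   "yes" and i-2 "no"). Default: no history (zero shift contribution).
#' @param session_id Identifier stored in the trial log.
#' @return A `data.frame` trial log, one row per trial, with columns
#'   `session_id`, `trial_index`, `trial_type`, `level`, `is_correction`,
#'   `internal_value`, `criterion_used`, `response`, `outcome`, `rewarded`,
#'   `centre_reward`.
#' @examples
#' p <- observer_params(9.2, 37.35, criterion_bias = 3.78, guess_rate = 0.01,
#'                      trial_shift_1 = 2, trial_shift_2 = 1.5)
#' st <- stimulus_set("limits", 47, noise_level = 48)
#' log <- run_session(session_config(st, seed = 1), p)
#' table(log$outcome)
#' @export
run_session <- function(config, params, history = NULL, session_id = "s1") {
  stopifnot(inherits(config, "session_config"),
            inherits(params, "observer_params"))
  if (!is.null(config$seed)) set.seed(config$seed)

  stim <- config$stimuli
  levels_set <- stim$signal_levels
  n_levels <- length(levels_set)
  c_base <- optimal_criterion(stim, params) + params$criterion_bias
  sd <- params$internal_sd
  ref <- params$reference_level
  g <- params$guess_rate
  s1 <- params$trial_shift_1
  s2 <- params$trial_shift_2
  use_corr <- config$use_correction_trials
  centre_p <- config$centre_reward_prob

  h <- history_to_signs(history)
  h1 <- h[1]; h2 <- h[2]

  ns_quota <- config$n_signal_trials
  nn_quota <- config$n_nosignal_trials
  cap <- config$max_trials

  # pre-draw random numbers in growable chunks (most sessions need ~1.3x
  # the quota; the cap only guards degenerate observers)
  chunk <- min(cap, as.integer(ceiling(1.6 * (ns_quota + nn_quota))) + 16L)
  z <- stats::rnorm(chunk)
  u_guess <- stats::runif(chunk)
  u_coin <- stats::runif(chunk)
  u_type <- stats::runif(chunk)
  u_centre <- if (centre_p > 0) stats::runif(chunk) else NULL
  lvl_idx <- if (n_levels > 1L) sample.int(n_levels, chunk, replace = TRUE)
             else NULL
  avail <- chunk

  type <- character(cap); lvl <- numeric(cap); corr <- logical(cap)
  iv <- numeric(cap); crit <- numeric(cap); resp <- logical(cap)

  ns_done <- 0L; nn_done <- 0L; i <- 0L
  pending <- FALSE; pend_signal <- FALSE; pend_level <- NA_real_

  while (i < cap && (pending || ns_done < ns_quota || nn_done < nn_quota)) {
    i <- i + 1L
    if (i > avail) {
      more <- min(chunk, cap - avail)
      z <- c(z, stats::rnorm(more))
      u_guess <- c(u_guess, stats::runif(more))
      u_coin <- c(u_coin, stats::runif(more))
      u_type <- c(u_type, stats::runif(more))
      if (centre_p > 0) u_centre <- c(u_centre, stats::runif(more))
      if (n_levels > 1L)
        lvl_idx <- c(lvl_idx, sample.int(n_levels, more, replace = TRUE))
      avail <- avail + more
    }
    if (pending) {
      is_signal <- pend_signal
      level_i <- pend_level
      corr[i] <- TRUE
    } else {
      if (ns_done >= ns_quota) is_signal <- FALSE
      else if (nn_done >= nn_quota) is_signal <- TRUE
      else is_signal <- u_type[i] < 0.5
      level_i <- if (is_signal) {
        if (n_levels > 1L) levels_set[lvl_idx[i]] else levels_set
      } else NA_real_
      if (is_signal) ns_done <- ns_done + 1L else nn_done <- nn_done + 1L
    }
    c_i <- c_base + s1 * h1 + s2 * h2
    iv_i <- (if (is_signal) level_i else ref) + sd * z[i]
    yes <- if (g > 0 && u_guess[i] < g) u_coin[i] < 0.5 else iv_i > c_i
    correct <- yes == is_signal

    type[i] <- if (is_signal) "signal" else "nosignal"
    lvl[i] <- level_i
    iv[i] <- iv_i
    crit[i] <- c_i
    resp[i] <- yes

    h2 <- h1
    h1 <- if (yes) 1 else -1
    if (use_corr && !correct) {
      pending <- TRUE; pend_signal <- is_signal; pend_level <- level_i
    } else {
      pending <- FALSE
    }
  }
  if (i == cap && (pending || ns_done < ns_quota || nn_done < nn_quota))
    warning("session hit the max_trials cap (", cap,
            ") before completing its trial quotas; log truncated")

  idx <- seq_len(i)
  type <- type[idx]; resp <- resp[idx]
  is_sig <- type == "signal"
  outcome <- ifelse(is_sig,
                    ifelse(resp, "hit", "miss"),
                    ifelse(resp, "false_alarm", "correct_rejection"))
  data.frame(
    session_id = session_id,
    trial_index = idx,
    trial_type = type,
    level = lvl[idx],
    is_correction = corr[idx],
    internal_value = iv[idx],
    criterion_used = crit[idx],
    response = ifelse(resp, "yes", "no"),
    outcome = outcome,
    rewarded = resp == is_sig,
    centre_reward = if (centre_p > 0) u_centre[idx] < centre_p
                    else rep(FALSE, i),
    stringsAsFactors = FALSE
  )
}

# Counts-only twin of run_session used by the fitting hot paths: identical
# trial-by-trial dynamics and random-number consumption (same seed => same
# sequence of trials), but it accumulates per-level response counts among
# non-correction trials instead of building a trial-log data.frame.
sim_session_counts <- function(params, levels_set, c_base,
                               ns_quota = 50L, nn_quota = 50L,
                               use_corr = TRUE, cap = NULL) {
  n_levels <- length(levels_set)
  sd <- params$internal_sd
  ref <- params$reference_level
  g <- params$guess_rate
  s1 <- params$trial_shift_1
  s2 <- params$trial_shift_2
  if (is.null(cap)) cap <- 40L * (ns_quota + nn_quota)

  chunk <- min(cap, as.integer(ceiling(1.6 * (ns_quota + nn_quota))) + 16L)
  z <- stats::rnorm(chunk)
  u_guess <- stats::runif(chunk)
  u_coin <- stats::runif(chunk)
  u_type <- stats::runif(chunk)
  lvl_idx <- if (n_levels > 1L) sample.int(n_levels, chunk, replace = TRUE)
             else NULL
  avail <- chunk

  sig_yes <- integer(n_levels); sig_n <- integer(n_levels)
  nos_yes <- 0L; nos_n <- 0L
  h1 <- 0; h2 <- 0
  ns_done <- 0L; nn_done <- 0L; i <- 0L
  pending <- FALSE; pend_signal <- FALSE; pend_idx <- 1L

  while (i < cap && (pending || ns_done < ns_quota || nn_done < nn_quota)) {
    i <- i + 1L
    if (i > avail) {
      more <- min(chunk, cap - avail)
      z <- c(z, stats::rnorm(more))
      u_guess <- c(u_guess, stats::runif(more))
      u_coin <- c(u_coin, stats::runif(more))
      u_type <- c(u_type, stats::runif(more))
      if (n_levels > 1L)
        lvl_idx <- c(lvl_idx, sample.int(n_levels, more, replace = TRUE))
      avail <- avail + more
    }
    if (pending) {
      is_signal <- pend_signal
      li <- pend_idx
      counted <- FALSE
    } else {
      if (ns_done >= ns_quota) is_signal <- FALSE
      else if (nn_done >= nn_quota) is_signal <- TRUE
      else is_signal <- u_type[i] < 0.5
      li <- if (is_signal && n_levels > 1L) lvl_idx[i] else 1L
      if (is_signal) ns_done <- ns_done + 1L else nn_done <- nn_done + 1L
      counted <- TRUE
    }
    c_i <- c_base + s1 * h1 + s2 * h2
    iv_i <- (if (is_signal) levels_set[li] else ref) + sd * z[i]
    yes <- if (g > 0 && u_guess[i] < g) u_coin[i] < 0.5 else iv_i > c_i
    if (counted) {
      if (is_signal) {
        sig_n[li] <- sig_n[li] + 1L
        if (yes) sig_yes[li] <- sig_yes[li] + 1L
      } else {
        nos_n <- nos_n + 1L
        if (yes) nos_yes <- nos_yes + 1L
      }
    }
    h2 <- h1
    h1 <- if (yes) 1 else -1
    if (use_corr && yes != is_signal) {
      pending <- TRUE; pend_signal <- is_signal; pend_idx <- li
    } else {
      pending <- FALSE
    }
  }
  list(levels = levels_set, sig_yes = sig_yes, sig_n = sig_n,
       nos_yes = nos_yes, nos_n = nos_n)
}

history_to_signs <- function(history) {
  if (is.null(history) || length(history) == 0L) return(c(0, 0))
  stopifnot(all(history %in% c("yes", "no")))
  sg <- ifelse(history == "yes", 1, -1)
  c(sg[1], if (length(sg) >= 2L) sg[2] else 0)
}

#' Analysis trials of a log
#'
#' Drops correction trials and centre-reward trials, the standard exclusion
#' applied before any rate is computed.
#'
#' @param trials A trial-log `data.frame`.
#' @return The filtered trial log.
#' @export
analysis_trials <- function(trials) {
  check_trial_log(trials)
  trials[!trials$is_correction & !trials$centre_reward, , drop = FALSE]
}

#' Raw hit/false-alarm rates of a trial log
#'
#' Pools all (non-correction, non-centre-reward) trials of a log into a
#' single [rate_pair()]. Per-level aggregation for psychometric functions is
#' done by [aggregate_rates()].
#'
#' @param trials A trial-log `data.frame`.
#' @return A [rate_pair()] with counts set.
#' @export
session_rates <- function(trials) {
  t <- analysis_trials(trials)
  sig <- t$trial_type == "signal"
  ns <- sum(sig); nn <- sum(!sig)
  if (ns == 0L || nn == 0L)
    stop("log must contain both signal and no-signal analysis trials")
  rate_pair(hit_rate = mean(t$response[sig] == "yes"),
            fa_rate = mean(t$response[!sig] == "yes"),
            n_signal = ns, n_nosignal = nn)
}

trial_log_columns <- c("session_id", "trial_index", "trial_type", "level",
                       "is_correction", "internal_value", "criterion_used",
                       "response", "outcome", "rewarded", "centre_reward")

check_trial_log <- function(trials) {
  if (!is.data.frame(trials))
    stop("trial log must be a data.frame")
  missing <- setdiff(trial_log_columns, names(trials))
  if (length(missing))
    stop("trial log is missing columns: ", paste(missing, collapse = ", "))
  invisible(trials)
}
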