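#' Per-level hit and false-alarm rates from a trial log
#'
#' Aggregates a block's trials into per-level [rate_pair()] summaries after
#' excluding correction and centre-reward trials.
#'
#' For the Method of Limits, sessions at the same level are pooled; a level
#' enters the result only when it has at least `min_sessions` sessions and
#' at least `min_signal` signal and `min_nosignal` no-signal trials
#' (otherwise it is omitted with a warning).
#'
#' For the Method of Constant Stimuli, no-signal trials carry no level, so
#' each level's false-alarm rate is computed from a without-replacement
#' random sample of the pooled no-signal trials whose size matches that
#' level's signal-trial count; hit and false-alarm rates are thereby based
#' on similar trial numbers. Samples are drawn level by level in increasing
#' level order from the current RNG stream (seed beforehand for
#' reproducibility).
#'
#' @param trials A `session_block` or a trial-log `data.frame` (which then
#'   needs `session_level` for the limits method).
#' @param method `"limits"` or `"constant"`; taken from the block when one
#'   is supplied.
#' @param noise_level Masker level used to report SNR; taken from the block
#'   when one is supplied.
#' @param min_signal,min_nosignal Minimum pooled trial counts per level.
#' @param min_sessions Minimum sessions per level (limits method). The
#'   default 1 makes the pooled trial minimum the operative filter, which is
#'   what the multi-session pooling convention achieves when session length
#'   varies; raise it to demand multi-session pooling outright.
#' @return A `data.frame` of class `psychometric_rates`: one row per
#'   retained level with `level`, `snr`, `n_sessions`, `n_signal`,
#'   `n_nosignal`, `hit_rate`, `fa_rate`, `dprime`, `pcmax`.
#' @export
aggregate_rates <- function(trials, method = NULL, noise_level = NA_real_,
                            min_signal = 50L, min_nosignal = 50L,
                            min_sessions = 1L) {
  if (inherits(trials, "session_block")) {
    if (is.null(method)) method <- trials$method
    if (is.na(noise_level)) noise_level <- trials$noise_level
    trials <- trials$trials
  }
  method <- match.arg(method, c("limits", "constant"))
  t <- analysis_trials(trials)

  if (method == "limits") {
    if (is.null(t$session_level))
      stop("limits aggregation needs a `session_level` column")
    out <- lapply(split(t, t$session_level), function(d) {
      sig <- d$trial_type == "signal"
      data.frame(level = d$session_level[1],
                 n_sessions = length(unique(d$session_id)),
                 n_signal = sum(sig), n_nosignal = sum(!sig),
                 hit_rate = mean(d$response[sig] == "yes"),
                 fa_rate = mean(d$response[!sig] == "yes"))
    })
    res <- do.call(rbind, out)
  } else {
    sig <- t[t$trial_type == "signal", , drop = FALSE]
    nosig_yes <- t$response[t$trial_type == "nosignal"] == "yes"
    n_pool <- length(nosig_yes)
    out <- lapply(split(sig, sig$level), function(d) {
      ns <- nrow(d)
      if (ns > n_pool) {
        warning("fewer pooled no-signal trials (", n_pool,
                ") than signal trials (", ns, ") at level ", d$level[1],
                "; using the full pool")
        take <- nosig_yes
      } else {
        take <- nosig_yes[sample.int(n_pool, ns)]
      }
      data.frame(level = d$level[1],
                 n_sessions = length(unique(d$session_id)),
                 n_signal = ns, n_nosignal = length(take),
                 hit_rate = mean(d$response == "yes"),
                 fa_rate = mean(take))
    })
    res <- do.call(rbind, out)
  }
  res <- res[order(res$level), , drop = FALSE]
  keep <- res$n_signal >= min_signal & res$n_nosignal >= min_nosignal &
    (method != "limits" | res$n_sessions >= min_sessions)
  if (any(!keep))
    warning("omitting level(s) with insufficient trials/sessions: ",
            paste(round(res$level[!keep], 2), collapse = ", "))
  res <- res[keep, , drop = FALSE]
  res$snr <- res$level - noise_level
  res$dprime <- dprime(res$hit_rate, res$fa_rate, res$n_signal,
                       res$n_nosignal)
  res$pcmax <- pcmax(res$dprime)
  rownames(res) <- NULL
  res <- res[, c("level", "snr", "n_sessions", "n_signal", "n_nosignal",
                 "hit_rate", "fa_rate", "dprime", "pcmax")]
  class(res) <- c("psychometric_rates", "data.frame")
  res
}

#' Fit a logistic psychometric function to P(c)max values
#'
#' Least-squares fit of the fixed-asymptote logistic
#' `P(x) = 0.5 + 0.5 / (1 + exp(-(x - m)/s))` with floor 0.5 (chance) and
#' ceiling 1.0; the observer's guess rate lives in the simulation model, not
#' in the psychometric curve, so no lapse parameters are fitted. The fit is
#' flagged low-confidence when fewer than three levels are available or the
#' levels do not span the 71% point.
#'
#' @param levels Tone levels, dB SPL.
#' @param pcmax_values P(c)max at each level.
#' @return An object of class `logistic_fit`: `midpoint` (m, the 75% point,
#'   dB), `scale` (s, dB), `sse`, `n_levels`, `low_confidence`.
#' @examples
#' x <- c(40, 44, 48, 52, 56)
#' fit <- fit_logistic(x, 0.5 + 0.5 / (1 + exp(-(x - 46) / 4)))
#' threshold_at(fit)
#' @export
fit_logistic <- function(levels, pcmax_values) {
  stopifnot(is.numeric(levels), is.numeric(pcmax_values),
            length(levels) == length(pcmax_values), length(levels) >= 2L,
            !anyNA(levels), !anyNA(pcmax_values))
  if (stats::sd(pcmax_values) < 1e-9)
    stop("P(c)max values are constant across levels: no slope information, ",
         "fit rejected")
  low_confidence <- length(levels) < 3L ||
    min(pcmax_values) > 0.71 || max(pcmax_values) < 0.71

  pred <- function(m, s, x) 0.5 + 0.5 / (1 + exp(-(x - m) / s))
  obj <- function(par) {
    r <- pcmax_values - pred(par[1], exp(par[2]), levels)
    sum(r * r)
  }
  m0 <- stats::approx(pcmax_values, levels, xout = 0.75, ties = mean,
                      rule = 2)$y
  s0 <- max(diff(range(levels)) / 6, 1)
  fit <- stats::optim(c(m0, log(s0)), obj, method = "Nelder-Mead",
                      control = list(reltol = 1e-14, maxit = 2000))
  # polish from a second start in case the first stalls
  fit2 <- stats::optim(fit$par, obj, method = "Nelder-Mead",
                       control = list(reltol = 1e-14, maxit = 2000))
  if (fit2$value < fit$value) fit <- fit2
  if (fit$convergence != 0)
    stop("logistic fit failed to converge (code ", fit$convergence,
         ", sse ", signif(fit$value, 6), ")")
  structure(list(midpoint = fit$par[1], scale = exp(fit$par[2]),
                 sse = fit$value, n_levels = length(levels),
                 low_confidence = low_confidence),
            class = "logistic_fit")
}

#' @export
print.logistic_fit <- function(x, ...) {
  cat(sprintf(
    "Logistic psychometric fit: midpoint %.3f dB, scale %.3f dB (sse %.3g)%s\n",
    x$midpoint, x$scale, x$sse,
    if (x$low_confidence) " [low confidence]" else ""))
  invisible(x)
}

#' Detection threshold from a fitted psychometric function
#'
#' Inverts the fixed-asymptote logistic at a P(c)max criterion, 71% by
#' convention: `m + s * log((2p - 1) / (2 - 2p))`.
#'
#' @param fit A `logistic_fit`, or a numeric `c(midpoint, scale)`.
#' @param criterion P(c)max criterion, strictly inside (0.5, 1).
#' @return Threshold level, dB SPL.
#' @export
threshold_at <- function(fit, criterion = 0.71) {
  if (inherits(fit, "logistic_fit")) {
    m <- fit$midpoint; s <- fit$scale
  } else {
    stopifnot(is.numeric(fit), length(fit) == 2L)
    m <- fit[1]; s <- fit[2]
  }
  if (criterion <= 0.5 || criterion >= 1)
    stop("threshold criterion must lie strictly inside (0.5, 1), got ",
         criterion)
  m + s * log((2 * criterion - 1) / (2 - 2 * criterion))
}

#' Psychometric function and threshold of a simulated block
#'
#' Convenience pipeline: [aggregate_rates()], [fit_logistic()] on the
#' per-level P(c)max values, [threshold_at()].
#'
#' @param block A `session_block` (or trial log plus `method`).
#' @param criterion P(c)max threshold criterion (default 0.71).
#' @param ... Passed to [aggregate_rates()].
#' @return A list of class `psychometric_result`: `rates`, `fit`,
#'   `threshold`, `criterion`.
#' @export
psychometric_result <- function(block, criterion = 0.71, ...) {
  rates <- aggregate_rates(block, ...)
  if (nrow(rates) < 2L)
    stop("need at least two retained levels to fit a psychometric function")
  fit <- fit_logistic(rates$level, rates$pcmax)
  structure(list(rates = rates, fit = fit,
                 threshold = threshold_at(fit, criterion),
                 criterion = criterion),
            class = "psychometric_result")
}

#' @export
print.psychometric_result <- function(x, ...) {
  print(x$fit)
  cat(sprintf("Threshold at P(c)max = %.2f: %.2f dB SPL\n",
              x$criterion, x$threshold))
  print(as.data.frame(x$rates), row.names = FALSE, digits = 4)
  invisible(x)
}

#' Simulation-based confidence bands for session statistics
#'
#' Repeatedly simulates sessions and reports empirical percentile bands
#' (2.5/50/97.5 by default) of P(c)max, hit rate and false-alarm rate per
#' signal level.
#'
#' @param levels Signal levels (dB SPL) at which bands are computed. For
#'   the limits method each level is simulated in its own sessions; for the
#'   constant method whole sessions presenting the full level set are
#'   simulated and split by level.
#' @param params An [observer_params()].
#' @param method `"limits"` or `"constant"`.
#' @param noise_level Masker level, dB SPL.
#' @param n_sessions Simulated sessions per level (limits) or in total
#'   (constant). Defaults: 200 for limits, 1000 for constant.
#' @param n_signal_trials,n_nosignal_trials Per-session quotas.
#' @param probs Percentiles reported (low, mid, high).
#' @param seed Optional integer seed.
#' @return A `data.frame`, one row per level, with `lo`/`med`/`hi` columns
#'   for each of `pcmax`, `hit_rate`, `fa_rate`.
#' @export
confidence_bands <- function(levels, params,
                             method = c("limits", "constant"),
                             noise_level = 0, n_sessions = NULL,
                             n_signal_trials = 50L, n_nosignal_trials = 50L,
                             probs = c(0.025, 0.5, 0.975), seed = NULL) {
  method <- match.arg(method)
  stopifnot(is.numeric(levels), length(levels) >= 1L,
            inherits(params, "observer_params"))
  if (!is.null(seed)) set.seed(seed)
  if (is.null(n_sessions))
    n_sessions <- if (method == "limits") 200L else 1000L

  per_level <- function(level) {
    st <- stimulus_set("limits", level, noise_level)
    cfg <- session_config(st, n_signal_trials, n_nosignal_trials)
    stats_mat <- vapply(seq_len(n_sessions), function(k) {
      rp <- session_rates(run_session(cfg, params))
      c(pcmax(dprime(rp)), rp$hit_rate, rp$fa_rate)
    }, numeric(3))
    stats_mat
  }
  if (method == "limits") {
    mats <- lapply(sort(levels), per_level)
  } else {
    stim <- stimulus_set("constant", levels, noise_level,
                         n_levels_bounds = c(1L, 20L))
    cfg <- session_config(stim, n_signal_trials, n_nosignal_trials)
    lvls <- sort(levels)
    acc <- lapply(lvls, function(l) matrix(NA_real_, 3, n_sessions))
    names(acc) <- as.character(lvls)
    for (k in seq_len(n_sessions)) {
      log <- analysis_trials(run_session(cfg, params))
      nos <- log$response[log$trial_type == "nosignal"] == "yes"
      for (l in lvls) {
        d <- log[log$trial_type == "signal" & log$level == l, , drop = FALSE]
        if (!nrow(d) || !length(nos)) next
        h <- mean(d$response == "yes")
        f <- mean(nos)
        dp <- dprime(h, f, nrow(d), length(nos))
        acc[[as.character(l)]][, k] <- c(pcmax(dp), h, f)
      }
    }
    mats <- acc
  }
  srt <- sort(levels)
  rows <- mapply(function(mat, level) {
    q <- apply(mat, 1, stats::quantile, probs = probs, na.rm = TRUE)
    data.frame(level = level,
               pcmax_lo = q[1, 1], pcmax_med = q[2, 1], pcmax_hi = q[3, 1],
               hit_lo = q[1, 2], hit_med = q[2, 2], hit_hi = q[3, 2],
               fa_lo = q[1, 3], fa_med = q[2, 3], fa_hi = q[3, 3])
  }, mats, srt, SIMPLIFY = FALSE)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Average threshold over replicate simulated Limits blocks
#'
#' The with/without-dependencies threshold experiment: simulate many Method
#' of Limits blocks with a given observer, fit each block's psychometric
#' function, and average the 71% thresholds. Setting both trial shifts to
#' zero (via `zero_shifts`) isolates the effect of the trial-by-trial
#' criterion dependencies on the measured threshold.
#'
#' @param params An [observer_params()].
#' @param block A [block_config()] with `method = "limits"`.
#' @param n_blocks Number of replicate blocks (800 in the full protocol).
#' @param zero_shifts If `TRUE`, both trial-shift parameters are set to 0.
#' @param criterion Threshold criterion (default 0.71).
#' @param seed Optional integer seed.
#' @param min_sessions Passed to [aggregate_rates()].
#' @param ... Passed to [run_limits_block()].
#' @return A list: `thresholds` (per block, dB SPL), `mean_threshold`,
#'   `n_failed` (blocks whose psychometric function could not be fitted).
#' @export
simulate_threshold_experiment <- function(params, block, n_blocks = 800L,
                                          zero_shifts = FALSE,
                                          criterion = 0.71, seed = NULL,
                                          min_sessions = 1L, ...) {
  stopifnot(inherits(params, "observer_params"),
            inherits(block, "block_config"), block$method == "limits")
  if (!is.null(seed)) set.seed(seed)
  if (zero_shifts) {
    params <- observer_params(params$internal_sd, params$reference_level,
                              params$criterion_bias, params$guess_rate,
                              0, 0)
  }
  th <- rep(NA_real_, n_blocks)
  for (b in seq_len(n_blocks)) {
    bl <- run_limits_block(block, params, block_id = sprintf("b%03d", b),
                           ...)
    res <- tryCatch(
      suppressWarnings(psychometric_result(bl, criterion = criterion,
                                           min_sessions = min_sessions)),
      error = function(e) NULL)
    if (!is.null(res)) th[b] <- res$threshold
  }
  list(thresholds = th,
       mean_threshold = mean(th, na.rm = TRUE),
       n_failed = sum(is.na(th)))
}
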