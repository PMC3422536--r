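#' Observer parameters for the equal-variance SDT model
#'
#' Bundles the parameters of the equal-variance signal detection theory
#' observer used throughout the package. The observer forms, on every trial,
#' an internal representation on a dB scale: for signal trials the signal
#' level plus Gaussian internal noise, for no-signal trials the reference
#' level plus the same noise. A "yes" response is given when the internal
#' value exceeds the decision criterion.
#'
#' @param internal_sd Standard deviation of the internal (sensory) noise, dB.
#'   Must be positive.
#' @param reference_level Signal level indistinguishable from a no-signal
#'   trial, dB SPL. Centre of the no-signal distribution.
#' @param criterion_bias Fixed, block-level offset of the decision criterion
#'   from the reward-optimal point, dB.
#' @param guess_rate Probability of an attentional lapse on which the
#'   response is a fair coin regardless of the stimulus; in `[0, 1]`.
#' @param trial_shift_1 Criterion shift (dB, non-negative) applied on trial
#'   i, added if the response on trial i-1 was "yes" and subtracted if "no".
#' @param trial_shift_2 As `trial_shift_1` but keyed to the response on
#'   trial i-2.
#'
#' @return An object of class `observer_params` (a named list).
#' @examples
#' observer_params(internal_sd = 9.2, reference_level = 37.35,
#'                 criterion_bias = 3.78, guess_rate = 0.01,
#'                 trial_shift_1 = 2, trial_shift_2 = 1.5)
#' @export
observer_params <- function(internal_sd, reference_level,
                            criterion_bias = 0, guess_rate = 0,
                            trial_shift_1 = 0, trial_shift_2 = 0) {
  stopifnot(is.numeric(internal_sd), length(internal_sd) == 1L,
            is.numeric(reference_level), length(reference_level) == 1L,
            is.numeric(criterion_bias), length(criterion_bias) == 1L,
            is.numeric(guess_rate), length(guess_rate) == 1L,
            is.numeric(trial_shift_1), length(trial_shift_1) == 1L,
            is.numeric(trial_shift_2), length(trial_shift_2) == 1L)
  if (internal_sd <= 0)
    stop("`internal_sd` must be positive (got ", internal_sd, ")")
  if (guess_rate < 0 || guess_rate > 1)
    stop("`guess_rate` must lie in [0, 1] (got ", guess_rate, ")")
  if (trial_shift_1 < 0 || trial_shift_2 < 0)
    stop("trial shifts must be non-negative")
  structure(list(internal_sd = internal_sd,
                 reference_level = reference_level,
                 criterion_bias = criterion_bias,
                 guess_rate = guess_rate,
                 trial_shift_1 = trial_shift_1,
                 trial_shift_2 = trial_shift_2),
            class = "observer_params")
}

#' @export
print.observer_params <- function(x, ...) {
  cat("SDT observer parameters\n")
  cat(sprintf("  internal s.d.   : %.4g dB\n", x$internal_sd))
  cat(sprintf("  reference level : %.4g dB SPL\n", x$reference_level))
  cat(sprintf("  criterion bias  : %.4g dB\n", x$criterion_bias))
  cat(sprintf("  guess rate      : %.4g\n", x$guess_rate))
  cat(sprintf("  trial shift i-1 : %.4g dB\n", x$trial_shift_1))
  cat(sprintf("  trial shift i-2 : %.4g dB\n", x$trial_shift_2))
  invisible(x)
}

#' Stimulus set for one behavioural session
#'
#' Describes the signal levels available within a session under one of the
#' three data-collection methods. Method of Limits sessions carry exactly
#' one signal level; Method of Constant Stimuli sessions carry a preset
#' group of levels (4-6 by convention); adaptive tracking starts from a
#' single level that the staircase then moves.
#'
#' @param method One of `"limits"`, `"constant"`, `"adaptive"`.
#' @param signal_levels Numeric vector of tone levels, dB SPL.
#' @param noise_level Masker level, dB SPL; SNR of a level is
#'   `signal_level - noise_level`.
#' @param n_levels_bounds Allowed number of levels for the constant method
#'   (inclusive bounds, default 4-6).
#'
#' @return An object of class `stimulus_set`.
#' @export
stimulus_set <- function(method = c("limits", "constant", "adaptive"),
                         signal_levels, noise_level = 0,
                         n_levels_bounds = c(4L, 6L)) {
  method <- match.arg(method)
  stopifnot(is.numeric(signal_levels), length(signal_levels) >= 1L,
            !anyNA(signal_levels), is.numeric(noise_level),
            length(noise_level) == 1L)
  if (method %in% c("limits", "adaptive") && length(signal_levels) != 1L)
    stop("method '", method, "' requires exactly one signal level, got ",
         length(signal_levels))
  if (method == "constant" &&
      (length(signal_levels) < n_levels_bounds[1] ||
       length(signal_levels) > n_levels_bounds[2]))
    stop("method 'constant' requires between ", n_levels_bounds[1], " and ",
         n_levels_bounds[2], " signal levels, got ", length(signal_levels))
  structure(list(method = method,
                 signal_levels = as.numeric(signal_levels),
                 noise_level = noise_level),
            class = "stimulus_set")
}

#' @export
print.stimulus_set <- function(x, ...) {
  cat(sprintf("Stimulus set (%s): levels %s dB SPL, noise %.4g dB SPL\n",
              x$method, paste(round(x$signal_levels, 2), collapse = ", "),
              x$noise_level))
  invisible(x)
}

#' Signal-to-noise ratios of a stimulus set
#'
#' @param stimuli A [stimulus_set()].
#' @return Numeric vector, `signal_levels - noise_level` in dB.
#' @export
snr <- function(stimuli) {
  stopifnot(inherits(stimuli, "stimulus_set"))
  stimuli$signal_levels - stimuli$noise_level
}

#' Draw internal representation values
#'
#' Samples the observer's internal variable: `level + N(0, internal_sd)` on
#' signal trials, `reference_level + N(0, internal_sd)` on no-signal trials.
#' Consumes the global RNG stream; seed with [set.seed()] for
#' reproducibility.
#'
#' @param trial_type `"signal"` or `"nosignal"`.
#' @param level Signal level in dB SPL; required for (and only used by)
#'   signal trials.
#' @param params An [observer_params()] object.
#' @param n Number of draws.
#' @return Numeric vector of internal values, dB.
#' @export
sample_internal_value <- function(trial_type = c("signal", "nosignal"),
                                  level = NULL, params, n = 1L) {
  trial_type <- match.arg(trial_type)
  stopifnot(inherits(params, "observer_params"))
  if (trial_type == "signal") {
    if (is.null(level) || !is.finite(level))
      stop("a finite `level` is required on signal trials")
    mu <- level
  } else {
    mu <- params$reference_level
  }
  mu + stats::rnorm(n, 0, params$internal_sd)
}

#' Closed-form hit and false-alarm probabilities
#'
#' Analytic expected rates for a fixed decision criterion under the
#' equal-variance Gaussian observer: `P(hit) = 1 - pnorm((c - level)/sd)` and
#' `P(fa) = 1 - pnorm((c - reference)/sd)`. With a non-zero guess rate g each
#' probability becomes `(1 - g) * p + g/2`.
#'
#' @param criterion Decision criterion, dB.
#' @param level Signal level, dB SPL (vectorised).
#' @param params An [observer_params()] object.
#' @return A `rate_pair` list with elements `hit_rate` and `fa_rate`
#'   (probabilities; counts unset).
#' @export
expected_rates <- function(criterion, level, params) {
  stopifnot(inherits(params, "observer_params"))
  s <- params$internal_sd
  g <- params$guess_rate
  hit <- 1 - stats::pnorm((criterion - level) / s)
  fa <- 1 - stats::pnorm((criterion - params$reference_level) / s)
  rate_pair(hit_rate = (1 - g) * hit + g / 2,
            fa_rate = (1 - g) * fa + g / 2)
}

#' Hit/false-alarm rate pair
#'
#' @param hit_rate,fa_rate Proportions in `[0, 1]`.
#' @param n_signal,n_nosignal Trial counts behind the rates (`NA` for
#'   analytic probabilities).
#' @return An object of class `rate_pair`.
#' @export
rate_pair <- function(hit_rate, fa_rate, n_signal = NA_integer_,
                      n_nosignal = NA_integer_) {
  if (any(hit_rate < 0 | hit_rate > 1, na.rm = TRUE) ||
      any(fa_rate < 0 | fa_rate > 1, na.rm = TRUE))
    stop("rates must lie in [0, 1]")
  if (any(stats::na.omit(c(n_signal, n_nosignal)) < 0))
    stop("counts must be non-negative")
  structure(list(hit_rate = hit_rate, fa_rate = fa_rate,
                 n_signal = n_signal, n_nosignal = n_nosignal),
            class = "rate_pair")
}

#' Reward-optimal decision criterion
#'
#' The optimal criterion places `P(false alarm) = P(miss)` for the session's
#' stimulus set. For a single signal level (Method of Limits) this is the
#' midpoint of the no-signal and signal distributions, `(reference + L)/2`.
#' For several levels (Method of Constant Stimuli) the signal distribution is
#' the equal-weight mixture of the per-level Gaussians and the criterion
#' solves `1 - pnorm((c - ref)/sd) = mean_j pnorm((c - L_j)/sd)` numerically;
#' it then lies below the midpoint between the reference and the mean level.
#'
#' @param stimuli A [stimulus_set()].
#' @param params An [observer_params()] object.
#' @param tol Absolute tolerance on the criterion root, dB.
#' @return Criterion in dB; the residual `|P(fa) - P(miss)|` is at most
#'   `1e-9`.
#' @export
optimal_criterion <- function(stimuli, params, tol = 1e-12) {
  stopifnot(inherits(stimuli, "stimulus_set"),
            inherits(params, "observer_params"))
  L <- stimuli$signal_levels
  ref <- params$reference_level
  s <- params$internal_sd
  if (length(L) == 1L)
    return((ref + L) / 2)
  f <- function(c) (1 - stats::pnorm((c - ref) / s)) -
    mean(stats::pnorm((c - L) / s))
  lo <- min(ref, min(L)) - 10 * s
  hi <- max(L) + 10 * s
  if (f(lo) <= 0 || f(hi) >= 0) {
    # widen once before giving up; both sides are strictly monotone in c
    lo <- min(ref, min(L)) - 20 * s
    hi <- max(L) + 20 * s
    if (f(lo) <= 0 || f(hi) >= 0)
      stop("failed to bracket the optimal criterion within ref +/- 20 sd")
  }
  root <- stats::uniroot(f, c(lo, hi), tol = tol)$root
  if (abs(f(root)) > 1e-9)
    stop("optimal criterion residual exceeds 1e-9")
  root
}

#' Sensitivity index d-prime
#'
#' `d' = qnorm(H) - qnorm(FA)`. Rates of exactly 0 or 1 are clipped to
#' `1/(2N)` and `1 - 1/(2N)` using the corresponding trial count, which keeps
#' d-prime finite and ties the clipping to the amount of data.
#'
#' @param hit_rate,fa_rate Proportions, or a single [rate_pair()] passed as
#'   `hit_rate`.
#' @param n_signal,n_nosignal Trial counts, needed only when a rate is
#'   exactly 0 or 1.
#' @return d-prime (scalar or vector).
#' @export
dprime <- function(hit_rate, fa_rate = NULL, n_signal = NULL,
                   n_nosignal = NULL) {
  if (inherits(hit_rate, "rate_pair")) {
    rp <- hit_rate
    hit_rate <- rp$hit_rate
    fa_rate <- rp$fa_rate
    if (is.null(n_signal)) n_signal <- rp$n_signal
    if (is.null(n_nosignal)) n_nosignal <- rp$n_nosignal
  }
  stats::qnorm(clip_rate(hit_rate, n_signal, "hit")) -
    stats::qnorm(clip_rate(fa_rate, n_nosignal, "false-alarm"))
}

clip_rate <- function(p, n, what) {
  at_edge <- p <= 0 | p >= 1
  if (!any(at_edge)) return(p)
  if (is.null(n) || anyNA(n[at_edge]) || any(n[at_edge] <= 0))
    stop(what, " rate of 0 or 1 cannot be clipped without its trial count")
  n <- rep_len(n, length(p))
  p <- pmax(p, 1 / (2 * n))
  pmin(p, 1 - 1 / (2 * n))
}

#' Maximum proportion correct for an unbiased observer
#'
#' `P(c)max = pnorm(d'/2)`: the percentage correct an unbiased observer
#' would achieve at a given sensitivity. Monotone increasing in d-prime.
#'
#' @param dprime_value Sensitivity index (vectorised).
#' @return Proportions in `[0, 1]`.
#' @export
pcmax <- function(dprime_value) stats::pnorm(dprime_value / 2)
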