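#' Reward earned as a function of the decision criterion
#'
#' The deterministic reward model: signal and no-signal Gaussian
#' distributions bisected by a static criterion, no guessing and no
#' history. Sweeping the criterion c over a grid gives, with equal numbers
#' of signal and no-signal trials and levels presented equally often,
#'
#' `P(yes)   = 0.5 * mean_j(1 - pnorm((c - L_j)/sd)) +
#'             0.5 * (1 - pnorm((c - ref)/sd))`
#' `reward   = 0.5 * mean_j(1 - pnorm((c - L_j)/sd)) +
#'             0.5 * pnorm((c - ref)/sd)`
#'
#' (reward 1 means 100% correct). The reward gradient with respect to
#' P(yes) is computed by centred finite differences along the swept curve.
#'
#' @param stimuli A [stimulus_set()]; a single level corresponds to a
#'   Method of Limits session, several levels to Constant Stimuli.
#' @param params An [observer_params()]; only `internal_sd` and
#'   `reference_level` enter the deterministic model.
#' @param grid Criterion grid, dB; default `ref - 4*sd` to
#'   `max(level) + 4*sd` in 0.05 dB steps.
#' @return A `data.frame` of class `reward_curve` with columns `criterion`,
#'   `p_yes`, `reward`, `gradient`; `p_yes` is strictly decreasing in the
#'   criterion. A warning is given when the grid fails to cover P(yes) in
#'   (0.01, 0.99).
#' @examples
#' p <- observer_params(9.2, 37.35)
#' rc <- reward_curve(stimulus_set("limits", 47.35, 48), p)
#' argmax_reward(rc)  # P(yes) = 0.5 at the midpoint criterion
#' @export
reward_curve <- function(stimuli, params, grid = NULL) {
  stopifnot(inherits(stimuli, "stimulus_set"),
            inherits(params, "observer_params"))
  s <- params$internal_sd
  ref <- params$reference_level
  L <- stimuli$signal_levels
  if (is.null(grid))
    grid <- seq(ref - 4 * s, max(L) + 4 * s, by = 0.05)
  p_sig <- vapply(grid, function(c) mean(1 - stats::pnorm((c - L) / s)),
                  numeric(1))
  p_fa <- 1 - stats::pnorm((grid - ref) / s)
  p_yes <- 0.5 * p_sig + 0.5 * p_fa
  reward <- 0.5 * p_sig + 0.5 * (1 - p_fa)
  if (min(p_yes) > 0.01 || max(p_yes) < 0.99)
    warning("criterion grid covers P(yes) in [", round(min(p_yes), 3),
            ", ", round(max(p_yes), 3),
            "]; widen it to span (0.01, 0.99)")
  n <- length(grid)
  gradient <- rep(NA_real_, n)
  gradient[2:(n - 1)] <- (reward[3:n] - reward[1:(n - 2)]) /
    (p_yes[3:n] - p_yes[1:(n - 2)])
  gradient[1] <- gradient[2]
  gradient[n] <- gradient[n - 1]
  out <- data.frame(criterion = grid, p_yes = p_yes, reward = reward,
                    gradient = gradient)
  attr(out, "stimuli") <- stimuli
  attr(out, "params") <- params
  class(out) <- c("reward_curve", "data.frame")
  out
}

reward_fun <- function(curve) {
  st <- attr(curve, "stimuli")
  p <- attr(curve, "params")
  function(c) {
    mean(1 - stats::pnorm((c - st$signal_levels) / p$internal_sd)) * 0.5 +
      0.5 * stats::pnorm((c - p$reference_level) / p$internal_sd)
  }
}

p_yes_fun <- function(curve) {
  st <- attr(curve, "stimuli")
  p <- attr(curve, "params")
  function(c) {
    0.5 * mean(1 - stats::pnorm((c - st$signal_levels) / p$internal_sd)) +
      0.5 * (1 - stats::pnorm((c - p$reference_level) / p$internal_sd))
  }
}

#' Criterion and P(yes) at the reward maximum
#'
#' Grid argmax refined by golden-section search on the analytic reward
#' function. For a single-level stimulus set the optimum is the midpoint
#' criterion `(reference + level)/2`, where P(yes) is exactly 0.5 by the
#' symmetry of the equal-variance Gaussians; the numerical optimum matches
#' it to better than 1e-6 dB.
#'
#' @param curve A [reward_curve()].
#' @return A list: `criterion` (dB), `p_yes`, `reward` at the maximum.
#' @export
argmax_reward <- function(curve) {
  stopifnot(inherits(curve, "reward_curve"))
  st <- attr(curve, "stimuli")
  p <- attr(curve, "params")
  rf <- reward_fun(curve)
  if (length(st$signal_levels) == 1L) {
    # closed form: P(fa) = P(miss) at the midpoint, P(yes) = 1/2 exactly
    c_star <- (p$reference_level + st$signal_levels) / 2
    return(list(criterion = c_star, p_yes = 0.5, reward = rf(c_star)))
  }
  i <- which.max(curve$reward)
  lo <- curve$criterion[max(1L, i - 2L)]
  hi <- curve$criterion[min(nrow(curve), i + 2L)]
  opt <- stats::optimize(rf, c(lo, hi), maximum = TRUE, tol = 1e-9)
  list(criterion = opt$maximum,
       p_yes = p_yes_fun(curve)(opt$maximum),
       reward = opt$objective)
}

#' Reward gradient at a given P(yes)
#'
#' Interpolates the finite-difference gradient of the reward curve at the
#' requested proportion of "yes" responses. The gradient is zero at the
#' reward maximum, changes sign across it, and is shallower at low SNR —
#' which is why criterion setting by reward feedback becomes unreliable for
#' hard stimuli.
#'
#' @param curve A [reward_curve()].
#' @param p_yes Proportion(s) of "yes" responses at which to evaluate.
#' @return Interpolated gradient value(s).
#' @export
gradient_at <- function(curve, p_yes) {
  stopifnot(inherits(curve, "reward_curve"))
  if (any(p_yes < min(curve$p_yes) | p_yes > max(curve$p_yes)))
    stop("p_yes outside the range covered by the curve")
  # p_yes decreases along the grid; approx() needs increasing x
  o <- order(curve$p_yes)
  stats::approx(curve$p_yes[o], curve$gradient[o], xout = p_yes,
                ties = mean)$y
}

#' Family of reward curves across SNRs, aligned at zero gradient
#'
#' Computes one reward curve per signal level and re-centres each curve's
#' P(yes) axis on its own reward maximum, so the gradients of different
#' SNRs can be compared at equal distances from the optimum.
#'
#' @param levels Signal levels, dB SPL (one curve each).
#' @param params An [observer_params()].
#' @param noise_level Masker level, dB SPL.
#' @return A `data.frame` with `level`, `snr`, `criterion`, `p_yes`,
#'   `p_yes_centred` (0 at the curve's own argmax), `reward`, `gradient`.
#' @export
reward_curve_family <- function(levels, params, noise_level = 0) {
  out <- lapply(levels, function(l) {
    rc <- reward_curve(stimulus_set("limits", l, noise_level), params)
    am <- argmax_reward(rc)
    data.frame(level = l, snr = l - noise_level,
               criterion = rc$criterion, p_yes = rc$p_yes,
               p_yes_centred = rc$p_yes - am$p_yes,
               reward = rc$reward, gradient = rc$gradient)
  })
  do.call(rbind, out)
}
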