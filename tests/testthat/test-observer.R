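test_that("observer_params validates its invariants", {
  expect_error(observer_params(0, 37.35), "positive")
  expect_error(observer_params(-1, 37.35), "positive")
  expect_error(observer_params(9.2, 37.35, guess_rate = 1.2), "guess_rate")
  expect_error(observer_params(9.2, 37.35, trial_shift_1 = -0.5),
               "non-negative")
  p <- observer_params(9.2, 37.35, 3.78, 0.01, 2, 1.5)
  expect_s3_class(p, "observer_params")
  expect_identical(p$internal_sd, 9.2)
})

test_that("stimulus sets enforce per-method level counts", {
  expect_error(stimulus_set("limits", c(40, 50)), "exactly one")
  expect_error(stimulus_set("constant", c(40, 50, 60)), "between 4 and 6")
  st <- stimulus_set("constant", c(40, 45, 50, 55), noise_level = 48)
  expect_equal(snr(st), c(-8, -3, 2, 7))
})

test_that("internal values have the stated means and spread", {
  p <- f2_params()
  # zero-noise limit pins the internal value to the distribution mean
  p0 <- f2_params(internal_sd = 1e-9)
  expect_equal(sample_internal_value("signal", 47.35, p0), 47.35,
               tolerance = 1e-6)
  expect_equal(sample_internal_value("nosignal", params = p0), 37.35,
               tolerance = 1e-6)
  expect_error(sample_internal_value("signal", level = NULL, params = p),
               "level")

  set.seed(101)
  x <- sample_internal_value("signal", 50, p, n = 1e5)
  se_mean <- 9.2 / sqrt(1e5)
  expect_lt(abs(mean(x) - 50), 3 * se_mean)
  se_sd <- 9.2 / sqrt(2 * (1e5 - 1))
  expect_lt(abs(sd(x) - 9.2), 3 * se_sd)
})

test_that("expected rates match the Gaussian closed form", {
  p <- f2_params(criterion_bias = 0, guess_rate = 0,
                 trial_shift_1 = 0, trial_shift_2 = 0)
  # degenerate criteria saturate both rates
  lo <- expected_rates(-1e6, 47.35, p)
  hi <- expected_rates(1e6, 47.35, p)
  expect_equal(c(lo$hit_rate, lo$fa_rate), c(1, 1))
  expect_equal(c(hi$hit_rate, hi$fa_rate), c(0, 0))
  # midpoint criterion: equal-variance symmetry gives P(hit) = 1 - P(fa)
  mid <- expected_rates(42.35, 47.35, p)
  expect_equal(mid$hit_rate, 1 - mid$fa_rate)
  expect_equal(mid$hit_rate, 0.7065997227, tolerance = 1e-9)

  # guessing mixes each probability with a fair coin
  pg <- f2_params(criterion_bias = 0, guess_rate = 0.2,
                  trial_shift_1 = 0, trial_shift_2 = 0)
  g <- expected_rates(42.35, 47.35, pg)
  expect_equal(g$hit_rate, 0.8 * mid$hit_rate + 0.1)
})

test_that("Monte-Carlo rates converge to the closed form", {
  p <- f2_params(guess_rate = 0, trial_shift_1 = 0, trial_shift_2 = 0)
  crit <- 44
  level <- 47.35
  n <- 1e5
  set.seed(202)
  hit_mc <- mean(sample_internal_value("signal", level, p, n = n) > crit)
  fa_mc <- mean(sample_internal_value("nosignal", params = p, n = n) > crit)
  an <- expected_rates(crit, level, p)
  expect_lt(abs(hit_mc - an$hit_rate),
            3 * sqrt(an$hit_rate * (1 - an$hit_rate) / n))
  expect_lt(abs(fa_mc - an$fa_rate),
            3 * sqrt(an$fa_rate * (1 - an$fa_rate) / n))
})

test_that("optimal criterion solves P(fa) = P(miss)", {
  p <- observer_params(9.2, 37.35)
  # single level: exact midpoint
  expect_identical(optimal_criterion(stimulus_set("limits", 47.35, 48), p),
                   (37.35 + 47.35) / 2)
  # a constant-stimuli set collapsed to one level reduces to the midpoint
  p10 <- observer_params(10, 30)
  st1 <- stimulus_set("constant", rep(40, 4), n_levels_bounds = c(4, 6))
  expect_equal(optimal_criterion(st1, p10), 35, tolerance = 1e-8)

  # two-level mixture against an independent bisection oracle
  st <- stimulus_set("constant", c(35, 45), n_levels_bounds = c(2, 6))
  c_star <- optimal_criterion(st, p10)
  f <- function(c) (1 - pnorm((c - 30) / 10)) -
    0.5 * (pnorm((c - 35) / 10) + pnorm((c - 45) / 10))
  lo <- -70; hi <- 145
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) lo <- mid else hi <- mid
  }
  expect_equal(c_star, (lo + hi) / 2, tolerance = 1e-7)
  # residual and position below the midpoint of reference and mean level
  expect_lt(abs(f(c_star)), 1e-9)
  expect_lt(c_star, (30 + 40) / 2)
})

test_that("d-prime follows the quantile definition with 1/(2N) clipping", {
  expect_equal(dprime(0.3, 0.3), 0)
  expect_equal(dprime(0.8413, 0.1587), 2, tolerance = 1e-3)
  # perfect hit rate clipped by trial count before the quantile transform
  expect_equal(dprime(1, 0.5, n_signal = 50), qnorm(0.99) - qnorm(0.5))
  expect_equal(dprime(0, 0, n_signal = 50, n_nosignal = 50),
               qnorm(0.01) - qnorm(0.01))
  expect_error(dprime(1, 0.5), "trial count")
  rp <- rate_pair(1, 0, n_signal = 25, n_nosignal = 50)
  expect_equal(dprime(rp), qnorm(1 - 1 / 50) - qnorm(1 / 100))
})

test_that("pcmax is the unbiased-observer percent correct", {
  expect_equal(pcmax(0), 0.5)
  expect_equal(pcmax(1e3), 1.0)
  expect_equal(pcmax(2), pnorm(1))
  expect_true(all(diff(pcmax(seq(-3, 3, 0.5))) > 0))
  # round trip: an unbiased observer with H = 1 - FA recovers H
  for (h in c(0.55, 0.71, 0.9, 0.99))
    expect_equal(pcmax(dprime(h, 1 - h)), h, tolerance = 1e-12)
})

test_that("aggregated d-prime is invariant to criterion bias", {
  base <- f2_params(criterion_bias = 0, guess_rate = 0,
                    trial_shift_1 = 0, trial_shift_2 = 0)
  shifted <- f2_params(criterion_bias = 5, guess_rate = 0,
                       trial_shift_1 = 0, trial_shift_2 = 0)
  level <- 47.35
  n <- 1e5
  est <- function(p, seed) {
    set.seed(seed)
    c_use <- optimal_criterion(stimulus_set("limits", level, 48), p) +
      p$criterion_bias
    h <- mean(sample_internal_value("signal", level, p, n = n) > c_use)
    f <- mean(sample_internal_value("nosignal", params = p, n = n) > c_use)
    dprime(h, f, n, n)
  }
  d0 <- est(base, 31)
  d5 <- est(shifted, 32)
  expect_lt(abs(d0 - d5), 0.05)  # ~3x the Monte-Carlo s.e. of the difference
  expect_equal(d0, (level - 37.35) / 9.2, tolerance = 0.05)
})

test_that("rate pairs reject invalid rates and counts", {
  expect_error(rate_pair(1.2, 0.1), "rates")
  expect_error(rate_pair(0.5, 0.1, n_signal = -2), "counts")
})
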