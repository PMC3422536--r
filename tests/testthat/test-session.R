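test_that("a separable observer makes no errors and no corrections", {
  p <- f2_params(internal_sd = 1e-3, criterion_bias = 0, guess_rate = 0,
                 trial_shift_1 = 0, trial_shift_2 = 0)
  cfg <- session_config(stimulus_set("limits", 37.35 + 1, 48), 30, 30,
                        seed = 1)
  log <- run_session(cfg, p)
  expect_equal(sort(unique(log$outcome)), c("correct_rejection", "hit"))
  expect_false(any(log$is_correction))
  expect_equal(nrow(log), 60)
})

test_that("a pure guesser answers yes half the time on both trial types", {
  p <- f2_params(guess_rate = 1, trial_shift_1 = 0, trial_shift_2 = 0)
  cfg <- session_config(stimulus_set("limits", 80, 48), 400, 400,
                        use_correction_trials = FALSE, seed = 2)
  log <- run_session(cfg, p)
  for (tt in c("signal", "nosignal")) {
    yes <- log$response[log$trial_type == tt] == "yes"
    expect_lt(abs(mean(yes) - 0.5), 3 * sqrt(0.25 / length(yes)))
  }
})

test_that("outcome bookkeeping is internally consistent", {
  set.seed(3)
  log <- limits_sessions(3, 42, f2_params())
  # outcome consistency with type and response
  expect_true(all(log$outcome[log$trial_type == "signal" &
                                log$response == "yes"] == "hit"))
  expect_true(all(log$outcome[log$trial_type == "nosignal" &
                                log$response == "no"] ==
                    "correct_rejection"))
  expect_identical(log$rewarded,
                   log$outcome %in% c("hit", "correct_rejection"))
  # conservation per session, on analysis trials
  for (d in split(analysis_trials(log), log$session_id[!log$is_correction &
                                                         !log$centre_reward])) {
    tab <- table(d$outcome)
    expect_equal(sum(tab[c("hit", "miss")], na.rm = TRUE),
                 sum(d$trial_type == "signal"))
    expect_equal(sum(tab[c("correct_rejection", "false_alarm")],
                     na.rm = TRUE),
                 sum(d$trial_type == "nosignal"))
  }
})

test_that("every error is followed by a matching correction trial", {
  set.seed(4)
  log <- limits_sessions(4, 40, f2_params())  # low SNR: plenty of errors
  for (d in split(log, log$session_id)) {
    n <- nrow(d)
    err <- d$outcome %in% c("miss", "false_alarm")
    # every error except a session-final one is followed by a correction
    # trial repeating the same stimulus
    inner <- which(err[-n])
    expect_true(all(d$is_correction[inner + 1]))
    expect_equal(d$trial_type[inner + 1], d$trial_type[inner])
    same_level <- is.na(d$level[inner]) |
      d$level[inner + 1] == d$level[inner]
    expect_true(all(same_level))
    # corrections only ever follow errors
    expect_true(all(err[which(d$is_correction) - 1]))
    # a signal trial never follows a false alarm
    after_fa <- which(d$outcome[-n] == "false_alarm") + 1
    expect_true(all(d$trial_type[after_fa] == "nosignal"))
  }
})

test_that("session logs are reproducible from (config, params, seed)", {
  p <- f2_params()
  cfg <- session_config(stimulus_set("constant", c(40, 45, 50, 55), 48),
                        seed = 77)
  expect_identical(run_session(cfg, p), run_session(cfg, p))
})

test_that("simulated rates with shifts disabled match the closed form", {
  p <- f2_params(trial_shift_1 = 0, trial_shift_2 = 0)
  level <- 37.35  # at the reference: hit and FA coincide in expectation
  cfg <- session_config(stimulus_set("limits", level, 48), 5000, 5000,
                        use_correction_trials = FALSE, seed = 6)
  rp <- session_rates(run_session(cfg, p))
  c_used <- (37.35 + level) / 2 + 3.78
  an <- expected_rates(c_used, level, p)
  se <- function(pr) sqrt(pr * (1 - pr) / 5000)
  expect_lt(abs(rp$hit_rate - an$hit_rate), 3 * se(an$hit_rate))
  expect_lt(abs(rp$fa_rate - an$fa_rate), 3 * se(an$fa_rate))
  expect_equal(an$hit_rate, an$fa_rate)  # level sits on the reference
})

test_that("criterion shifts follow the previous two responses", {
  p <- f2_params()
  cfg <- session_config(stimulus_set("limits", 45, 48), 40, 40, seed = 8)
  log <- run_session(cfg, p)
  c_base <- (37.35 + 45) / 2 + 3.78
  sgn <- ifelse(log$response == "yes", 1, -1)
  n <- nrow(log)
  expected <- c_base + c(0, 2 * sgn[-n]) +
    c(0, 0, 1.5 * sgn[-c(n - 1, n)])
  expect_equal(log$criterion_used, expected)
  # an incoming history state seeds the first two shifts
  log2 <- run_session(session_config(stimulus_set("limits", 45, 48),
                                     5, 5, seed = 9),
                      p, history = c("yes", "no"))
  expect_equal(log2$criterion_used[1], c_base + 2 - 1.5)
})

test_that("history-driven shifts raise P(yes) after a correct rejection", {
  p <- f2_params(criterion_bias = 0, guess_rate = 0,
                 trial_shift_1 = 3, trial_shift_2 = 0)
  # low SNR signal trials: a preceding CR (criterion lowered) must yield
  # more "yes" than a preceding hit (criterion raised)
  set.seed(10)
  raw <- limits_sessions(40, 40, p)
  p_yes_after <- function(prev_outcome) {
    num <- 0L; den <- 0L
    for (d in split(raw, raw$session_id)) {
      i <- which(d$outcome[-nrow(d)] == prev_outcome) + 1
      i <- i[d$trial_type[i] == "signal"]
      num <- num + sum(d$response[i] == "yes")
      den <- den + length(i)
    }
    num / den
  }
  expect_gt(p_yes_after("correct_rejection"), p_yes_after("hit"))
})

test_that("the counts-only fitting path reproduces run_session exactly", {
  # sim_session_counts mirrors run_session's dynamics and random-number
  # consumption, so the same seed must give identical analysis counts
  p <- f2_params()
  for (lv in c(42, 55)) {
    cfg <- session_config(stimulus_set("limits", lv, 48))
    set.seed(91)
    log <- analysis_trials(run_session(cfg, p))
    set.seed(91)
    ct <- sdtyesno:::sim_session_counts(p, lv, (37.35 + lv) / 2 + 3.78)
    sig <- log$trial_type == "signal"
    expect_identical(sum(log$response[sig] == "yes"), ct$sig_yes)
    expect_identical(sum(log$response[!sig] == "yes"), ct$nos_yes)
    expect_identical(sum(sig), ct$sig_n)
    expect_identical(sum(!sig), as.integer(ct$nos_n))
  }
})

test_that("degenerate always-wrong observers hit the correction cap", {
  # criterion far above every stimulus: signal trials are always misses,
  # so corrections repeat forever and the cap must fire
  p <- observer_params(1e-3, 0, criterion_bias = 1e6)
  cfg <- session_config(stimulus_set("limits", 10, 0), 5, 5,
                        max_trials = 50, seed = 11)
  expect_warning(log <- run_session(cfg, p), "max_trials")
  expect_equal(nrow(log), 50)
})
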