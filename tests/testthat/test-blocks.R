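test_that("limits staircase obeys its step rules and brackets threshold", {
  p <- f2_params()
  bc <- block_config("limits", start_level = 72, noise_level = 48)
  bl <- run_limits_block(bc, p, seed = 21)
  sched <- bl$schedule

  # steps in the level sequence are only 0, -10 or -5 dB
  steps <- diff(sched$level)
  expect_true(all(steps %in% c(0, -5, -10)))
  # start level held for at least two sessions
  expect_gte(sum(sched$level == 72), 2)
  # 5-dB-phase levels carry two or three sessions each
  small <- table(sched$level[sched$phase == "small_step"])
  expect_true(all(small %in% 2:3))
  # final tested levels bracket the analytic 71% point ref + 2*sd*z(0.71)
  pt71 <- 37.35 + 2 * 9.2 * qnorm(0.71)
  expect_lt(min(sched$level), pt71)
  expect_gt(max(sched$level), pt71)
  # the block stops because pooled performance fell below 71%
  last_level <- min(sched$level)
  pooled <- bl$trials[bl$trials$session_level == last_level, ]
  expect_lt(pcmax(dprime(session_rates(pooled))), 0.71)
})

test_that("a near-deterministic observer ends the staircase at the
           separability boundary", {
  p <- f2_params(internal_sd = 0.5, criterion_bias = 0, guess_rate = 0,
                 trial_shift_1 = 0, trial_shift_2 = 0)
  bc <- block_config("limits", start_level = 72, noise_level = 48)
  bl <- suppressWarnings(run_limits_block(bc, p, seed = 22))
  # with sd = 0.5 dB performance is perfect until the level approaches the
  # reference, then collapses; the staircase must terminate close to it
  # (within one big + one small step below, given the 10/5 dB quantisation)
  expect_lt(min(bl$schedule$level), 37.35 + 2 * 0.5 * qnorm(0.71) + 5)
  expect_gte(min(bl$schedule$level), 37.35 - 15)
})

test_that("staircases abort once levels sit 60 dB below the reference", {
  # a start level already deep below the observer's reference: the guard
  # must stop the block before it descends further
  p <- observer_params(9.2, 200, criterion_bias = 0, guess_rate = 0)
  bc <- block_config("limits", start_level = 72, noise_level = 48)
  w <- capture_warnings(
    bl <- run_limits_block(bc, p, seed = 23, n_signal_trials = 10L,
                           n_nosignal_trials = 10L))
  expect_true(any(grepl("60 dB below", w)))
  # only the start-level sessions were collected; no level below start
  expect_equal(min(bl$schedule$level), 72)
})

test_that("constant-stimuli blocks present the full set each session", {
  p <- f2_params()
  bc <- block_config("constant", level_set = c(42, 47, 52, 57, 72),
                     noise_level = 48)
  bl <- run_constant_block(bc, p, n_sessions = 4, seed = 24)
  expect_equal(nrow(bl$schedule), 4)
  t <- analysis_trials(bl$trials)
  for (d in split(t, t$session_id)) {
    expect_setequal(unique(d$level[d$trial_type == "signal"]),
                    c(42, 47, 52, 57, 72))
    # about half the trials are no-signal
    expect_lt(abs(mean(d$trial_type == "nosignal") - 0.5), 0.2)
  }
  # a set with nothing detectable warns
  bc_bad <- block_config("constant", level_set = c(30, 32, 34, 36),
                         noise_level = 48)
  expect_warning(run_constant_block(bc_bad, p, n_sessions = 1, seed = 25),
                 "easily detectable")
})

test_that("adaptive tracks follow the three-phase up-down rules", {
  p <- f2_params(guess_rate = 0, trial_shift_1 = 0, trial_shift_2 = 0)
  bc <- block_config("adaptive", start_level = 72, noise_level = 48)
  res <- run_adaptive_track(bc, p, seed = 26)
  tr <- res$track
  n <- nrow(tr)
  dl <- diff(tr$level)
  moved <- which(dl != 0)
  step_size <- c(6, 4, 2)
  for (i in moved) {
    expect_equal(abs(dl[i]), step_size[tr$phase[i]])
    if (dl[i] > 0) {
      # level only rises right after an incorrect response
      expect_false(tr$correct[i])
    } else {
      # level only falls after the required run of correct responses
      need <- if (tr$phase[i] == 1) 5 else 2
      expect_true(all(tr$correct[(i - need + 1):i]))
    }
  }
  # threshold is the mean of the final-phase reversal levels
  expect_equal(res$threshold, mean(res$reversal_levels))
  expect_equal(length(res$reversal_levels), 8)
})

test_that("a low-noise adaptive track converges near the boundary", {
  p <- f2_params(internal_sd = 1, criterion_bias = 0, guess_rate = 0,
                 trial_shift_1 = 0, trial_shift_2 = 0)
  bc <- block_config("adaptive", start_level = 72, noise_level = 48)
  res <- run_adaptive_track(bc, p, seed = 27)
  # with tiny internal noise the track oscillates around the reference,
  # where trials stop being separable; threshold within a final step + sd
  expect_lt(abs(res$threshold - 37.35), 6)
})

test_that("adaptive thresholds vary more than constant-stimuli ones on a
           matched trial budget", {
  p <- f2_params(trial_shift_1 = 0, trial_shift_2 = 0)
  bc_a <- block_config("adaptive", start_level = 72, noise_level = 48)
  set.seed(28)
  th_a <- replicate(12, run_adaptive_track(bc_a, p)$threshold)
  bc_c <- block_config("constant", level_set = c(42, 47, 52, 62, 72),
                       noise_level = 48)
  th_c <- replicate(12, {
    bl <- run_constant_block(bc_c, p, n_sessions = 2, n_signal_trials = 40,
                             n_nosignal_trials = 40)
    r <- suppressWarnings(aggregate_rates(bl, min_signal = 10,
                                          min_nosignal = 10))
    threshold_at(fit_logistic(r$level, r$pcmax))
  })
  expect_gt(sd(th_a), sd(th_c))
})
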