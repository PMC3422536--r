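test_that("a hand-checkable alternating log yields exact conditionals", {
  # nosignal(no), signal(yes) repeated: every signal trial follows a CR and
  # is a yes; every nosignal trial follows a hit and is a no
  log <- manual_log(rep(c("nosignal", "signal"), 8),
                    rep(c("no", "yes"), 8), level = 45)
  log$session_level <- 45
  tree <- build_dependency_tree(log, depth = 1, noise_level = 48)
  nd <- tree$nodes
  pick <- function(tt, prev) nd$p_yes[nd$trial_type == tt &
                                        !is.na(nd$prev1) &
                                        nd$prev1 == prev &
                                        is.na(nd$prev2)]
  expect_identical(pick("signal", "correct_rejection"), 1)
  expect_identical(pick("nosignal", "hit"), 0)
  # count-weighted children recompose the marginal P(yes)
  root_sig <- nd[nd$trial_type == "signal" & is.na(nd$prev1), ]
  kids <- nd[nd$trial_type == "signal" & !is.na(nd$prev1) &
               is.na(nd$prev2), ]
  expect_equal(sum(kids$n_yes) / sum(kids$n_trials),
               root_sig$n_yes / root_sig$n_trials)
})

test_that("signal-after-false-alarm paths are absent with corrections", {
  set.seed(51)
  log <- limits_sessions(6, 42, f2_params())
  tree <- build_dependency_tree(log, depth = 1, noise_level = 48)
  nd <- tree$nodes
  expect_false(any(nd$trial_type == "signal" & !is.na(nd$prev1) &
                     nd$prev1 == "false_alarm"))
})

test_that("shift-free simulations show no dependency; shifted ones do", {
  # null observer: after-CR and after-hit P(yes) agree within binomial CI
  p0 <- f2_params(trial_shift_1 = 0, trial_shift_2 = 0)
  set.seed(52)
  log0 <- limits_sessions(40, 42, p0)
  t0 <- build_dependency_tree(log0, depth = 1, noise_level = 48)
  nd0 <- t0$nodes
  get <- function(nd, prev) nd[nd$trial_type == "signal" &
                                 !is.na(nd$prev1) & nd$prev1 == prev &
                                 is.na(nd$prev2), ]
  cr <- get(nd0, "correct_rejection")
  hh <- get(nd0, "hit")
  pooled <- (cr$n_yes + hh$n_yes) / (cr$n_trials + hh$n_trials)
  se <- sqrt(pooled * (1 - pooled) * (1 / cr$n_trials + 1 / hh$n_trials))
  expect_lt(abs(cr$p_yes - hh$p_yes), 3 * se)

  # shifted observer at low SNR: a CR at i-1 lowers the criterion, so
  # P(yes|CR) - P(yes|Hit) > 0 on signal trials
  p1 <- f2_params()
  set.seed(53)
  log1 <- limits_sessions(40, 42, p1)
  t1 <- test_dependencies(build_dependency_tree(log1, depth = 1,
                                                noise_level = 48))
  nd1 <- t1$nodes
  expect_gt(get(nd1, "correct_rejection")$p_yes, get(nd1, "hit")$p_yes)
  sig_cmp <- t1$comparisons[t1$comparisons$trial_type == "signal", ]
  expect_lt(sig_cmp$p_adj, 0.05)
})

test_that("the dependency shrinks as SNR grows and the slope is negative", {
  p <- f2_params()
  set.seed(54)
  logs <- do.call(rbind, lapply(c(40, 45, 50, 58, 66), function(l) {
    x <- limits_sessions(12, l, p)
    x$session_id <- paste0(x$session_id, "_L", l)
    x
  }))
  tree <- build_dependency_tree(logs, depth = 1, noise_level = 48)
  sl <- dependency_slope(tree, trial_types = "signal")
  d <- sl$points$diff[order(sl$points$snr)]
  expect_gt(d[1], d[length(d)])  # larger effect at the lowest SNR
  expect_lt(sl$slope, 0)
  expect_gt(sl$f_statistic, 0)
})

test_that("the 2x2 chi-squared statistic matches the textbook formula", {
  log_a <- manual_log(rep("signal", 50), rep(c("yes", "no"), c(30, 20)))
  # counts (yes, no) = (30, 20) after CR vs (20, 30) after hit:
  # chi2 = N (ad - bc)^2 / (r1 r2 c1 c2) = 100 * 500^2 / 50^4 = 4
  m <- rbind(c(30, 20), c(20, 30))
  ct <- suppressWarnings(stats::chisq.test(m, correct = FALSE))
  n <- sum(m)
  hand <- n * (m[1, 1] * m[2, 2] - m[1, 2] * m[2, 1])^2 /
    prod(rowSums(m), colSums(m))
  expect_equal(unname(ct$statistic), hand)
  expect_equal(hand, 4)
})

test_that("identical branch counts give chi-squared 0 and p = 1", {
  # two sessions engineered so after-hit and after-CR counts coincide
  log <- manual_log(rep(c("nosignal", "signal", "signal", "signal"), 6),
                    rep(c("no", "yes", "yes", "no"), 6), level = 45)
  log$session_level <- 45
  tree <- test_dependencies(build_dependency_tree(log, depth = 1))
  cmp <- tree$comparisons
  same <- cmp[abs(cmp$p_yes_1 - cmp$p_yes_2) < 1e-12, ]
  if (nrow(same)) {
    expect_true(all(same$chisq < 1e-10))
    expect_true(all(same$p > 1 - 1e-10))
  }
  succeed()
})

test_that("Holm-corrected families control the family-wise error rate", {
  p0 <- f2_params(trial_shift_1 = 0, trial_shift_2 = 0, guess_rate = 0)
  set.seed(55)
  n_rep <- 150
  any_sig <- logical(n_rep)
  for (r in seq_len(n_rep)) {
    log <- limits_sessions(6, 44, p0, n_signal = 30L, n_nosignal = 30L)
    tree <- test_dependencies(build_dependency_tree(log, depth = 2,
                                                    noise_level = 48))
    cmp <- tree$comparisons
    any_sig[r] <- !is.null(cmp) && any(cmp$p_adj < 0.05, na.rm = TRUE)
  }
  fwer <- mean(any_sig)
  # each family tests several comparisons; Holm should keep the rate of
  # any-false-positive at or below alpha, within Monte-Carlo error
  expect_lt(fwer, 0.05 + 3 * sqrt(0.05 * 0.95 / n_rep))
})

test_that("two-back dependencies are recoverable from a depth-2 tree", {
  p <- f2_params(trial_shift_1 = 0, trial_shift_2 = 3)
  set.seed(56)
  log <- limits_sessions(40, 42, p)
  tree <- build_dependency_tree(log, depth = 2, noise_level = 48)
  nd <- tree$nodes
  two_back <- function(p1, p2) {
    x <- nd[nd$trial_type == "signal" & !is.na(nd$prev2) &
              nd$prev1 == p1 & nd$prev2 == p2, ]
    if (nrow(x) == 1) x$p_yes else NA_real_
  }
  # within the after-hit branch, a CR two back still lowers the criterion
  expect_gt(two_back("hit", "correct_rejection"), two_back("hit", "hit"))
})
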