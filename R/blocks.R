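#' Configuration for a block of sessions
#'
#' A block is a contiguous series of sessions collected under one method.
#' For the Method of Limits the across-session staircase is governed by
#' P(c)max landmarks: hold the start level for two sessions, drop 10 dB per
#' session while P(c)max stays at or above `mid_pc`, then 5 dB every other
#' session until the pooled P(c)max at a level falls below `stop_pc` (71%),
#' adding a third session at a level whenever its two sessions differ by
#' more than `variation_trigger`. Adaptive tracking uses a three-phase
#' transformed up-down rule (6 dB 1-up/5-down, then 4 dB 1-up/2-down, then
#' 2 dB 1-up/2-down after `reversal_switch` reversals).
#'
#' @param method `"limits"`, `"constant"` or `"adaptive"`.
#' @param start_level Starting tone level, dB SPL (limits/adaptive).
#' @param level_set Preset tone levels, dB SPL (constant method).
#' @param noise_level Masker level, dB SPL.
#' @param high_pc,mid_pc,stop_pc Staircase P(c)max landmarks (defaults 0.90,
#'   0.85, 0.71).
#' @param big_step,small_step Level decrements for the two Limits phases
#'   (10 and 5 dB).
#' @param variation_trigger Between-session P(c)max difference above which a
#'   third session is added at a level (0.10).
#' @param initial_step,main_step,final_step Adaptive-track step sizes
#'   (6, 4, 2 dB).
#' @param reversal_switch Number of main-phase reversals before switching to
#'   the final step size (midpoint 5 of the conventional 4-6).
#' @param n_final_reversals Final-phase reversals collected before the track
#'   stops (default 8); the threshold averages their levels.
#' @return An object of class `block_config`.
#' @export
block_config <- function(method = c("limits", "constant", "adaptive"),
                         start_level = NULL, level_set = NULL,
                         noise_level = 0,
                         high_pc = 0.90, mid_pc = 0.85, stop_pc = 0.71,
                         big_step = 10, small_step = 5,
                         variation_trigger = 0.10,
                         initial_step = 6, main_step = 4, final_step = 2,
                         reversal_switch = 5L, n_final_reversals = 8L) {
  method <- match.arg(method)
  if (method %in% c("limits", "adaptive") && is.null(start_level))
    stop("method '", method, "' requires `start_level`")
  if (method == "constant" && is.null(level_set))
    stop("method 'constant' requires `level_set`")
  stopifnot(big_step > 0, small_step > 0, initial_step > 0, main_step > 0,
            final_step > 0,
            high_pc > 0.5, high_pc < 1, mid_pc > 0.5, mid_pc < 1,
            stop_pc > 0.5, stop_pc < 1)
  structure(list(method = method, start_level = start_level,
                 level_set = level_set, noise_level = noise_level,
                 high_pc = high_pc, mid_pc = mid_pc, stop_pc = stop_pc,
                 big_step = big_step, small_step = small_step,
                 variation_trigger = variation_trigger,
                 initial_step = initial_step, main_step = main_step,
                 final_step = final_step,
                 reversal_switch = as.integer(reversal_switch),
                 n_final_reversals = as.integer(n_final_reversals)),
            class = "block_config")
}

session_pcmax <- function(trials) {
  # degenerate logs (e.g. a correction loop truncated at the trial cap can
  # leave a single trial type) count as floor performance for staircase
  # decisions rather than aborting the block
  tryCatch(pcmax(dprime(session_rates(trials))),
           error = function(e) 0)
}

new_session_block <- function(trials, schedule, method, block_id,
                              noise_level) {
  structure(list(trials = trials, schedule = schedule, method = method,
                 block_id = block_id, noise_level = noise_level),
            class = "session_block")
}

#' @export
print.session_block <- function(x, ...) {
  cat(sprintf("Session block '%s' (%s): %d sessions, %d trials\n",
              x$block_id, x$method, nrow(x$schedule), nrow(x$trials)))
  print(x$schedule, row.names = FALSE)
  invisible(x)
}

#' Simulate a Method of Limits block
#'
#' Runs the across-session descending staircase: two sessions at the start
#' level, then 10 dB down per session while the session P(c)max is at or
#' above `mid_pc`, then 5 dB down every other session (two sessions per
#' level, a third when the two differ by more than `variation_trigger`)
#' until the pooled P(c)max at a level falls below `stop_pc`.
#'
#' @param block A [block_config()] with `method = "limits"`.
#' @param params An [observer_params()].
#' @param n_signal_trials,n_nosignal_trials Per-session trial quotas.
#' @param use_correction_trials Passed to [session_config()].
#' @param seed Optional integer seed set once at block start; sessions then
#'   consume the RNG stream sequentially.
#' @param block_id Identifier prefixed to session ids.
#' @return A `session_block`: combined trial log (with a `session_level`
#'   column), plus a per-session `schedule` of levels, phases and P(c)max.
#' @export
run_limits_block <- function(block, params, n_signal_trials = 50L,
                             n_nosignal_trials = 50L,
                             use_correction_trials = TRUE, seed = NULL,
                             block_id = "b1") {
  stopifnot(inherits(block, "block_config"), block$method == "limits",
            inherits(params, "observer_params"))
  if (!is.null(seed)) set.seed(seed)
  ref <- params$reference_level
  floor_level <- ref - 60

  sessions <- list()
  sched <- list()
  k <- 0L
  run_one <- function(level, phase) {
    k <<- k + 1L
    cfg <- session_config(stimulus_set("limits", level,
                                       block$noise_level),
                          n_signal_trials, n_nosignal_trials,
                          use_correction_trials)
    log <- run_session(cfg, params,
                       session_id = sprintf("%s_s%02d", block_id, k))
    log$session_level <- level
    log$session_index <- k
    sessions[[k]] <<- log
    pc <- session_pcmax(log)
    sched[[k]] <<- data.frame(session_index = k,
                              session_id = log$session_id[1],
                              level = level, phase = phase, pcmax = pc,
                              stringsAsFactors = FALSE)
    pc
  }
  # a level tested with two sessions, plus a third if they disagree
  run_pair <- function(level, phase) {
    pc <- c(run_one(level, phase), run_one(level, phase))
    if (abs(pc[1] - pc[2]) > block$variation_trigger)
      pc <- c(pc, run_one(level, phase))
    pc
  }

  level <- block$start_level
  run_pair(level, "start")
  repeat {
    level <- level - block$big_step
    if (level < floor_level) {
      warning("limits staircase fell 60 dB below the reference level; ",
              "aborting block")
      break
    }
    pc <- run_one(level, "big_step")
    if (pc < block$mid_pc) break
  }
  while (level >= floor_level) {
    level <- level - block$small_step
    if (level < floor_level) {
      warning("limits staircase fell 60 dB below the reference level; ",
              "aborting block")
      break
    }
    pc <- run_pair(level, "small_step")
    # stopping decision uses the level's pooled sessions
    idx <- vapply(sched, function(s) s$level == level, logical(1))
    pooled <- do.call(rbind, sessions[idx])
    if (session_pcmax(pooled) < block$stop_pc) break
  }
  new_session_block(do.call(rbind, sessions), do.call(rbind, sched),
                    "limits", block_id, block$noise_level)
}

#' Simulate a Method of Constant Stimuli block
#'
#' Each session presents the full preset level set, signal trials drawing
#' their level uniformly, with 50% no-signal trials overall. A warning is
#' issued when no level in the set is easily detectable (expected P(c)max
#' below `high_pc` at every level), since suprathreshold trials are what
#' maintains stimulus control.
#'
#' @param block A [block_config()] with `method = "constant"`.
#' @param params An [observer_params()].
#' @param n_sessions Number of sessions in the block.
#' @inheritParams run_limits_block
#' @return A `session_block`.
#' @export
run_constant_block <- function(block, params, n_sessions = 3L,
                               n_signal_trials = 50L,
                               n_nosignal_trials = 50L,
                               use_correction_trials = TRUE, seed = NULL,
                               block_id = "b1") {
  stopifnot(inherits(block, "block_config"), block$method == "constant",
            inherits(params, "observer_params"), n_sessions >= 1L)
  if (!is.null(seed)) set.seed(seed)
  stim <- stimulus_set("constant", block$level_set, block$noise_level)
  exp_pc <- pcmax((stim$signal_levels - params$reference_level) /
                    params$internal_sd)
  if (max(exp_pc) < block$high_pc)
    warning("no easily detectable level in the set (max expected P(c)max ",
            round(max(exp_pc), 3), " < ", block$high_pc, ")")
  sessions <- vector("list", n_sessions)
  sched <- vector("list", n_sessions)
  for (k in seq_len(n_sessions)) {
    cfg <- session_config(stim, n_signal_trials, n_nosignal_trials,
                          use_correction_trials)
    log <- run_session(cfg, params,
                       session_id = sprintf("%s_s%02d", block_id, k))
    log$session_level <- NA_real_
    log$session_index <- k
    sessions[[k]] <- log
    sched[[k]] <- data.frame(session_index = k,
                             session_id = log$session_id[1],
                             level = NA_real_, phase = "constant",
                             pcmax = session_pcmax(log),
                             stringsAsFactors = FALSE)
  }
  new_session_block(do.call(rbind, sessions), do.call(rbind, sched),
                    "constant", block_id, block$noise_level)
}

#' Simulate an adaptive (transformed up-down) track
#'
#' Three-phase staircase within a single session: 6 dB steps with a
#' 1-up/5-down rule until the first incorrect response, then 4 dB steps with
#' 1-up/2-down until `reversal_switch` reversals have occurred, then 2 dB
#' steps with the same rule until `n_final_reversals` final-phase reversals
#' are collected. The threshold is the mean of the reversal levels in the
#' final phase. Correction trials are not used while tracking (the level
#' moves with every outcome), and the observer's optimal criterion tracks
#' the current level.
#'
#' @param block A [block_config()] with `method = "adaptive"`.
#' @param params An [observer_params()].
#' @param max_trials Safety cap on track length.
#' @param seed Optional integer seed.
#' @return A list with `track` (a `data.frame` of trial, level, phase,
#'   trial type, response, correctness and reversal flags),
#'   `reversal_levels` (final phase) and `threshold` (dB SPL).
#' @export
run_adaptive_track <- function(block, params, max_trials = 2000L,
                               seed = NULL) {
  stopifnot(inherits(block, "block_config"), block$method == "adaptive",
            inherits(params, "observer_params"))
  if (!is.null(seed)) set.seed(seed)
  ref <- params$reference_level
  sd <- params$internal_sd
  g <- params$guess_rate
  s1 <- params$trial_shift_1
  s2 <- params$trial_shift_2

  level <- block$start_level
  phase <- 1L              # 1: initial, 2: main, 3: final
  step <- block$initial_step
  need_down <- 5L          # 1-up/5-down initially
  consec <- 0L
  last_dir <- 0L           # -1 down, +1 up, 0 none yet
  n_rev_main <- 0L
  rev_final <- numeric(0)
  h1 <- 0; h2 <- 0

  lev <- numeric(max_trials); ph <- integer(max_trials)
  tt <- character(max_trials); rs <- character(max_trials)
  ok <- logical(max_trials); rv <- logical(max_trials)
  i <- 0L
  while (i < max_trials) {
    i <- i + 1L
    is_signal <- stats::runif(1) < 0.5
    crit <- (ref + level) / 2 + params$criterion_bias + s1 * h1 + s2 * h2
    iv <- (if (is_signal) level else ref) + sd * stats::rnorm(1)
    yes <- if (g > 0 && stats::runif(1) < g) stats::runif(1) < 0.5
           else iv > crit
    correct <- yes == is_signal
    lev[i] <- level; ph[i] <- phase
    tt[i] <- if (is_signal) "signal" else "nosignal"
    rs[i] <- if (yes) "yes" else "no"
    ok[i] <- correct
    h2 <- h1; h1 <- if (yes) 1 else -1

    moved <- 0L
    if (correct) {
      consec <- consec + 1L
      if (consec >= need_down) {
        level <- level - step
        consec <- 0L
        moved <- -1L
      }
    } else {
      level <- level + step
      consec <- 0L
      moved <- 1L
    }
    if (moved != 0L) {
      reversal <- last_dir != 0L && moved != last_dir
      rv[i] <- reversal
      if (phase == 1L && moved == 1L) {
        # first incorrect ends the initial descent
        phase <- 2L; step <- block$main_step; need_down <- 2L
      } else if (reversal && phase == 2L) {
        n_rev_main <- n_rev_main + 1L
        if (n_rev_main >= block$reversal_switch) {
          phase <- 3L; step <- block$final_step
        }
      } else if (reversal && phase == 3L) {
        rev_final <- c(rev_final, lev[i])
        if (length(rev_final) >= block$n_final_reversals) break
      }
      last_dir <- moved
    }
  }
  if (length(rev_final) < block$n_final_reversals)
    warning("adaptive track hit max_trials with only ", length(rev_final),
            " final-phase reversals")
  idx <- seq_len(i)
  list(track = data.frame(trial = idx, level = lev[idx], phase = ph[idx],
                          trial_type = tt[idx], response = rs[idx],
                          correct = ok[idx], reversal = rv[idx],
                          stringsAsFactors = FALSE),
       reversal_levels = rev_final,
       threshold = if (length(rev_final)) mean(rev_final) else NA_real_)
}
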