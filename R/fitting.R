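#' Observed per-level rates from a set of blocks
#'
#' Stacks the [aggregate_rates()] summaries of several blocks into the long
#' table the fitting stages consume.
#'
#' @param blocks A list of `session_block` objects (one method).
#' @param ... Passed to [aggregate_rates()].
#' @return A `data.frame` with a `block` column plus the per-level rate
#'   columns; attribute `method` records the data-collection method.
#' @export
observed_rates <- function(blocks, ...) {
  stopifnot(length(blocks) >= 1L,
            all(vapply(blocks, inherits, logical(1), "session_block")))
  method <- unique(vapply(blocks, `[[`, character(1), "method"))
  if (length(method) != 1L)
    stop("all blocks must share one data-collection method")
  out <- do.call(rbind, lapply(blocks, function(b) {
    r <- aggregate_rates(b, ...)
    cbind(block = b$block_id, as.data.frame(r))
  }))
  rownames(out) <- NULL
  attr(out, "method") <- method
  out
}

#' Mean squared error between observed and simulated rates
#'
#' Mean of squared differences over all hit-rate entries and all
#' false-alarm entries, each entry weighted equally. For the Method of
#' Limits every (block, level) row contributes one hit and one false-alarm
#' entry; for the Method of Constant Stimuli the false-alarm rate is a
#' single per-block entry (no-signal trials carry no level).
#'
#' @param observed,simulated `data.frame`s with matching `block`, `level`,
#'   `hit_rate` and `fa_rate` columns (row order is aligned on
#'   block + level).
#' @param method `"limits"` or `"constant"`.
#' @return Non-negative scalar loss.
#' @export
mse_loss <- function(observed, simulated, method = c("limits", "constant")) {
  method <- match.arg(method)
  key_o <- paste(observed$block, observed$level)
  key_s <- paste(simulated$block, simulated$level)
  m <- match(key_o, key_s)
  if (anyNA(m))
    stop("simulated rates are missing conditions: ",
         paste(key_o[is.na(m)], collapse = "; "))
  sim <- simulated[m, , drop = FALSE]
  hit_err <- (observed$hit_rate - sim$hit_rate)^2
  if (method == "limits") {
    fa_err <- (observed$fa_rate - sim$fa_rate)^2
  } else {
    first <- !duplicated(observed$block)
    fa_err <- (observed$fa_rate[first] - sim$fa_rate[first])^2
  }
  mean(c(hit_err, fa_err))
}

#' Mean simulated rates for a set of observed conditions
#'
#' Simulates `n_sim` sessions for every (block, level) condition of a
#' Method of Limits design, or `n_sim` whole sessions per block for the
#' Method of Constant Stimuli, and returns the session-averaged hit and
#' false-alarm rates in the same layout as [observed_rates()]. Per-block
#' criterion biases come from `biases` (recycled if scalar). Seed before
#' calling to use common random numbers across candidate parameter values.
#'
#' @param params An [observer_params()]; its `criterion_bias` is overridden
#'   per block by `biases`.
#' @param design A `data.frame` with columns `block` and `level` (observed
#'   conditions); for the constant method all levels of a block form its
#'   session level set.
#' @param method `"limits"` or `"constant"`.
#' @param biases Numeric vector of per-block criterion biases, named by
#'   block id (or a scalar).
#' @param noise_level Masker level, dB SPL.
#' @param n_sim Simulated sessions per condition (100 in the standard
#'   fitting protocol).
#' @param n_signal_trials,n_nosignal_trials Per-session quotas.
#' @return A `data.frame` with `block`, `level`, `hit_rate`, `fa_rate`.
#' @export
simulate_rates <- function(params, design, method = c("limits", "constant"),
                           biases = 0, noise_level = 0, n_sim = 100L,
                           n_signal_trials = 50L, n_nosignal_trials = 50L) {
  method <- match.arg(method)
  stopifnot(inherits(params, "observer_params"),
            all(c("block", "level") %in% names(design)))
  blocks <- unique(design$block)
  if (length(biases) == 1L && is.null(names(biases)))
    biases <- stats::setNames(rep(biases, length(blocks)), blocks)
  out <- list()
  for (b in blocks) {
    p_b <- params
    p_b$criterion_bias <- unname(biases[[b]])
    lv <- sort(unique(design$level[design$block == b]))
    if (method == "limits") {
      for (l in lv) {
        c_base <- (p_b$reference_level + l) / 2 + p_b$criterion_bias
        hs <- vapply(seq_len(n_sim), function(k) {
          # cap correction loops early: pathological candidates (criterion
          # far outside both distributions) would otherwise stall the fit
          ct <- sim_session_counts(p_b, l, c_base, n_signal_trials,
                                   n_nosignal_trials,
                                   cap = 8L * (n_signal_trials +
                                                 n_nosignal_trials))
          c(if (ct$sig_n > 0) ct$sig_yes / ct$sig_n else 0.5,
            if (ct$nos_n > 0) ct$nos_yes / ct$nos_n else 0.5)
        }, numeric(2))
        out[[length(out) + 1L]] <- data.frame(
          block = b, level = l, hit_rate = mean(hs[1, ]),
          fa_rate = mean(hs[2, ]), stringsAsFactors = FALSE)
      }
    } else {
      stim <- stimulus_set("constant", lv, noise_level,
                           n_levels_bounds = c(1L, 20L))
      c_base <- optimal_criterion(stim, p_b) + p_b$criterion_bias
      hit_acc <- numeric(length(lv)); n_acc <- numeric(length(lv))
      fa_acc <- 0
      for (k in seq_len(n_sim)) {
        ct <- sim_session_counts(p_b, lv, c_base, n_signal_trials,
                                 n_nosignal_trials,
                                 cap = 8L * (n_signal_trials +
                                               n_nosignal_trials))
        fa_acc <- fa_acc + ct$nos_yes / max(ct$nos_n, 1L)
        hit_acc <- hit_acc + ct$sig_yes
        n_acc <- n_acc + ct$sig_n
      }
      out[[length(out) + 1L]] <- data.frame(
        block = b, level = lv, hit_rate = hit_acc / n_acc,
        fa_rate = fa_acc / n_sim, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

loss_for <- function(params, observed, method, biases, noise_level, n_sim,
                     n_signal_trials, n_nosignal_trials, crn_seed) {
  set.seed(crn_seed)  # common random numbers across candidates
  sim <- simulate_rates(params, observed, method, biases, noise_level,
                        n_sim, n_signal_trials, n_nosignal_trials)
  mse_loss(observed, sim, method)
}

# method-of-moments criterion bias implied by a block's false-alarm rates:
# FA = 1 - pnorm((c - ref)/sd)  =>  c = ref + sd * qnorm(1 - FA)
implied_bias <- function(observed_block, sigma, ref, method, noise_level) {
  fa <- pmin(pmax(observed_block$fa_rate, 0.01), 0.99)
  c_impl <- ref + sigma * stats::qnorm(1 - fa)
  c_opt <- vapply(observed_block$level, function(l) {
    if (method == "limits") (ref + l) / 2
    else optimal_criterion(
      stimulus_set("constant", sort(unique(observed_block$level)),
                   noise_level, n_levels_bounds = c(1L, 20L)),
      observer_params(sigma, ref))
  }, numeric(1))
  mean(c_impl - c_opt)
}

#' Stage 1: fit internal s.d., reference level and per-block criterion bias
#'
#' Coarse grid map over (internal s.d., reference level) with the per-block
#' criterion bias initialised from the block's false-alarm rates, followed
#' by Nelder-Mead polish over all of (s.d., reference, biases). The trial
#' shifts and guess rate stay fixed at their initial values (2 dB, 1.5 dB,
#' 1% by convention). Every candidate is evaluated with common random
#' numbers (the same `crn_seed`) so the simulated loss surface is
#' deterministic.
#'
#' @param observed An [observed_rates()] table.
#' @param method `"limits"` or `"constant"` (defaults to the table's
#'   attribute).
#' @param noise_level Masker level, dB SPL.
#' @param init Fixed values for the non-fitted parameters:
#'   `trial_shift_1`, `trial_shift_2`, `guess_rate`.
#' @param sigma_grid,ref_grid Coarse grid values; defaults span 5-15 dB and
#'   the observed threshold region.
#' @param n_sim Simulated sessions per condition and candidate.
#' @param n_signal_trials,n_nosignal_trials Per-session quotas.
#' @param crn_seed Seed reused for every candidate evaluation.
#' @param maxit Nelder-Mead iteration cap.
#' @param reltol Nelder-Mead relative convergence tolerance on the loss.
#' @return A list of class `stage1_fit`: `params` (an [observer_params()]
#'   with the mean bias), `biases` (per block), `loss`, `grid` (the coarse
#'   map), `n_sim`.
#' @export
fit_stage1 <- function(observed, method = NULL, noise_level = 0,
                       init = list(trial_shift_1 = 2, trial_shift_2 = 1.5,
                                   guess_rate = 0.01),
                       sigma_grid = NULL, ref_grid = NULL, n_sim = 100L,
                       n_signal_trials = 50L, n_nosignal_trials = 50L,
                       crn_seed = 1L, maxit = 150L, reltol = 1e-5) {
  if (is.null(method)) method <- attr(observed, "method")
  method <- match.arg(method, c("limits", "constant"))
  blocks <- unique(observed$block)

  if (is.null(sigma_grid)) sigma_grid <- seq(5, 15, by = 2.5)
  if (is.null(ref_grid)) {
    # the reference must sit below levels the observer detects reliably
    lo <- min(observed$level) - 20
    hi <- max(observed$level[observed$hit_rate < 0.95],
              min(observed$level))
    ref_grid <- seq(lo, hi, length.out = 5)
  }

  mk_params <- function(sigma, ref) {
    observer_params(sigma, ref, 0, init$guess_rate,
                    init$trial_shift_1, init$trial_shift_2)
  }
  eval_cand <- function(sigma, ref, biases = NULL) {
    p <- mk_params(sigma, ref)
    if (is.null(biases)) {
      biases <- vapply(blocks, function(b) {
        implied_bias(observed[observed$block == b, , drop = FALSE],
                     sigma, ref, method, noise_level)
      }, numeric(1))
      names(biases) <- blocks
    }
    list(loss = loss_for(p, observed, method, biases, noise_level, n_sim,
                         n_signal_trials, n_nosignal_trials, crn_seed),
         biases = biases)
  }

  grid <- expand.grid(sigma = sigma_grid, ref = ref_grid)
  grid$loss <- NA_real_
  best <- NULL
  for (i in seq_len(nrow(grid))) {
    cand <- eval_cand(grid$sigma[i], grid$ref[i])
    grid$loss[i] <- cand$loss
    if (is.null(best) || cand$loss < best$loss)
      best <- c(cand, list(sigma = grid$sigma[i], ref = grid$ref[i]))
  }

  par0 <- c(log(best$sigma), best$ref, best$biases)
  obj <- function(par) {
    sigma <- exp(par[1])
    biases <- stats::setNames(par[-(1:2)], blocks)
    eval_cand(sigma, par[2], biases)$loss
  }
  opt <- stats::optim(par0, obj, method = "Nelder-Mead",
                      control = list(maxit = maxit, reltol = reltol))
  sigma <- exp(opt$par[1])
  ref <- opt$par[2]
  biases <- stats::setNames(opt$par[-(1:2)], blocks)
  params <- observer_params(sigma, ref, mean(biases), init$guess_rate,
                            init$trial_shift_1, init$trial_shift_2)
  structure(list(params = params, biases = biases, loss = opt$value,
                 grid = grid, n_sim = n_sim, crn_seed = crn_seed,
                 method = method, noise_level = noise_level),
            class = "stage1_fit")
}

#' Stage 2: fit the guess rate over a preset grid
#'
#' Holding the stage-1 parameters fixed, evaluates the simulated loss for a
#' preset range of guess-rate values (common random numbers) and returns
#' the best one. Stage-1 parameters are never modified.
#'
#' @param observed An [observed_rates()] table.
#' @param stage1 A `stage1_fit`.
#' @param grid Guess-rate proportions to try.
#' @param n_sim,n_signal_trials,n_nosignal_trials As in [fit_stage1()].
#' @return A list: `guess_rate`, `loss`, `trace` (loss per grid value).
#' @export
fit_stage2_guess <- function(observed, stage1,
                             grid = c(0, 0.01, 0.013, 0.02, 0.05, 0.1),
                             n_sim = NULL, n_signal_trials = 50L,
                             n_nosignal_trials = 50L) {
  stopifnot(inherits(stage1, "stage1_fit"))
  if (is.null(n_sim)) n_sim <- stage1$n_sim
  losses <- vapply(grid, function(g) {
    p <- stage1$params
    p$guess_rate <- g
    loss_for(p, observed, stage1$method, stage1$biases,
             stage1$noise_level, n_sim, n_signal_trials,
             n_nosignal_trials, stage1$crn_seed)
  }, numeric(1))
  best <- which.min(losses)
  list(guess_rate = grid[best], loss = losses[best],
       trace = data.frame(guess_rate = grid, loss = losses))
}

#' Stage 3: fit the trial-shift parameters against the dependency tree
#'
#' The trial shifts barely move session-level hit and false-alarm rates, so
#' they are fitted to an identifiable target instead: the after-hit and
#' after-correct-rejection conditional P(yes) values of the observed
#' dependency tree. A grid of (shift i-1, shift i-2) values is scored by
#' the squared error between observed and simulated conditional
#' probabilities (common random numbers), holding every other parameter
#' fixed.
#'
#' @param observed_tree A [build_dependency_tree()] of the observed trials
#'   (depth 1 suffices).
#' @param params Current [observer_params()] (stage-1/2 values; not
#'   modified).
#' @param design A `data.frame` of `block`, `level` conditions to simulate
#'   (typically the observed conditions).
#' @param method,noise_level,biases As in [simulate_rates()].
#' @param grid Candidate shift values in dB (applied to both lags).
#' @param n_sim Simulated sessions per condition and candidate.
#' @param n_signal_trials,n_nosignal_trials Per-session quotas.
#' @param crn_seed Common-random-number seed.
#' @return A list: `trial_shift_1`, `trial_shift_2`, `loss`, `trace`.
#' @export
fit_stage3_shifts <- function(observed_tree, params, design,
                              method = c("limits", "constant"),
                              noise_level = 0, biases = 0,
                              grid = seq(0, 5, by = 0.5), n_sim = 50L,
                              n_signal_trials = 50L,
                              n_nosignal_trials = 50L, crn_seed = 1L) {
  method <- match.arg(method)
  stopifnot(inherits(observed_tree, "dependency_tree"),
            inherits(params, "observer_params"))
  obs <- dep_targets(observed_tree)
  blocks <- unique(design$block)
  if (length(biases) == 1L && is.null(names(biases)))
    biases <- stats::setNames(rep(biases, length(blocks)), blocks)

  score <- function(s1, s2) {
    p <- params
    p$trial_shift_1 <- s1
    p$trial_shift_2 <- s2
    set.seed(crn_seed)
    sims <- list()
    for (b in blocks) {
      p_b <- p
      p_b$criterion_bias <- unname(biases[[b]])
      lv <- sort(unique(design$level[design$block == b]))
      for (l in lv) {
        cfg <- session_config(stimulus_set(method, if (method == "limits") l
                                           else lv, noise_level,
                                           n_levels_bounds = c(1L, 20L)),
                              n_signal_trials, n_nosignal_trials)
        sims[[length(sims) + 1L]] <-
          do.call(rbind, lapply(seq_len(n_sim), function(k) {
            log <- run_session(cfg, p_b, session_id = paste0(b, "_", l,
                                                             "_", k))
            log$session_level <- if (method == "limits") l else NA_real_
            log
          }))
        if (method == "constant") break  # one level set per block
      }
    }
    sim_tree <- build_dependency_tree(do.call(rbind, sims), depth = 1L)
    sim <- dep_targets(sim_tree)
    key_o <- paste(obs$trial_type, obs$level, obs$prev1)
    key_s <- paste(sim$trial_type, sim$level, sim$prev1)
    m <- match(key_o, key_s)
    ok <- !is.na(m)
    if (!any(ok)) stop("no overlapping dependency-tree nodes to score")
    mean((obs$p_yes[ok] - sim$p_yes[m[ok]])^2)
  }
  combos <- expand.grid(s1 = grid, s2 = grid)
  combos$loss <- mapply(score, combos$s1, combos$s2)
  best <- which.min(combos$loss)
  list(trial_shift_1 = combos$s1[best], trial_shift_2 = combos$s2[best],
       loss = combos$loss[best], trace = combos)
}

dep_targets <- function(tree) {
  nd <- tree$nodes
  nd[!is.na(nd$prev1) & is.na(nd$prev2) &
       nd$prev1 %in% c("hit", "correct_rejection"), , drop = FALSE]
}

#' Correlation-based goodness of fit
#'
#' Scores a fitted observer by the correlation protocol: each observed
#' block's per-level P(c)max, hit-rate and false-alarm values are
#' correlated against the session-averaged simulated values at matched
#' levels ("exp-sim" r^2), and the model is also correlated against itself
#' ("sim-sim") by repeatedly (100 times) drawing one simulated block of
#' sessions from the pool and correlating it with the mean of the
#' remainder, which bounds the attainable correlation under the protocol's
#' trial counts. False-alarm correlations are skipped for the Method of
#' Constant Stimuli, where no-signal trials carry no SNR.
#'
#' @param observed An [observed_rates()] table.
#' @param params A fitted [observer_params()].
#' @param method,noise_level,biases As in [simulate_rates()].
#' @param n_sim Simulated sessions per condition in the pool (200 per SNR
#'   for limits, 1000 for constant by convention).
#' @param n_draws Self-correlation draws (default 100).
#' @param n_signal_trials,n_nosignal_trials Per-session quotas.
#' @param seed Optional seed.
#' @return A list of class `fit_evaluation`: `exp_sim` and `sim_sim`, each
#'   with `r2_pcmax`, `r2_hits`, `r2_fa` (`NA` where not meaningful).
#' @export
evaluate_fit <- function(observed, params,
                         method = c("limits", "constant"),
                         noise_level = 0, biases = NULL, n_sim = NULL,
                         n_draws = 100L, n_signal_trials = 50L,
                         n_nosignal_trials = 50L, seed = NULL) {
  method <- match.arg(method)
  stopifnot(inherits(params, "observer_params"))
  if (!is.null(seed)) set.seed(seed)
  if (is.null(n_sim)) n_sim <- if (method == "limits") 200L else 1000L
  if (is.null(biases)) biases <- params$criterion_bias
  levels <- sort(unique(observed$level))

  # pool: per level, n_sim sessions' (pcmax, hit, fa)
  pool <- lapply(levels, function(l) {
    stim <- if (method == "limits")
      stimulus_set("limits", l, noise_level)
    else stimulus_set("constant", levels, noise_level,
                      n_levels_bounds = c(1L, 20L))
    cfg <- session_config(stim, n_signal_trials, n_nosignal_trials)
    p_b <- params
    p_b$criterion_bias <- if (length(biases) == 1L) biases else
      mean(unlist(biases))
    vapply(seq_len(n_sim), function(k) {
      log <- analysis_trials(run_session(cfg, p_b))
      sig <- log$trial_type == "signal" &
        (method == "limits" | log$level == l)
      nos <- log$trial_type == "nosignal"
      h <- mean(log$response[sig] == "yes")
      f <- mean(log$response[nos] == "yes")
      dp <- dprime(h, f, sum(sig), sum(nos))
      c(pcmax = pcmax(dp), hit = h, fa = f)
    }, numeric(3))
  })
  names(pool) <- as.character(levels)
  sim_mean <- vapply(pool, rowMeans, numeric(3))

  r2 <- function(x, y) {
    ok <- is.finite(x) & is.finite(y)
    if (sum(ok) < 3L || stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0)
      return(NA_real_)
    stats::cor(x[ok], y[ok])^2
  }
  m <- match(as.character(observed$level), colnames(sim_mean))
  obs_pc <- pcmax(dprime(observed$hit_rate, observed$fa_rate,
                         observed$n_signal, observed$n_nosignal))
  exp_sim <- list(
    r2_pcmax = r2(obs_pc, sim_mean["pcmax", m]),
    r2_hits = r2(observed$hit_rate, sim_mean["hit", m]),
    r2_fa = if (method == "constant") NA_real_
            else r2(observed$fa_rate, sim_mean["fa", m]))

  draw_r2 <- matrix(NA_real_, n_draws, 3)
  for (d in seq_len(n_draws)) {
    pick <- sample.int(n_sim, 1L)
    one <- vapply(pool, function(mat) mat[, pick], numeric(3))
    rest <- vapply(pool, function(mat) rowMeans(mat[, -pick, drop = FALSE]),
                   numeric(3))
    draw_r2[d, ] <- c(r2(one["pcmax", ], rest["pcmax", ]),
                      r2(one["hit", ], rest["hit", ]),
                      if (method == "constant") NA_real_
                      else r2(one["fa", ], rest["fa", ]))
  }
  sim_sim <- list(r2_pcmax = mean(draw_r2[, 1], na.rm = TRUE),
                  r2_hits = mean(draw_r2[, 2], na.rm = TRUE),
                  r2_fa = if (method == "constant") NA_real_
                          else mean(draw_r2[, 3], na.rm = TRUE))
  structure(list(exp_sim = exp_sim, sim_sim = sim_sim, n_sim = n_sim,
                 n_draws = n_draws, method = method),
            class = "fit_evaluation")
}

#' @export
print.fit_evaluation <- function(x, ...) {
  cat(sprintf("Fit evaluation (%s; %d sessions per condition)\n",
              x$method, x$n_sim))
  cat(sprintf("  exp-sim r2: pcmax %.3f, hits %.3f, fa %s\n",
              x$exp_sim$r2_pcmax, x$exp_sim$r2_hits,
              ifelse(is.na(x$exp_sim$r2_fa), "-",
                     sprintf("%.3f", x$exp_sim$r2_fa))))
  cat(sprintf("  sim-sim r2: pcmax %.3f, hits %.3f, fa %s\n",
              x$sim_sim$r2_pcmax, x$sim_sim$r2_hits,
              ifelse(is.na(x$sim_sim$r2_fa), "-",
                     sprintf("%.3f", x$sim_sim$r2_fa))))
  invisible(x)
}
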