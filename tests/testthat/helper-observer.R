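# Shared fixtures: the ferret-F2 Method-of-Limits observer and small
# simulation helpers. All randomness is seeded inside each test.

f2_params <- function(...) {
  defaults <- list(internal_sd = 9.2, reference_level = 37.35,
                   criterion_bias = 3.78, guess_rate = 0.01,
                   trial_shift_1 = 2, trial_shift_2 = 1.5)
  do.call(observer_params, utils::modifyList(defaults, list(...)))
}

# n sessions at one level, stacked with session_level metadata
limits_sessions <- function(n_sessions, level, params, noise_level = 48,
                            n_signal = 50L, n_nosignal = 50L,
                            use_correction = TRUE) {
  do.call(rbind, lapply(seq_len(n_sessions), function(k) {
    cfg <- session_config(stimulus_set("limits", level, noise_level),
                          n_signal, n_nosignal, use_correction)
    log <- run_session(cfg, params, session_id = sprintf("s%03d", k))
    log$session_level <- level
    log
  }))
}

# hand-built minimal trial log (already consistent outcome/reward fields)
manual_log <- function(trial_type, response, level = NA_real_,
                       session_id = "m1", is_correction = FALSE) {
  outcome <- ifelse(trial_type == "signal",
                    ifelse(response == "yes", "hit", "miss"),
                    ifelse(response == "yes", "false_alarm",
                           "correct_rejection"))
  data.frame(session_id = session_id,
             trial_index = seq_along(trial_type),
             trial_type = trial_type,
             level = ifelse(trial_type == "signal", level, NA_real_),
             is_correction = is_correction,
             internal_value = NA_real_, criterion_used = NA_real_,
             response = response, outcome = outcome,
             rewarded = outcome %in% c("hit", "correct_rejection"),
             centre_reward = FALSE, stringsAsFactors = FALSE)
}
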