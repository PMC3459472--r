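# Short steady-state protocol for module tests (acceptance tests use the
# package default of 20 s settle / 10 s analysis).
short_steady <- function(model, ...) {
  run_to_steady(model, settle_ms = 6000, window_ms = 4000, output_dt = 0.25, ...)
}

# Action set with exactly one ISO action enabled.
only_action <- function(dose, keep) {
  args <- as.list(stats::setNames(rep(FALSE, length(iso_action_names())),
                                  paste0("enable_", iso_action_names())))
  args[[paste0("enable_", keep)]] <- TRUE
  do.call(iso_action_set, c(list(dose = dose), args))
}

# Two-beat synthetic action-potential-like waveform with known features:
# period `cl` ms, minimum `mdp` mV, peak `peak` mV; upstroke is a sharp ramp.
synthetic_beats <- function(cl = 300, mdp = -65, peak = 20, n_beats = 4,
                            dt = 0.1, t0 = 0) {
  t <- seq(0, n_beats * cl, by = dt)
  phase <- (t %% cl) / cl
  v <- ifelse(phase < 0.05, mdp + (peak - mdp) * phase / 0.05,        # upstroke
       ifelse(phase < 0.35, peak - (peak - mdp) * (phase - 0.05) / 0.3, # repolarization
              mdp))                                                     # diastole
  out <- tibble::tibble(time = t + t0, vm = v)
  attr(out, "output_dt") <- dt
  class(out) <- c("san_trace", class(out))
  out
}
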