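# Shared simulation protocol, computed once per test run: the default
# fibre, its fully remyelinated counterpart, the propagation threshold of
# the fully remyelinated model, the 2x-threshold study stimulus, and the
# two uniform endpoint velocities. A 12 ms window comfortably covers the
# ~10-16 m/s velocities of this membrane model over the 80.5 mm span.

protocol_env <- new.env(parent = emptyenv())

study_protocol <- function() {
  if (!is.null(protocol_env$p)) {
    return(protocol_env$p)
  }
  cfg <- sim_config(t_total_ms = 12)
  base <- make_uniform_layout(120, 1150, 0.69)
  full <- remyelinate(base, 1)
  thr <- find_threshold(full, config = cfg)
  amp <- 2 * thr
  protocol_env$p <- list(
    base = base, full = full, threshold_nA = thr, amplitude_nA = amp,
    cv_long = simulate_cv(base, amp, config = cfg)$cv_m_per_s,
    cv_short = simulate_cv(full, amp, config = cfg)$cv_m_per_s,
    cfg = cfg
  )
  protocol_env$p
}

# reduced-ensemble configuration sharing the cached stimulus amplitude
ensemble_config <- function(n_models, master_seed = 20180112) {
  proto <- study_protocol()
  cfg <- default_config()
  cfg$study$n_models <- n_models
  cfg$study$master_seed <- master_seed
  cfg$simulation$t_total_ms <- 12
  cfg$stimulus$amplitude_nA <- proto$amplitude_nA
  cfg
}
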