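# Simulation protocol objects, integration wrapper, threshold-crossing
# detection and conduction-velocity measurement.

#' Stimulus protocol
#'
#' Rectangular current injection at a single node. The study protocol
#' injects twice the propagation threshold of the fully remyelinated fibre
#' for 0.1 ms.
#'
#' @param node 1-based node index of the stimulated node of Ranvier.
#' @param amplitude_nA Injected current, nA.
#' @param duration_ms Pulse duration, ms (default 0.1).
#' @param onset_ms Pulse onset, ms.
#' @return A `stimulus_protocol` list.
#' @export
stimulus_protocol <- function(node, amplitude_nA, duration_ms = 0.1,
                              onset_ms = 0) {
  node <- check_count(node, "node", lower = 1L)
  check_number(amplitude_nA, "amplitude_nA")
  check_number(duration_ms, "duration_ms", lower = 0, strict_lower = TRUE)
  check_number(onset_ms, "onset_ms", lower = 0)
  structure(list(node = node, amplitude_nA = amplitude_nA,
                 duration_ms = duration_ms, onset_ms = onset_ms),
            class = "stimulus_protocol")
}

#' Simulation configuration
#'
#' @param dt_ms Fixed integration time step, ms (default 5e-4).
#' @param t_total_ms Simulated duration, ms. The default 6 ms covers the
#'   default 80.5 mm recording span for conduction velocities above about
#'   15 m/s; [simulate_cv()] extends the window once (doubling it) if the
#'   distal electrode has not yet crossed threshold.
#' @param threshold_mV Detection threshold for spike timing, mV
#'   (default -40; crossing times are linearly interpolated).
#' @param v_init_mV Initial potential; defaults to the membrane model's
#'   resting potential.
#' @param auto_extend Whether [simulate_cv()] may double `t_total_ms` once.
#' @return A `sim_config` list.
#' @export
sim_config <- function(dt_ms = 5e-4, t_total_ms = 6, threshold_mV = -40,
                       v_init_mV = NULL, auto_extend = TRUE) {
  check_number(dt_ms, "dt_ms", lower = 0, strict_lower = TRUE)
  check_number(t_total_ms, "t_total_ms", lower = 0, strict_lower = TRUE)
  check_number(threshold_mV, "threshold_mV")
  check_number(v_init_mV, "v_init_mV", allow_null = TRUE)
  structure(list(dt_ms = dt_ms, t_total_ms = t_total_ms,
                 threshold_mV = threshold_mV, v_init_mV = v_init_mV,
                 auto_extend = isTRUE(auto_extend)),
            class = "sim_config")
}

#' Integrate a cable system
#'
#' Advances the assembled discrete cable under a stimulus with the
#' semi-implicit scheme (Crank-Nicolson coupling, Rush-Larsen gates,
#' explicit ionic current). Deterministic: identical inputs give
#' bit-identical traces.
#'
#' @param system A [assemble_cable()] system.
#' @param stimulus A [stimulus_protocol()].
#' @param config A [sim_config()].
#' @param record Compartment indices whose voltage traces to keep;
#'   default all node compartments. First threshold-crossing times are
#'   always computed for every compartment.
#' @param stop_at_node Optional 1-based node index: integration stops once
#'   this node crosses threshold (used for ensemble runs).
#' @return A `cable_sim` list: `time` (ms), `v` (matrix, one column per
#'   recorded compartment), `crossing_ms` (per compartment, `NA` if never
#'   crossed), plus the inputs.
#' @export
simulate_cable <- function(system, stimulus, config = sim_config(),
                           record = NULL, stop_at_node = NULL) {
  stopifnot(inherits(system, "cable_system"),
            inherits(stimulus, "stimulus_protocol"),
            inherits(config, "sim_config"))
  record <- record %||% system$node_comp
  if (stimulus$node > system$n_nodes) abort("stimulus node index out of range")
  stim_comp <- system$node_comp[stimulus$node]
  stop_comp <- if (is.null(stop_at_node)) 0L else {
    system$node_comp[check_count(stop_at_node, "stop_at_node", lower = 1L)]
  }
  v_init <- config$v_init_mV %||% system$membrane$v_rest
  n_steps <- as.integer(ceiling(config$t_total_ms / config$dt_ms))
  res <- cable_integrate_cpp(
    system$capacitance_nF, system$g_axial_uS, system$is_node,
    system$area_cm2, system$g_pas_uS, system$e_pas_mV,
    unclass(system$membrane), config$dt_ms, n_steps, v_init,
    config$threshold_mV, as.integer(record), as.integer(stim_comp),
    stimulus$amplitude_nA, stimulus$onset_ms, stimulus$duration_ms,
    as.integer(stop_comp)
  )
  keep <- seq_len(res$steps_done + 1L)
  structure(
    list(time = (keep - 1L) * config$dt_ms,
         v = res$v[keep, , drop = FALSE],
         record = record,
         crossing_ms = res$crossing_ms,
         steps_done = res$steps_done,
         system = system, stimulus = stimulus, config = config),
    class = "cable_sim"
  )
}

#' First upward threshold crossing of a voltage trace
#'
#' Linear interpolation between the two samples bracketing the first
#' upward crossing.
#'
#' @param trace Numeric vector of voltage samples (mV) taken every `dt`.
#' @param threshold Crossing threshold, mV.
#' @param dt Sampling interval, ms.
#' @return Crossing time in ms, or `NA_real_` if the trace never reaches
#'   threshold (no propagation).
#' @export
#' @examples
#' detect_crossing(c(-65, -30), threshold = -40, dt = 0.1) # 0.0714 ms
detect_crossing <- function(trace, threshold, dt) {
  stopifnot(is.numeric(trace), length(trace) >= 1)
  check_number(dt, "dt", lower = 0, strict_lower = TRUE)
  if (trace[1] > threshold) {
    abort("trace is already above threshold at t = 0")
  }
  hit <- which(trace >= threshold)
  if (length(hit) == 0) return(NA_real_)
  i <- hit[1]
  if (i == 1L) return(0)
  (i - 2) * dt + dt * (threshold - trace[i - 1]) / (trace[i] - trace[i - 1])
}

#' Conduction velocity between two recording nodes
#'
#' Physical separation of the recording nodes divided by the difference of
#' their first threshold-crossing times.
#'
#' @param system The simulated `cable_system`.
#' @param sim A [simulate_cable()] result for that system.
#' @param rec_nodes Two 1-based node indices (proximal, distal).
#' @return One-row tibble with `t1_ms`, `t2_ms`, `separation_um` and
#'   `cv_m_per_s`.
#' @export
measure_cv <- function(system, sim, rec_nodes) {
  stopifnot(inherits(system, "cable_system"), inherits(sim, "cable_sim"),
            length(rec_nodes) == 2)
  comp <- system$node_comp[rec_nodes]
  t1 <- sim$crossing_ms[comp[1]]
  t2 <- sim$crossing_ms[comp[2]]
  if (is.na(t1) || is.na(t2)) {
    abort("propagation failure: a recording electrode never crossed threshold")
  }
  sep <- system$position_um[comp[2]] - system$position_um[comp[1]]
  if (t2 <= t1) abort("distal electrode crossed before the proximal one")
  tibble(t1_ms = t1, t2_ms = t2, separation_um = sep,
         cv_m_per_s = sep / (t2 - t1) * 1e-3) # um/ms -> m/s
}

#' Simulate a layout and measure its conduction velocity
#'
#' High-level driver: resolves the electrodes on the layout, assembles the
#' cable, injects the stimulus at the stimulation node, integrates (with
#' early stopping once the distal electrode has crossed), and reports the
#' conduction velocity over the recording span. If the distal electrode
#' has not crossed within the configured window the window is doubled once
#' before declaring a propagation failure.
#'
#' @param layout An `axon_layout`.
#' @param amplitude_nA Stimulus amplitude, nA.
#' @param electrodes An [electrode_set()].
#' @param params A [fiber_params()].
#' @param membrane A [hh_model()].
#' @param config A [sim_config()].
#' @param duration_ms Stimulus duration, ms.
#' @param keep_sim Attach the full `cable_sim` as attribute `"sim"`.
#' @return One-row tibble as [measure_cv()], plus `stim_node`, `rec1_node`,
#'   `rec2_node`.
#' @export
simulate_cv <- function(layout, amplitude_nA,
                        electrodes = default_electrodes(),
                        params = fiber_params(), membrane = hh_model(),
                        config = sim_config(), duration_ms = 0.1,
                        keep_sim = FALSE) {
  el <- resolve_electrodes(layout, electrodes)
  system <- assemble_cable(layout, params, membrane)
  stim <- stimulus_protocol(el$node[1], amplitude_nA, duration_ms)
  run <- function(cfg) {
    simulate_cable(system, stim, cfg, record = system$node_comp[el$node],
                   stop_at_node = el$node[3])
  }
  sim <- run(config)
  if (is.na(sim$crossing_ms[system$node_comp[el$node[3]]]) &&
      config$auto_extend) {
    cfg2 <- config
    cfg2$t_total_ms <- 2 * config$t_total_ms
    sim <- run(cfg2)
  }
  out <- measure_cv(system, sim, el$node[2:3])
  out$stim_node <- el$node[1]
  out$rec1_node <- el$node[2]
  out$rec2_node <- el$node[3]
  if (keep_sim) attr(out, "sim") <- sim
  out
}

# does a 0.1 ms pulse of this amplitude elicit a crossing at the distal
# recording electrode?
propagates <- function(layout, amplitude_nA, electrodes, params, membrane,
                       config) {
  el <- resolve_electrodes(layout, electrodes)
  system <- assemble_cable(layout, params, membrane)
  stim <- stimulus_protocol(el$node[1], amplitude_nA)
  sim <- simulate_cable(system, stim, config, record = integer(0),
                        stop_at_node = el$node[3])
  crossed <- !is.na(sim$crossing_ms[system$node_comp[el$node[3]]])
  if (!crossed && config$auto_extend) {
    cfg2 <- config
    cfg2$t_total_ms <- 2 * config$t_total_ms
    sim <- simulate_cable(system, stim, cfg2, record = integer(0),
                          stop_at_node = el$node[3])
    crossed <- !is.na(sim$crossing_ms[system$node_comp[el$node[3]]])
  }
  crossed
}

#' Propagation threshold of a layout
#'
#' Minimal amplitude of a 0.1 ms rectangular pulse that elicits a
#' threshold crossing at the distal recording electrode, found by doubling
#' to bracket and bisection to a 1% relative tolerance. Returns the upper
#' (suprathreshold) end of the final bracket.
#'
#' @inheritParams simulate_cv
#' @param amplitude_init_nA Starting guess for the bracket search.
#' @param max_amplitude_nA Cap on the doubling search.
#' @param rel_tol Relative bracket width at termination.
#' @return Threshold amplitude in nA.
#' @export
find_threshold <- function(layout, electrodes = default_electrodes(),
                           params = fiber_params(), membrane = hh_model(),
                           config = sim_config(), amplitude_init_nA = 1,
                           max_amplitude_nA = 1024, rel_tol = 0.01) {
  go <- function(a) propagates(layout, a, electrodes, params, membrane, config)
  upper <- amplitude_init_nA
  while (!go(upper)) {
    upper <- 2 * upper
    if (upper > max_amplitude_nA) {
      abort(sprintf("no propagation up to %g nA", max_amplitude_nA))
    }
  }
  lower <- upper / 2
  while (lower > 0 && go(lower)) {
    upper <- lower
    lower <- lower / 2
    if (lower < 1e-6) break
  }
  while ((upper - lower) / upper > rel_tol) {
    mid <- (upper + lower) / 2
    if (go(mid)) upper <- mid else lower <- mid
  }
  upper
}

#' Time-step convergence of the conduction velocity
#'
#' Relative change of the measured conduction velocity when the time step
#' is halved: `|CV(dt/2) - CV(dt)| / CV(dt/2)`.
#'
#' @inheritParams simulate_cv
#' @return Relative change (dimensionless).
#' @export
convergence_check <- function(layout, amplitude_nA,
                              electrodes = default_electrodes(),
                              params = fiber_params(),
                              membrane = hh_model(),
                              config = sim_config()) {
  cv1 <- simulate_cv(layout, amplitude_nA, electrodes, params, membrane,
                     config)$cv_m_per_s
  cfg2 <- config
  cfg2$dt_ms <- config$dt_ms / 2
  cv2 <- simulate_cv(layout, amplitude_nA, electrodes, params, membrane,
                     cfg2)$cv_m_per_s
  abs(cv2 - cv1) / cv2
}

#' Dump recorded voltage traces to CSV
#'
#' Time column plus one column per recorded compartment.
#'
#' @param sim A [simulate_cable()] result.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_traces <- function(sim, path) {
  stopifnot(inherits(sim, "cable_sim"))
  df <- as.data.frame(sim$v)
  names(df) <- paste0("comp_", sim$record)
  readr::write_csv(dplyr::bind_cols(tibble(time_ms = sim$time), df), path)
  invisible(path)
}
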