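# Closed-form velocity theory for partially remyelinated axons:
# harmonic-mean benchmark velocity, sqrt(internode length) scaling, the
# perturbative transition-delay estimator, and composite travel-time
# estimates built from per-transition delays.

#' Benchmark conduction velocity of a partially remyelinated axon
#'
#' Naive travel-time estimate: every internode is assumed to be traversed
#' at the speed it would have in the corresponding uniform axon, so the
#' reciprocal velocity is the mixture `1/v = (1-p)/v_long + p/v_short`,
#' i.e.
#' `v(p) = v_long * v_short / ((1-p) * v_short + p * v_long)`.
#'
#' @param v_long Conduction velocity of the all-normal uniform axon, m/s.
#' @param v_short Conduction velocity of the fully remyelinated
#'   (half-length internode) uniform axon, m/s.
#' @param p Remyelination fraction in \[0, 1\] (vectorised).
#' @return Benchmark velocity in m/s.
#' @export
#' @examples
#' benchmark_velocity(40.44, 31.91, 0.5) # 35.67 m/s
benchmark_velocity <- function(v_long, v_short, p) {
  if (any(v_long <= 0) || any(v_short <= 0)) {
    abort("uniform speeds must be positive")
  }
  stopifnot(all(p >= 0 & p <= 1))
  if (any(v_long < v_short)) {
    warn("v_long < v_short: outside the usual regime where shortening slows conduction")
  }
  v_long * v_short / ((1 - p) * v_short + p * v_long)
}

#' Benchmark travel time over a span
#'
#' @inheritParams benchmark_velocity
#' @param span_um Span length, micrometres.
#' @return Travel time in ms.
#' @export
benchmark_time <- function(v_long, v_short, p, span_um) {
  stopifnot(all(span_um > 0))
  span_um / benchmark_velocity(v_long, v_short, p) * 1e-3 # um/(m/s) = us
}

#' Predicted velocity ratio under square-root internode-length scaling
#'
#' In the discrete-cable idealisation with negligible node length, the
#' conduction velocity of a uniform axon scales as the square root of the
#' internode length, so two axons with lengths `l1` and `l2` should differ
#' in speed by `sqrt(l1/l2)`.
#'
#' @param l1,l2 Internode lengths (same units).
#' @return `sqrt(l1 / l2)`.
#' @export
#' @examples
#' sqrt_scaling_ratio(1150, 575) # sqrt(2) = 1.41
sqrt_scaling_ratio <- function(l1, l2) {
  stopifnot(all(l1 > 0), all(l2 > 0))
  sqrt(l1 / l2)
}

#' Perturbative fractional delay at an internode-length transition
#'
#' At a node flanked by internodes of different lengths, the travel time
#' across the incoming internode (uniform-axon speed `v_a`) deviates from
#' its uniform value by the fraction
#' `((v_a - v_b)/v_b) * (1 - (2 mu Rc Cm / d) v_a)^(-1)`,
#' where `v_b` is the uniform-axon speed of the outgoing internode and
#' `d`, `mu`, `Rc`, `Cm` are the nodal geometry and electrical parameters.
#' A positive fraction means the action potential is slowed. The estimate
#' is perturbative: it is only valid while the correction factor in
#' parentheses stays positive, and the function errors otherwise.
#'
#' @param v_a Uniform-axon speed of the incoming internode, m/s.
#' @param v_b Uniform-axon speed of the outgoing internode, m/s.
#' @param params A [fiber_params()] supplying `d`, `mu`, `Rc`, `Cm`.
#' @return One-row tibble with `v_a`, `v_b`, `correction_factor` and
#'   `fraction` (the fractional change in transit time, dimensionless).
#' @export
#' @examples
#' transition_delay_fraction(40.44, 31.91)$fraction # 0.41
#' transition_delay_fraction(31.91, 40.44)$fraction # -0.29
transition_delay_fraction <- function(v_a, v_b, params = fiber_params()) {
  check_number(v_a, "v_a", lower = 0, strict_lower = TRUE)
  check_number(v_b, "v_b", lower = 0, strict_lower = TRUE)
  stopifnot(inherits(params, "fiber_params"))
  mu_cm <- params$node_length_um * 1e-4
  d_cm <- params$node_diameter_um * 1e-4
  rc <- params$axial_resistivity_ohm_cm          # Ohm cm
  cm_F <- params$membrane_capacitance_uF_cm2 * 1e-6 # F/cm^2
  va_cms <- v_a * 100                            # m/s -> cm/s
  correction <- 1 - (2 * mu_cm * rc * cm_F / d_cm) * va_cms
  if (correction <= 0) {
    abort(sprintf(
      "perturbative regime violated: correction factor %.3f <= 0 (node too large or speed too high)",
      correction))
  }
  tibble(v_a = v_a, v_b = v_b, correction_factor = correction,
         fraction = ((v_a - v_b) / v_b) / correction)
}

#' Perturbative speed estimate for a semi-uniform axon
#'
#' Speed over a span containing a single transition between a half of
#' normal internodes (length `internode_length_um`, speed `v_long`) and a
#' half of half-length internodes (speed `v_short`): the benchmark travel
#' time at p = 0.5 plus the perturbative delay accumulated on the incoming
#' internode at the transition node.
#'
#' @inheritParams benchmark_velocity
#' @param params A [fiber_params()].
#' @param direction `"long_to_short"` if the action potential meets the
#'   transition coming from the normal half, `"short_to_long"` otherwise.
#' @param span_um Measurement span, micrometres (default the 70-internode
#'   span 80500 um).
#' @param internode_length_um Normal nodal separation, micrometres.
#' @return One-row tibble with the direction, the unrounded delay fraction,
#'   the unperturbed incoming transit time `tau_a_us`, the transition delay
#'   `delta_tau_us`, the benchmark `base_time_ms` and the resulting
#'   `speed_m_per_s`.
#' @export
#' @examples
#' semi_uniform_estimate(40.44, 31.91)$speed_m_per_s               # 35.49
#' semi_uniform_estimate(40.44, 31.91,
#'                       direction = "short_to_long")$speed_m_per_s # 35.75
semi_uniform_estimate <- function(v_long, v_short, params = fiber_params(),
                                  direction = c("long_to_short",
                                                "short_to_long"),
                                  span_um = 80500,
                                  internode_length_um = 1150) {
  direction <- match.arg(direction)
  check_number(span_um, "span_um", lower = 0, strict_lower = TRUE)
  check_number(internode_length_um, "internode_length_um", lower = 0,
               strict_lower = TRUE)
  if (direction == "long_to_short") {
    est <- transition_delay_fraction(v_long, v_short, params)
    tau_a_us <- internode_length_um / v_long # um / (m/s) = us
  } else {
    est <- transition_delay_fraction(v_short, v_long, params)
    tau_a_us <- (internode_length_um / 2) / v_short
  }
  base_us <- benchmark_time(v_long, v_short, 0.5, span_um) * 1e3
  delta_us <- est$fraction * tau_a_us
  tibble(direction = direction, v_a = est$v_a, v_b = est$v_b,
         fraction = est$fraction, tau_a_us = tau_a_us,
         delta_tau_us = delta_us, base_time_ms = base_us * 1e-3,
         span_um = span_um,
         speed_m_per_s = span_um / (base_us + delta_us))
}

#' Per-transition delay implied by a measured speed
#'
#' Difference between the measured and benchmark travel times over a span,
#' attributed to a single transition: positive values are slowing.
#'
#' @param v_measured Measured speed over the span, m/s.
#' @param v_benchmark Benchmark speed over the same span, m/s.
#' @param span_um Span, micrometres.
#' @return Delay in microseconds.
#' @export
#' @examples
#' per_transition_delay(35.51, 35.67, 80500) # about +10.2 us
per_transition_delay <- function(v_measured, v_benchmark, span_um = 80500) {
  stopifnot(all(v_measured > 0), all(v_benchmark > 0), all(span_um > 0))
  span_um / v_measured - span_um / v_benchmark # um/(m/s) = us
}

#' Composite speed estimate from transition counts and delays
#'
#' Travel time over the span is the benchmark time plus `n_ls` long-to-
#' short slowing delays minus `n_sl` short-to-long speed-up delays.
#'
#' @param n_ls,n_sl Number of long-to-short and short-to-long transitions.
#' @param delay_ls_us,delay_sl_us Magnitudes of the per-transition slowing
#'   and speed-up, microseconds.
#' @inheritParams benchmark_velocity
#' @param span_um Span, micrometres.
#' @return Estimated speed in m/s.
#' @export
#' @examples
#' composite_estimate(17, 18, 10.2, 6.8, 40.44, 31.91) # about 34.88 m/s
composite_estimate <- function(n_ls, n_sl, delay_ls_us, delay_sl_us,
                               v_long, v_short, p = 0.5, span_um = 80500) {
  n_ls <- check_count(n_ls, "n_ls")
  n_sl <- check_count(n_sl, "n_sl")
  t_us <- benchmark_time(v_long, v_short, p, span_um) * 1e3 +
    n_ls * delay_ls_us - n_sl * delay_sl_us
  if (t_us <= 0) abort("non-physical negative total travel time")
  span_um / t_us
}

#' Remyelination fraction implied by a relative velocity drop
#'
#' Solves the benchmark-velocity relation for the fraction `p` at which
#' the velocity has fallen by `relative_drop` below the normal-axon value:
#' since `1/v(p)` is linear in `p`,
#' `p = (1/v_target - 1/v_at_0) / (1/v_at_1 - 1/v_at_0)` with
#' `v_target = (1 - relative_drop) * v_at_0`.
#'
#' @param v_at_0 Normal-axon velocity, m/s.
#' @param v_at_1 Fully remyelinated velocity, m/s.
#' @param relative_drop Requested fractional decrease (e.g. 0.10 for 10%).
#' @return The implied fraction `p` in \[0, 1\].
#' @export
#' @examples
#' implied_fraction_for_drop(40.44, 31.91, 0.10) # about 0.42
#' implied_fraction_for_drop(5.61, 4.99, 0.10)   # about 0.89
implied_fraction_for_drop <- function(v_at_0, v_at_1, relative_drop) {
  check_number(v_at_0, "v_at_0", lower = 0, strict_lower = TRUE)
  check_number(v_at_1, "v_at_1", lower = 0, strict_lower = TRUE)
  max_drop <- 1 - v_at_1 / v_at_0
  check_number(relative_drop, "relative_drop", lower = 0)
  if (relative_drop > max_drop) {
    abort(sprintf(
      "a %.1f%% drop is unattainable: the fully remyelinated axon is only %.1f%% slower",
      100 * relative_drop, 100 * max_drop))
  }
  v_target <- (1 - relative_drop) * v_at_0
  (1 / v_target - 1 / v_at_0) / (1 / v_at_1 - 1 / v_at_0)
}
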