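# Active nodal membrane: classical Hodgkin-Huxley kinetics.
#
# The nodal model is pluggable through a parameter list: any model with
# m/h/n-style gates, maximal conductances and reversal potentials fits this
# interface (state init, gate stepping, ionic current), and the compiled
# cable integrator consumes the same parameter list.

#' Hodgkin-Huxley nodal membrane model
#'
#' Classical squid-axon kinetics used as the active membrane at nodes of
#' Ranvier. Conductances are per unit nodal area (mS/cm^2), potentials in
#' mV, rates in 1/ms. By default the leak reversal is adjusted so that the
#' configured resting potential is an exact fixed point of the full system
#' (gates at steady state, zero net ionic current), which keeps an
#' unstimulated fibre quiescent to machine precision.
#'
#' @param g_na,g_k,g_leak Maximal conductances, mS/cm^2.
#' @param e_na,e_k,e_leak Reversal potentials, mV.
#' @param v_rest Resting potential, mV.
#' @param rate_scale Multiplicative factor on all gating rates (a Q10 = 3
#'   temperature correction corresponds to `3^((T - 6.3)/10)`); default 1,
#'   i.e. the rates as originally fitted.
#' @param balance_leak If `TRUE` (default), recompute `e_leak` so the net
#'   ionic current vanishes exactly at `v_rest`.
#' @return A `membrane_model` parameter list.
#' @export
#' @examples
#' m <- hh_model()
#' ionic_current(m, m$v_rest, init_steady_state(m, m$v_rest)) # ~0
hh_model <- function(g_na = 120, g_k = 36, g_leak = 0.3,
                     e_na = 50, e_k = -77, e_leak = -54.3,
                     v_rest = -65, rate_scale = 1, balance_leak = TRUE) {
  for (nm in c("g_na", "g_k", "g_leak")) {
    check_number(get(nm), nm, lower = 0)
  }
  check_number(rate_scale, "rate_scale", lower = 0, strict_lower = TRUE)
  model <- structure(
    list(g_na = g_na, g_k = g_k, g_leak = g_leak,
         e_na = e_na, e_k = e_k, e_leak = e_leak,
         v_rest = v_rest, rate_scale = rate_scale),
    class = "membrane_model"
  )
  if (balance_leak && g_leak > 0) {
    s <- init_steady_state(model, v_rest)
    i_na <- g_na * s[["m"]]^3 * s[["h"]] * (v_rest - e_na)
    i_k <- g_k * s[["n"]]^4 * (v_rest - e_k)
    model$e_leak <- v_rest + (i_na + i_k) / g_leak
  }
  model
}

# x / (1 - exp(-x)) with a stable expansion through x = 0
xexp <- function(x) {
  ifelse(abs(x) < 1e-7, 1 + x / 2, x / (1 - exp(-x)))
}

# voltage-dependent opening/closing rates (1/ms), vectorised over v
hh_rates <- function(v) {
  list(
    alpha_m = xexp((v + 40) / 10),
    beta_m = 4 * exp(-(v + 65) / 18),
    alpha_h = 0.07 * exp(-(v + 65) / 20),
    beta_h = 1 / (1 + exp(-(v + 35) / 10)),
    alpha_n = 0.1 * xexp((v + 55) / 10),
    beta_n = 0.125 * exp(-(v + 65) / 80)
  )
}

#' Steady-state gating variables at a holding potential
#'
#' @param model A [hh_model()].
#' @param v Membrane potential, mV.
#' @return Named numeric vector with components `m`, `h`, `n`, each the
#'   fixed point `alpha / (alpha + beta)` at `v`.
#' @export
init_steady_state <- function(model, v = model$v_rest) {
  r <- hh_rates(v)
  c(m = r$alpha_m / (r$alpha_m + r$beta_m),
    h = r$alpha_h / (r$alpha_h + r$beta_h),
    n = r$alpha_n / (r$alpha_n + r$beta_n))
}

#' Ionic membrane current density
#'
#' Sum of sodium, potassium and leak currents, outward positive, in
#' uA/cm^2.
#'
#' @param model A [hh_model()].
#' @param v Membrane potential, mV.
#' @param state Gating state as returned by [init_steady_state()] or
#'   [step_gates()].
#' @return Current density in uA/cm^2 (positive = outward).
#' @export
ionic_current <- function(model, v, state) {
  model$g_na * state[["m"]]^3 * state[["h"]] * (v - model$e_na) +
    model$g_k * state[["n"]]^4 * (v - model$e_k) +
    model$g_leak * (v - model$e_leak)
}

#' Advance gating variables one time step (exponential update)
#'
#' Rush-Larsen step: each gate relaxes exactly along its linear dynamics at
#' the frozen voltage, `x <- x_inf + (x - x_inf) * exp(-dt / tau_x)`, and
#' therefore stays in \[0, 1\] for any step size.
#'
#' @inheritParams ionic_current
#' @param dt Time step, ms.
#' @return Updated gating state.
#' @export
step_gates <- function(model, state, v, dt) {
  check_number(dt, "dt", lower = 0, strict_lower = TRUE)
  r <- hh_rates(v)
  phi <- model$rate_scale
  advance <- function(x, a, b) {
    xinf <- a / (a + b)
    tau <- 1 / (phi * (a + b))
    xinf + (x - xinf) * exp(-dt / tau)
  }
  c(m = advance(state[["m"]], r$alpha_m, r$beta_m),
    h = advance(state[["h"]], r$alpha_h, r$beta_h),
    n = advance(state[["n"]], r$alpha_n, r$beta_n))
}
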