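# Independent R re-implementation of the integration scheme (dense linear
# algebra, R-level gate updates) used to validate the compiled integrator
# on tiny systems.

coupling_laplacian <- function(system) {
  n <- length(system$capacitance_nF)
  L <- matrix(0, n, n)
  g <- system$g_axial_uS
  for (i in seq_len(n - 1)) {
    L[i, i] <- L[i, i] + g[i]
    L[i + 1, i + 1] <- L[i + 1, i + 1] + g[i]
    L[i, i + 1] <- -g[i]
    L[i + 1, i] <- -g[i]
  }
  L
}

reference_integrate <- function(system, stim_node, amplitude_nA,
                                duration_ms, dt, t_total) {
  n <- length(system$capacitance_nF)
  L <- coupling_laplacian(system)
  model <- system$membrane
  A <- diag(system$capacitance_nF / dt, n) + 0.5 * L +
    diag(0.5 * system$g_pas_uS, n)
  v <- rep(model$v_rest, n)
  states <- replicate(n, init_steady_state(model, model$v_rest),
                      simplify = FALSE)
  stim_comp <- system$node_comp[stim_node]
  n_steps <- round(t_total / dt)
  out <- matrix(NA_real_, n_steps + 1, n)
  out[1, ] <- v
  for (k in 0:(n_steps - 1)) {
    t <- k * dt
    I <- numeric(n)
    for (i in seq_len(n)) {
      if (system$is_node[i]) {
        states[[i]] <- step_gates(model, states[[i]], v[i], dt)
        I[i] <- system$area_cm2[i] * ionic_current(model, v[i], states[[i]]) * 1e3
      }
    }
    rhs <- system$capacitance_nF / dt * v - 0.5 * drop(L %*% v) -
      0.5 * system$g_pas_uS * (v - system$e_pas_mV) +
      0.5 * system$g_pas_uS * system$e_pas_mV - I
    if (t >= 0 && t < duration_ms) rhs[stim_comp] <- rhs[stim_comp] + amplitude_nA
    v <- solve(A, rhs)
    out[k + 2, ] <- v
  }
  out
}
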