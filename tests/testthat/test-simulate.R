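# small test fibre: 20 internodes, electrodes at nodes 6 / 11 / 18
small_axon <- function() make_uniform_layout(20, 1150, 0.69)
small_electrodes <- function() electrode_set(5750, c(11500, 19550))
small_config <- function(...) sim_config(t_total_ms = 3, ...)

test_that("the compiled integrator reproduces a dense R reference of the same scheme", {
  sys <- assemble_cable(make_uniform_layout(3, 1150, 0.69))
  dt <- 1e-3
  t_total <- 0.5
  sim <- simulate_cable(sys, stimulus_protocol(1, 0.3, duration_ms = 0.1),
                        sim_config(dt_ms = dt, t_total_ms = t_total))
  ref <- reference_integrate(sys, 1, 0.3, 0.1, dt, t_total)
  expect_equal(unname(sim$v), unname(ref), tolerance = 1e-8)
})

test_that("an unstimulated fibre stays within 0.1 mV of rest for 50 ms", {
  sys <- assemble_cable(make_uniform_layout(20, 1150, 0.69))
  sim <- simulate_cable(sys, stimulus_protocol(1, 0),
                        sim_config(dt_ms = 0.01, t_total_ms = 50))
  expect_lt(max(abs(sim$v + 65)), 0.1)
  expect_true(all(is.na(sim$crossing_ms)))
})

test_that("the passive system matches a matrix-exponential oracle within 0.1%", {
  passive <- hh_model(g_na = 0, g_k = 0) # leak only; e_leak -> v_rest
  sys <- assemble_cable(make_uniform_layout(4, 1150, 0.69),
                        membrane = passive)
  amp <- 0.05
  t_end <- 2
  sim <- simulate_cable(sys, stimulus_protocol(1, amp, duration_ms = 10),
                        sim_config(dt_ms = 5e-4, t_total_ms = t_end))
  # independent linear-algebra solution of C u' = -(L + G_leak) u + b
  n <- length(sys$capacitance_nF)
  L <- coupling_laplacian(sys)
  g_leak_uS <- sys$area_cm2 * passive$g_leak * 1e3
  M <- -(L + diag(g_leak_uS, n)) / sys$capacitance_nF
  b <- c(amp, rep(0, n - 1)) / sys$capacitance_nF
  u_end <- as.numeric(
    solve(M, (as.matrix(Matrix::expm(M * t_end)) - diag(n)) %*% b)
  )
  v_oracle <- -65 + u_end
  v_sim <- sim$v[nrow(sim$v), ]
  expect_lt(max(abs(v_sim - v_oracle)) / max(abs(u_end)), 1e-3)
})

test_that("threshold crossings are linearly interpolated", {
  expect_equal(detect_crossing(c(-65, -30), -40, dt = 0.1), 0.1 * 25 / 35)
  expect_equal(detect_crossing(c(-65, -50, -40, -20), -40, dt = 0.2), 0.4)
  expect_true(is.na(detect_crossing(c(-65, -50, -45), -40, dt = 0.1)))
  expect_error(detect_crossing(c(-30, -20), -40, dt = 0.1), "above threshold")
  # agreement with the integrator's own interpolated crossing times
  sys <- assemble_cable(small_axon())
  sim <- simulate_cv(small_axon(), 1.5, small_electrodes(),
                     config = small_config(), keep_sim = TRUE)
  full <- attr(sim, "sim")
  trace <- full$v[, which(full$record == sys$node_comp[11])]
  expect_equal(detect_crossing(trace, -40, 5e-4),
               full$crossing_ms[sys$node_comp[11]], tolerance = 1e-10)
})

test_that("conduction velocity is separation over crossing-time difference", {
  sys <- assemble_cable(make_uniform_layout(70, 1150, 0.69))
  fake <- structure(list(crossing_ms = c(1, rep(NA_real_, 69), 3)),
                    class = "cable_sim")
  cv <- measure_cv(sys, fake, c(1, 71))
  expect_equal(cv$separation_um, 80500)
  expect_equal(cv$cv_m_per_s, 40.25)
  fail <- structure(list(crossing_ms = c(1, rep(NA_real_, 70))),
                    class = "cable_sim")
  expect_error(measure_cv(sys, fail, c(1, 71)), "propagation failure")
})

test_that("propagation is saltatory and translation invariant on a uniform axon", {
  proto <- study_protocol()
  res <- simulate_cv(proto$base, proto$amplitude_nA, config = proto$cfg,
                     keep_sim = TRUE)
  sim <- attr(res, "sim")
  cross <- sim$crossing_ms[11:101]
  expect_true(all(is.finite(cross)))
  expect_true(all(diff(cross) > 0)) # strictly increasing node by node

  pos <- node_positions(proto$base)
  cv_pair <- function(i, j) {
    (pos[j] - pos[i]) / (sim$crossing_ms[j] - sim$crossing_ms[i]) * 1e-3
  }
  expect_equal(cv_pair(41, 91), cv_pair(31, 101), tolerance = 0.01)
  expect_equal(res$cv_m_per_s, cv_pair(31, 101), tolerance = 1e-10)
})

test_that("a midpoint stimulus propagates symmetrically", {
  sys <- assemble_cable(make_uniform_layout(40, 1150, 0.69))
  sim <- simulate_cable(sys, stimulus_protocol(21, 1.5),
                        sim_config(t_total_ms = 4))
  for (k in c(5, 10, 15)) {
    expect_equal(sim$crossing_ms[21 - k], sim$crossing_ms[21 + k],
                 tolerance = 1e-6)
  }
})

test_that("find_threshold brackets the minimal propagating amplitude", {
  thr <- find_threshold(small_axon(), small_electrodes(),
                        config = small_config(), rel_tol = 0.005)
  expect_gt(thr, 0)
  ok <- simulate_cv(small_axon(), 1.01 * thr, small_electrodes(),
                    config = small_config())
  expect_true(ok$cv_m_per_s > 0)
  expect_error(simulate_cv(small_axon(), 0.985 * thr, small_electrodes(),
                           config = small_config(auto_extend = FALSE)),
               "propagation failure")

  # more sodium conductance cannot raise the threshold
  thr_hot <- find_threshold(small_axon(), small_electrodes(),
                            membrane = hh_model(g_na = 240),
                            config = small_config(), rel_tol = 0.005)
  expect_lte(thr_hot, thr * 1.01)

  # a fully remyelinated variant has its own (different) threshold
  short <- remyelinate(small_axon(), 1)
  thr_short <- find_threshold(short, small_electrodes(),
                              config = small_config(), rel_tol = 0.005)
  expect_false(isTRUE(all.equal(thr_short, thr, tolerance = 1e-3)))
})

test_that("halving the time step changes the CV only slightly, and less again on re-halving", {
  cv_at <- function(dt) {
    simulate_cv(small_axon(), 1.5, small_electrodes(),
                config = small_config(dt_ms = dt))$cv_m_per_s
  }
  cv1 <- cv_at(5e-4); cv2 <- cv_at(2.5e-4); cv4 <- cv_at(1.25e-4)
  c21 <- abs(cv2 - cv1) / cv2
  c42 <- abs(cv4 - cv2) / cv4
  expect_lt(c21, 0.01)
  expect_lt(c42, c21 * 1.1 + 1e-7) # allow a small noise floor

  expect_equal(convergence_check(small_axon(), 1.5, small_electrodes(),
                                 config = small_config()),
               c21, tolerance = 1e-6)
})

test_that("simulation is deterministic and extends its window once if needed", {
  a <- simulate_cv(small_axon(), 1.5, small_electrodes(),
                   config = small_config(), keep_sim = TRUE)
  b <- simulate_cv(small_axon(), 1.5, small_electrodes(),
                   config = small_config(), keep_sim = TRUE)
  expect_identical(attr(a, "sim")$v, attr(b, "sim")$v)
  expect_identical(a$t2_ms, b$t2_ms)

  short_window <- sim_config(t_total_ms = 0.6 * a$t2_ms)
  c <- simulate_cv(small_axon(), 1.5, small_electrodes(),
                   config = short_window)
  expect_equal(c$cv_m_per_s, a$cv_m_per_s, tolerance = 1e-9)
})

test_that("numerical blow-up aborts with a diagnostic", {
  sys <- assemble_cable(small_axon())
  expect_error(simulate_cable(sys, stimulus_protocol(1, 1e9),
                              sim_config(t_total_ms = 0.1)),
               "blow-up")
})

test_that("voltage traces can be dumped to CSV", {
  path <- withr::local_tempfile(fileext = ".csv")
  sys <- assemble_cable(make_uniform_layout(3, 1150, 0.69))
  sim <- simulate_cable(sys, stimulus_protocol(1, 0.5),
                        sim_config(t_total_ms = 0.2))
  write_traces(sim, path)
  df <- readr::read_csv(path, show_col_types = FALSE)
  expect_equal(names(df)[1], "time_ms")
  expect_equal(nrow(df), length(sim$time))
})
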