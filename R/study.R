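# Ensemble study pipeline: sweep the remyelination fraction, simulate the
# ensemble, and summarise conduction velocity against the benchmark
# velocity and the uniform-average control.

# fiber/membrane/sim/electrode objects from a nested config list
cfg_fiber <- function(config) do.call(fiber_params, config$fiber)
cfg_membrane <- function(config) do.call(hh_model, config$membrane)
cfg_sim <- function(config) {
  do.call(sim_config, config$simulation)
}
cfg_electrodes <- function(config) {
  electrode_set(config$electrodes$stim_um, unlist(config$electrodes$rec_um))
}
cfg_base_layout <- function(config) {
  make_uniform_layout(config$layout$n_internodes,
                      config$layout$internode_length_um,
                      config$layout$g_ratio)
}

#' Original-internode slots spanned by the recording electrodes
#'
#' The slots of the base axon whose internodes lie between the two
#' recording positions; remyelinated counts and transition counts of the
#' measurement span are computed over these slots (70 slots for the
#' default configuration).
#'
#' @param config A [default_config()]-style configuration list.
#' @return Integer vector of slot indices.
#' @export
measurement_slots <- function(config = default_config()) {
  base <- cfg_base_layout(config)
  el <- resolve_electrodes(base, cfg_electrodes(config))
  seq(el$node[2], el$node[3] - 1L)
}

#' Stimulus amplitude for the study protocol
#'
#' The configured amplitude if set, otherwise twice the propagation
#' threshold of the fully remyelinated fibre (the study protocol).
#'
#' @param config Configuration list.
#' @return Amplitude in nA.
#' @export
study_amplitude <- function(config = default_config()) {
  if (!is.null(config$stimulus$amplitude_nA)) {
    return(config$stimulus$amplitude_nA)
  }
  full <- remyelinate(cfg_base_layout(config), 1)
  2 * find_threshold(full, cfg_electrodes(config), cfg_fiber(config),
                     cfg_membrane(config), cfg_sim(config))
}

#' Simulate an ensemble of remyelinated axons at one fraction
#'
#' Draws `n_models` remyelinated layouts (binomial placement under
#' counter-based child seeds, or exact-composition placement when
#' `exact_k` is given), simulates each, and records the conduction
#' velocity together with the remyelinated count and the transition counts
#' within the measurement span. Propagation failures are flagged, never
#' silently dropped.
#'
#' @param config Configuration list.
#' @param p Remyelination fraction.
#' @param amplitude_nA Stimulus amplitude; computed via [study_amplitude()]
#'   if `NULL`.
#' @param n_models,master_seed Optional overrides of the config values.
#' @param exact_k If given, every draw has exactly `exact_k` remyelinated
#'   internodes within the measurement span (fixed composition), with
#'   binomial placement at probability `p` outside it.
#' @return Tibble with one row per draw: `draw`, `seed`,
#'   `n_remyelinated`, `n_remyelinated_span`, `n_ls`, `n_sl`,
#'   `cv_m_per_s`, `ok`.
#' @export
run_cv_ensemble <- function(config = default_config(), p,
                            amplitude_nA = NULL, n_models = NULL,
                            master_seed = NULL, exact_k = NULL) {
  check_number(p, "p", lower = 0, upper = 1)
  n_models <- check_count(n_models %||% config$study$n_models, "n_models",
                          lower = 1L)
  master_seed <- master_seed %||% config$study$master_seed
  amplitude_nA <- amplitude_nA %||% study_amplitude(config)
  base <- cfg_base_layout(config)
  electrodes <- cfg_electrodes(config)
  params <- cfg_fiber(config)
  membrane <- cfg_membrane(config)
  sim_cfg <- cfg_sim(config)
  span <- measurement_slots(config)
  rg <- config$layout$remyelinated_g_ratio
  seeds <- child_seed(master_seed, seq_len(n_models))

  rows <- purrr::map(seq_len(n_models), function(i) {
    layout <- if (is.null(exact_k)) {
      remyelinate(base, p, seed = seeds[i], remyelinated_g_ratio = rg)
    } else {
      remyelinate_exact(base, exact_k, slots = span, p_outside = p,
                        seed = seeds[i], remyelinated_g_ratio = rg)
    }
    tr <- count_transitions(layout, slots = span)
    cv <- tryCatch(
      simulate_cv(layout, amplitude_nA, electrodes, params, membrane,
                  sim_cfg)$cv_m_per_s,
      error = function(e) NA_real_
    )
    tibble(draw = i, seed = seeds[i],
           n_remyelinated = sum(attr(layout, "mask")),
           n_remyelinated_span = sum(attr(layout, "mask")[span]),
           n_ls = tr$n_long_to_short, n_sl = tr$n_short_to_long,
           cv_m_per_s = cv, ok = !is.na(cv))
  })
  out <- dplyr::bind_rows(rows)
  out$p <- p
  out
}

#' Run the remyelination study
#'
#' For each fraction in the configured grid: simulate the ensemble, then
#' attach the benchmark velocity (computed from this simulator's own
#' uniform endpoint velocities) and the uniform-average control (a uniform
#' axon whose internode length equals the remyelinated axon's average
#' internode length). The endpoints p = 0 and p = 1 carry no randomness
#' and are simulated once.
#'
#' @param config Configuration list; see [default_config()].
#' @return A `remyelination_study` tibble with one row per fraction:
#'   `p`, `n_models`, `n_success`, `mean_cv`, `sd_cv`, `v_benchmark`,
#'   `cv_uniform_control`, `mean_n_ls`, `mean_n_sl`. The per-draw tables
#'   are kept in `attr(, "draws")`; uniform endpoint velocities and the
#'   stimulus amplitude in attributes.
#' @export
run_study <- function(config = default_config()) {
  p_grid <- unlist(config$study$p_grid)
  stopifnot(all(p_grid >= 0 & p_grid <= 1))
  n_models <- check_count(config$study$n_models, "n_models", lower = 1L)
  base <- cfg_base_layout(config)
  electrodes <- cfg_electrodes(config)
  params <- cfg_fiber(config)
  membrane <- cfg_membrane(config)
  sim_cfg <- cfg_sim(config)
  l0 <- config$layout$internode_length_um
  n0 <- config$layout$n_internodes

  amplitude <- study_amplitude(config)
  message(sprintf("stimulus amplitude: %.4g nA", amplitude))

  uniform_cv <- function(layout) {
    simulate_cv(layout, amplitude, electrodes, params, membrane,
                sim_cfg)$cv_m_per_s
  }
  cv_long <- uniform_cv(base)
  cv_short <- uniform_cv(remyelinate(base, 1,
                                     remyelinated_g_ratio =
                                       config$layout$remyelinated_g_ratio))
  message(sprintf("uniform endpoints: %.2f m/s (p=0), %.2f m/s (p=1)",
                  cv_long, cv_short))

  control_cv <- function(p) {
    if (p == 0) return(cv_long)
    n_ctrl <- as.integer(round(n0 * (1 + p)))
    l_ctrl <- n0 * l0 / n_ctrl
    uniform_cv(make_uniform_layout(n_ctrl, l_ctrl, config$layout$g_ratio))
  }

  draws_list <- list()
  rows <- purrr::map(p_grid, function(p) {
    if (p %in% c(0, 1)) {
      cv <- if (p == 0) cv_long else cv_short
      row <- tibble(p = p, n_models = n_models, n_success = n_models,
                    mean_cv = cv, sd_cv = 0,
                    mean_n_ls = 0, mean_n_sl = 0)
    } else {
      draws <- run_cv_ensemble(config, p, amplitude_nA = amplitude)
      draws_list[[as.character(p)]] <<- draws
      good <- draws[draws$ok, ]
      if (nrow(good) == 0) {
        abort(sprintf("all %d draws failed to propagate at p = %g",
                      n_models, p))
      }
      if (nrow(good) < nrow(draws)) {
        warn(sprintf("%d of %d draws failed to propagate at p = %g",
                     nrow(draws) - nrow(good), nrow(draws), p))
      }
      row <- tibble(p = p, n_models = n_models, n_success = nrow(good),
                    mean_cv = mean(good$cv_m_per_s),
                    sd_cv = sd(good$cv_m_per_s),
                    mean_n_ls = mean(good$n_ls),
                    mean_n_sl = mean(good$n_sl))
    }
    row$v_benchmark <- benchmark_velocity(cv_long, cv_short, p)
    row$cv_uniform_control <- if (p == 1) cv_short else control_cv(p)
    message(sprintf("p = %.2f: mean CV %.2f m/s (n = %d)", p, row$mean_cv,
                    row$n_success))
    row
  })
  out <- dplyr::bind_rows(rows)
  out <- out[, c("p", "n_models", "n_success", "mean_cv", "sd_cv",
                 "v_benchmark", "cv_uniform_control", "mean_n_ls",
                 "mean_n_sl")]
  attr(out, "v_long") <- cv_long
  attr(out, "v_short") <- cv_short
  attr(out, "amplitude_nA") <- amplitude
  attr(out, "draws") <- draws_list
  attr(out, "config") <- config
  class(out) <- c("remyelination_study", class(out))
  out
}

#' Restricted-sample analysis at a fixed remyelinated count
#'
#' Filters an ensemble at fraction `p` to the draws with exactly `k`
#' remyelinated original internodes within the measurement span (removing
#' the binomial-count spread), and summarises their conduction velocities
#' and transition counts.
#'
#' @inheritParams run_cv_ensemble
#' @param k Conditioned remyelinated count within the measurement span.
#' @return One-row tibble: `p`, `k`, `n_draws`, `n_qualifying`, `mean_cv`,
#'   `sd_cv`, `mean_n_ls`, `mean_n_sl`; qualifying per-draw rows in
#'   `attr(, "draws")`.
#' @export
restricted_sample <- function(config = default_config(), p, k,
                              amplitude_nA = NULL, n_models = NULL,
                              master_seed = NULL) {
  span <- measurement_slots(config)
  k <- check_count(k, "k")
  if (k > length(span)) abort("`k` cannot exceed the measurement-span size")
  draws <- run_cv_ensemble(config, p, amplitude_nA = amplitude_nA,
                           n_models = n_models, master_seed = master_seed)
  q <- draws[draws$n_remyelinated_span == k & draws$ok, ]
  if (nrow(q) == 0) {
    abort(sprintf("no qualifying draws with exactly %d remyelinated internodes in the span", k))
  }
  out <- tibble(p = p, k = k, n_draws = nrow(draws), n_qualifying = nrow(q),
                mean_cv = mean(q$cv_m_per_s), sd_cv = sd(q$cv_m_per_s),
                mean_n_ls = mean(q$n_ls), mean_n_sl = mean(q$n_sl))
  attr(out, "draws") <- q
  out
}

#' Benchmark deficit of the ensemble mean, per fraction
#'
#' How many ensemble standard deviations the benchmark velocity sits above
#' the ensemble mean: `(v_benchmark - mean_cv) / sd_cv`, with a
#' delta-method Monte-Carlo standard error. Endpoint rows (where mean and
#' benchmark agree by construction) report a deficit of 0.
#'
#' @param study A [run_study()] result.
#' @return Tibble with `p`, `deficit_sd` and `deficit_se`.
#' @export
compare_to_benchmark <- function(study) {
  stopifnot(inherits(study, "remyelination_study"))
  tbl <- as_tibble(study)
  purrr::pmap(tbl[, c("p", "mean_cv", "sd_cv", "v_benchmark", "n_success")],
              function(p, mean_cv, sd_cv, v_benchmark, n_success) {
    diff <- v_benchmark - mean_cv
    if (sd_cv == 0) {
      if (abs(diff) > 1e-9 * max(1, abs(v_benchmark))) {
        abort(sprintf("zero ensemble sd with nonzero deficit at p = %g", p))
      }
      return(tibble(p = p, deficit_sd = 0, deficit_se = 0))
    }
    d <- diff / sd_cv
    tibble(p = p, deficit_sd = d,
           deficit_se = sqrt(1 / n_success + d^2 / (2 * (n_success - 1))))
  }) |> dplyr::bind_rows()
}

#' @export
print.remyelination_study <- function(x, ...) {
  cat(sprintf("<remyelination_study> uniform endpoints %.2f / %.2f m/s, stimulus %.3g nA\n",
              attr(x, "v_long"), attr(x, "v_short"),
              attr(x, "amplitude_nA")))
  NextMethod()
}

#' @rdname run_study
#' @param x A `remyelination_study`.
#' @param ... Unused.
#' @export
tidy.remyelination_study <- function(x, ...) {
  out <- as_tibble(x)
  class(out) <- setdiff(class(out), "remyelination_study")
  out
}

#' @rdname run_study
#' @export
glance.remyelination_study <- function(x, ...) {
  tibble(v_long = attr(x, "v_long"), v_short = attr(x, "v_short"),
         amplitude_nA = attr(x, "amplitude_nA"),
         n_fractions = nrow(x),
         n_simulations = sum(x$n_success),
         speed_ratio = attr(x, "v_long") / attr(x, "v_short"))
}

#' Write a study table (CSV) with a provenance JSON companion
#'
#' @param study A [run_study()] result.
#' @param path CSV path; the companion JSON (full configuration, seeds,
#'   endpoint velocities) is written next to it with extension `.json`.
#' @return `path`, invisibly.
#' @export
write_study <- function(study, path) {
  stopifnot(inherits(study, "remyelination_study"))
  readr::write_csv(tidy(study), path)
  prov <- list(config = unclass(attr(study, "config")),
               v_long = attr(study, "v_long"),
               v_short = attr(study, "v_short"),
               amplitude_nA = attr(study, "amplitude_nA"))
  jsonlite::write_json(prov, sub("\\.csv$", ".json", path),
                       auto_unbox = TRUE, null = "null", digits = NA)
  invisible(path)
}
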