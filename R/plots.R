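# ggplot2 graphics for study and simulation results.

#' Plot a remyelination study
#'
#' Mean ensemble conduction velocity with +/- one standard deviation per
#' remyelination fraction (black squares), the benchmark velocity curve
#' computed from the simulator's own uniform endpoints (blue line), and
#' the uniform-average control axons (red circles).
#'
#' @param object A [run_study()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.remyelination_study <- function(object, ...) {
  tbl <- tidy(object)
  bench <- tibble(
    p = seq(0, 1, by = 0.01),
    v = benchmark_velocity(attr(object, "v_long"), attr(object, "v_short"),
                           seq(0, 1, by = 0.01))
  )
  ggplot2::ggplot(tbl, ggplot2::aes(x = .data$p, y = .data$mean_cv)) +
    ggplot2::geom_line(data = bench, ggplot2::aes(y = .data$v),
                       colour = "blue") +
    ggplot2::geom_point(ggplot2::aes(y = .data$cv_uniform_control),
                        colour = "red", shape = 1, size = 2.5) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean_cv - .data$sd_cv,
                                        ymax = .data$mean_cv + .data$sd_cv),
                           width = 0.02) +
    ggplot2::geom_point(shape = 15, size = 2.5) +
    ggplot2::labs(x = "remyelination fraction p",
                  y = "conduction velocity (m/s)",
                  title = "Conduction velocity along progressively remyelinated axons",
                  subtitle = "squares: ensemble mean ± sd; blue: benchmark; red: uniform-average control") +
    ggplot2::theme_minimal()
}

#' Plot simulated voltage traces
#'
#' One line per recorded compartment, against time.
#'
#' @param object A [simulate_cable()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cable_sim <- function(object, ...) {
  df <- as.data.frame(object$v)
  names(df) <- paste0("comp_", object$record)
  df$time_ms <- object$time
  long <- tidyr::pivot_longer(df, -"time_ms", names_to = "compartment",
                              values_to = "v_mV")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$time_ms, y = .data$v_mV,
                                     colour = .data$compartment)) +
    ggplot2::geom_line(show.legend = length(object$record) <= 12) +
    ggplot2::labs(x = "time (ms)", y = "membrane potential (mV)") +
    ggplot2::theme_minimal()
}

#' @importFrom rlang .data
#' @export
plot.remyelination_study <- function(x, ...) print(autoplot(x, ...))
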