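# Hierarchical run configuration: every numerical default of the study is
# listed explicitly here, loadable/serialisable as YAML, with unknown keys
# rejected and physical values validated.

#' Default run configuration
#'
#' Nested list with sections `study`, `layout`, `fiber`, `membrane`,
#' `simulation`, `stimulus` and `electrodes`; all defaults are explicit.
#' A fully defaulted configuration reproduces the study protocol: 120
#' internodes of 1150 um (g-ratio 0.69), electrodes at 11500 / 34500 /
#' 115000 um, dt = 5e-4 ms, -40 mV detection, 0.1 ms stimulus at twice the
#' fully-remyelinated threshold (`amplitude_nA: NULL` means "auto"), and
#' 500 binomially remyelinated models per fraction.
#'
#' @return A `remyelin_config` nested list.
#' @export
default_config <- function() {
  structure(list(
    study = list(
      p_grid = c(0, 0.25, 0.5, 0.75, 1),
      n_models = 500,
      master_seed = 20180112
    ),
    layout = list(
      n_internodes = 120,
      internode_length_um = 1150,
      g_ratio = 0.69,
      remyelinated_g_ratio = NULL
    ),
    fiber = list(
      node_diameter_um = 3.3,
      node_length_um = 1,
      axial_resistivity_ohm_cm = 70,
      membrane_capacitance_uF_cm2 = 2,
      internode_diameter_um = NULL,
      internode_mode = "ideal_resistive",
      myelin_attenuation = 100,
      lamella_capacitance_uF_cm2 = 1,
      lamella_conductance_mS_cm2 = 1
    ),
    membrane = list(
      g_na = 120, g_k = 36, g_leak = 0.3,
      e_na = 50, e_k = -77, e_leak = -54.3,
      v_rest = -65, rate_scale = 1, balance_leak = TRUE
    ),
    simulation = list(
      dt_ms = 5e-4,
      t_total_ms = 6,
      threshold_mV = -40,
      v_init_mV = NULL,
      auto_extend = TRUE
    ),
    stimulus = list(
      amplitude_nA = NULL,
      duration_ms = 0.1,
      onset_ms = 0
    ),
    electrodes = list(
      stim_um = 11500,
      rec_um = c(34500, 115000)
    )
  ), class = "remyelin_config")
}

# recursively reject keys absent from the reference structure
check_unknown_keys <- function(x, ref, path = "") {
  bad <- setdiff(names(x), names(ref))
  if (length(bad) > 0) {
    abort(sprintf("unknown configuration key%s: %s",
                  if (length(bad) > 1) "s" else "",
                  paste0(path, bad, collapse = ", ")))
  }
  for (nm in names(x)) {
    if (is.list(ref[[nm]]) && !is.null(names(ref[[nm]])) && is.list(x[[nm]])) {
      check_unknown_keys(x[[nm]], ref[[nm]], paste0(path, nm, "."))
    }
  }
  invisible(TRUE)
}

# overlay user values on the defaults, keeping NULL-able keys
merge_config <- function(defaults, user) {
  for (nm in names(user)) {
    if (is.list(defaults[[nm]]) && !is.null(names(defaults[[nm]])) &&
        is.list(user[[nm]])) {
      defaults[[nm]] <- merge_config(defaults[[nm]], user[[nm]])
    } else {
      defaults[nm] <- list(user[[nm]]) # keeps explicit NULLs
    }
  }
  defaults
}

#' Validate (and complete) a configuration
#'
#' Unknown keys are rejected; missing keys are filled from
#' [default_config()]; physical values must be positive and fractions in
#' \[0, 1\]. Constructing the parameter objects exercises their own
#' validation too.
#'
#' @param config A (possibly partial) nested configuration list.
#' @return A complete validated `remyelin_config`.
#' @export
validate_config <- function(config) {
  defaults <- default_config()
  check_unknown_keys(config, defaults)
  cfg <- merge_config(unclass(defaults), config)
  stopifnot(all(unlist(cfg$study$p_grid) >= 0),
            all(unlist(cfg$study$p_grid) <= 1))
  check_count(cfg$study$n_models, "study.n_models", lower = 1L)
  check_count(cfg$study$master_seed, "study.master_seed")
  cfg_fiber(cfg)
  cfg_membrane(cfg)
  cfg_sim(cfg)
  cfg_electrodes(cfg)
  cfg_base_layout(cfg)
  check_number(cfg$stimulus$amplitude_nA, "stimulus.amplitude_nA",
               lower = 0, strict_lower = TRUE, allow_null = TRUE)
  check_number(cfg$stimulus$duration_ms, "stimulus.duration_ms",
               lower = 0, strict_lower = TRUE)
  structure(cfg, class = "remyelin_config")
}

#' Read / write a configuration as YAML
#'
#' `read_config()` validates and completes the file against the defaults,
#' so a round trip through `write_config()` is the identity on the
#' completed configuration.
#'
#' @param path YAML file path.
#' @param config A configuration list.
#' @return `read_config()` a validated `remyelin_config`;
#'   `write_config()` the path, invisibly.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) abort(sprintf("config file not found: %s", path))
  validate_config(yaml::read_yaml(path))
}

#' @rdname read_config
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(validate_config(config)), path)
  invisible(path)
}
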