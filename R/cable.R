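# Discrete cable assembly: isopotential active nodes coupled through
# internodal axial resistances.
#
# Internal unit system (self-consistent, no hidden factors):
#   potential mV, time ms, current nA, capacitance nF, conductance uS,
#   position um.  nF * mV / ms = nA = uS * mV.
# All geometry enters in um / Ohm cm / uF cm^-2 and is converted here, at
# the assembly boundary, and nowhere else.

#' Fibre geometry and electrical parameters
#'
#' Defaults follow the 10-um mammalian motor fibre used throughout the
#' package: node diameter 3.3 um, node length 1 um, cytoplasmic resistivity
#' 70 Ohm cm, nodal membrane capacitance 2 uF/cm^2.
#'
#' In `"ideal_resistive"` mode (default) internodes carry no transmembrane
#' current at all and act as pure axial resistors between nodes, which is
#' the idealisation behind the analytical velocity estimates. In
#' `"leaky_cable"` mode each internode contributes an additional passive RC
#' compartment whose per-area capacitance is divided by, and resistance
#' multiplied by, the lamella count `myelin_attenuation * (1/g_ratio - 1)`,
#' allowing qualitative exploration of thin (large g-ratio) remyelinated
#' sheaths.
#'
#' @param node_diameter_um Node of Ranvier diameter, um.
#' @param node_length_um Node length, um.
#' @param axial_resistivity_ohm_cm Cytoplasmic resistivity, Ohm cm.
#' @param membrane_capacitance_uF_cm2 Nodal membrane capacitance, uF/cm^2.
#' @param internode_diameter_um Axon diameter inside internodes; defaults
#'   to the node diameter (the single-diameter idealisation used by the
#'   analytical estimates).
#' @param internode_mode `"ideal_resistive"` or `"leaky_cable"`.
#' @param myelin_attenuation Dimensionless lamella scale factor; with the
#'   default 100 the myelin capacitance (resistance) of a g = 0.69 sheath
#'   is attenuated (boosted) about 45-fold.
#' @param lamella_capacitance_uF_cm2,lamella_conductance_mS_cm2 Per-lamella
#'   membrane properties, leaky mode only.
#' @return A `fiber_params` list.
#' @export
fiber_params <- function(node_diameter_um = 3.3,
                         node_length_um = 1,
                         axial_resistivity_ohm_cm = 70,
                         membrane_capacitance_uF_cm2 = 2,
                         internode_diameter_um = NULL,
                         internode_mode = c("ideal_resistive", "leaky_cable"),
                         myelin_attenuation = 100,
                         lamella_capacitance_uF_cm2 = 1,
                         lamella_conductance_mS_cm2 = 1) {
  internode_mode <- match.arg(internode_mode)
  for (nm in c("node_diameter_um", "node_length_um",
               "axial_resistivity_ohm_cm", "membrane_capacitance_uF_cm2",
               "myelin_attenuation", "lamella_capacitance_uF_cm2",
               "lamella_conductance_mS_cm2")) {
    check_number(get(nm), nm, lower = 0, strict_lower = TRUE)
  }
  check_number(internode_diameter_um, "internode_diameter_um",
               lower = 0, strict_lower = TRUE, allow_null = TRUE)
  structure(
    list(node_diameter_um = node_diameter_um,
         node_length_um = node_length_um,
         axial_resistivity_ohm_cm = axial_resistivity_ohm_cm,
         membrane_capacitance_uF_cm2 = membrane_capacitance_uF_cm2,
         internode_diameter_um = internode_diameter_um,
         internode_mode = internode_mode,
         myelin_attenuation = myelin_attenuation,
         lamella_capacitance_uF_cm2 = lamella_capacitance_uF_cm2,
         lamella_conductance_mS_cm2 = lamella_conductance_mS_cm2),
    class = "fiber_params"
  )
}

# axial coupling conductance of an internode piece, in uS:
# g = pi d^2 / (4 Rc l), d and l converted um -> cm, S -> uS
axial_conductance_uS <- function(diameter_um, length_um, resistivity_ohm_cm) {
  d_cm <- diameter_um * 1e-4
  l_cm <- length_um * 1e-4
  pi * d_cm^2 / (4 * resistivity_ohm_cm * l_cm) * 1e6
}

#' Assemble the discrete cable system for a layout
#'
#' Builds the electrical network: one isopotential compartment per node of
#' Ranvier (capacitance `pi d mu Cm`), coupled through per-gap axial
#' conductances `pi d^2 / (4 Rc l_n)` computed from each gap's own nodal
#' separation, so unequal flanking internodes produce the corresponding
#' asymmetric coupling automatically. Ends are sealed (terminal nodes
#' couple to a single gap). In leaky-cable mode a passive mid-internode
#' compartment is inserted in every gap.
#'
#' @param layout An [make_uniform_layout()]-family `axon_layout`.
#' @param params A [fiber_params()].
#' @param membrane A [hh_model()].
#' @return A `cable_system` list with per-compartment capacitances (nF),
#'   axial conductances (uS), passive leaks, positions (um), and the map
#'   from node index to compartment index.
#' @export
#' @examples
#' sys <- assemble_cable(make_uniform_layout(3, 1150, 0.69))
#' sys$g_axial_uS # 0.0106 uS per gap
assemble_cable <- function(layout, params = fiber_params(),
                           membrane = hh_model()) {
  stopifnot(inherits(layout, "axon_layout"), inherits(params, "fiber_params"),
            inherits(membrane, "membrane_model"))
  if (any(layout$length_um <= 0)) abort("degenerate zero-length internode")
  if (params$node_length_um >= 0.25 * min(layout$length_um)) {
    warn("node length is not small compared to the shortest internode; the discrete-cable idealisation may be poor")
  }
  d <- params$node_diameter_um
  di <- params$internode_diameter_um %||% d
  mu <- params$node_length_um
  rc <- params$axial_resistivity_ohm_cm
  cm <- params$membrane_capacitance_uF_cm2

  n_pieces <- nrow(layout)
  n_nodes <- n_pieces + 1L
  node_area_cm2 <- pi * d * mu * 1e-8
  node_cap_nF <- node_area_cm2 * cm * 1e3 # uF -> nF
  pos_nodes <- node_positions(layout)

  if (params$internode_mode == "ideal_resistive") {
    cap <- rep(node_cap_nF, n_nodes)
    g_ax <- axial_conductance_uS(di, layout$length_um, rc)
    system <- list(
      capacitance_nF = cap,
      g_axial_uS = g_ax,
      is_node = rep(TRUE, n_nodes),
      area_cm2 = rep(node_area_cm2, n_nodes),
      g_pas_uS = rep(0, n_nodes),
      e_pas_mV = rep(membrane$v_rest, n_nodes),
      position_um = pos_nodes,
      node_comp = seq_len(n_nodes)
    )
  } else {
    # interleave passive myelin compartments at internode midpoints
    n_comp <- n_nodes + n_pieces
    node_comp <- seq(1L, n_comp, by = 2L)
    mid_comp <- seq(2L, n_comp, by = 2L)
    n_lam <- params$myelin_attenuation * (1 / layout$g_ratio - 1)
    my_area_cm2 <- pi * di * layout$length_um * 1e-8
    cap <- numeric(n_comp)
    cap[node_comp] <- node_cap_nF
    cap[mid_comp] <- my_area_cm2 * params$lamella_capacitance_uF_cm2 /
      n_lam * 1e3
    g_pas <- numeric(n_comp)
    g_pas[mid_comp] <- my_area_cm2 * params$lamella_conductance_mS_cm2 /
      n_lam * 1e3 # mS -> uS
    g_half <- axial_conductance_uS(di, layout$length_um / 2, rc)
    g_ax <- as.vector(rbind(g_half, g_half))
    pos <- numeric(n_comp)
    pos[node_comp] <- pos_nodes
    pos[mid_comp] <- pos_nodes[-n_nodes] + layout$length_um / 2
    area <- numeric(n_comp)
    area[node_comp] <- node_area_cm2
    system <- list(
      capacitance_nF = cap,
      g_axial_uS = g_ax,
      is_node = seq_len(n_comp) %in% node_comp,
      area_cm2 = area,
      g_pas_uS = g_pas,
      e_pas_mV = rep(membrane$v_rest, n_comp),
      position_um = pos,
      node_comp = node_comp
    )
  }
  system$n_nodes <- n_nodes
  system$membrane <- membrane
  system$params <- params
  system$layout <- layout
  class(system) <- "cable_system"
  system
}

#' @export
print.cable_system <- function(x, ...) {
  cat(sprintf("<cable_system> %d compartments (%d nodes), %.0f um, mode %s\n",
              length(x$capacitance_nF), x$n_nodes,
              max(x$position_um), x$params$internode_mode))
  invisible(x)
}
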