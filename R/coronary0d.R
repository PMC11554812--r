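# Reduced epicardial-outlet surrogate.  The full 3D coronary fluid dynamics is
# out of scope here; what survives of the outlet coupling contract is the flux
# through each outlet, driven by the gap between the inlet (aortic) pressure
# and the territory-averaged first-compartment pressure through the coupling
# conductance alpha in series with an optional lumped epicardial resistance.

#' Build the epicardial outlet network
#'
#' @param outlets an `outlet_table`.
#' @param inlet_waveform a `pressure_waveform` for the aortic/inlet pressure.
#' @param alpha coupling conductance, m^3/s/Pa (> 0).
#' @return an `outlet_network` object.
#' @export
outlet_network <- function(outlets, inlet_waveform, alpha) {
  stopifnot(inherits(inlet_waveform, "pressure_waveform"))
  if (!is.finite(alpha) || alpha <= 0) rlang::abort("alpha must be positive")
  structure(list(
    outlets = outlets,
    inlet_waveform = inlet_waveform,
    alpha = alpha
  ), class = "outlet_network")
}

#' Territory-averaged first-compartment pressure
#'
#' Volume-weighted (lumped) mean of p1 over each perfusion territory.
#'
#' @param p1 per-node compartment-1 pressures, Pa.
#' @param mesh a `wall_mesh`.
#' @param tmap a `territory_map`.
#' @return named numeric vector, one mean per outlet id.
#' @export
territory_mean_p1 <- function(p1, mesh, tmap) {
  v <- mesh$node_volumes
  means <- vapply(seq_along(tmap$outlet_id), function(j) {
    sel <- tmap$nodes_by_territory[[as.character(j)]]
    if (is.null(sel) || length(sel) == 0) {
      rlang::abort(paste0("territory of outlet ", tmap$outlet_id[j], " is empty"))
    }
    sum(p1[sel] * v[sel]) / sum(v[sel])
  }, numeric(1))
  stats::setNames(means, tmap$outlet_id)
}

#' Outlet flows of the reduced epicardial model
#'
#' q_k = (P_in(t) - mean p1 over territory k) / (R_k + 1/alpha): the series of
#' the coupling conductance and the optional lumped epicardial resistance.
#' Negative (retrograde) flows are admissible.
#'
#' @param network an `outlet_network`.
#' @param t time, s.
#' @param mean_p1 named vector of territory-mean p1, Pa (from
#'   [territory_mean_p1()]).
#' @return flows in m^3/s, one per outlet.
#' @export
outlet_flow <- function(network, t, mean_p1) {
  p_in <- waveform_value(network$inlet_waveform, t)
  (p_in - as.numeric(mean_p1)) /
    (network$outlets$resistance + 1 / network$alpha)
}

#' Distributed arterial mass source from outlet flows
#'
#' theta_1(x) = sum_k chi^k(x) q_k / |Omega^k|, in 1/s (flow per unit tissue
#' volume); its lumped volume integral equals sum_k q_k exactly.
#'
#' @param flows outlet flows, m^3/s.
#' @param mesh a `wall_mesh`.
#' @param tmap a `territory_map`.
#' @return per-node source, 1/s.
#' @export
theta1_source <- function(flows, mesh, tmap) {
  vol_m3 <- tmap$volumes$volume_mm3 * 1e-9
  if (any(vol_m3 <= 0)) rlang::abort("theta1_source: empty territory")
  dens <- as.numeric(flows) / vol_m3
  dens[tmap$label_index]
}

#' Venous return sink
#'
#' theta_3(x) = -gamma (p_3(x) - p_ra), in 1/s; the total venous outflow is
#' `-integral of theta_3` = gamma * sum_n V_n (p3_n - p_ra).
#'
#' @param p3 per-node capillary pressures, Pa.
#' @param params a `perf_params`.
#' @return per-node sink, 1/s (negative where p3 > p_ra).
#' @export
theta3_sink <- function(p3, params) {
  -params$venous_conductance * (p3 - params$right_atrium_pressure)
}
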