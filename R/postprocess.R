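# Derived quantities: inter-compartment flows, myocardial blood flow (MBF)
# maps, microvessel diameters, transmural sample waveforms and flow-morphology
# ratios.

# Frozen-coefficient convention: flows at step k use the exchange conductances
# evaluated at the state of step k-1 (the same lagging the solver applies),
# with the pressure differences of step k.
frozen_exchange <- function(sim, k) {
  S <- length(sim$times)
  km1 <- if (k == 1) S else k - 1       # periodic predecessor
  t_km1 <- if (k == 1) sim$times[S] - sim$params$period else sim$times[km1]
  pim <- evaluate_pim(sim$pim, t_km1)
  p_old <- sim$p[km1, , ]
  rigid <- sim$rigid
  dp <- function(i) if (rigid) rep(0, nrow(sim$mesh$nodes)) else p_old[, i] - pim
  list(
    beta12 = exchange_conductance(1, 2, dp(1), dp(2), sim$params, refit = sim$refit),
    beta23 = exchange_conductance(2, 3, dp(2), dp(3), sim$params, refit = sim$refit)
  )
}

#' Per-node inter-compartment flow rates
#'
#' Arteriolar flow = beta_{1,2} (p1 - p2); capillary flow = beta_{2,3}
#' (p2 - p3), both in 1/s (volume flow per unit tissue volume), with the
#' exchange conductances evaluated at the given state.
#'
#' @param p N x 3 nodal pressures, Pa.
#' @param pim per-node intramyocardial pressure, Pa.
#' @param params a `perf_params`.
#' @param refit see [vessel_area()].
#' @return list with numeric vectors `arteriolar` and `capillary`.
#' @export
compartment_flows <- function(p, pim, params, refit = FALSE) {
  b12 <- exchange_conductance(1, 2, p[, 1] - pim, p[, 2] - pim, params, refit = refit)
  b23 <- exchange_conductance(2, 3, p[, 2] - pim, p[, 3] - pim, params, refit = refit)
  list(arteriolar = b12 * (p[, 1] - p[, 2]),
       capillary = b23 * (p[, 2] - p[, 3]))
}

#' Myocardial blood flow map
#'
#' Nodal MBF = time-averaged capillary flow over the final beat, converted to
#' ml/min per 100 g of tissue: `mean_t[beta_{2,3}(p2 - p3)] * 60 * 100 /
#' rho_tissue`.  Territory means are volume-weighted; the global mean is the
#' volume-weighted mean of the nodal map.
#'
#' @param sim a `perf_sim` run with `store_fields = TRUE`.
#' @return an `mbf_map` list: `nodal` (per-node MBF), `per_territory`
#'   (tibble id / volume / mean MBF), `global_mean`.
#' @export
mbf_map <- function(sim) {
  stopifnot(inherits(sim, "perf_sim"))
  if (is.null(sim$p)) rlang::abort("simulation was run with store_fields = FALSE")
  S <- length(sim$times)
  n <- nrow(sim$mesh$nodes)
  acc <- numeric(n)
  for (k in seq_len(S)) {
    bx <- frozen_exchange(sim, k)
    acc <- acc + bx$beta23 * (sim$p[k, , 2] - sim$p[k, , 3])
  }
  flow <- acc / S                               # 1/s, time-averaged
  mbf <- flow * 60 * 100 / sim$params$tissue_density
  vn <- sim$mesh$node_volumes
  terr <- purrr::map_dfr(sim$tmap$outlet_id, function(id) {
    sel <- sim$tmap$label == id
    tibble::tibble(
      id = id,
      volume_mm3 = sum(vn[sel]),
      mbf = sum(mbf[sel] * vn[sel]) / sum(vn[sel])
    )
  })
  structure(list(
    nodal = mbf,
    per_territory = terr,
    global_mean = sum(mbf * vn) / sum(vn)
  ), class = "mbf_map")
}

#' @export
print.mbf_map <- function(x, ...) {
  cat(sprintf("<mbf_map> global mean %.1f ml/min/100g over %d territories\n",
              x$global_mean, nrow(x$per_territory)))
  print(x$per_territory)
  invisible(x)
}

#' @method tidy mbf_map
#' @export
tidy.mbf_map <- function(x, ...) x$per_territory

#' Microvessel diameters from nodal pressures
#'
#' d_i = 2 sqrt(A_i / pi) with A_i from the constitutive law at the nodal
#' transluminal pressure, reported in micrometers.
#'
#' @inheritParams compartment_flows
#' @return tibble with columns `d1_um`, `d2_um`, `d3_um` (one row per node).
#' @export
vessel_diameters <- function(p, pim, params, refit = FALSE) {
  d_um <- function(i) 2 * sqrt(vessel_area(i, p[, i] - pim, refit) / pi) * 1000
  tibble::tibble(d1_um = d_um(1), d2_um = d_um(2), d3_um = d_um(3))
}

#' Transmural sample-point waveforms
#'
#' Samples arteriolar/capillary flow and arteriolar/capillary diameters over
#' the final beat at nodes chosen by transmural depth along a wall-crossing
#' ray: among nodes within `ray_tol` (mm) of the given in-plane position, the
#' node whose transmural coordinate is closest to each target is used.
#' Default depths: subendocardium (1 mm above the endocardial surface),
#' mid-wall, subepicardium (1 mm below the epicardial surface).
#'
#' @param sim a `perf_sim` with stored fields.
#' @param depths named numeric vector of target transmural coordinates
#'   lambda in [0, 1]; defaults use the wall thickness implied by the mesh.
#' @param ray_xy length-2 in-plane (x, y) position of the sampling ray, mm;
#'   defaults to the volume centroid.
#' @param ray_tol in-plane search radius, mm (grown until nodes are found).
#' @return tibble: `site`, `lambda`, `node`, `t`, `arteriolar_flow`,
#'   `capillary_flow`, `d2_um`, `d3_um`.
#' @export
sample_waveforms <- function(sim, depths = NULL, ray_xy = NULL, ray_tol = NULL) {
  stopifnot(inherits(sim, "perf_sim"))
  if (is.null(sim$p)) rlang::abort("simulation was run with store_fields = FALSE")
  mesh <- sim$mesh
  lam <- mesh$transmural
  if (is.null(depths)) {
    thick <- stats::quantile(mesh$nodes[, 3], 0.999) - stats::quantile(mesh$nodes[, 3], 0.001)
    off <- min(0.45, 1 / max(thick, 2))        # ~1 mm in lambda units
    depths <- c(subendo = off, mid = 0.5, subepi = 1 - off)
  }
  vn <- mesh$node_volumes
  if (is.null(ray_xy)) {
    ray_xy <- c(sum(mesh$nodes[, 1] * vn), sum(mesh$nodes[, 2] * vn)) / sum(vn)
  }
  if (is.null(ray_tol)) ray_tol <- 2 * sim$params$mesh_size
  r2 <- (mesh$nodes[, 1] - ray_xy[1])^2 + (mesh$nodes[, 2] - ray_xy[2])^2
  sel <- which(r2 <= ray_tol^2)
  while (length(sel) < length(depths)) {
    ray_tol <- ray_tol * 2
    sel <- which(r2 <= ray_tol^2)
    if (ray_tol > 1e6) rlang::abort("sampling ray misses the domain")
  }
  nodes <- vapply(depths, function(lt) sel[which.min(abs(lam[sel] - lt))],
                  integer(1))
  S <- length(sim$times)
  purrr::map_dfr(seq_along(depths), function(j) {
    nd <- nodes[j]
    art <- cap <- d2 <- d3 <- numeric(S)
    for (k in seq_len(S)) {
      bx <- frozen_exchange(sim, k)
      art[k] <- bx$beta12[nd] * (sim$p[k, nd, 1] - sim$p[k, nd, 2])
      cap[k] <- bx$beta23[nd] * (sim$p[k, nd, 2] - sim$p[k, nd, 3])
      pim_k <- evaluate_pim(sim$pim, sim$times[k])[nd]
      dp2 <- if (sim$rigid) 0 else sim$p[k, nd, 2] - pim_k
      dp3 <- if (sim$rigid) 0 else sim$p[k, nd, 3] - pim_k
      d2[k] <- 2 * sqrt(vessel_area(2, dp2, sim$refit) / pi) * 1000
      d3[k] <- 2 * sqrt(vessel_area(3, dp3, sim$refit) / pi) * 1000
    }
    tibble::tibble(
      site = names(depths)[j], lambda = lam[nd], node = nd, t = sim$times,
      arteriolar_flow = art, capillary_flow = cap, d2_um = d2, d3_um = d3
    )
  })
}

#' Flow-morphology ratios of an inflow waveform
#'
#' Systolic/diastolic peak-flow ratio, systolic/diastolic mean-flow ratio and
#' mean/peak ratios within each phase, computed on the total arterial inflow
#' over one period with the systolic window taken from the driving waveform.
#'
#' @param x a `perf_sim`, or a numeric flow series.
#' @param times,window for the numeric method: sample times (s) and the
#'   systolic window `c(t_on, t_off)` within the period.
#' @param ... unused.
#' @return a one-row tibble of the four ratios plus the phase means/peaks.
#' @export
flow_ratios <- function(x, ...) UseMethod("flow_ratios")

#' @rdname flow_ratios
#' @export
flow_ratios.perf_sim <- function(x, ...) {
  flow_ratios(x$inflow * 6e7, times = x$times, window = x$systolic_window)
}

#' @rdname flow_ratios
#' @export
flow_ratios.numeric <- function(x, times, window, ...) {
  period <- max(times)
  tt <- times %% period
  sys <- tt >= window[1] & tt < window[2]
  if (!any(sys) || all(sys)) rlang::abort("systolic window is empty or covers the whole period")
  s <- x[sys]; d <- x[!sys]
  tibble::tibble(
    sys_dia_peak_ratio = max(s) / max(d),
    sys_dia_mean_ratio = mean(s) / mean(d),
    mean_peak_systole = mean(s) / max(s),
    mean_peak_diastole = mean(d) / max(d),
    mean_systolic = mean(s),
    mean_diastolic = mean(d),
    peak_systolic = max(s),
    peak_diastolic = max(d)
  )
}

#' Recompute the venous outflow series from stored pressure snapshots
#'
#' Post-hoc recomputation of `-integral theta_3 dV` from the stored capillary
#' pressures; matches the per-step logged series to solver precision.
#'
#' @param sim a `perf_sim` with stored fields.
#' @return numeric vector, m^3/s.
#' @export
recompute_venous_outflow <- function(sim) {
  stopifnot(inherits(sim, "perf_sim"))
  if (is.null(sim$p)) rlang::abort("simulation was run with store_fields = FALSE")
  vn <- sim$mesh$node_volumes * 1e-9
  vapply(seq_len(length(sim$times)), function(k) {
    sum(vn * sim$params$venous_conductance *
          (sim$p[k, , 3] - sim$params$right_atrium_pressure))
  }, numeric(1))
}
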