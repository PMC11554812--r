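# Coupled time integration.  Within each time step the reduced epicardial
# outlet model and the Darcy solve are iterated to a fixed point with
# under-relaxation of the outlet flows (the stiffest interface quantity);
# across steps, heartbeats are repeated until the pressure fields are
# cycle-periodic.

#' Relaxed fixed-point iteration of a generic map
#'
#' x_s = eta * F(x_{s-1}) + (1 - eta) * x_{s-1}, stopping when the normalized
#' difference between consecutive iterates falls below `eps`.  For an affine
#' map with slope m the relaxed iteration contracts geometrically with factor
#' |1 - eta + eta m|.
#'
#' @param f the map (vector to vector).
#' @param x0 starting point.
#' @param eta relaxation factor in (0, 1].
#' @param eps normalized-difference tolerance.
#' @param s_max iteration cap.
#' @return list with `x`, `diffs` (per-iteration normalized differences),
#'   `iterations`, `converged`.
#' @export
relaxed_fixed_point <- function(f, x0, eta = 0.1, eps = 1e-10, s_max = 200L) {
  x <- x0
  diffs <- numeric(0)
  for (s in seq_len(s_max)) {
    xn <- eta * f(x) + (1 - eta) * x
    d <- sqrt(sum((xn - x)^2)) / max(sqrt(sum(xn^2)), .Machine$double.xmin)
    diffs <- c(diffs, d)
    x <- xn
    if (d < eps) {
      return(list(x = x, diffs = diffs, iterations = s, converged = TRUE))
    }
  }
  list(x = x, diffs = diffs, iterations = s_max, converged = FALSE)
}

#' One coupled time step (relaxed fixed point between outlet model and Darcy)
#'
#' Iterates, from the previous step's flows: (i) outlet flows from the
#' current territory-mean p1; (ii) relaxation of the flows; (iii) Darcy solve
#' with the corresponding arterial source.  Stops when the normalized flow
#' difference (Euclidean) and pressure difference (volume-weighted L2, per
#' compartment) all fall below the tolerance.
#'
#' @param p N x 3 nodal pressures at t^n, Pa.
#' @param q_prev outlet flows of the previous step (warm start), m^3/s.
#' @param t_next time t^{n+1}, s.
#' @param mesh,tmap,network,params simulation ingredients.
#' @param pim_n per-node intramyocardial pressure at t^n, Pa.
#' @param dpim_dt per-node discrete dP_im/dt, Pa/s.
#' @param structure precomputed [darcy_structure()] (built when omitted).
#' @param factor reusable Cholesky factor (numerically updated once per step;
#'   reused without refactoring across the inner iterations).
#' @param rigid logical, rigid-microcirculation mode.
#' @param refit see [vessel_area()].
#' @param accelerate use Aitken dynamic relaxation (starting from the
#'   configured eta) instead of the plain fixed-eta relaxation; both converge
#'   to the same fixed point under the same stopping rule.
#' @return list: `p` (N x 3 at t^{n+1}), `q`, `theta1`, `iterations`,
#'   `diff_flow`, `diff_pressure` (per-iteration), `converged`, `factor`,
#'   `system`.
#' @export
fixed_point_step <- function(p, q_prev, t_next, mesh, tmap, network, params,
                             pim_n, dpim_dt, structure = NULL, factor = NULL,
                             rigid = FALSE, refit = FALSE, accelerate = FALSE) {
  sys <- assemble_step(mesh, p, pim_n, params, dpim_dt = dpim_dt,
                       dt = params$dt, rigid = rigid, structure = structure,
                       refit = refit)
  eta <- params$relaxation
  eps <- params$fp_tolerance
  s_max <- params$max_fp_iterations
  vn <- sys$vn
  p_it <- p
  q_it <- q_prev
  diff_flow <- diff_p <- numeric(0)
  converged <- FALSE
  theta1 <- NULL
  r_prev <- NULL
  first <- TRUE
  for (s in seq_len(s_max)) {
    mp1 <- territory_mean_p1(p_it[, 1], mesh, tmap)
    resid <- outlet_flow(network, t_next, mp1) - q_it
    if (accelerate && !is.null(r_prev)) {
      dr <- resid - r_prev
      den <- sum(dr^2)
      if (den > 0) eta <- max(1e-4, min(1, -eta * sum(r_prev * dr) / den))
    }
    q_new <- q_it + eta * resid
    r_prev <- resid
    theta1 <- theta1_source(q_new, mesh, tmap)
    sol <- solve_step(sys, theta1 = theta1, factor = factor, refactor = first)
    factor <- sol$factor
    first <- FALSE
    dq <- sqrt(sum((q_new - q_it)^2)) /
      max(sqrt(sum(q_new^2)), .Machine$double.xmin)
    dp <- max(vapply(1:3, function(i) {
      sqrt(sum(vn * (sol$p[, i] - p_it[, i])^2)) /
        max(sqrt(sum(vn * sol$p[, i]^2)), .Machine$double.xmin)
    }, numeric(1)))
    diff_flow <- c(diff_flow, dq)
    diff_p <- c(diff_p, dp)
    p_it <- sol$p
    q_it <- q_new
    if (dq < eps && dp < eps) { converged <- TRUE; break }
  }
  if (!converged) {
    rlang::warn(sprintf(
      "fixed-point step at t = %.4f s hit the iteration cap (%d); last diffs %.2g / %.2g",
      t_next, s_max, diff_flow[length(diff_flow)], diff_p[length(diff_p)]))
  }
  list(p = p_it, q = q_it, theta1 = theta1, iterations = length(diff_flow),
       diff_flow = diff_flow, diff_pressure = diff_p, converged = converged,
       factor = factor, system = sys)
}

# Steady coupled solve (used for the initial condition): rigid coefficients,
# no compliance.  The steady problem is affine in the outlet flows, so the
# interface system is solved exactly with one probe solve per outlet instead
# of a fixed-point iteration (whose steady-state gain far exceeds the
# per-time-step one).
steady_initial_state <- function(mesh, tmap, network, params, pim0,
                                 structure, refit = FALSE) {
  n <- nrow(mesh$nodes)
  nq <- nrow(network$outlets)
  p0 <- matrix(params$right_atrium_pressure, n, 3)
  sys <- assemble_step(mesh, p0, pim0, params, dt = Inf, rigid = TRUE,
                       structure = structure, refit = refit)
  sol0 <- solve_step(sys, theta1 = rep(0, n))
  factor <- sol0$factor
  a <- territory_mean_p1(sol0$p[, 1], mesh, tmap)
  qscale <- 1e-7                         # probe magnitude, m^3/s
  B <- matrix(0, nq, nq)
  for (k in seq_len(nq)) {
    qk <- rep(0, nq); qk[k] <- qscale
    sk <- solve_step(sys, theta1 = theta1_source(qk, mesh, tmap), factor = factor)
    B[, k] <- (territory_mean_p1(sk$p[, 1], mesh, tmap) - a) / qscale
  }
  d_cond <- 1 / (network$outlets$resistance + 1 / network$alpha)
  p_in <- waveform_value(network$inlet_waveform, 0)
  q <- solve(diag(nq) + d_cond * B, d_cond * (p_in - as.numeric(a)))
  sol <- solve_step(sys, theta1 = theta1_source(q, mesh, tmap), factor = factor)
  list(p = sol$p, q = q)
}

#' Run the coupled simulation to a periodic state
#'
#' Integrates the compliant (or rigid) multi-compartment Darcy model coupled
#' to the reduced epicardial outlet model over successive heartbeats, starting
#' from a steady rigid solve at the diastolic baseline.  Stops when the
#' volume-weighted L2 difference of all nodal pressures between consecutive
#' cycles, normalized by the cycle mean magnitude, drops below `cycle_tol`,
#' or after `n_beats` beats.  The returned object holds the last full cycle.
#'
#' @param mesh a `wall_mesh` (with transmural coordinate).
#' @param outlets an `outlet_table`.
#' @param params a `perf_params`.
#' @param n_beats maximum number of heartbeats.
#' @param cycle_tol cycle-to-cycle periodicity tolerance (default 1%).
#' @param rigid logical: rigid-microcirculation mode (zero compliance, areas
#'   frozen at zero transluminal pressure).
#' @param plv,aortic optional `pressure_waveform`s overriding the parametric
#'   defaults built from `params`.
#' @param refit see [vessel_area()].
#' @param accelerate use Aitken dynamic relaxation in the per-step coupling
#'   iteration (default); `FALSE` keeps the plain fixed-eta relaxation.
#' @param store_fields store the full nodal pressure series of the last beat
#'   (needed for MBF maps and sample waveforms).
#' @return a `perf_sim` object; see [tidy.perf_sim()], [glance.perf_sim()],
#'   [mbf_map()], [flow_ratios()].
#' @export
run_heartbeats <- function(mesh, outlets, params, n_beats = 10L,
                           cycle_tol = 0.01, rigid = FALSE,
                           plv = NULL, aortic = NULL, refit = FALSE,
                           accelerate = TRUE, store_fields = TRUE) {
  stopifnot(inherits(mesh, "wall_mesh"))
  if (is.null(mesh$transmural)) {
    mesh$transmural <- compute_transmural_coordinate(mesh)
  }
  if (is.null(plv)) {
    plv <- build_plv_waveform(params$peak_pressure, params$period,
                              params$systolic_fraction,
                              params$lv_diastolic_pressure)
  }
  if (is.null(aortic)) {
    aortic <- build_aortic_waveform(params$peak_pressure, params$period,
                                    params$systolic_fraction)
  }
  pim <- pim_field(plv, mesh$transmural)
  tmap <- assign_territories(mesh, outlets)
  network <- outlet_network(outlets, aortic, params$coupling_conductance)
  structure <- darcy_structure(mesh)

  S <- max(1L, as.integer(round(params$period / params$dt)))
  dt <- params$period / S
  params$dt <- dt
  times <- dt * seq_len(S)

  init <- steady_initial_state(mesh, tmap, network, params,
                               evaluate_pim(pim, 0), structure, refit)
  p <- init$p; q <- init$q
  n <- nrow(mesh$nodes)
  factor <- NULL
  prev_series <- NULL
  cycle_diffs <- numeric(0)
  iters <- integer(0)
  beat_done <- 0L
  series <- NULL

  for (beat in seq_len(n_beats)) {
    p_series <- array(NA_real_, c(S, n, 3))
    q_series <- matrix(NA_real_, S, nrow(outlets))
    balance <- numeric(S)
    inflow <- venous <- numeric(S)
    for (k in seq_len(S)) {
      t_n <- (beat - 1) * params$period + (k - 1) * dt
      pim_n <- evaluate_pim(pim, t_n)
      dpim <- pim_time_derivative(pim, t_n, dt)
      st <- fixed_point_step(p, q, t_n + dt, mesh, tmap, network, params,
                             pim_n, dpim, structure = structure,
                             factor = factor, rigid = rigid, refit = refit,
                             accelerate = accelerate)
      if (anyNA(st$p)) {
        rlang::abort(sprintf("non-finite state at beat %d, step %d (t = %.4f s)",
                             beat, k, t_n + dt))
      }
      bal <- step_mass_balance(st$system, st$p, p, dpim, st$theta1, params)
      p <- st$p; q <- st$q; factor <- st$factor
      p_series[k, , ] <- p
      q_series[k, ] <- q
      iters <- c(iters, st$iterations)
      balance[k] <- bal$residual
      inflow[k] <- bal$inflow
      venous[k] <- bal$venous_outflow
    }
    series <- list(p = p_series, q = q_series, balance = balance,
                   inflow = inflow, venous = venous)
    beat_done <- beat
    if (!is.null(prev_series)) {
      num <- sqrt(mean((p_series - prev_series)^2))
      den <- sqrt(mean(p_series^2))
      cycle_diffs <- c(cycle_diffs, num / den)
      if (cycle_diffs[length(cycle_diffs)] < cycle_tol) break
    }
    prev_series <- p_series
  }

  structure(list(
    mesh = mesh, params = params, outlets = outlets, tmap = tmap,
    plv = plv, aortic = aortic, pim = pim, rigid = rigid, refit = refit,
    times = times,
    p = if (store_fields) series$p else NULL,
    q = series$q,
    inflow = series$inflow,
    venous_outflow = series$venous,
    balance_residual = series$balance,
    systolic_window = plv$meta$systolic_window %||% c(0, params$systolic_fraction * params$period),
    report = list(
      beats = beat_done,
      cycle_diffs = cycle_diffs,
      iterations = iters,
      mean_iterations = mean(iters),
      converged_periodic = length(cycle_diffs) > 0 &&
        cycle_diffs[length(cycle_diffs)] < cycle_tol
    )
  ), class = "perf_sim")
}

#' @rdname run_heartbeats
#' @export
simulate_perfusion <- run_heartbeats

#' @export
print.perf_sim <- function(x, ...) {
  cat(sprintf("<perf_sim> %s microcirculation, %d beats (cycle diff %.3g)\n",
              if (x$rigid) "rigid" else "compliant", x$report$beats,
              if (length(x$report$cycle_diffs)) utils::tail(x$report$cycle_diffs, 1) else NA))
  cat(sprintf("  mesh: %d nodes, %d outlets; mean fixed-point iterations %.1f\n",
              nrow(x$mesh$nodes), nrow(x$outlets), x$report$mean_iterations))
  cat(sprintf("  mean inflow %.2f ml/min, mean venous outflow %.2f ml/min\n",
              mean(x$inflow) * 6e7, mean(x$venous_outflow) * 6e7))
  invisible(x)
}

#' Per-step time series of a simulation
#'
#' One row per time step of the final (periodic) beat: total arterial inflow,
#' venous outflow (both ml/min), per-compartment volume-averaged pressures
#' (mmHg) and the systole indicator.
#'
#' @param x a `perf_sim`.
#' @param ... unused.
#' @return a tibble.
#' @method tidy perf_sim
#' @export
tidy.perf_sim <- function(x, ...) {
  vn <- x$mesh$node_volumes
  wmean <- function(v) sum(v * vn) / sum(vn)
  pm <- if (!is.null(x$p)) {
    vapply(1:3, function(i) apply(x$p[, , i, drop = FALSE], 1, wmean), numeric(length(x$times)))
  } else matrix(NA_real_, length(x$times), 3)
  w <- x$systolic_window
  tibble::tibble(
    t = x$times,
    inflow_ml_min = x$inflow * 6e7,
    venous_outflow_ml_min = x$venous_outflow * 6e7,
    p1_mmHg = pa_to_mmhg(pm[, 1]),
    p2_mmHg = pa_to_mmhg(pm[, 2]),
    p3_mmHg = pa_to_mmhg(pm[, 3]),
    systole = (x$times %% x$params$period) >= w[1] &
      (x$times %% x$params$period) < w[2]
  )
}

#' One-row summary of a simulation
#'
#' @param x a `perf_sim`.
#' @param ... unused.
#' @return a tibble with beats, periodicity diff, mean flows, mean pressures
#'   and global mean MBF.
#' @method glance perf_sim
#' @export
glance.perf_sim <- function(x, ...) {
  d <- tidy(x)
  mbf <- tryCatch(mbf_map(x)$global_mean, error = function(e) NA_real_)
  tibble::tibble(
    beats = x$report$beats,
    cycle_diff = if (length(x$report$cycle_diffs)) utils::tail(x$report$cycle_diffs, 1) else NA_real_,
    mean_fp_iterations = x$report$mean_iterations,
    mean_inflow_ml_min = mean(d$inflow_ml_min),
    mean_venous_ml_min = mean(d$venous_outflow_ml_min),
    mean_p1_mmHg = mean(d$p1_mmHg),
    mean_p2_mmHg = mean(d$p2_mmHg),
    mean_p3_mmHg = mean(d$p3_mmHg),
    mean_mbf = mbf
  )
}

#' Plot phasic inflow / outflow of a simulation
#'
#' @param object a `perf_sim`.
#' @param ... unused.
#' @return a ggplot of total arterial inflow and venous outflow over the
#'   final beat, with the systolic interval shaded.
#' @method autoplot perf_sim
#' @export
autoplot.perf_sim <- function(object, ...) {
  d <- tidy(object)
  long <- tidyr::pivot_longer(
    d[, c("t", "inflow_ml_min", "venous_outflow_ml_min")],
    -"t", names_to = "signal", values_to = "flow"
  )
  w <- object$systolic_window
  ggplot2::ggplot(long, ggplot2::aes(x = .data$t, y = .data$flow,
                                     colour = .data$signal)) +
    ggplot2::annotate("rect", xmin = w[1], xmax = w[2], ymin = -Inf, ymax = Inf,
                      alpha = 0.12) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time in cycle [s]", y = "flow [ml/min]", colour = NULL)
}
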