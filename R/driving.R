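# Time-periodic driving pressures: the left-ventricular chamber waveform that
# generates the intramyocardial pressure, and the aortic (coronary inlet)
# waveform that drives the epicardial outlet surrogate.
#
# Both are built from a C^1 parametric family (smoothstep rise - plateau -
# smoothstep fall over the systolic interval) whose two personalization knobs
# are the peak pressure and the systolic interval; tabulated waveforms can be
# imported from CSV instead and are interpolated with a periodic spline.

smoothstep <- function(u) {
  u <- pmin(1, pmax(0, u))
  u * u * (3 - 2 * u)
}

new_waveform <- function(fun, period, meta = list()) {
  grid <- seq(0, period, length.out = 513)
  structure(list(
    fun = fun, period = period,
    samples = tibble::tibble(t = grid, value = fun(grid)),
    meta = meta
  ), class = "pressure_waveform")
}

#' Evaluate a pressure waveform
#'
#' @param w a `pressure_waveform`.
#' @param t time(s) in s; evaluated periodically.
#' @return pressures in Pa.
#' @export
waveform_value <- function(w, t) {
  stopifnot(inherits(w, "pressure_waveform"))
  w$fun(t %% w$period)
}

#' Left-ventricular chamber pressure waveform
#'
#' C^1 periodic surrogate of the chamber pressure: a diastolic baseline with a
#' smoothstep rise - plateau - smoothstep fall bump over the systolic
#' interval `[0, systolic_fraction * period)`; the plateau attains `peak`
#' exactly.  The fall ramp (isovolumic relaxation) is centered on the end of
#' the systolic interval: at aortic valve closure the chamber pressure is
#' mid-fall, and relaxation completes in early diastole — this is what drives
#' the early-diastolic coronary refill surge.
#'
#' @param peak peak pressure, Pa.
#' @param period heartbeat period T, s.
#' @param systolic_fraction fraction of the period occupied by systole
#'   (ejection), in (0, 1).
#' @param baseline diastolic baseline pressure, Pa (must be < `peak`).
#' @param rise_fraction fraction of the systolic interval used by each of the
#'   rise and fall ramps (plateau covers the rest; the fall ramp straddles
#'   the end of the interval symmetrically).
#' @return a `pressure_waveform` whose `meta$systolic_window` is
#'   `c(0, systolic_fraction * period)`.
#' @examples
#' w <- build_plv_waveform(mmhg_to_pa(140), 0.714, 0.37, mmhg_to_pa(8))
#' max(w$samples$value) == mmhg_to_pa(140)
#' @export
build_plv_waveform <- function(peak, period, systolic_fraction = 0.37,
                               baseline = mmhg_to_pa(8), rise_fraction = 0.3) {
  if (!(systolic_fraction > 0 && systolic_fraction < 1)) {
    rlang::abort("systolic_fraction must lie in (0, 1)")
  }
  if (baseline < 0 || baseline >= peak) rlang::abort("need 0 <= baseline < peak")
  w <- systolic_fraction * period
  fl <- rise_fraction * w              # fall-ramp length
  t_rise <- rise_fraction * w
  t_f0 <- w - fl / 2                   # fall starts before end-systole
  t_f1 <- w + fl / 2                   # ... and completes in early diastole
  if (t_f1 >= period) rlang::abort("systolic interval too long for this period")
  fun <- function(t) {
    t <- t %% period
    v <- ifelse(t < t_rise, smoothstep(t / t_rise),
                ifelse(t < t_f0, 1,
                       ifelse(t < t_f1, smoothstep((t_f1 - t) / fl), 0)))
    baseline + (peak - baseline) * v
  }
  new_waveform(fun, period, meta = list(
    kind = "plv", peak = peak, baseline = baseline,
    systolic_fraction = systolic_fraction,
    bump_support = c(0, t_f1),
    systolic_window = c(0, w)
  ))
}

#' Aortic (coronary inlet) pressure waveform
#'
#' C^1 periodic arterial-like curve: during systole a rise from the diastolic
#' floor to `peak` followed by a fall to an end-systolic shoulder; during
#' diastole a smooth decay from the shoulder back to the floor.  If
#' `mean_target` is given, the curve is affinely rescaled about its peak so
#' the time average matches while the maximum stays exactly `peak`.
#'
#' @inheritParams build_plv_waveform
#' @param diastolic_floor minimum diastolic pressure, Pa
#'   (default `0.55 * peak`).
#' @param shoulder end-systolic pressure, Pa (default `0.75 * peak`).
#' @param mean_target optional time-average pressure to enforce, Pa.
#' @param lag timing offset (s) of this waveform relative to the chamber
#'   waveform (positive delays the aortic systole).
#' @return a `pressure_waveform`.
#' @export
build_aortic_waveform <- function(peak, period, systolic_fraction = 0.37,
                                  diastolic_floor = 0.55 * peak,
                                  shoulder = 0.75 * peak,
                                  mean_target = NULL, lag = 0) {
  if (!(systolic_fraction > 0 && systolic_fraction < 1)) {
    rlang::abort("systolic_fraction must lie in (0, 1)")
  }
  if (diastolic_floor <= 0 || diastolic_floor >= peak) {
    rlang::abort("need 0 < diastolic_floor < peak")
  }
  if (shoulder <= diastolic_floor || shoulder >= peak) {
    rlang::abort("need diastolic_floor < shoulder < peak")
  }
  w <- systolic_fraction * period
  s_pk <- 0.45                       # peak position within systole
  base_fun <- function(t) {
    t <- (t - lag) %% period
    ifelse(t < w, {
      s <- t / w
      ifelse(s < s_pk,
             diastolic_floor + (peak - diastolic_floor) * smoothstep(s / s_pk),
             shoulder + (peak - shoulder) * smoothstep((1 - s) / (1 - s_pk)))
    },
    diastolic_floor + (shoulder - diastolic_floor) *
      (1 - smoothstep((t - w) / (period - w))))
  }
  fun <- base_fun
  if (!is.null(mean_target)) {
    if (mean_target >= peak) rlang::abort("mean_target must be below peak")
    grid <- seq(0, period, length.out = 4097)[-4097]
    m0 <- mean(base_fun(grid))
    b <- (peak - mean_target) / (peak - m0)
    if (b <= 0) rlang::abort("mean_target is infeasible for this waveform family")
    fun <- function(t) peak + b * (base_fun(t) - peak)
  }
  new_waveform(fun, period, meta = list(
    kind = "aortic", peak = peak, diastolic_floor = diastolic_floor,
    systolic_fraction = systolic_fraction, lag = lag,
    systolic_window = c(lag, lag + w)
  ))
}

#' Import / export waveforms as two-column CSV
#'
#' CSV columns: `t` (s over one period) and `p_mmHg`.  Imported samples are
#' interpolated with a periodic cubic spline.
#'
#' @param path CSV path.
#' @param period optional period override (defaults to the last sample time).
#' @return `read_waveform_csv`: a `pressure_waveform`; `write_waveform_csv`:
#'   the path, invisibly.
#' @export
read_waveform_csv <- function(path, period = NULL) {
  d <- utils::read.csv(path)
  if (!all(c("t", "p_mmHg") %in% names(d))) {
    rlang::abort("waveform CSV must have columns t, p_mmHg")
  }
  d <- d[order(d$t), ]
  if (is.null(period)) period <- max(d$t)
  tt <- d$t; pp <- mmhg_to_pa(d$p_mmHg)
  if (abs(tt[1]) > 1e-12) { tt <- c(0, tt); pp <- c(pp[length(pp)], pp) }
  if (abs(tt[length(tt)] - period) > 1e-12) { tt <- c(tt, period); pp <- c(pp, pp[1]) }
  pp[length(pp)] <- pp[1]            # enforce periodicity
  sf <- stats::splinefun(tt, pp, method = "periodic")
  new_waveform(function(t) sf(t %% period), period,
               meta = list(kind = "tabulated", source = path))
}

#' @rdname read_waveform_csv
#' @param w a `pressure_waveform`.
#' @param n number of samples over one period.
#' @export
write_waveform_csv <- function(w, path, n = 512) {
  grid <- seq(0, w$period, length.out = n + 1)
  utils::write.csv(
    data.frame(t = grid, p_mmHg = pa_to_mmhg(waveform_value(w, grid))),
    path, row.names = FALSE
  )
  invisible(path)
}

#' Intramyocardial pressure field
#'
#' Couples a chamber waveform to the transmural coordinate of a mesh:
#' `P_im(x, t) = [endo_factor - (endo_factor - epi_factor) * lambda(x)] * P_LV(t)`,
#' i.e. 0.9 of the chamber pressure at the endocardium decreasing linearly to
#' 0.3 at the epicardium (experimental transmural decay of tissue pressure).
#'
#' @param waveform a `pressure_waveform` for the chamber pressure.
#' @param lambda per-node transmural coordinate in [0, 1] (from
#'   [compute_transmural_coordinate()]), or a `wall_mesh` carrying one.
#' @param endo_factor,epi_factor ratios of tissue to chamber pressure at the
#'   two surfaces (defaults 0.9 and 0.3).
#' @return a `pim_field` object.
#' @export
pim_field <- function(waveform, lambda, endo_factor = 0.9, epi_factor = 0.3) {
  if (inherits(lambda, "wall_mesh")) lambda <- lambda$transmural
  stopifnot(inherits(waveform, "pressure_waveform"), is.numeric(lambda))
  structure(list(
    waveform = waveform,
    factor = endo_factor - (endo_factor - epi_factor) * lambda,
    endo_factor = endo_factor, epi_factor = epi_factor
  ), class = "pim_field")
}

#' Evaluate the intramyocardial pressure at a time instant
#'
#' @param field a `pim_field`.
#' @param t time, s.
#' @return per-node pressures, Pa.
#' @export
evaluate_pim <- function(field, t) {
  stopifnot(inherits(field, "pim_field"))
  field$factor * waveform_value(field$waveform, t)
}

#' Discrete time derivative of the intramyocardial pressure
#'
#' Exactly the difference quotient used by the semi-implicit solver:
#' `[P_im(t + dt) - P_im(t)] / dt` nodewise.
#'
#' @param field a `pim_field`.
#' @param t time, s.
#' @param dt time step, s (> 0).
#' @return per-node rates, Pa/s.
#' @export
pim_time_derivative <- function(field, t, dt) {
  if (dt <= 0) rlang::abort("dt must be positive")
  (evaluate_pim(field, t + dt) - evaluate_pim(field, t)) / dt
}

#' @export
print.pressure_waveform <- function(x, ...) {
  cat(sprintf("<pressure_waveform> %s: T = %.3f s, range %.1f-%.1f mmHg\n",
              x$meta$kind %||% "custom", x$period,
              pa_to_mmhg(min(x$samples$value)), pa_to_mmhg(max(x$samples$value))))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Plot a pressure waveform
#'
#' @param object a `pressure_waveform`.
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot pressure_waveform
#' @export
autoplot.pressure_waveform <- function(object, ...) {
  d <- object$samples
  ggplot2::ggplot(d, ggplot2::aes(x = .data$t, y = pa_to_mmhg(.data$value))) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time [s]", y = "pressure [mmHg]")
}
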