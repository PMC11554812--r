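# Desk-scale in-silico studies: the rigid-versus-compliant comparison and the
# parameter sensitivity sweeps (specific permeability, length-density and
# morphometry-factor scalings, per-compartment length-density scenarios).

#' Compare compliant and rigid microcirculation models
#'
#' Runs the coupled simulation twice on identical mesh, outlets and waveforms:
#' once with the full compliant formulation and once with zero compliances and
#' cross-sections frozen at zero transluminal pressure.  Reports paired flow
#' waveforms and flow-morphology ratio tables.
#'
#' @inheritParams run_heartbeats
#' @return a `perf_comparison` list: `compliant`, `rigid` (both `perf_sim`),
#'   `waveforms` (long tibble) and `ratios` (tibble with a `model` column).
#' @export
compare_rigid <- function(mesh, outlets, params, n_beats = 10L,
                          cycle_tol = 0.01, refit = FALSE) {
  runs <- list(
    compliant = run_heartbeats(mesh, outlets, params, n_beats = n_beats,
                               cycle_tol = cycle_tol, rigid = FALSE,
                               refit = refit),
    rigid = run_heartbeats(mesh, outlets, params, n_beats = n_beats,
                           cycle_tol = cycle_tol, rigid = TRUE, refit = refit)
  )
  waveforms <- purrr::imap_dfr(runs, function(s, nm) {
    dplyr::mutate(tidy(s), model = nm)
  })
  ratios <- purrr::imap_dfr(runs, function(s, nm) {
    dplyr::mutate(flow_ratios(s), model = nm)
  })
  structure(list(
    compliant = runs$compliant, rigid = runs$rigid,
    waveforms = waveforms, ratios = ratios
  ), class = "perf_comparison")
}

#' @export
print.perf_comparison <- function(x, ...) {
  cat("<perf_comparison> compliant vs rigid microcirculation\n")
  print(x$ratios[, c("model", "sys_dia_peak_ratio", "sys_dia_mean_ratio")])
  invisible(x)
}

apply_sweep_value <- function(params, parameter, value) {
  switch(parameter,
    kappa = { params$specific_permeability <- value; params },
    nL_scale = { params$length_density <- params$length_density * value; params },
    delta_scale = { params$morphometry_factor <- params$morphometry_factor * value; params },
    nL_per_compartment = {
      if (length(value) != 3) rlang::abort("nL_per_compartment values must be length-3 scale vectors")
      params$length_density <- params$length_density * value
      params
    },
    rlang::abort(paste0("unknown sweep parameter: ", parameter))
  )
}

#' Parameter sensitivity sweep
#'
#' Reruns the coupled simulation to a periodic state for each value of one
#' model parameter and summarizes: global mean MBF, regional MBF variance
#' (across territory means), mean and diastolic-mean arteriolar pressure, and
#' mean systolic / diastolic inflow.  A non-convergent member is recorded as a
#' failed row and the sweep continues.
#'
#' @param mesh,outlets,params as in [run_heartbeats()].
#' @param parameter one of `"kappa"`, `"nL_scale"`, `"delta_scale"`,
#'   `"nL_per_compartment"`.
#' @param values numeric vector of parameter values / scale factors, or for
#'   `nL_per_compartment` a list of length-3 scale vectors.
#' @param n_beats,cycle_tol,refit forwarded to [run_heartbeats()].
#' @return a `perf_sweep` tibble, one row per sweep member.
#' @export
sensitivity_sweep <- function(mesh, outlets, params,
                              parameter = c("kappa", "nL_scale", "delta_scale",
                                            "nL_per_compartment"),
                              values, n_beats = 10L, cycle_tol = 0.01,
                              refit = FALSE) {
  parameter <- match.arg(parameter)
  if (length(values) == 0) rlang::abort("values must be nonempty")
  if (parameter == "nL_per_compartment" && !is.list(values)) {
    values <- list(values)
  }
  vlist <- if (is.list(values)) values else as.list(values)
  rows <- purrr::imap(vlist, function(v, idx) {
    label <- if (length(v) == 1) format(v) else paste(v, collapse = "x")
    res <- tryCatch({
      pv <- apply_sweep_value(params, parameter, v)
      sim <- run_heartbeats(mesh, outlets, pv, n_beats = n_beats,
                            cycle_tol = cycle_tol, refit = refit)
      d <- tidy(sim)
      m <- mbf_map(sim)
      tibble::tibble(
        parameter = parameter, value = label,
        value_num = if (length(v) == 1) as.numeric(v) else NA_real_,
        mean_mbf = m$global_mean,
        regional_mbf_variance = stats::var(m$per_territory$mbf),
        mean_p2_mmHg = mean(d$p2_mmHg),
        diastolic_p2_mmHg = mean(d$p2_mmHg[!d$systole]),
        mean_inflow_ml_min = mean(d$inflow_ml_min),
        systolic_inflow_ml_min = mean(d$inflow_ml_min[d$systole]),
        diastolic_inflow_ml_min = mean(d$inflow_ml_min[!d$systole]),
        beats = sim$report$beats,
        converged = sim$report$converged_periodic,
        failed = FALSE, error = NA_character_
      )
    }, error = function(e) {
      tibble::tibble(
        parameter = parameter, value = label,
        value_num = if (length(v) == 1) as.numeric(v) else NA_real_,
        mean_mbf = NA_real_, regional_mbf_variance = NA_real_,
        mean_p2_mmHg = NA_real_, diastolic_p2_mmHg = NA_real_,
        mean_inflow_ml_min = NA_real_, systolic_inflow_ml_min = NA_real_,
        diastolic_inflow_ml_min = NA_real_, beats = NA_integer_,
        converged = FALSE, failed = TRUE, error = conditionMessage(e)
      )
    })
    res
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("perf_sweep", class(out))
  out
}

#' Plot a sensitivity sweep summary
#'
#' @param object a `perf_sweep`.
#' @param y summary column to plot (default global mean MBF).
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot perf_sweep
#' @export
autoplot.perf_sweep <- function(object, y = "mean_mbf", ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$value_num, y = .data[[y]])) +
    ggplot2::geom_point() + ggplot2::geom_line() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = unique(object$parameter), y = y)
}
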