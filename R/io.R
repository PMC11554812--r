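# Run output surface: CSV/VTU/JSON artifacts of a simulation plus a manifest
# with configuration hash, input checksums and seeds, so a run directory is
# reproducible and self-describing.

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Write the artifacts of a simulation run
#'
#' Creates `dir` with: `waveforms.csv` (per-step inflow/outflow/pressures),
#' `flows_by_outlet.csv`, `territory_mbf.csv`, `flow_ratios.csv`,
#' `final_state.vtu` (pressures, P_im, MBF, diameters, lambda, territory
#' label at the final step), `report.json` and `manifest.json`.
#'
#' @param sim a `perf_sim`.
#' @param dir output directory (created).
#' @param inputs named character vector of input file paths to checksum into
#'   the manifest (optional).
#' @param seed integer seed recorded in the manifest.
#' @return `dir`, invisibly.
#' @export
write_run <- function(sim, dir, inputs = character(), seed = NA_integer_) {
  stopifnot(inherits(sim, "perf_sim"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  d <- tidy(sim)
  utils::write.csv(d, file.path(dir, "waveforms.csv"), row.names = FALSE)
  qd <- as.data.frame(sim$q * 6e7)
  names(qd) <- paste0("q_", sim$outlets$id, "_ml_min")
  utils::write.csv(cbind(t = sim$times, qd),
                   file.path(dir, "flows_by_outlet.csv"), row.names = FALSE)
  ratios <- flow_ratios(sim)
  utils::write.csv(ratios, file.path(dir, "flow_ratios.csv"), row.names = FALSE)
  m <- if (!is.null(sim$p)) mbf_map(sim) else NULL
  if (!is.null(m)) {
    utils::write.csv(m$per_territory, file.path(dir, "territory_mbf.csv"),
                     row.names = FALSE)
  }
  if (!is.null(sim$p)) {
    S <- length(sim$times)
    pim_S <- evaluate_pim(sim$pim, sim$times[S])
    p_S <- sim$p[S, , ]
    dia <- vessel_diameters(p_S, pim_S, sim$params, sim$refit)
    write_vtu(sim$mesh, file.path(dir, "final_state.vtu"), point_data = list(
      p1_mmHg = pa_to_mmhg(p_S[, 1]),
      p2_mmHg = pa_to_mmhg(p_S[, 2]),
      p3_mmHg = pa_to_mmhg(p_S[, 3]),
      pim_mmHg = pa_to_mmhg(pim_S),
      mbf = if (!is.null(m)) m$nodal else rep(NA_real_, nrow(sim$mesh$nodes)),
      d2_um = dia$d2_um, d3_um = dia$d3_um,
      territory = as.numeric(sim$tmap$label)
    ))
  }
  report <- list(
    model = if (sim$rigid) "rigid" else "compliant",
    beats = sim$report$beats,
    cycle_diffs = sim$report$cycle_diffs,
    mean_fp_iterations = sim$report$mean_iterations,
    max_balance_residual_m3_s = max(abs(sim$balance_residual)),
    mean_inflow_ml_min = mean(sim$inflow) * 6e7,
    mean_venous_outflow_ml_min = mean(sim$venous_outflow) * 6e7,
    global_mean_mbf = if (!is.null(m)) m$global_mean else NULL
  )
  jsonlite::write_json(report, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  outputs <- setdiff(list.files(dir), "manifest.json")
  manifest <- list(
    package = "myoperf",
    version = as.character(utils::packageVersion("myoperf")),
    created = format(Sys.time(), tz = "UTC"),
    seed = seed,
    config_hash = config_hash(sim$params),
    inputs = lapply(inputs, function(f) {
      list(path = f, md5 = unname(tools::md5sum(f)))
    }),
    outputs = lapply(outputs, function(f) {
      list(path = f, md5 = unname(tools::md5sum(file.path(dir, f))))
    })
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

config_hash <- function(params) {
  s <- paste(vapply(sort(names(unclass(params))), function(k) {
    paste0(k, "=", paste(format(params[[k]], digits = 17), collapse = ","))
  }, character(1)), collapse = ";")
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(s, tf)
  unname(tools::md5sum(tf))
}

#' Verify a run manifest
#'
#' Recomputes the checksums of the outputs listed in `manifest.json`.
#'
#' @param dir run directory.
#' @return `TRUE` if all checksums match; otherwise a character vector of
#'   mismatching paths.
#' @export
verify_manifest <- function(dir) {
  mf <- jsonlite::read_json(file.path(dir, "manifest.json"))
  bad <- character()
  for (o in mf$outputs) {
    f <- file.path(dir, o$path)
    if (!file.exists(f) || unname(tools::md5sum(f)) != o$md5) bad <- c(bad, o$path)
  }
  if (length(bad) == 0) TRUE else bad
}
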