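#' @importFrom tibble tibble as_tibble
#' @importFrom rlang abort warn .data
NULL

#' Conversion factor between mmHg and Pa
#'
#' 1 mmHg = 133.322 Pa. All pressures are held internally in Pa; mmHg appears
#' only at user-facing boundaries (configuration keys suffixed `_mmHg`,
#' printed summaries).
#'
#' @keywords internal
MMHG_PA <- 133.322

#' Convert pressures between mmHg and Pa
#'
#' @param x numeric vector of pressures.
#' @return converted numeric vector.
#' @examples
#' pa_to_mmhg(mmhg_to_pa(2)) # exactly 2
#' @export
mmhg_to_pa <- function(x) x * MMHG_PA

#' @rdname mmhg_to_pa
#' @export
pa_to_mmhg <- function(x) x / MMHG_PA

# Default parameter values.  Pressures stored in Pa; per-compartment arrays are
# ordered small arteries (1), arterioles (2), capillaries (3).
default_parameter_list <- function() {
  list(
    # vascular morphometry
    length_density       = c(0.5, 15, 8000),  # (nL)_i, mm mm^-3 (= mm^-2)
    morphometry_factor   = c(0.005, 0.05, 10),# delta_i, mm^-2 s^-1 Pa^-1
    specific_permeability = 1.75e-10,         # kappa, m^2
    # coupling / sinks
    coupling_conductance = 3e-10,             # alpha, m^3 s^-1 Pa^-1
    venous_conductance   = 8e-6,              # gamma, Pa^-1 s^-1
    right_atrium_pressure = mmhg_to_pa(2),    # p_ra, Pa
    # blood
    blood_density        = 1063,              # rho, kg m^-3
    blood_viscosity      = 0.0035,            # mu, Pa s
    # driving waveform personalization
    peak_pressure        = mmhg_to_pa(140),   # Pa (brachial/aortic peak)
    period               = 0.714,             # T, s
    systolic_fraction    = 0.37,              # dimensionless
    lv_diastolic_pressure = mmhg_to_pa(8),    # LV baseline, Pa
    # numerics
    dt                   = 2e-3,              # s
    mesh_size            = 1.5,               # h, mm
    fp_tolerance         = 1e-10,             # epsilon
    relaxation           = 0.1,               # eta
    max_fp_iterations    = 200,
    # post-processing
    tissue_density       = 1.05               # g ml^-1, for MBF per 100 g
  )
}

# Keys accepted with an _mmHg suffix in configuration documents.
pressure_keys <- function() {
  c("right_atrium_pressure", "peak_pressure", "lv_diastolic_pressure")
}

#' Load and validate the model parameter set
#'
#' Builds a complete parameter set from a configuration document (a YAML file
#' path or a named list), filling unspecified keys with the package defaults:
#' length densities (nL) = (0.5, 15, 8000) mm/mm^3, morphometry factors
#' delta = (0.005, 0.05, 10), specific permeability kappa = 1.75e-10 m^2,
#' coupling conductance alpha = 3e-10 m^3/s/Pa, venous conductance
#' gamma = 8e-6 /Pa/s, right atrium pressure 2 mmHg, blood viscosity
#' 0.0035 Pa s, time step 2 ms, mesh size 1.5 mm, fixed-point tolerance 1e-10
#' and relaxation 0.1.
#'
#' Pressures are stored internally in Pa (1 mmHg = 133.322 Pa); any pressure
#' key may be given in mmHg by suffixing it `_mmHg`
#' (e.g. `right_atrium_pressure_mmHg: 2`).  Unknown keys are rejected.
#'
#' @param config `NULL` (all defaults), a named list, or the path of a flat
#'   YAML key-value file.
#' @return an object of class `perf_params`: a named list of validated,
#'   unit-normalized parameters.
#' @examples
#' p <- load_parameters()
#' p$length_density
#' p2 <- load_parameters(list(period = 0.782, peak_pressure_mmHg = 130))
#' @export
load_parameters <- function(config = NULL) {
  if (is.character(config)) {
    if (length(config) != 1 || !file.exists(config)) {
      abort(paste0("configuration file not found: ", config))
    }
    config <- yaml::read_yaml(config)
    if (is.null(config)) config <- list()
  }
  if (is.null(config)) config <- list()
  if (!is.list(config)) abort("config must be NULL, a named list or a file path")

  defaults <- default_parameter_list()
  known <- names(defaults)
  known_mmhg <- paste0(pressure_keys(), "_mmHg")

  bad <- setdiff(names(config), c(known, known_mmhg))
  if (length(bad) > 0) {
    abort(paste0("unknown configuration key(s): ", paste(bad, collapse = ", ")))
  }
  for (k in names(config)) {
    v <- config[[k]]
    if (!is.numeric(v) || anyNA(v)) {
      abort(paste0("configuration key '", k, "' must be numeric and non-missing"))
    }
  }
  # mmHg-suffixed keys win over bare keys if both are present
  p <- defaults
  for (k in intersect(names(config), known)) p[[k]] <- as.numeric(config[[k]])
  for (k in intersect(names(config), known_mmhg)) {
    base <- sub("_mmHg$", "", k)
    p[[base]] <- mmhg_to_pa(as.numeric(config[[k]]))
  }
  p <- structure(p, class = "perf_params")

  v <- validate_parameters(p)
  if (nrow(v) > 0) {
    abort(paste0(
      "invalid parameter(s): ",
      paste(sprintf("%s = %s (%s)", v$field, v$value, v$bound), collapse = "; ")
    ))
  }
  p
}

#' Report invariant violations of a parameter set
#'
#' Checks positivity of conductances, densities, viscosity, time step and
#' period, the bounds 0 < relaxation <= 1 and 0 < systolic fraction < 1, and
#' that per-compartment arrays have exactly three entries.  Reporting only:
#' never throws.
#'
#' @param p a `perf_params` object or plain named list.
#' @return a tibble with columns `field`, `value`, `bound`; zero rows iff all
#'   invariants hold.
#' @examples
#' validate_parameters(load_parameters()) # 0 rows
#' @export
validate_parameters <- function(p) {
  out <- list()
  note <- function(field, value, bound) {
    out[[length(out) + 1]] <<- tibble(
      field = field,
      value = paste(signif(value, 6), collapse = ","),
      bound = bound
    )
  }
  tri <- c("length_density", "morphometry_factor")
  for (k in tri) {
    if (length(p[[k]]) != 3) note(k, p[[k]], "must have exactly 3 entries")
  }
  pos <- c(
    "specific_permeability", "coupling_conductance", "venous_conductance",
    "blood_density", "blood_viscosity", "peak_pressure", "period", "dt",
    "mesh_size", "fp_tolerance", "tissue_density"
  )
  for (k in pos) {
    if (!is.numeric(p[[k]]) || length(p[[k]]) != 1 || !is.finite(p[[k]]) ||
        p[[k]] <= 0) {
      note(k, p[[k]], "must be a single strictly positive number")
    }
  }
  nonneg <- c("right_atrium_pressure", "lv_diastolic_pressure")
  for (k in nonneg) {
    if (!is.numeric(p[[k]]) || length(p[[k]]) != 1 || !is.finite(p[[k]]) ||
        p[[k]] < 0) {
      note(k, p[[k]], "must be a single nonnegative number")
    }
  }
  for (k in tri) {
    if (length(p[[k]]) == 3 && (anyNA(p[[k]]) || any(p[[k]] < 0))) {
      note(k, p[[k]], "entries must be nonnegative")
    }
  }
  if (!is.numeric(p$relaxation) || length(p$relaxation) != 1 ||
      !is.finite(p$relaxation) || p$relaxation <= 0 || p$relaxation > 1) {
    note("relaxation", p$relaxation, "must satisfy 0 < eta <= 1")
  }
  sf <- p$systolic_fraction
  if (!is.numeric(sf) || length(sf) != 1 || !is.finite(sf) || sf <= 0 || sf >= 1) {
    note("systolic_fraction", sf, "must satisfy 0 < fraction < 1")
  }
  if (!is.numeric(p$max_fp_iterations) || p$max_fp_iterations < 1) {
    note("max_fp_iterations", p$max_fp_iterations, "must be >= 1")
  }
  if (length(out) == 0) {
    tibble(field = character(), value = character(), bound = character())
  } else {
    dplyr::bind_rows(out)
  }
}

#' Serialize a parameter set to YAML
#'
#' Writes every field with its internal (SI) value, so that
#' `load_parameters(write_parameters(p, f))` reproduces `p` bit-exactly.
#'
#' @param p a `perf_params` object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_parameters <- function(p, path) {
  stopifnot(inherits(p, "perf_params"))
  yaml::write_yaml(unclass(p), path, precision = 17)
  invisible(path)
}

#' @export
print.perf_params <- function(x, ...) {
  cat("<perf_params> compliant multi-compartment Darcy parameter set\n")
  cat(sprintf("  (nL)_i  : %s mm/mm^3\n", paste(x$length_density, collapse = ", ")))
  cat(sprintf("  delta_i : %s /mm^2/Pa/s\n", paste(x$morphometry_factor, collapse = ", ")))
  cat(sprintf("  kappa   : %.3g m^2   alpha: %.3g m^3/s/Pa   gamma: %.3g /Pa/s\n",
              x$specific_permeability, x$coupling_conductance, x$venous_conductance))
  cat(sprintf("  p_ra    : %.3g mmHg  peak: %.3g mmHg  T: %.3g s  sys frac: %.3g\n",
              pa_to_mmhg(x$right_atrium_pressure), pa_to_mmhg(x$peak_pressure),
              x$period, x$systolic_fraction))
  cat(sprintf("  dt      : %.3g s  h: %.3g mm  eps: %.1g  eta: %.3g\n",
              x$dt, x$mesh_size, x$fp_tolerance, x$relaxation))
  invisible(x)
}
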