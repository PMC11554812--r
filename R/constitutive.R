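# Pressure-area constitutive laws for the three intramural compartments.
#
# All areas are evaluated in mm^2 with the transluminal pressure difference
# dp = p_i - P_im in Pa, exactly as the fitted coefficients are printed; unit
# conversion to SI happens only where these quantities enter the FEM assembly.
# The curves describe maximal hyperemia: vascular tone is exhausted and the
# wall is fully passive, so area depends on dp alone.

check_compartment <- function(i) {
  if (!all(i %in% c(1L, 2L, 3L))) {
    rlang::abort("compartment index must be 1 (small arteries), 2 (arterioles) or 3 (capillaries)")
  }
  as.integer(i)
}

# Sigmoid coefficients of the arteriolar negative branch.  The printed set
# (amplitude 0.0050, rate 3.02e-4, no offset) leaves a ~2.6% value jump against
# the logarithmic branch at dp = 0; `refit = TRUE` recomputes amplitude, rate
# and offset to enforce continuity of value, slope and curvature there while
# keeping the 0.003 mm^2 asymptotic minimum.
a2_sigmoid_coefs <- function(refit = FALSE) {
  if (!refit) {
    return(list(amin = 0.0030, s = 0.0050, k = 3.02e-4, c = 0))
  }
  v0 <- 0.0011 * log(3500) - 0.0033        # log-branch value at 0
  m0 <- 0.0011 * 1.2 / 3500                # slope at 0
  c2 <- -0.0011 * 1.2^2 / 3500^2           # curvature at 0
  # 0.003 + s/(1+exp(-k dp - c)); match value/slope/curvature at dp = 0
  ku  <- m0 / (v0 - 0.0030)                # k (1 - sigma)
  k   <- 2 * ku - c2 / m0
  u   <- ku / k
  sig <- 1 - u
  list(amin = 0.0030, s = (v0 - 0.0030) / sig, k = k, c = log(sig / u))
}

#' Vessel cross-sectional area of a compartment
#'
#' Mean cross-sectional area A_i (mm^2) of the vessels in compartment `i` as a
#' function of the transluminal pressure difference `dp = p_i - P_im` (Pa):
#' * compartment 1 (small arteries): rigid, A = 0.07 mm^2;
#' * compartment 2 (arterioles): a logarithmic fit to isolated-arteriole data
#'   for dp >= 0 and a sigmoid extension with asymptotic minimum 0.003 mm^2
#'   for dp < 0 (dp = 0 itself uses the logarithmic branch);
#' * compartment 3 (capillaries): a single sigmoid between 1 um^2 and 25 um^2.
#'
#' @param i compartment index in 1:3 (scalar).
#' @param dp numeric vector of transluminal pressures, Pa.
#' @param refit logical; recompute the arteriolar sigmoid coefficients to make
#'   the dp = 0 junction C^2 against the logarithmic branch (default keeps the
#'   printed coefficients).
#' @return areas in mm^2, same length as `dp`.
#' @examples
#' vessel_area(1, 0)        # 0.07
#' vessel_area(2, 0)        # 0.0011*log(3500) - 0.0033
#' vessel_area(3, -1e7)     # ~1e-6 asymptote
#' @export
vessel_area <- function(i, dp, refit = FALSE) {
  i <- check_compartment(i)
  stopifnot(length(i) == 1)
  dp <- as.numeric(dp)
  if (i == 1L) return(rep(0.07, length(dp)))
  if (i == 2L) {
    co <- a2_sigmoid_coefs(refit)
    neg <- co$amin + co$s * stats::plogis(co$k * dp + co$c)
    pos <- 0.0011 * log(pmax(1.2 * dp + 3500, .Machine$double.xmin)) - 0.0033
    return(ifelse(dp < 0, neg, pos))
  }
  1e-6 + 2.4e-5 * stats::plogis(3e-4 * dp + 0.5)
}

#' Vessel distensibility of a compartment
#'
#' C_i = dA_i/d(dp) in mm^2/Pa, computed as the exact analytic derivative of
#' the implemented area law (not the separately rounded closed forms), so that
#' the compliance term of the Darcy model is consistent with the area law it
#' derives from.  C_1 = 0 (rigid small arteries).
#'
#' @inheritParams vessel_area
#' @return distensibilities in mm^2/Pa.
#' @export
vessel_distensibility <- function(i, dp, refit = FALSE) {
  i <- check_compartment(i)
  stopifnot(length(i) == 1)
  dp <- as.numeric(dp)
  if (i == 1L) return(rep(0, length(dp)))
  if (i == 2L) {
    co <- a2_sigmoid_coefs(refit)
    sg <- stats::plogis(co$k * dp + co$c)
    neg <- co$s * co$k * sg * (1 - sg)
    pos <- 0.0011 * 1.2 / (1.2 * dp + 3500)
    return(ifelse(dp < 0, neg, pos))
  }
  sg <- stats::plogis(3e-4 * dp + 0.5)
  2.4e-5 * 3e-4 * sg * (1 - sg)
}

#' Compartment porosity (fluid volume fraction)
#'
#' phi_i = (nL)_i A_i(dp): length density (mm/mm^3) times mean cross section
#' (mm^2), dimensionless.
#'
#' @inheritParams vessel_area
#' @param params a `perf_params` parameter set.
#' @return porosities, same length as `dp`.
#' @export
vessel_porosity <- function(i, dp, params, refit = FALSE) {
  i <- check_compartment(i)
  params$length_density[i] * vessel_area(i, dp, refit)
}

#' Darcy permeability of a compartment
#'
#' K_i = (kappa / mu) phi_i(dp), in m^2/Pa/s: direct proportionality between
#' permeability and porosity with a compartment-independent specific
#' permeability kappa (m^2) and blood viscosity mu (Pa s).
#'
#' @inheritParams vessel_porosity
#' @return permeabilities in m^2/Pa/s.
#' @export
darcy_permeability <- function(i, dp, params, refit = FALSE) {
  params$specific_permeability / params$blood_viscosity *
    vessel_porosity(i, dp, params, refit)
}

#' Intra-compartment network conductance
#'
#' beta_i = delta_i (nL)_i A_i(dp)^2 in /Pa/s: each vessel is a Poiseuille-like
#' resistor (conductance proportional to A^2), scaled to the compartment by the
#' length density and a calibrated morphometry factor delta_i that encodes the
#' series/parallel arrangement of the network.
#'
#' @inheritParams vessel_porosity
#' @return conductances in /Pa/s.
#' @export
compartment_conductance <- function(i, dp, params, refit = FALSE) {
  i <- check_compartment(i)
  params$morphometry_factor[i] * params$length_density[i] *
    vessel_area(i, dp, refit)^2
}

#' Inter-compartment exchange conductance
#'
#' beta_{i,j} = (beta_i + beta_j)/2, the arithmetic mean of the upstream and
#' downstream network conductances, each evaluated at its own transluminal
#' pressure.  Only hierarchically adjacent pairs exchange mass by default: the
#' (1,3) pair returns 0 unless `allow_nonadjacent = TRUE` (the hierarchical
#' network has no direct artery-to-capillary anastomosis).
#'
#' @param i,j distinct compartment indices in 1:3.
#' @param dp_i,dp_j transluminal pressures (Pa) at which the two compartment
#'   conductances are evaluated.
#' @param params a `perf_params` parameter set.
#' @param allow_nonadjacent if `TRUE`, apply the mean-conductance formula to
#'   the (1,3) pair as well.
#' @param refit see [vessel_area()].
#' @return conductances in /Pa/s; symmetric in (i, j).
#' @export
exchange_conductance <- function(i, j, dp_i, dp_j, params,
                                 allow_nonadjacent = FALSE, refit = FALSE) {
  i <- check_compartment(i); j <- check_compartment(j)
  if (i == j) rlang::abort("exchange conductance requires two distinct compartments")
  if (abs(i - j) == 2L && !allow_nonadjacent) {
    return(rep(0, max(length(dp_i), length(dp_j))))
  }
  (compartment_conductance(i, dp_i, params, refit) +
     compartment_conductance(j, dp_j, params, refit)) / 2
}

#' Tabulate the constitutive curves
#'
#' Evaluates area and distensibility of the distensible compartments over a
#' grid of transluminal pressures, for plotting or CSV export.
#'
#' @param dp numeric grid of transluminal pressures, Pa.
#' @param compartments which compartments to tabulate.
#' @param refit see [vessel_area()].
#' @return a tibble with columns `compartment`, `dp_pa`, `area_mm2`,
#'   `distensibility_mm2_pa`.
#' @examples
#' tabulate_constitutive(seq(-1e4, 2e4, length.out = 5))
#' @export
tabulate_constitutive <- function(dp = seq(-1e4, 2e4, length.out = 601),
                                  compartments = c(2L, 3L), refit = FALSE) {
  purrr::map_dfr(check_compartment(compartments), function(i) {
    tibble::tibble(
      compartment = i,
      dp_pa = dp,
      area_mm2 = vessel_area(i, dp, refit),
      distensibility_mm2_pa = vessel_distensibility(i, dp, refit)
    )
  })
}
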