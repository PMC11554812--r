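# Semi-implicit finite-element step of the compliant three-compartment Darcy
# system.  Nonlinear coefficients (permeabilities, compliances, exchange
# conductances) are frozen at the previous step's transluminal pressures;
# pressures are implicit, including the inter-compartment exchange and the
# venous sink, which makes each step a single symmetric positive definite
# solve on the 3N stacked unknowns.
#
# Units: mesh coordinates are mm (basis gradients 1/mm, volumes mm^3);
# stiffness entries are scaled by 1e-3 to SI (K in m^2/Pa/s) and all lumped
# volume terms use node volumes in m^3.  Pressures are Pa, sources 1/s.

MM_TO_M <- 1e-3

#' Precompute the assembly structure of a mesh
#'
#' Triplet layout of the P1 stiffness pattern plus lumped node volumes,
#' reused by every time step.
#'
#' @param mesh a `wall_mesh`.
#' @return an opaque list consumed by [assemble_step()].
#' @export
darcy_structure <- function(mesh) {
  nt <- nrow(mesh$tets)
  g <- mesh$tet_grads
  vol <- mesh$tet_volume
  ii <- jj <- xx <- vector("list", 16)
  k <- 0
  for (a in 1:4) for (b in 1:4) {
    k <- k + 1
    ii[[k]] <- mesh$tets[, a]
    jj[[k]] <- mesh$tets[, b]
    xx[[k]] <- vol * rowSums(g[[a]] * g[[b]])
  }
  list(
    I = unlist(ii), J = unlist(jj), GEO = unlist(xx),
    ELEM = rep.int(seq_len(nt), 16),
    n = nrow(mesh$nodes),
    vn_m3 = mesh$node_volumes * 1e-9,
    tets = mesh$tets
  )
}

# Nodal coefficient fields frozen at the state (p, pim).
darcy_coefficients <- function(p, pim, params, rigid = FALSE, refit = FALSE) {
  n <- length(pim)
  K <- nlC <- beta <- matrix(0, n, 3)
  for (i in 1:3) {
    dp <- if (rigid) rep(0, n) else p[, i] - pim
    K[, i] <- darcy_permeability(i, dp, params, refit)
    nlC[, i] <- if (rigid) 0 else
      params$length_density[i] * vessel_distensibility(i, dp, refit)
    beta[, i] <- compartment_conductance(i, dp, params, refit)
  }
  list(
    K = K, nlC = nlC,
    beta12 = (beta[, 1] + beta[, 2]) / 2,
    beta23 = (beta[, 2] + beta[, 3]) / 2
  )
}

#' Assemble one semi-implicit time step
#'
#' Builds the 3N x 3N SPD system for the pressures at t^{n+1}: per compartment
#' a stiffness block with the frozen permeability, a lumped compliance block
#' (nL)_i C_i / dt, implicit symmetric exchange between adjacent compartments,
#' and the implicit venous sink on compartment 3.  The right-hand side carries
#' the arterial source theta_1, the venous reference gamma p_ra, the
#' compliance history term and the intramyocardial-pressure rate term
#' (nL)_i C_i dP_im/dt.
#'
#' @param mesh a `wall_mesh`.
#' @param p N x 3 matrix of nodal pressures at t^n, Pa.
#' @param pim per-node intramyocardial pressure at t^n, Pa.
#' @param params a `perf_params`.
#' @param theta1 per-node arterial source at t^{n+1}, 1/s (may be updated
#'   later via [step_rhs()]).
#' @param dpim_dt per-node discrete rate (P_im^{n+1} - P_im^n)/dt, Pa/s.
#' @param dt time step, s; `Inf` drops the compliance terms (steady solve).
#' @param rigid logical: freeze areas at dp = 0 and zero the compliances.
#' @param structure optional precomputed [darcy_structure()].
#' @param refit see [vessel_area()].
#' @return a `step_system` list with the symmetric matrix `M`, the
#'   theta1-independent right-hand side `rhs0`, and bookkeeping fields.
#' @export
assemble_step <- function(mesh, p, pim, params, theta1 = NULL, dpim_dt = NULL,
                          dt = params$dt, rigid = FALSE, structure = NULL,
                          refit = FALSE) {
  if (is.null(structure)) structure <- darcy_structure(mesh)
  n <- structure$n
  if (anyNA(p) || anyNA(pim)) {
    bad <- which(is.na(rowSums(p) + pim))[1]
    rlang::abort(paste0("assemble_step: non-finite state at node ", bad))
  }
  co <- darcy_coefficients(p, pim, params, rigid, refit)
  if (anyNA(co$K) || anyNA(co$nlC)) {
    rlang::abort("assemble_step: non-finite coefficient field")
  }
  vn <- structure$vn_m3
  inv_dt <- if (is.finite(dt)) 1 / dt else 0

  blocks_i <- list(); blocks_j <- list(); blocks_x <- list()
  add <- function(bi, bj, i, j, x) {
    blocks_i[[length(blocks_i) + 1]] <<- i + (bi - 1L) * n
    blocks_j[[length(blocks_j) + 1]] <<- j + (bj - 1L) * n
    blocks_x[[length(blocks_x) + 1]] <<- x
  }
  idx <- seq_len(n)
  for (i in 1:3) {
    # stiffness with element-mean permeability, scaled mm -> m
    ke <- rowMeans(matrix(co$K[structure$tets, i], ncol = 4))
    add(i, i, structure$I, structure$J, ke[structure$ELEM] * structure$GEO * MM_TO_M)
    # lumped compliance
    add(i, i, idx, idx, vn * co$nlC[, i] * inv_dt)
  }
  # implicit exchange, pairwise symmetric
  for (pair in list(list(1L, 2L, co$beta12), list(2L, 3L, co$beta23))) {
    i <- pair[[1]]; j <- pair[[2]]; b <- vn * pair[[3]]
    add(i, i, idx, idx, b); add(j, j, idx, idx, b)
    add(i, j, idx, idx, -b); add(j, i, idx, idx, -b)
  }
  # implicit venous sink
  add(3L, 3L, idx, idx, vn * params$venous_conductance)

  M <- Matrix::sparseMatrix(
    i = unlist(blocks_i), j = unlist(blocks_j), x = unlist(blocks_x),
    dims = c(3L * n, 3L * n)
  )
  M <- Matrix::forceSymmetric((M + Matrix::t(M)) / 2)

  rhs0 <- numeric(3 * n)
  if (is.null(dpim_dt)) dpim_dt <- numeric(n)
  for (i in 1:3) {
    r <- vn * co$nlC[, i] * (inv_dt * p[, i] + dpim_dt)
    if (i == 3) r <- r + vn * params$venous_conductance * params$right_atrium_pressure
    rhs0[idx + (i - 1L) * n] <- r
  }
  sys <- structure(list(
    M = M, rhs0 = rhs0, n = n, vn = vn, coef = co, dt = dt
  ), class = "step_system")
  if (!is.null(theta1)) sys$rhs <- step_rhs(sys, theta1)
  sys
}

#' Right-hand side of a step for a given arterial source
#'
#' @param system a `step_system`.
#' @param theta1 per-node source, 1/s.
#' @return length-3N numeric right-hand side.
#' @export
step_rhs <- function(system, theta1) {
  rhs <- system$rhs0
  rhs[seq_len(system$n)] <- rhs[seq_len(system$n)] + system$vn * theta1
  rhs
}

#' Solve one assembled step
#'
#' Sparse Cholesky solve of the SPD step system; the symbolic factorization is
#' reused across steps via the `factor` argument (the sparsity pattern never
#' changes).  The relative residual is checked against 1e-10.
#'
#' @param system a `step_system`.
#' @param theta1 per-node arterial source, 1/s (ignored when `rhs` given).
#' @param rhs explicit right-hand side (overrides `theta1`).
#' @param factor a previous Cholesky factor to update in place.
#' @param refactor if `FALSE`, reuse `factor` without a numeric update (valid
#'   while the matrix is unchanged, e.g. across fixed-point iterations of one
#'   time step).
#' @return list with `p` (N x 3 nodal pressures), `factor` (reusable Cholesky)
#'   and `residual` (relative).
#' @export
solve_step <- function(system, theta1 = NULL, rhs = NULL, factor = NULL,
                       refactor = TRUE) {
  if (is.null(rhs)) {
    rhs <- if (!is.null(theta1)) step_rhs(system, theta1)
    else system$rhs %||% system$rhs0
  }
  if (refactor || is.null(factor)) {
    factor <- tryCatch({
      if (is.null(factor)) Matrix::Cholesky(system$M, LDL = FALSE)
      else Matrix::update(factor, system$M)
    }, error = function(e) {
      rlang::abort(paste0(
        "step system is singular (pure-Neumann null space: no venous sink and ",
        "no compliance regularize the pressure level): ", conditionMessage(e)))
    })
  }
  x <- as.numeric(Matrix::solve(factor, rhs))
  res <- sqrt(sum((as.numeric(system$M %*% x) - rhs)^2)) /
    max(sqrt(sum(rhs^2)), .Machine$double.xmin)
  if (!is.finite(res) || res > 1e-8) {
    rlang::abort(sprintf(
      "step solve residual %.3g exceeds tolerance (singular system? a model with no venous sink and no compliance has a pure-Neumann null space)",
      res))
  }
  list(p = matrix(x, ncol = 3), factor = factor, residual = res)
}

#' Discrete mass balance of a solved step
#'
#' Total arterial inflow + total venous source - storage rate, each in m^3/s;
#' the stiffness and exchange contributions cancel exactly over the domain,
#' so the residual is at the level of the linear-solver accuracy.
#'
#' @param system the `step_system` used for the solve.
#' @param p_new N x 3 solution at t^{n+1}.
#' @param p_old N x 3 state at t^n.
#' @param dpim_dt per-node (P_im^{n+1} - P_im^n)/dt, Pa/s.
#' @param theta1 per-node arterial source, 1/s.
#' @param params a `perf_params`.
#' @return list with `inflow`, `venous_outflow`, `storage_rate`, `residual`
#'   (all m^3/s).
#' @export
step_mass_balance <- function(system, p_new, p_old, dpim_dt, theta1, params) {
  vn <- system$vn
  inv_dt <- if (is.finite(system$dt)) 1 / system$dt else 0
  inflow <- sum(vn * theta1)
  venous <- params$venous_conductance *
    sum(vn * (p_new[, 3] - params$right_atrium_pressure))
  storage <- 0
  for (i in 1:3) {
    storage <- storage +
      sum(vn * system$coef$nlC[, i] * ((p_new[, i] - p_old[, i]) * inv_dt - dpim_dt))
  }
  list(
    inflow = inflow, venous_outflow = venous, storage_rate = storage,
    residual = inflow - venous - storage
  )
}
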