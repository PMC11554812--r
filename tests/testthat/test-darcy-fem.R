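params <- load_parameters()

test_that("step matrix is symmetric with the expected structure", {
  m <- generate_idealized_wall("slab", c(10, 10, 5), h = 2.5)
  n <- nrow(m$nodes)
  set.seed(2)
  p <- matrix(mmhg_to_pa(stats::runif(3 * n, 20, 100)), n, 3)
  pim <- mmhg_to_pa(stats::runif(n, 0, 60))
  sys <- assemble_step(m, p, pim, params, dt = 2e-3)
  M <- sys$M
  expect_lt(Matrix::norm(M - Matrix::t(M), "F") / Matrix::norm(M, "F"), 1e-12)
  # SPD: smallest eigenvalue positive (venous sink grounds the system)
  ev <- min(eigen(as.matrix(M), symmetric = TRUE, only.values = TRUE)$values)
  expect_gt(ev, 0)
  # exchange blocks: cross-compartment row sums cancel pairwise, so a
  # pressure vector constant across compartments only feels stiffness + sink
  ones <- rep(1, 3 * n)
  resp <- as.numeric(M %*% ones)
  vn <- m$node_volumes * 1e-9
  expect_equal(resp[1:n], vn * sys$coef$nlC[, 1] / 2e-3, tolerance = 1e-9)
  expect_equal(resp[2 * n + 1:n],
               vn * (sys$coef$nlC[, 3] / 2e-3 + params$venous_conductance),
               tolerance = 1e-9)
})

test_that("pure stiffness blocks have the Neumann null space", {
  m <- generate_idealized_wall("slab", c(10, 10, 5), h = 2.5)
  n <- nrow(m$nodes)
  p <- matrix(mmhg_to_pa(60), n, 3)
  p0 <- params
  p0$venous_conductance <- 0            # no sink at all
  sys <- assemble_step(m, p, rep(0, n), p0, dt = Inf, rigid = TRUE)
  # constants per compartment are (numerically) in the null space
  ones <- rep(1, 3 * n)
  expect_lt(max(abs(sys$M %*% ones)), 1e-12 * Matrix::norm(sys$M, "I"))
})

test_that("equilibrium at atrial pressure is a fixed point of the step", {
  m <- generate_idealized_wall("slab", c(10, 10, 5), h = 5)
  n <- nrow(m$nodes)
  p <- matrix(params$right_atrium_pressure, n, 3)
  sys <- assemble_step(m, p, rep(0, n), params, theta1 = rep(0, n),
                       dpim_dt = rep(0, n), dt = 2e-3)
  sol <- solve_step(sys)
  expect_equal(sol$p, p, tolerance = 1e-10)
  expect_lt(sol$residual, 1e-10)
})

test_that("non-finite states are rejected with location information", {
  m <- generate_idealized_wall("slab", c(10, 10, 5), h = 5)
  n <- nrow(m$nodes)
  p <- matrix(mmhg_to_pa(60), n, 3)
  p[3, 2] <- NA
  expect_error(assemble_step(m, p, rep(0, n), params), "node 3")
})

test_that("uniform fields stay uniform and track the DAE reference to first order", {
  p <- load_parameters()
  pim_fun <- function(t) mmhg_to_pa(40) * (1 - cos(2 * pi * t / 0.4)) / 2
  dpim_fun <- function(t) mmhg_to_pa(40) * pi / 0.4 * sin(2 * pi * t / 0.4)
  theta_fun <- function(t) 0.03
  p0 <- uniform_steady_state(p, 0, 0.03)
  t_end <- 0.2                            # half a contraction cycle
  ref <- ode_reference(p, pim_fun, dpim_fun, theta_fun, p0, c(0, t_end))
  p_ref <- ref[nrow(ref), 2:4]
  errs <- vapply(c(2e-3, 1e-3), function(dt) {
    r <- run_uniform_steps(p, pim_fun, theta_fun, p0, dt, t_end)
    expect_lt(r$spread, 1e-6 * max(abs(r$p)))      # spatial uniformity
    max(abs(colMeans(r$p) - p_ref))
  }, numeric(1))
  # first order: halving dt (roughly) halves the error
  expect_lt(errs[2], 0.7 * errs[1])
  expect_gt(errs[2], 0.3 * errs[1])
  # and the error itself is small relative to the pressure scale
  expect_lt(errs[1] / mmhg_to_pa(40), 0.05)
})

test_that("per-step lumped mass balance closes to solver precision", {
  m <- generate_idealized_wall("slab", c(10, 10, 5), h = 2.5)
  n <- nrow(m$nodes)
  set.seed(9)
  p <- matrix(mmhg_to_pa(stats::runif(3 * n, 30, 90)), n, 3)
  pim <- mmhg_to_pa(30) * m$transmural
  th <- stats::runif(n, 0, 0.05)
  dpim <- stats::rnorm(n, sd = 100)
  sys <- assemble_step(m, p, pim, params, theta1 = th, dpim_dt = dpim, dt = 2e-3)
  sol <- solve_step(sys)
  bal <- step_mass_balance(sys, sol$p, p, dpim, th, params)
  expect_lt(abs(bal$residual), 1e-10 * abs(bal$inflow))
})

test_that("a sink-free incompliant system reports the Neumann singularity", {
  m <- generate_idealized_wall("slab", c(10, 10, 5), h = 5)
  n <- nrow(m$nodes)
  p <- matrix(mmhg_to_pa(60), n, 3)
  p0 <- params
  p0$venous_conductance <- 0
  sys <- assemble_step(m, p, rep(0, n), p0, dt = Inf, rigid = TRUE)
  expect_error(solve_step(sys, theta1 = rep(0.01, n)), "singular|Neumann")
})
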