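test_that("relaxed fixed point contracts geometrically at the closed-form rate", {
  # affine map with slope m: relaxed iteration factor |1 - eta + eta m|
  m_slope <- -3.5; a <- 2
  f <- function(x) a + m_slope * x
  r <- relaxed_fixed_point(f, x0 = 0, eta = 0.1, eps = 1e-10, s_max = 300)
  expect_true(r$converged)
  expect_equal(r$x, a / (1 - m_slope), tolerance = 1e-8)
  ratios <- r$diffs[-1] / r$diffs[-length(r$diffs)]
  observed <- exp(mean(log(ratios[5:(length(ratios) - 2)])))
  expect_equal(observed, abs(1 - 0.1 + 0.1 * m_slope), tolerance = 0.05)
})

test_that("decoupled limit converges immediately and reports diffs below tolerance", {
  m <- test_slab()
  ot <- test_outlets()
  p <- test_params()
  p$coupling_conductance <- 1e-22        # alpha -> 0: flows vanish
  plv <- build_plv_waveform(p$peak_pressure, p$period, p$systolic_fraction,
                            p$lv_diastolic_pressure)
  ao <- build_aortic_waveform(p$peak_pressure, p$period, p$systolic_fraction)
  pim <- pim_field(plv, m$transmural)
  tm <- assign_territories(m, ot)
  net <- outlet_network(ot, ao, p$coupling_conductance)
  n <- nrow(m$nodes)
  p0 <- matrix(p$right_atrium_pressure, n, 3)
  st <- fixed_point_step(p0, rep(0, 4), p$dt, m, tm, net, p,
                         evaluate_pim(pim, 0),
                         pim_time_derivative(pim, 0, p$dt), accelerate = TRUE)
  expect_true(st$converged)
  expect_lte(st$iterations, 5)
  expect_lt(utils::tail(st$diff_flow, 1), p$fp_tolerance)
  expect_lt(utils::tail(st$diff_pressure, 1), p$fp_tolerance)
})

test_that("fixed-eta iteration diffs decrease monotonically near convergence", {
  # single outlet feeding the whole slab: interface gain is small enough for
  # the tabulated default eta = 0.1 to contract
  m <- test_slab()
  ot <- outlet_table(1, x = 10, y = 10, z = 10, radius = 1.2)
  p <- load_parameters()                 # eta = 0.1
  plv <- build_plv_waveform(p$peak_pressure, p$period, p$systolic_fraction,
                            p$lv_diastolic_pressure)
  ao <- build_aortic_waveform(p$peak_pressure, p$period, p$systolic_fraction)
  pim <- pim_field(plv, m$transmural)
  tm <- assign_territories(m, ot)
  net <- outlet_network(ot, ao, p$coupling_conductance)
  st0 <- myoperf:::steady_initial_state(m, tm, net, p, evaluate_pim(pim, 0),
                                        darcy_structure(m))
  st <- fixed_point_step(st0$p, st0$q, p$dt, m, tm, net, p,
                         evaluate_pim(pim, 0),
                         pim_time_derivative(pim, 0, p$dt),
                         accelerate = FALSE)
  expect_true(st$converged)
  tail3 <- utils::tail(st$diff_flow, 4)
  expect_true(all(diff(tail3) <= 0))
})

test_that("autonomous rigid problem reaches steady state within one beat", {
  m <- generate_idealized_wall("slab", c(10, 10, 5), h = 2.5)
  ot <- outlet_table(1, x = 5, y = 5, z = 5, radius = 1)
  p <- test_params(period = 0.1, dt = 2e-3)
  # constant waveforms via the tabulated-import path
  f <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(data.frame(t = seq(0, 0.1, length.out = 11), p_mmHg = 90),
                   f, row.names = FALSE)
  const_w <- read_waveform_csv(f)
  sim <- run_heartbeats(m, ot, p, n_beats = 3, cycle_tol = 1e-8, rigid = TRUE,
                        plv = const_w, aortic = const_w)
  expect_lte(sim$report$beats, 2)
  # flows and pressures constant over the cycle
  expect_lt(diff(range(sim$inflow)) / max(abs(sim$inflow)), 1e-8)
  expect_lt(utils::tail(sim$report$cycle_diffs, 1), 1e-8)
})

test_that("compliant default run reaches cycle periodicity within ten beats", {
  sim <- default_sim()
  expect_true(sim$report$converged_periodic)
  expect_lte(sim$report$beats, 10)
  expect_lt(utils::tail(sim$report$cycle_diffs, 1), 5e-4)
  # hierarchical pressure cascade of the time-averaged means
  d <- tidy(sim)
  expect_gt(mean(d$p1_mmHg), mean(d$p2_mmHg))
  expect_gt(mean(d$p2_mmHg), mean(d$p3_mmHg))
  # doubling the spin-up does not change cycle-averaged MBF appreciably
  sim2 <- run_heartbeats(test_slab(), test_outlets(), test_params(),
                         n_beats = sim$report$beats + 1, cycle_tol = 1e-9)
  expect_lt(abs(mbf_map(sim2)$global_mean - mbf_map(sim)$global_mean) /
              mbf_map(sim)$global_mean, 0.005)
})

test_that("tidy/glance/autoplot surfaces expose the run", {
  sim <- default_sim()
  d <- tidy(sim)
  expect_s3_class(d, "tbl_df")
  expect_equal(nrow(d), length(sim$times))
  expect_true(all(c("inflow_ml_min", "venous_outflow_ml_min", "systole") %in% names(d)))
  g <- glance(sim)
  expect_equal(nrow(g), 1)
  expect_gt(g$mean_mbf, 0)
  pl <- autoplot(sim)
  expect_s3_class(pl, "ggplot")
})
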