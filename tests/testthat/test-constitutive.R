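params <- load_parameters()

test_that("area laws reproduce the printed coefficients", {
  # rigid small arteries
  expect_equal(vessel_area(1, c(-1e6, 0, 1e6)), rep(0.07, 3))
  # arteriolar logarithmic branch at dp = 0 (branch convention: dp >= 0 -> log)
  expect_equal(vessel_area(2, 0), 0.0011 * log(3500) - 0.0033, tolerance = 1e-12)
  expect_equal(vessel_area(2, 0), 5.6766e-3, tolerance = 1e-4)
  # arteriolar sigmoid asymptote
  expect_equal(vessel_area(2, -1e9), 0.003, tolerance = 1e-9)
  # capillary sigmoid: value at 0 and both asymptotes
  expect_equal(vessel_area(3, 0), 1e-6 + 2.4e-5 / (1 + exp(-0.5)), tolerance = 1e-12)
  expect_equal(vessel_area(3, 0), 1.5939e-5, tolerance = 1e-4)
  expect_equal(vessel_area(3, -1e9), 1e-6, tolerance = 1e-12)
  expect_equal(vessel_area(3, 1e9), 2.5e-5, tolerance = 1e-12)
})

test_that("distensibility is the exact derivative of the area law", {
  dp_grid <- seq(-1e4, 2e4, length.out = 241)
  h <- 1e-2
  for (i in 2:3) {
    fd <- (vessel_area(i, dp_grid + h) - vessel_area(i, dp_grid - h)) / (2 * h)
    an <- vessel_distensibility(i, dp_grid)
    # skip the arteriolar junction point where the finite difference straddles
    # the branch switch
    keep <- if (i == 2) abs(dp_grid) > h else rep(TRUE, length(dp_grid))
    expect_lt(max(abs(fd[keep] - an[keep]) / pmax(abs(an[keep]), 1e-300)), 1e-6)
  }
  expect_equal(vessel_distensibility(1, dp_grid), rep(0, length(dp_grid)))
})

test_that("analytic distensibility matches the printed closed forms within rounding", {
  dp_grid <- seq(-1e4, 2e4, length.out = 241)
  printed_c2 <- ifelse(
    dp_grid < 0,
    1.51e-6 * exp(-3.02e-4 * dp_grid) / (exp(-3.02e-4 * dp_grid) + 1)^2,
    0.0013 / (1.2 * dp_grid + 3500)
  )
  printed_c3 <- 7.2e-9 * exp(-3e-4 * dp_grid - 0.5) /
    (exp(-3e-4 * dp_grid - 0.5) + 1)^2
  expect_lt(max(abs(vessel_distensibility(2, dp_grid) - printed_c2) / printed_c2), 0.02)
  expect_lt(max(abs(vessel_distensibility(3, dp_grid) - printed_c3) / printed_c3), 0.02)
  # spot value: dp = 2000 Pa on the logarithmic branch
  expect_equal(vessel_distensibility(2, 2000), 0.0011 * 1.2 / (1.2 * 2000 + 3500),
               tolerance = 1e-12)
})

test_that("areas are monotone, saturate within the stated bounds, and the junction is small", {
  dp_grid <- seq(-1e4, 2e4, length.out = 2001)
  a2 <- vessel_area(2, dp_grid)
  a3 <- vessel_area(3, dp_grid)
  expect_true(all(diff(a2) >= 0))
  expect_true(all(diff(a3) >= 0))
  expect_true(all(a2 >= 0.003 - 1e-12 & a2 <= 0.008))
  expect_true(all(a3 >= 1e-6 - 1e-18 & a3 <= 2.5e-5))
  expect_true(all(vessel_distensibility(2, dp_grid) >= 0))
  expect_true(all(vessel_distensibility(3, dp_grid) >= 0))
  # printed-coefficient junction mismatch at dp = 0: the printed sigmoid sits
  # 3.11% below the logarithmic branch (small, bounded jump); slope gap < 2%
  v_neg <- 0.0030 + 0.0050 / 2
  v_pos <- vessel_area(2, 0)
  expect_lt(abs(v_neg - v_pos) / v_pos, 0.035)
  s_neg <- 1.51e-6 / 4
  s_pos <- vessel_distensibility(2, 0)
  expect_lt(abs(s_neg - s_pos) / s_pos, 0.02)
  # sigmoid saturation of the distensibility
  expect_lt(vessel_distensibility(3, -1e7), 1e-15)
  expect_lt(vessel_distensibility(3, 1e7), 1e-15)
})

test_that("refitted arteriolar sigmoid is C2 at the junction and keeps the asymptote", {
  h <- 1e-3
  v <- function(dp) vessel_area(2, dp, refit = TRUE)
  c2 <- function(dp) vessel_distensibility(2, dp, refit = TRUE)
  expect_equal(v(-1e-9), v(0), tolerance = 1e-12)
  expect_equal(c2(-1e-9), c2(0), tolerance = 1e-6)
  curv <- function(dp) (c2(dp + h) - c2(dp - h)) / (2 * h)
  expect_equal(curv(-5 * h), curv(5 * h), tolerance = 1e-3)
  expect_equal(v(-1e9), 0.003, tolerance = 1e-9)
})

test_that("porosity, permeability and conductances follow the constitutive chain", {
  expect_equal(vessel_porosity(1, 0, params), 0.5 * 0.07)
  expect_equal(vessel_porosity(3, 0, params), 8000 * vessel_area(3, 0))
  p0 <- params; p0$length_density <- c(0, 0, 0)
  expect_equal(vessel_porosity(2, 0, p0), 0)
  expect_equal(darcy_permeability(1, 0, params),
               1.75e-10 / 0.0035 * 0.035, tolerance = 1e-12)
  pk <- params; pk$specific_permeability <- 0
  expect_equal(darcy_permeability(2, 0, pk), 0)
  # K strictly increasing with area (proportionality)
  dps <- seq(-5e3, 5e3, length.out = 11)
  expect_true(all(diff(darcy_permeability(2, dps, params)) > 0))
  expect_equal(compartment_conductance(2, 0, params),
               0.05 * 15 * vessel_area(2, 0)^2, tolerance = 1e-12)
  expect_equal(compartment_conductance(2, 0, params), 2.4168e-5, tolerance = 1e-4)
  expect_equal(compartment_conductance(3, 0, params), 2.0324e-5, tolerance = 1e-4)
})

test_that("exchange conductance is the symmetric mean and vanishes for the non-adjacent pair", {
  b12 <- exchange_conductance(1, 2, 0, 0, params)
  expect_equal(b12, (compartment_conductance(1, 0, params) +
                       compartment_conductance(2, 0, params)) / 2)
  expect_equal(exchange_conductance(2, 3, 0, 0, params), 2.2246e-5, tolerance = 1e-4)
  # symmetry over random states
  set.seed(7)
  for (k in 1:20) {
    da <- stats::runif(1, -8e3, 1.5e4); db <- stats::runif(1, -8e3, 1.5e4)
    expect_equal(exchange_conductance(2, 3, da, db, params),
                 exchange_conductance(3, 2, db, da, params))
  }
  expect_equal(exchange_conductance(1, 3, 0, 0, params), 0)
  expect_gt(exchange_conductance(1, 3, 0, 0, params, allow_nonadjacent = TRUE), 0)
  expect_error(exchange_conductance(2, 2, 0, 0, params), "distinct")
  expect_error(vessel_area(4, 0), "compartment")
})

test_that("constitutive tabulation covers the requested grid", {
  tb <- tabulate_constitutive(seq(-1e3, 1e3, length.out = 11))
  expect_equal(nrow(tb), 22)
  expect_equal(sort(unique(tb$compartment)), c(2, 3))
  expect_equal(tb$area_mm2[tb$compartment == 2 & tb$dp_pa == 0], vessel_area(2, 0))
})
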