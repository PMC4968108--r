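test_that("pk_rhs implements the four coupled equations", {
  p <- reference_params("deamidation")
  # all rates zero -> no flux
  p0 <- attribute_params(0, 0, 0, 0, 0, V = 1)
  expect_equal(pk_rhs(c(1, 2, 3, 4), p0), rep(0, 4))
  # hand evaluation of the original-central equation at unit state
  expect_equal(pk_rhs(c(1, 0, 0, 0), p)[[1]], -(0.17 + 0.01 + 0.13))
  # mass balance: conversion and distribution conserve; only central
  # clearance removes drug
  for (state in list(c(1, 0, 0, 0), c(0.3, 0.2, 0.4, 0.1),
                     c(0, 1, 0, 2))) {
    expect_equal(sum(pk_rhs(state, p)),
                 -p$kcl0 * state[[1]] - p$kclmod * state[[3]])
  }
})

test_that("simulate_attribute honours initial conditions and rejects bad grids", {
  p <- reference_params("deamidation", dose = 2, f = 0.3)
  traj <- simulate_attribute(p, c(0, 1, 2))
  expect_equal(traj$AC0[[1]] + traj$ACmod[[1]], 2)
  expect_equal(traj$ACmod[[1]], 0.3 * 2)
  expect_equal(traj$AP0[[1]], 0)
  expect_equal(traj$APmod[[1]], 0)
  expect_error(simulate_attribute(p, c(0, 2, 1)), "increasing")
  expect_error(simulate_attribute(p, c(1, 2)), "start at 0")
  expect_error(attribute_params(-0.1, 0.093, 0.01, 0.13, 0.13, 3.34),
               "kCP")
  expect_error(attribute_params(0.17, 0.093, 0.01, 0.13, 0.13, V = -1),
               "V")
})

test_that("ODE solution matches the equal-clearance fraction law", {
  times <- seq(0, 42, by = 0.5)
  for (f in c(0, 0.056, 0.278)) {
    p <- reference_params("deamidation", f = f)
    traj <- simulate_attribute(p, times)
    frac <- traj$ACmod / (traj$AC0 + traj$ACmod)
    expected <- equal_clearance_fraction(f, p$ktr, times)
    expect_lt(max(abs(frac - expected) / pmax(expected, 1e-12)), 1e-6)
  }
  # frozen closed-form value: day 42 at f = 0 is 1 - exp(-0.42)
  p <- reference_params("deamidation", f = 0)
  traj <- simulate_attribute(p, c(0, 42))
  expect_equal(traj$ACmod[[2]] / (traj$AC0[[2]] + traj$ACmod[[2]]),
               0.342953, tolerance = 1e-4)
})

test_that("ODE solution matches the biexponential eigen-solution when ktr = 0", {
  p <- reference_params("man5", f = 0)  # pure original form
  times <- seq(0, 42, by = 0.5)
  traj <- simulate_attribute(p, times)
  bx <- biexp_coefficients(p$kCP, p$kPC, p$kcl0)
  expected <- biexp_profile(bx, times) * p$dose / p$V
  expect_lt(max(abs(traj$C0 - expected) / expected), 1e-6)
  # same law for the modified form alone
  pm <- reference_params("man5", f = 1)
  trajm <- simulate_attribute(pm, times)
  bxm <- biexp_coefficients(pm$kCP, pm$kPC, pm$kclmod)
  expectedm <- biexp_profile(bxm, times) * pm$dose / pm$V
  expect_lt(max(abs(trajm$Cmod - expectedm) / expectedm), 1e-6)
})

test_that("biexp_coefficients: frozen value, limits, normalization", {
  bx <- biexp_coefficients(kCP = 0.18, kPC = 0.096, kcl = 0.127)
  # quadratic formula by hand: ((a+b) - sqrt((a+b)^2 - 4 b kcl)) / 2
  expect_equal(bx$lambda2, 0.0329466, tolerance = 1e-5)
  expect_equal(bx$A + bx$B, 1)
  # no distribution: rates separate into {kcl, kPC}
  bx0 <- biexp_coefficients(kCP = 0, kPC = 0.096, kcl = 0.127)
  expect_equal(sort(c(bx0$lambda1, bx0$lambda2)), sort(c(0.127, 0.096)))
  # one-compartment limit
  bx1 <- biexp_coefficients(kCP = 0, kPC = 0, kcl = 0.127)
  expect_equal(bx1$A, 1)
  # A + B = 1 across a parameter sweep
  for (i in 1:20) {
    set.seed(i)
    r <- runif(3, 0.01, 1)
    bxi <- biexp_coefficients(r[1], r[2], r[3])
    if (!bxi$degenerate) expect_equal(bxi$A + bxi$B, 1)
  }
  expect_warning(biexp_coefficients(0, 0.1, 0.1), "degenerate")
})

test_that("simulated amounts are non-negative, conservative without clearance, linear in dose", {
  times <- seq(0, 42, length.out = 50)
  p <- reference_params("man5", f = 0.149)
  traj <- simulate_attribute(p, times)
  expect_true(all(traj$AC0 >= -1e-10 & traj$ACmod >= -1e-10 &
                    traj$AP0 >= -1e-10 & traj$APmod >= -1e-10))
  # conservation with zero clearance
  pc <- attribute_params(0.17, 0.093, 0.01, 0, 0, V = 3.34, dose = 1,
                         f = 0.2)
  trc <- simulate_attribute(pc, times)
  total <- trc$AC0 + trc$AP0 + trc$ACmod + trc$APmod
  expect_lt(max(abs(total - 1)), 1e-8)
  # doubling dose doubles every amount
  p2 <- p; p2$dose <- 2
  tr2 <- simulate_attribute(p2, times)
  expect_equal(tr2$AC0, 2 * traj$AC0, tolerance = 1e-8)
  expect_equal(tr2$ACmod, 2 * traj$ACmod, tolerance = 1e-8)
})

test_that("terminal log-linear slope equals the slow eigen-rate", {
  p <- reference_params("man5", f = 0)
  times <- seq(30, 42, by = 0.5)
  traj <- simulate_attribute(p, c(0, times))[-1, ]
  slope <- coef(lm(log(traj$C0) ~ traj$time_days))[[2]]
  bx <- biexp_coefficients(p$kCP, p$kPC, p$kcl0)
  expect_equal(slope, -bx$lambda2, tolerance = 0.01)
})

test_that("analytic and integrator routes agree", {
  times <- seq(0, 42, by = 1)
  for (attr in c("deamidation", "man5")) {
    p <- reference_params(attr, f = 0.1)
    ta <- simulate_attribute(p, times, method = "analytic")
    tl <- simulate_attribute(p, times, method = "lsoda")
    expect_lt(max(abs(ta$AC0 - tl$AC0) / pmax(tl$AC0, 1e-12)), 1e-6)
    expect_lt(max(abs(ta$ACmod - tl$ACmod) / pmax(tl$ACmod, 1e-12)), 1e-6)
  }
})

test_that("apply_constraints enforces the attribute-specific assumptions", {
  p <- attribute_params(0.17, 0.093, 0.01, 0.13, kclmod = 0.2, V = 3.34)
  expect_equal(apply_constraints(p, "deamidation-like")$kclmod, 0.13)
  pm <- attribute_params(0.18, 0.096, ktr = 0.05, 0.127, 0.295, V = 3.32)
  expect_equal(apply_constraints(pm, "man5-like")$ktr, 0)
  # reference Man5 parameters already satisfy their constraint
  ref <- reference_params("man5")
  expect_identical(apply_constraints(ref, "man5-like"), ref)
  expect_error(apply_constraints(p, "oxidation-like"))
})
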