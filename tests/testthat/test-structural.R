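test_that("closed-form profile matches numerical integration", {
  spec <- final_spec()
  par <- final_params()
  doses <- data.frame(time = 0, amount = 1000, tinf = 1)
  tt <- c(15, 30, 60, 120, 180, 360)
  pa <- predict_profile(spec, par, doses, tt, method = "analytic")
  po <- predict_profile(spec, par, doses, tt, method = "ode")
  expect_equal(pa$plasma, po$plasma, tolerance = 1e-6)
  expect_equal(pa$urine_cumulative, po$urine_cumulative, tolerance = 1e-6)
  # also for a 3-compartment spec and a peripheral-elimination spec
  s3 <- structural_spec(3)
  p3 <- structural_params(CL = 0.1, V1 = 9, Q = 0.3, V2 = 9, Q2 = 0.05,
                          V3 = 20)
  a3 <- predict_profile(s3, p3, doses, tt, method = "analytic")
  o3 <- predict_profile(s3, p3, doses, tt, method = "ode")
  expect_equal(a3$plasma, o3$plasma, tolerance = 1e-6)
  sb <- structural_spec(2, elim_peripheral = "first_order")
  pb <- structural_params(CL = 0.1, V1 = 9, Q = 0.3, V2 = 9, CLB = 0.05)
  ab <- predict_profile(sb, pb, doses, tt, method = "analytic")
  ob <- predict_profile(sb, pb, doses, tt, method = "ode")
  expect_equal(ab$plasma, ob$plasma, tolerance = 1e-6)
})

test_that("profiles respect null input, superposition and mass balance", {
  spec <- final_spec()
  par <- final_params()
  tt <- c(15, 60, 180, 360)
  # zero dose
  z <- predict_profile(spec, par, data.frame(time = 0, amount = 0,
                                             tinf = 1), tt)
  expect_true(all(z$plasma == 0) && all(z$urine_cumulative == 0))
  # superposition of a rescue dose
  d1 <- data.frame(time = 0, amount = 1000, tinf = 1)
  d2 <- data.frame(time = 87, amount = 500, tinf = 1)
  both <- predict_profile(spec, par, rbind(d1, d2), tt)
  sum2 <- predict_profile(spec, par, d1, tt)$plasma +
    predict_profile(spec, par, d2, tt)$plasma
  expect_equal(both$plasma, sum2, tolerance = 1e-8)
  # complete urinary elimination recovers the dose
  thalf <- terminal_half_life(spec, par)
  p1 <- final_params(p_urine = 1)
  u <- predict_profile(spec, p1, d1, 50 * thalf)$urine_cumulative
  expect_equal(u, 1000, tolerance = 1e-3)
  # fractional urinary elimination recovers p_urine of the dose
  u54 <- predict_profile(spec, par, d1, 50 * thalf)$urine_cumulative
  expect_equal(u54 / 1000, 0.54, tolerance = 1e-3)
  # cumulative urine is non-decreasing, plasma non-negative
  pr <- predict_profile(spec, par, d1, 0:360)
  expect_true(all(diff(pr$urine_cumulative) >= -1e-12))
  expect_true(all(pr$plasma >= 0))
})

test_that("terminal half-life follows the eigenvalues of the disposition", {
  one <- structural_spec(1)
  expect_equal(terminal_half_life(one, structural_params(CL = 0.1,
                                                         V1 = 10)),
               log(2) / 0.01, tolerance = 1e-12)
  # published typicals give 1.8 h
  expect_equal(round(terminal_half_life(final_spec(), final_params()) / 60,
                     1), 1.8)
  # vanishing diffusional clearance degenerates to one compartment
  p0 <- structural_params(CL = 0.1, V1 = 10, Q = 1e-9, V2 = 5,
                          p_urine = 0.5)
  expect_equal(terminal_half_life(final_spec(), p0), log(2) / 0.01,
               tolerance = 1e-4)
  # saturable elimination has no terminal eigen-rate
  mm <- structural_spec(2, elim_urinary = "michaelis_menten")
  expect_error(terminal_half_life(mm, structural_params(
    V1 = 10, Q = 0.3, V2 = 9, Vmax = 10, Km = 50)), "unsupported|linear")
})

test_that("saturable elimination converges to first order as Km grows", {
  doses <- data.frame(time = 0, amount = 1000, tinf = 1)
  tt <- c(15, 60, 180, 360)
  fo <- predict_profile(final_spec(), final_params(p_urine = 1), doses, tt)
  mm <- structural_spec(2, elim_urinary = "michaelis_menten")
  cl <- final_params()$CL
  for (km in c(1e3, 1e5)) {
    pm <- structural_params(V1 = 9.25, Q = 0.32, V2 = 9.49,
                            Vmax = cl * km, Km = km)
    prm <- predict_profile(mm, pm, doses, tt)
    dev <- max(abs(prm$plasma / fo$plasma - 1))
    if (km == 1e5) expect_lt(dev, 1e-3)
  }
})

test_that("typical values apply the covariate relations exactly", {
  theta <- c(CL = 0.077, V1 = 9.25)
  betas <- list(covariate_relation("CL", "eclcr", "linear", value = 0.0039),
                covariate_relation("V1", "bw", "power", ref = 70,
                                   value = 1.41))
  tv <- typical_value(theta, betas, c(eclcr = 150, bw = 70))
  expect_equal(unname(tv["CL"]), 0.077 * exp(0.585), tolerance = 1e-12)
  expect_equal(round(unname(tv["CL"]), 2), 0.14)
  expect_equal(unname(tv["V1"]), 9.25)
  # null coefficient leaves theta untouched
  b0 <- list(covariate_relation("CL", "eclcr", "linear", value = 0))
  expect_equal(typical_value(theta, b0, c(eclcr = 999))[["CL"]], 0.077)
  # missing reference covariate is a configuration error
  expect_error(typical_value(theta, betas, c(eclcr = 150)), "bw")
})

test_that("the candidate spec set enumerates the screened topologies", {
  cs <- candidate_specs()
  expect_length(cs, 10)
  expect_true(all(vapply(cs, inherits, TRUE, "structural_spec")))
  expect_error(structural_spec(1, elim_peripheral = "first_order"),
               "requires")
  expect_error(structural_params(CL = -1, V1 = 10), "> 0")
  expect_error(structural_params(CL = 1, V1 = 10, p_urine = 1.2),
               "p_urine")
})
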