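test_that("covariate sampler reproduces the target baseline moments", {
  s <- sample_covariates(10000, "TXA0.5g", seed = 301)
  expect_equal(mean(s$age), 34, tolerance = 0.02)
  expect_equal(mean(s$height), 166, tolerance = 0.02)
  expect_equal(mean(s$bw_before), 73.2, tolerance = 0.02)
  # derived renal clearance lands near the reported group means
  p <- derive_covariates(cbind(s, covariate_missing = FALSE))
  expect_equal(mean(p$eclcr_cg_bef), 150.5, tolerance = 0.10)
  s1 <- sample_covariates(10000, "TXA1g", seed = 302)
  p1 <- derive_covariates(s1)
  expect_equal(mean(p1$eclcr_cg_bef), 143.4, tolerance = 0.10)
  # determinism at n = 1
  a <- sample_covariates(1, "TXA1g", seed = 303)
  b <- sample_covariates(1, "TXA1g", seed = 303)
  expect_identical(a, b)
})

test_that("cohort means of the derived panel sit within 2 SD of the
           reference table", {
  tr <- generate_trial(seed = 305)
  p <- derive_covariates(tr$dataset)
  arm <- tr$dataset$subjects$arm
  ref <- list( # (mean, sd) per arm: TXA0.5g then TXA1g
    age = rbind(c(34, 5), c(33, 4)),
    height = rbind(c(166, 8), c(164, 7)),
    iw = rbind(c(58.3, 7.0), c(56.3, 6.3)),
    bw_before = rbind(c(73.2, 21.1), c(72, 17)),
    bw = rbind(c(84.3, 18.6), c(83.0, 15.2)),
    bmi_bef = rbind(c(26.4, 7.0), c(26.6, 6.0)),
    bmi = rbind(c(30.4, 6.0), c(30.8, 5.1)),
    abw_bef = rbind(c(68.7, 10.0), c(67.0, 8.3)),
    lbw_bef = rbind(c(43.9, 7.4), c(43.0, 6.3)),
    lbw = rbind(c(47.8, 6.4), c(46.9, 5.4)),
    bsa_bef = rbind(c(1.8, 0.2), c(1.8, 0.2)),
    bsa = rbind(c(1.9, 0.2), c(1.9, 0.2)),
    eclcr_cg_bef = rbind(c(150.5, 64.5), c(143.4, 53.2)),
    eclcr_cg = rbind(c(172.3, 62.3), c(166.3, 56.1)),
    egfr_ckdepi_bef = rbind(c(122.5, 20.8), c(119.7, 17.2)),
    egfr_ckdepi = rbind(c(130.3, 19.1), c(127.9, 16.4)),
    egfr_mdrd_bef = rbind(c(117.1, 37.1), c(111.9, 35.5)),
    egfr_mdrd = rbind(c(124.5, 37.5), c(119.5, 37.0)))
  for (v in names(ref)) for (a in 1:2) {
    got <- mean(p[[v]][arm == c("TXA0.5g", "TXA1g")[a]])
    expect_lt(abs(got - ref[[v]][a, 1]), 2 * ref[[v]][a, 2],
              label = paste(v, "arm", a, "=", round(got, 2)))
  }
  expect_true(all(p$bleeding_volume >= 800, na.rm = TRUE) ||
                all(tr$dataset$subjects$bleeding_volume >= 800))
})

test_that("generated trials respect the design arithmetic and pass
           validation", {
  tr <- generate_trial(seed = 306)
  ds <- tr$dataset
  expect_identical(validate_pk_dataset(ds), ds)
  expect_equal(nrow(ds$subjects), 79)
  expect_equal(table(ds$subjects$arm)[["TXA0.5g"]], 34)
  expect_equal(sum(ds$observations$kind == "plasma"), 79 * 6)
  expect_equal(sum(ds$observations$kind == "urine"), 79 * 2)
  # sampling times never precede the end of infusion
  expect_gt(min(ds$observations$time), 1)
  # determinism
  tr2 <- generate_trial(seed = 306)
  expect_identical(tr2$dataset, ds)
})

test_that("the noise-free limit reproduces the deterministic model", {
  truth <- population_model(
    final_spec(),
    theta = c(CL = 0.138, V1 = 9.25, Q = 0.32, V2 = 9.49, purine = 0.54),
    omega = NULL,
    betas = list(),
    error_plasma = list(type = "additive", a = 1e-12),
    error_urine = list(type = "proportional", b = 1e-12))
  tr <- generate_trial(trial_design(n_per_arm = c(TXA1g = 3),
                                    rescue_prob = 0), truth, seed = 307)
  ds <- tr$dataset
  par <- structural_params(CL = 0.138, V1 = 9.25, Q = 0.32, V2 = 9.49,
                           p_urine = 0.54)
  for (id in ds$subjects$id) {
    oi <- ds$observations[ds$observations$id == id &
                            ds$observations$kind == "plasma", ]
    pr <- predict_profile(final_spec(), par,
                          ds$doses[ds$doses$id == id, -1], oi$time)
    expect_equal(oi$value, pr$plasma, tolerance = 1e-6)
    ui <- ds$observations[ds$observations$id == id &
                            ds$observations$kind == "urine", ]
    pu <- predict_profile(final_spec(), par,
                          ds$doses[ds$doses$id == id, -1],
                          c(180, 360))$urine_cumulative
    amounts <- ui$value * ui$urine_volume
    expect_equal(amounts, c(pu[1], pu[2] - pu[1]), tolerance = 1e-6)
    # urine mass balance: excreted amount within the p_urine share
    expect_lte(sum(amounts), 0.54 * sum(ds$doses$amount[ds$doses$id == id]))
  }
})

test_that("urine concentrations scale inversely with collected volume", {
  spec <- final_spec()
  par <- structural_params(CL = 0.138, V1 = 9.25, Q = 0.32, V2 = 9.49,
                           p_urine = 0.54)
  doses <- data.frame(time = 0, amount = 1000, tinf = 1)
  amt <- predict_profile(spec, par, doses, 180)$urine_cumulative
  expect_equal((amt / 0.4) / (amt / 0.8), 2, tolerance = 1e-12)
})
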