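small_design <- function(n1 = 8, n2 = 10)
  trial_design(n_per_arm = c(`TXA0.5g` = n1, TXA1g = n2))

test_that("SAEM degenerates to pooled regression without BSV", {
  truth <- population_model(
    final_spec(),
    theta = c(CL = 0.10, V1 = 9, Q = 0.3, V2 = 9, purine = 0.6),
    omega = c(CL = 0, V1 = 0, Q = 0, V2 = 0, purine = 0),
    error_plasma = list(type = "combined", a = 1e-3, b = 1e-3),
    error_urine = list(type = "proportional", b = 1e-3))
  tr <- generate_trial(small_design(), truth, seed = 51)
  fit <- saem_fit(tr$dataset, truth,
                  control = replicate_control(), seed = 52)
  expect_equal(unname(fit$theta), unname(truth$theta), tolerance = 0.01)
})

test_that("identical seed and settings give a bit-identical fit", {
  truth <- reference_model()
  tr <- generate_trial(small_design(), truth, seed = 61)
  ctrl <- saem_control(n_explore = 60, n_smooth = 30, n_chains = 2,
                       ll_draws = 200, cond_iter = 30)
  f1 <- saem_fit(tr$dataset, truth, control = ctrl, seed = 62)
  f2 <- saem_fit(tr$dataset, truth, control = ctrl, seed = 62)
  expect_identical(f1$theta, f2$theta)
  expect_identical(f1$omega, f2$omega)
  expect_identical(f1$trace, f2$trace)
  expect_identical(f1$minus2ll, f2$minus2ll)
})

test_that("marginal likelihood behaves like a likelihood", {
  truth <- reference_model()
  tr <- generate_trial(small_design(10, 12), truth, seed = 71)
  base <- population_model(
    final_spec(),
    theta = c(CL = 0.1, V1 = 10, Q = 0.3, V2 = 10, purine = 0.5),
    omega = c(CL = 0.3, V1 = 0.3, Q = 0.3, V2 = 0.3, purine = 0.3))
  ctrl <- replicate_control()
  bfit <- saem_fit(tr$dataset, base, control = ctrl, seed = 72)
  rich_model <- base
  rich_model$betas <- list(covariate_relation("CL", "eclcr_cg_bef",
                                              "linear"))
  rfit <- saem_fit(tr$dataset, rich_model, control = ctrl, seed = 73,
                   init = list(theta = bfit$theta, omega = bfit$omega,
                               error = bfit$error))
  # a nested richer model cannot fit worse (up to Monte Carlo noise)
  expect_lte(rfit$minus2ll,
             bfit$minus2ll + 3 * (rfit$minus2ll_se + bfit$minus2ll_se))

  # Monte Carlo SE scales like 1/sqrt(draws)
  l1 <- log_likelihood(bfit, mc_size = 1500, seed = 1)
  l2 <- log_likelihood(bfit, mc_size = 6000, seed = 2)
  expect_equal(l1$minus2ll, l2$minus2ll,
               tolerance = 6 * (l1$se + l2$se) / abs(l2$minus2ll))
  expect_lt(l2$se, l1$se)

  # rich data: conditional shrinkage is small for well-informed parameters
  fit_sh <- shrinkage(bfit)
  expect_lt(abs(fit_sh[["CL"]]), 35)
  expect_lt(abs(fit_sh[["V1"]]), 35)
})

test_that("without random effects the marginal likelihood is direct", {
  ds <- make_toy_dataset()
  mod <- population_model(
    final_spec(),
    theta = c(CL = 0.1, V1 = 10, Q = 0.3, V2 = 10, purine = 0.6),
    omega = NULL)
  dat <- txapopk:::prepare_data(ds)
  panel <- derive_covariates(ds)
  m <- txapopk:::m_matrix(txapopk:::build_design(mod, panel),
                          txapopk:::model_coefs(mod))
  errv <- txapopk:::err_par_vector(mod)
  ert <- txapopk:::err_type_vector(mod)
  fake <- structure(list(model = mod, omega = mod$omega, m = m, dat = dat,
                         error = errv, errtype = ert,
                         eta_mode = m * 0,
                         cond_samples = array(0, c(dat$ns, 5, 2))),
                    class = "saem_fit")
  ll <- log_likelihood(fake, mc_size = 10)
  # independent R computation of the residual log-likelihood
  f <- txapopk:::cpp_pred(txapopk:::psi_matrix(m, mod), dat,
                          txapopk:::spec_flags(mod$spec))
  sd_row <- sqrt(txapopk:::resid_var(f, dat$obs_type, errv, ert))
  expect_equal(ll$minus2ll, -2 * sum(dnorm(dat$obs_y, f, sd_row,
                                           log = TRUE)),
               tolerance = 1e-10)
  expect_equal(ll$se, 0)
})

test_that("exponential residuals equal an additive model on the log scale", {
  ds <- make_toy_dataset()
  mod <- population_model(
    final_spec(),
    theta = c(CL = 0.1, V1 = 10, Q = 0.3, V2 = 10, purine = 0.6),
    error_plasma = list(type = "exponential", b = 0.2),
    error_urine = list(type = "exponential", b = 0.3))
  dat <- txapopk:::prepare_data(ds)
  panel <- derive_covariates(ds)
  m <- txapopk:::m_matrix(txapopk:::build_design(mod, panel),
                          txapopk:::model_coefs(mod))
  psi <- txapopk:::psi_matrix(m, mod)
  flags <- txapopk:::spec_flags(mod$spec)
  errv <- txapopk:::err_par_vector(mod)
  ll <- sum(txapopk:::cpp_ll(psi, dat, flags, errv,
                             txapopk:::err_type_vector(mod)))
  f <- txapopk:::cpp_pred(psi, dat, flags)
  b <- ifelse(dat$obs_type == 0L, 0.2, 0.3)
  ll_log <- sum(dnorm(log(dat$obs_y), log(f), b, log = TRUE) -
                  log(dat$obs_y))
  expect_equal(ll, ll_log, tolerance = 1e-10)
})

test_that("BICc applies the hybrid sample-size penalty", {
  ds <- make_toy_dataset()
  mod <- reference_model() # 5 varying parameters, 2 betas, 3 error pars
  pen <- log(3) * (5 + 2) + log(24) * (5 + 3)
  expect_equal(compute_bicc(1000, mod, ds), 1000 + pen, tolerance = 1e-12)
  # an extra coefficient with unchanged -2LL always costs
  mod2 <- mod
  mod2$betas <- c(mod2$betas,
                  list(covariate_relation("Q", "age", "linear")))
  expect_gt(compute_bicc(1000, mod2, ds), compute_bicc(1000, mod, ds))
})

test_that("Wald and Shapiro-Wilk helpers give textbook values", {
  expect_equal(wald_test(0, 1), 1)
  expect_equal(wald_test(1.96, 1), 0.05, tolerance = 1e-3)
  expect_equal(wald_test(3.89, 1), 1.0e-4, tolerance = 0.02)
  expect_error(wald_test(1, 0), "se")

  expect_error(shapiro_wilk_check(c(1, 2)), "at least 3")
  expect_error(shapiro_wilk_check(rep(1, 10)), "constant")
  set.seed(10)
  pnorm_ok <- mean(replicate(100,
    shapiro_wilk_check(rnorm(79))$p.value > 0.05))
  expect_gte(pnorm_ok, 0.9)
  pexp_rej <- mean(replicate(100,
    shapiro_wilk_check(rexp(79))$p.value < 0.05))
  expect_gte(pexp_rej, 0.9)
})

test_that("sparser sampling inflates conditional shrinkage", {
  truth <- reference_model()
  rich <- generate_trial(small_design(10, 12), truth, seed = 81)
  sparse_design <- trial_design(n_per_arm = c(`TXA0.5g` = 10, TXA1g = 12),
                                nominal_times = c(60),
                                urine_breaks = c(0, 360))
  sparse <- generate_trial(sparse_design, truth, seed = 81)
  ctrl <- saem_control(n_explore = 120, n_smooth = 60, n_chains = 2,
                       ll_draws = 200, cond_iter = 60,
                       compute_fim = FALSE, compute_ll = FALSE)
  frich <- saem_fit(rich$dataset, truth, control = ctrl, seed = 82,
                    init = "model")
  fsparse <- saem_fit(sparse$dataset, truth, control = ctrl, seed = 82,
                      init = "model")
  expect_gt(shrinkage(fsparse)[["CL"]], shrinkage(frich)[["CL"]])
})
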