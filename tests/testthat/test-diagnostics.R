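test_that("VPC covers its own generative model and flags misspecification", {
  tr <- generate_trial(seed = 9)
  v <- vpc(tr$dataset, tr$truth, n_sim = 200, seed = 3)
  expect_gte(vpc_coverage(v), 0.8)
  # same seed, same result
  v2 <- vpc(tr$dataset, tr$truth, n_sim = 200, seed = 3)
  expect_identical(v$bands, v2$bands)
  # doubling V1 pushes the early observed median outside the band
  wrong <- tr$truth
  wrong$theta["V1"] <- wrong$theta["V1"] * 2
  vw <- vpc(tr$dataset, wrong, n_sim = 200, seed = 3)
  med_band <- vw$bands[vw$bands$percentile == 50 & vw$bands$bin == 15, ]
  obs_med <- vw$observed$p50[vw$observed$bin == 15]
  expect_true(obs_med < med_band$lo || obs_med > med_band$hi)
})

test_that("VPC bands collapse without variability", {
  tr <- generate_trial(seed = 19)
  degen <- population_model(
    final_spec(),
    theta = tr$truth$theta, omega = NULL, betas = tr$truth$betas,
    error_plasma = list(type = "additive", a = 1e-9),
    error_urine = list(type = "proportional", b = 1e-9))
  v <- vpc(tr$dataset, degen, n_sim = 120, seed = 4)
  expect_lt(max(v$bands$hi - v$bands$lo), 1e-6)
})

test_that("NPDE is standard normal under the true model", {
  tr <- generate_trial(seed = 9)
  nd <- npde(tr$dataset, tr$truth, n_sim = 300, seed = 4)
  expect_lt(abs(nd$plasma$mean), 0.1)
  expect_gt(nd$plasma$var, 0.8)
  expect_lt(nd$plasma$var, 1.2)
  # plasma and urine streams are reported separately
  expect_gt(nd$urine$n, 0)
  expect_true(is.finite(nd$urine$frac_outside90))
  expect_true(!is.null(nd$plasma$shapiro))
})

test_that("NPDE reduces to the marginal rank transform for single
           observations", {
  subjects <- data.frame(id = paste0("S", 1:5), age = 30, height = 165,
                         bw_before = 70, bw = 80, scr = 6.5, arm = "TXA1g",
                         bleeding_volume = 1000)
  doses <- data.frame(id = subjects$id, time = 0, amount = 1000, tinf = 1)
  obs <- data.frame(id = subjects$id, time = 60,
                    value = c(20, 25, 30, 35, 40), kind = "plasma",
                    interval_start = NA_real_, urine_volume = NA_real_)
  ds <- pk_dataset(subjects, doses, obs)
  mod <- reference_model()
  n_sim <- 200
  nd <- npde(ds, mod, n_sim = n_sim, seed = 8)
  sims <- txapopk:::simulate_observations(ds, mod, n_sim, seed = 8)
  manual <- qnorm((rowSums(sims < obs$value) + 0.5) / (n_sim + 1))
  expect_equal(nd$npde, manual, tolerance = 1e-12)
})

test_that("simulation machinery agrees with a brute-force simulator", {
  # independent path: per-subject ODE profiles + hand-rolled noise
  set.seed(123)
  subjects <- sample_covariates(5, "TXA1g")
  doses <- data.frame(id = subjects$id, time = 0, amount = 1000, tinf = 1)
  tt <- c(15, 60, 180)
  obs <- do.call(rbind, lapply(subjects$id, function(id)
    data.frame(id = id, time = tt, value = 1, kind = "plasma",
               interval_start = NA_real_, urine_volume = NA_real_)))
  ds <- pk_dataset(subjects, doses, obs)
  mod <- reference_model()
  n_sim <- 400
  sims <- txapopk:::simulate_observations(ds, mod, n_sim, seed = 31)

  panel <- derive_covariates(subjects)
  spec <- mod$spec
  brute <- matrix(NA_real_, nrow(obs), n_sim)
  set.seed(32)
  for (s in seq_len(n_sim)) {
    for (i in seq_len(5)) {
      cl_typ <- mod$theta[["CL"]] * exp(0.0039 * panel$eclcr_cg_bef[i])
      v1_typ <- mod$theta[["V1"]] * (panel$bw_before[i] / 70)^1.41
      psi <- structural_params(
        CL = cl_typ * exp(rnorm(1, 0, 0.20)),
        V1 = v1_typ * exp(rnorm(1, 0, 0.59)),
        Q = 0.32 * exp(rnorm(1, 0, 0.67)),
        V2 = 9.49 * exp(rnorm(1, 0, 0.13)),
        p_urine = plogis(qlogis(0.54) + rnorm(1, 0, 0.46)))
      f <- predict_profile(spec, psi, doses[1, -1], tt,
                           method = "ode")$plasma
      brute[(i - 1) * 3 + 1:3, s] <- f +
        sqrt(0.44^2 + 0.15^2 * f^2) * rnorm(3)
    }
  }
  # same distribution summaries within Monte Carlo tolerance
  # (rows align: both orderings group by subject in id order, time sorted)
  m_pkg <- rowMeans(sims)
  m_brt <- rowMeans(brute)
  expect_equal(mean(m_pkg), mean(m_brt), tolerance = 0.1)
  expect_equal(sd(as.vector(sims)), sd(as.vector(brute)),
               tolerance = 0.15)
  q_pkg <- quantile(as.vector(sims), c(0.1, 0.5, 0.9))
  q_brt <- quantile(as.vector(brute), c(0.1, 0.5, 0.9))
  expect_equal(unname(q_pkg), unname(q_brt), tolerance = 0.12)
})

test_that("bootstrap summaries keep their invariants", {
  tr <- generate_trial(trial_design(n_per_arm = c(`TXA0.5g` = 8,
                                                  TXA1g = 10)), seed = 41)
  ctrl <- saem_control(n_explore = 80, n_smooth = 40, n_chains = 2,
                       ll_draws = 200, cond_iter = 40,
                       compute_fim = FALSE)
  fit <- saem_fit(tr$dataset, tr$truth, control = ctrl, seed = 42)
  bs <- pk_bootstrap(tr$dataset, tr$truth, fit, n_rep = 2, seed = 43)
  expect_true(all(bs$summary$q1 <= bs$summary$median + 1e-12))
  expect_true(all(bs$summary$median <= bs$summary$q3 + 1e-12))
  expect_lte(nrow(bs$draws), 2)
})

test_that("bootstrapping clones of one subject has near-zero spread", {
  tr <- generate_trial(trial_design(n_per_arm = c(TXA1g = 1)), seed = 44)
  ds <- tr$dataset
  # clone the single subject 8 times
  subjects <- ds$subjects[rep(1, 8), ]
  subjects$id <- paste0("C", 1:8)
  doses <- do.call(rbind, lapply(subjects$id, function(cid) {
    x <- ds$doses; x$id <- cid; x
  }))
  obs <- do.call(rbind, lapply(subjects$id, function(cid) {
    x <- ds$observations; x$id <- cid; x
  }))
  clones <- pk_dataset(subjects, doses, obs)
  # identical covariates make covariate designs collinear, so the clone
  # experiment uses the covariate-free structure
  mod <- population_model(
    final_spec(),
    theta = c(CL = 0.14, V1 = 9.25, Q = 0.32, V2 = 9.49, purine = 0.54),
    omega = c(CL = 0.2, V1 = 0.3, Q = 0.3, V2 = 0.13, purine = 0.3),
    error_plasma = list(type = "combined", a = 0.44, b = 0.15),
    error_urine = list(type = "proportional", b = 0.52))
  ctrl <- saem_control(n_explore = 80, n_smooth = 40, n_chains = 2,
                       ll_draws = 200, cond_iter = 40,
                       compute_fim = FALSE, compute_ll = FALSE)
  fit <- saem_fit(clones, mod, control = ctrl, seed = 45)
  bs <- pk_bootstrap(clones, mod, fit, n_rep = 3, seed = 46,
                     control = ctrl)
  iqr_rel <- with(bs$summary[1:5, ], (q3 - q1) / pmax(abs(median), 1e-9))
  expect_lt(max(iqr_rel), 0.15)
})
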