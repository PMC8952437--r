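base_model_for <- function() {
  population_model(
    final_spec(),
    theta = c(CL = 0.1, V1 = 10, Q = 0.3, V2 = 10, purine = 0.5),
    omega = c(CL = 0.3, V1 = 0.3, Q = 0.3, V2 = 0.3, purine = 0.3))
}

test_that("screening ranks the generative covariates first", {
  tr <- generate_trial(seed = 91)
  bfit <- saem_fit(tr$dataset, base_model_for(),
                   control = replicate_control(compute_ll = FALSE,
                                               compute_fim = FALSE),
                   seed = 92)
  sc <- screen_covariates(bfit)
  top_cl <- sc[sc$target == "CL", ][1, ]
  expect_match(top_cl$covariate, "eclcr|egfr") # a renal measure leads CL
  top_v1 <- sc[sc$target == "V1", ][1, ]
  expect_match(top_v1$covariate, "bw|bsa|lbw|abw|bmi") # body size leads V1
  # r2 of the body-weight relation on V1 is substantial
  r2_v1 <- sc[sc$target == "V1" & sc$covariate == "bw_before" &
                sc$form == "power", "r2"]
  expect_gt(r2_v1, 0.1)
  expect_lt(r2_v1, 0.8)
  # a permuted covariate carries no signal
  set.seed(93)
  pan <- bfit$panel
  pan$shuffled <- sample(pan$eclcr_cg_bef)
  bfit2 <- bfit
  bfit2$panel <- pan
  sc2 <- screen_covariates(bfit2, targets = "CL",
                           covariates = "shuffled")
  expect_true(all(sc2$r2 < 0.15))
})

test_that("forward selection returns the base model when nothing helps", {
  # truth with no covariate effects at all
  truth <- population_model(
    final_spec(),
    theta = c(CL = 0.138, V1 = 9.25, Q = 0.32, V2 = 9.49, purine = 0.54),
    omega = c(CL = 0.2, V1 = 0.3, Q = 0.3, V2 = 0.13, purine = 0.3),
    error_plasma = list(type = "combined", a = 0.44, b = 0.15),
    error_urine = list(type = "proportional", b = 0.52))
  tr <- generate_trial(trial_design(n_per_arm = c(`TXA0.5g` = 12,
                                                  TXA1g = 14)),
                       truth, seed = 94)
  ctrl <- saem_control(n_explore = 150, n_smooth = 75, n_chains = 2,
                       ll_draws = 800, cond_iter = 60)
  bfit <- saem_fit(tr$dataset, truth, control = ctrl, seed = 95)
  fs <- forward_select(tr$dataset, bfit,
                       list(covariate_relation("CL", "age", "linear")),
                       control = ctrl, seed = 96)
  expect_false(any(fs$ledger$accepted))
  expect_length(fs$model$betas, 0)
  expect_identical(fs$fit$theta, bfit$theta)
})

test_that("selection ledgers are seed-reproducible and BICc-consistent", {
  tr <- generate_trial(trial_design(n_per_arm = c(`TXA0.5g` = 12,
                                                  TXA1g = 14)),
                       seed = 97)
  ctrl <- saem_control(n_explore = 120, n_smooth = 60, n_chains = 2,
                       ll_draws = 600, cond_iter = 60)
  bfit <- saem_fit(tr$dataset, base_model_for(), control = ctrl,
                   seed = 98)
  cands <- list(covariate_relation("CL", "eclcr_cg_bef", "linear"),
                covariate_relation("V1", "bw_before", "power", ref = 70))
  fs1 <- forward_select(tr$dataset, bfit, cands, control = ctrl, seed = 99)
  fs2 <- forward_select(tr$dataset, bfit, cands, control = ctrl, seed = 99)
  expect_identical(fs1$ledger, fs2$ledger)
  # every accepted step bought at least the threshold
  n_acc <- sum(fs1$ledger$accepted)
  if (n_acc > 0)
    expect_lte(fs1$fit$bicc, bfit$bicc - 3.84 * n_acc)
})
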