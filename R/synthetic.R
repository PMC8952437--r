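#' Design of a two-arm caesarean-delivery PK trial
#'
#' Default values emulate the reference obstetric-hemorrhage design:
#' two dose arms (0.5 g, n = 34; 1 g, n = 45) given as a 1-minute infusion
#' at T0, plasma samples at 15/30/60/120/180/360 min jittered uniformly
#' within +/- 10 min, two urine collections covering (0, 180] and
#' (180, 360] min, and a roughly 10% rate of rescue doses (the subject's
#' arm dose again) at a log-normal time with median 87 min.
#'
#' @param n_per_arm Named counts per arm; names are the arm labels and the
#'   numeric part of the label (in g) is parsed as the dose.
#' @param nominal_times Plasma sampling times (min).
#' @param jitter Half-width of the uniform sampling-time jitter (min).
#' @param urine_breaks Boundaries of consecutive urine-collection
#'   intervals (min).
#' @param urine_vol_meanlog,urine_vol_sdlog Log-normal parameters of the
#'   collected urine volume (L); the default median is 0.4 L.
#' @param rescue_prob Probability that a subject receives a rescue dose.
#' @param rescue_meanlog,rescue_sdlog Log-normal rescue-time parameters
#'   (median 87 min).
#' @param tinf Infusion duration (min).
#' @return A list of class `trial_design`.
#' @export
trial_design <- function(n_per_arm = c(`TXA0.5g` = 34, TXA1g = 45),
                         nominal_times = c(15, 30, 60, 120, 180, 360),
                         jitter = 10,
                         urine_breaks = c(0, 180, 360),
                         urine_vol_meanlog = log(0.4),
                         urine_vol_sdlog = 0.4,
                         rescue_prob = 8 / 79,
                         rescue_meanlog = log(87), rescue_sdlog = 0.45,
                         tinf = 1) {
  structure(list(n_per_arm = n_per_arm, nominal_times = nominal_times,
                 jitter = jitter, urine_breaks = urine_breaks,
                 urine_vol_meanlog = urine_vol_meanlog,
                 urine_vol_sdlog = urine_vol_sdlog,
                 rescue_prob = rescue_prob,
                 rescue_meanlog = rescue_meanlog,
                 rescue_sdlog = rescue_sdlog, tinf = tinf),
            class = "trial_design")
}

arm_dose_mg <- function(arm) {
  as.numeric(sub("^[^0-9]*([0-9.]+)g$", "\\1", arm)) * 1000
}

#' Baseline covariate distribution of the parturient population
#'
#' Per-arm means and standard deviations of age, height, pre-pregnancy
#' weight, pregnancy weight gain, serum creatinine (mg/L) and bleeding
#' volume, with truncation bounds. Defaults reproduce the baseline table of
#' the reference trial; weight gain is an independent truncated normal
#' calibrated so the at-caesarean weight moments match.
#'
#' @return A list of per-arm moment tables.
#' @export
covariate_moments <- function() {
  list(
    `TXA0.5g` = data.frame(
      var = c("age", "height", "bw_before", "gain", "scr", "bleed"),
      mean = c(34, 166, 73.2, 11.1, 6.5, 1091),
      sd = c(5, 8, 21.1, 4, 1.5, 273),
      lo = c(18, 145, 30, 0, 3, 800),
      hi = c(50, 190, 150, 30, 13, 3000)),
    TXA1g = data.frame(
      var = c("age", "height", "bw_before", "gain", "scr", "bleed"),
      mean = c(33, 164, 72, 11, 6.7, 1163),
      sd = c(4, 7, 17, 4, 1.6, 318),
      lo = c(18, 145, 30, 0, 3, 800),
      hi = c(50, 190, 150, 30, 13, 3000)))
}

# Exact truncated-normal sampling by inverse-CDF.
rtruncnorm <- function(n, mean, sd, lo, hi) {
  plo <- pnorm(lo, mean, sd); phi <- pnorm(hi, mean, sd)
  if (phi <= plo) stop("configuration error: empty truncation interval",
                       call. = FALSE)
  qnorm(runif(n, plo, phi), mean, sd)
}

#' Sample baseline subject records
#'
#' Draws subject covariates from truncated normals at the per-arm moments
#' of [covariate_moments()]. Bleeding volume is truncated at the 800 mL
#' inclusion criterion.
#'
#' @param n Number of subjects.
#' @param arm Arm label (must name a moments entry).
#' @param moments See [covariate_moments()].
#' @param seed Optional seed.
#' @param id_prefix Prefix for generated subject ids.
#' @return A subjects data.frame as required by [pk_dataset()].
#' @export
sample_covariates <- function(n, arm = "TXA1g", moments = covariate_moments(),
                              seed = NULL, id_prefix = "S") {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(n >= 1, arm %in% names(moments))
  mo <- moments[[arm]]
  g <- function(v) {
    r <- mo[mo$var == v, ]
    rtruncnorm(n, r$mean, r$sd, max(r$lo, if (v == "bleed") 800 else r$lo),
               r$hi)
  }
  bw_before <- g("bw_before")
  data.frame(id = paste0(id_prefix, seq_len(n)),
             age = g("age"), height = g("height"),
             bw_before = bw_before, bw = bw_before + g("gain"),
             scr = g("scr"), arm = arm,
             bleeding_volume = g("bleed"),
             stringsAsFactors = FALSE)
}

#' The reported final covariate model
#'
#' [population_model()] populated with the published estimates of the final
#' two-compartment double-elimination model: CL 0.077 L/min at eClcr = 0
#' scaled by `exp(0.0039 * eClcr_CG(pre-pregnancy weight))`, V1 9.25 L at
#' 70 kg scaled by `(BW_before/70)^1.41`, Q 0.32 L/min, V2 9.49 L, urinary
#' fraction 0.54; BSV standard deviations 0.20/0.59/0.67/0.13/0.46;
#' combined plasma error (a = 0.44 mg/L, b = 0.15) and proportional urine
#' error (b = 0.52). Used as the generative truth of the synthetic trial
#' and as the simulation model for dose exploration.
#'
#' @return A [population_model()].
#' @export
reference_model <- function() {
  population_model(
    spec = structural_spec(2, elim_nonurinary = "first_order"),
    theta = c(CL = 0.077, V1 = 9.25, Q = 0.32, V2 = 9.49, purine = 0.54),
    omega = c(CL = 0.20, V1 = 0.59, Q = 0.67, V2 = 0.13, purine = 0.46),
    betas = list(
      covariate_relation("CL", "eclcr_cg_bef", "linear", value = 0.0039),
      covariate_relation("V1", "bw_before", "power", ref = 70,
                         value = 1.41)),
    error_plasma = list(type = "combined", a = 0.44, b = 0.15),
    error_urine = list(type = "proportional", b = 0.52))
}

#' Generate a synthetic trial from a generative truth
#'
#' Samples covariates per arm, draws individual parameters from the
#' model's between-subject distribution (with covariate relations applied),
#' simulates plasma concentrations with the plasma error model and urine
#' interval concentrations with the urine error model, and codifies rescue
#' doses as additional dosing events. The hidden individual parameters are
#' returned for recovery scoring.
#'
#' Residual noise can drive a simulated concentration negative under an
#' additive component; such values are truncated at zero and counted rather
#' than resampled, keeping the error model honest.
#'
#' @param design A [trial_design()].
#' @param truth A [population_model()]; defaults to [reference_model()].
#' @param seed Seed for the whole trial.
#' @param moments Covariate moments, see [covariate_moments()].
#' @return A list of class `synthetic_trial`: `dataset` ([pk_dataset()]),
#'   `psi` (individual structural parameters), `eta`, `subjects`, `truth`,
#'   `n_truncated`.
#' @export
generate_trial <- function(design = trial_design(),
                           truth = reference_model(), seed = NULL,
                           moments = covariate_moments()) {
  if (!is.null(seed)) set.seed(seed)
  arms <- names(design$n_per_arm)
  subjects <- do.call(rbind, lapply(seq_along(arms), function(a)
    sample_covariates(design$n_per_arm[[a]], arms[a], moments,
                      id_prefix = paste0("A", a, "S"))))
  ns <- nrow(subjects)
  panel <- derive_covariates(subjects)
  X <- build_design(truth, panel)
  m <- m_matrix(X, model_coefs(truth))
  P <- length(truth$theta)
  omega <- unname(truth$omega)
  eta <- matrix(0, ns, P)
  for (l in seq_len(P))
    if (omega[l] > 0) eta[, l] <- rnorm(ns, 0, omega[l])
  phi <- m + eta
  psi <- psi_matrix(phi, truth)

  # dosing events (1-min infusion at T0, optional rescue)
  dose_amt <- arm_dose_mg(subjects$arm)
  has_rescue <- runif(ns) < design$rescue_prob
  rescue_t <- rlnorm(ns, design$rescue_meanlog, design$rescue_sdlog)
  doses <- data.frame(id = subjects$id, time = 0, amount = dose_amt,
                      tinf = design$tinf)
  if (any(has_rescue))
    doses <- rbind(doses,
                   data.frame(id = subjects$id[has_rescue],
                              time = round(rescue_t[has_rescue], 1),
                              amount = dose_amt[has_rescue],
                              tinf = design$tinf))

  # observation design
  nt <- length(design$nominal_times)
  samp_t <- pmax(rep(design$nominal_times, each = ns) +
                   runif(ns * nt, -design$jitter, design$jitter),
                 design$tinf + 0.1)
  obs_pl <- data.frame(id = rep(subjects$id, nt),
                       time = round(samp_t, 1), value = 0,
                       kind = "plasma", interval_start = NA_real_,
                       urine_volume = NA_real_)
  nb <- length(design$urine_breaks) - 1L
  uv <- rlnorm(ns * nb, design$urine_vol_meanlog, design$urine_vol_sdlog)
  obs_ur <- data.frame(
    id = rep(subjects$id, nb),
    time = rep(design$urine_breaks[-1], each = ns),
    value = 0, kind = "urine",
    interval_start = rep(design$urine_breaks[-(nb + 1L)], each = ns),
    urine_volume = round(uv, 3))
  dataset <- pk_dataset(subjects, doses, rbind(obs_pl, obs_ur))
  # prepare_data applies the same stable (subject, time) ordering as
  # pk_dataset, so predictions map positionally onto the observation rows
  dat <- prepare_data(dataset)
  f <- cpp_pred(psi, dat, spec_flags(truth$spec))

  ipl <- dat$obs_type == 0L
  y <- numeric(length(f))
  ep <- truth$error_plasma; eu <- truth$error_urine
  noise <- function(f, e, n) {
    switch(e$type,
           additive = f + rnorm(n, 0, e$a),
           proportional = f * (1 + rnorm(n, 0, e$b)),
           combined = f + sqrt(e$a^2 + e$b^2 * f^2) * rnorm(n),
           exponential = f * exp(rnorm(n, 0, e$b)))
  }
  y[ipl] <- noise(f[ipl], ep, sum(ipl))
  y[!ipl] <- noise(f[!ipl], eu, sum(!ipl))
  n_trunc <- sum(y < 0)
  y <- pmax(y, 0)
  obs <- dataset$observations
  stopifnot(identical(obs$id, dat$obs_id),
            identical(as.numeric(obs$time), dat$obs_time))
  obs$value <- y
  dataset <- pk_dataset(subjects, doses, obs)

  pn <- names(truth$theta)
  psi_named <- as.data.frame(psi[, psi_slots[ifelse(pn == "purine",
                                                    "purine", pn)],
                                 drop = FALSE])
  names(psi_named) <- pn
  psi_named <- cbind(id = subjects$id, psi_named)
  colnames(eta) <- pn
  structure(list(dataset = dataset, psi = psi_named, eta = eta,
                 subjects = subjects, truth = truth,
                 n_truncated = n_trunc, design = design),
            class = "synthetic_trial")
}

#' @export
print.synthetic_trial <- function(x, ...) {
  cat("<synthetic_trial>\n")
  print(x$dataset)
  cat("truncated-at-zero observations: ", x$n_truncated, "\n", sep = "")
  invisible(x)
}
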