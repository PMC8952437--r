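#' Monte Carlo simulation of a dosing regimen over a virtual population
#'
#' Samples a virtual parturient population (covariates from the baseline
#' generator, individual parameters from the model's between-subject
#' distribution with covariate relations applied) and evaluates each
#' subject's plasma concentration on a 1-minute grid. Residual error is
#' excluded by default: regimen summaries are about the underlying
#' concentration, not the assay.
#'
#' @param model A [population_model()]; defaults to [reference_model()].
#' @param n Number of simulated subjects.
#' @param dose Dose amount (mg) of the single bolus, or use `doses` for a
#'   full schedule.
#' @param doses Optional data.frame `time`, `amount`, `tinf` overriding
#'   `dose`.
#' @param tinf Infusion duration (min) of the single bolus.
#' @param times Evaluation grid (min).
#' @param covariates Optional subjects data.frame; sampled from
#'   [covariate_moments()] (arm label by dose) when omitted.
#' @param include_bsv Draw between-subject variability (FALSE collapses the
#'   population onto the typical subject profile per covariate vector).
#' @param seed Seed.
#' @return An object of class `population_simulation`: `conc`
#'   (subjects x times matrix, mg/L), `times`, `psi`, `subjects`.
#' @export
simulate_population <- function(model = reference_model(), n = 1000,
                                dose = 1000, doses = NULL, tinf = 1,
                                times = 0:360, covariates = NULL,
                                include_bsv = TRUE, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(n >= 1)
  if (is.null(doses))
    doses <- data.frame(time = 0, amount = dose, tinf = tinf)
  if (is.null(covariates)) {
    arm <- if (max(doses$amount) <= 500) "TXA0.5g" else "TXA1g"
    covariates <- sample_covariates(n, arm)
  }
  if (nrow(covariates) != n)
    stop("configuration error: covariates must have n rows", call. = FALSE)
  panel <- derive_covariates(covariates)
  for (b in model$betas)
    if (is.null(panel[[b$covariate]]))
      stop("configuration error: sampler lacks covariate ", b$covariate,
           call. = FALSE)
  m <- m_matrix(build_design(model, panel), model_coefs(model))
  P <- length(model$theta)
  omega <- unname(model$omega)
  eta <- matrix(0, n, P)
  if (include_bsv)
    for (l in seq_len(P))
      if (omega[l] > 0) eta[, l] <- rnorm(n, 0, omega[l])
  psi <- psi_matrix(m + eta, model)
  conc <- cpp_profile_many(psi, spec_flags(model$spec),
                           as.matrix(doses[, c("time", "amount", "tinf")]),
                           as.numeric(times))
  pn <- names(model$theta)
  psi_named <- as.data.frame(
    psi[, psi_slots[ifelse(pn == "purine", "purine", pn)], drop = FALSE])
  names(psi_named) <- pn
  structure(list(conc = conc, times = as.numeric(times), psi = psi_named,
                 subjects = covariates, doses = doses),
            class = "population_simulation")
}

#' Summarize a population simulation
#'
#' Mean and 10th/90th percentile concentration at the reporting times, and
#' threshold-coverage fractions: for each `(threshold mg/L, window min)`
#' pair, the fraction of subjects whose concentration stays at or above the
#' threshold at every grid time from the end of infusion through the
#' window.
#'
#' @param sim A [simulate_population()] result.
#' @param report_times Times (min) summarized in the concentration table.
#' @param thresholds List of `c(threshold, window)` pairs.
#' @return An object of class `simulation_summary` with `table` and
#'   `coverage` data.frames.
#' @export
summarize_simulation <- function(sim, report_times = c(15, 30, 60, 120,
                                                       360),
                                 thresholds = list(c(30, 15), c(15, 15))) {
  stopifnot(inherits(sim, "population_simulation"))
  if (nrow(sim$conc) == 0)
    stop("degenerate input: empty profile set", call. = FALSE)
  idx <- match(report_times, sim$times)
  if (anyNA(idx))
    stop("report_times must lie on the simulation grid", call. = FALSE)
  tab <- data.frame(
    time = report_times,
    mean = colMeans(sim$conc[, idx, drop = FALSE]),
    p10 = apply(sim$conc[, idx, drop = FALSE], 2, quantile, 0.10),
    p90 = apply(sim$conc[, idx, drop = FALSE], 2, quantile, 0.90))
  t_end_inf <- max(sim$doses$time + sim$doses$tinf)
  cov <- do.call(rbind, lapply(thresholds, function(th) {
    win <- sim$times > t_end_inf & sim$times <= th[2]
    mins <- apply(sim$conc[, win, drop = FALSE], 1, min)
    data.frame(threshold = th[1], window = th[2],
               fraction = mean(mins >= th[1]))
  }))
  structure(list(table = tab, coverage = cov, n = nrow(sim$conc)),
            class = "simulation_summary")
}

#' @export
print.simulation_summary <- function(x, ...) {
  cat("<simulation_summary> n = ", x$n, "\n", sep = "")
  tab <- x$table
  tab[, -1] <- round(tab[, -1], 1)
  print(tab, row.names = FALSE)
  cov <- x$coverage
  for (i in seq_len(nrow(cov)))
    cat(sprintf("P(conc >= %g mg/L through %g min) = %.1f%%\n",
                cov$threshold[i], cov$window[i], 100 * cov$fraction[i]))
  invisible(x)
}
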