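#' Importance-sampling marginal log-likelihood
#'
#' Estimates `-2 log L` of a converged fit by per-subject importance
#' sampling with a multivariate t proposal (5 degrees of freedom) centered
#' on the conditional modes with the conditional-sample covariance as scale.
#'
#' @param fit A [saem_fit()].
#' @param mc_size Draws per subject.
#' @param seed Optional seed.
#' @return List with `minus2ll`, `se` (Monte Carlo standard error) and
#'   `subject_ll`.
#' @export
log_likelihood <- function(fit, mc_size = 10000, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(inherits(fit, "saem_fit"))
  dat <- fit$dat
  model <- fit$model
  omega <- unname(fit$omega)
  P <- length(omega)
  act <- which(omega > 0)
  Pa <- length(act)
  nu <- 5
  flags <- spec_flags(model$spec)
  trans <- param_transforms(model)
  slot1 <- unname(psi_slots[ifelse(names(model$theta) == "purine",
                                   "purine", names(model$theta))])
  ns <- dat$ns
  ll_i <- se2_i <- numeric(ns)
  if (Pa == 0) { # no random effects: the marginal likelihood is direct
    psi <- psi_matrix(fit$m, model)
    ll_i <- cpp_ll(psi, dat, flags, fit$error, fit$errtype)
    return(list(minus2ll = -2 * sum(ll_i), se = 0, subject_ll = ll_i))
  }
  lcq <- lgamma((nu + Pa) / 2) - lgamma(nu / 2) -
    0.5 * Pa * log(nu * pi)
  for (i in seq_len(ns)) {
    ctr <- fit$eta_mode[i, act]
    Sg <- var(t(matrix(fit$cond_samples[i, act, ], nrow = Pa)))
    Sg <- matrix(Sg, Pa, Pa)
    diag(Sg) <- diag(Sg) + 1e-8 + 1e-4 * diag(Sg)
    L <- t(chol(Sg))
    Z <- matrix(rnorm(mc_size * Pa), mc_size, Pa)
    w <- rchisq(mc_size, nu) / nu
    E <- sweep(Z %*% t(L) / sqrt(w), 2, ctr, `+`)
    d2 <- colSums(forwardsolve(L, t(E) - ctr)^2)
    logq <- lcq - sum(log(diag(L))) -
      (nu + Pa) / 2 * log1p(d2 / nu)
    logprior <- rowSums(sapply(seq_len(Pa), function(k)
      dnorm(E[, k], 0, omega[act[k]], log = TRUE)))
    phi <- matrix(fit$m[i, ], mc_size, P, byrow = TRUE)
    phi[, act] <- phi[, act] + E
    psi <- matrix(rep(c(0, 0, 0, 0, 0, 0, 0, 1), each = mc_size),
                  mc_size, 8)
    for (k in seq_len(P))
      psi[, slot1[k]] <- if (trans[k] == 1L) plogis(phi[, k])
                         else exp(phi[, k])
    lld <- cpp_ll_draws(psi, dat, flags, i, fit$error, fit$errtype)
    logw <- lld + logprior - logq
    mx <- max(logw)
    wt <- exp(logw - mx)
    mu <- mean(wt)
    ll_i[i] <- mx + log(mu)
    se2_i[i] <- var(wt) / (mc_size * mu^2)
  }
  list(minus2ll = -2 * sum(ll_i), se = 2 * sqrt(sum(se2_i)),
       subject_ll = ll_i)
}

#' Corrected Bayesian information criterion
#'
#' Hybrid-penalty BIC for nonlinear mixed-effects model comparison: fixed
#' effects and covariate coefficients are penalized by `log(N subjects)`;
#' the between-subject variability and residual-error parameters (and the
#' fixed effects of parameters without a random effect) by
#' `log(total observations)`. A candidate model is preferred when its BICc
#' is lower by at least 3.84 (the 5% chi-square point with 1 df).
#'
#' @param minus2ll Deviance (`-2 log L`).
#' @param model A [population_model()].
#' @param dataset The fitted [pk_dataset()] (for the sample sizes).
#' @return The BICc value.
#' @export
compute_bicc <- function(minus2ll, model, dataset) {
  ns <- nrow(dataset$subjects)
  nobs <- nrow(dataset$observations)
  varying <- sum(model$omega > 0)
  fixed0 <- sum(model$omega == 0)
  nbeta <- length(model$betas)
  minus2ll + log(ns) * (varying + nbeta) +
    log(nobs) * (fixed0 + varying + n_error_pars(model))
}

# g^2 (residual variance) per observation row given predictions f.
resid_var <- function(f, type_row, errpar, errtype) {
  a <- ifelse(type_row == 0L, errpar[1], errpar[3])
  b <- ifelse(type_row == 0L, errpar[2], errpar[4])
  et <- errtype[type_row + 1L]
  s2 <- numeric(length(f))
  s2[et == 0] <- a[et == 0]^2
  s2[et == 1] <- (b[et == 1] * f[et == 1])^2
  s2[et == 2] <- a[et == 2]^2 + (b[et == 2] * f[et == 2])^2
  s2[et == 3] <- b[et == 3]^2
  pmax(s2, 1e-12)
}

#' Standard errors, relative standard errors and condition number
#'
#' Fisher information by first-order linearization of the model around the
#' empirical-Bayes conditional modes: the fixed-effect block is
#' `sum_i F_i' V_i^{-1} F_i` with `V_i` the linearized marginal covariance,
#' and the variance-parameter block uses the standard
#' `0.5 tr(V^{-1} dV V^{-1} dV)` form. The condition number `kappa` is the
#' ratio of the extreme eigenvalues of the correlation matrix of the
#' estimates; `kappa > 100` flags over-parameterization.
#'
#' @param fit A [saem_fit()].
#' @param h Finite-difference step on the transformed parameter scale.
#' @return List with `se` and `rse` (named, per reported parameter),
#'   `kappa`, `wald` (a data.frame of covariate-coefficient Wald tests) and
#'   the two covariance blocks.
#' @export
fisher_information <- function(fit, h = 1e-4) {
  dat <- fit$dat
  model <- fit$model
  pn <- names(model$theta)
  P <- length(pn)
  omega <- unname(fit$omega)
  flags <- spec_flags(model$spec)
  phi <- fit$m + fit$eta_mode
  f0 <- cpp_pred(psi_matrix(phi, model), dat, flags)
  dF <- matrix(0, length(f0), P)
  for (l in seq_len(P)) {
    up <- phi; up[, l] <- up[, l] + h
    dn <- phi; dn[, l] <- dn[, l] - h
    dF[, l] <- (cpp_pred(psi_matrix(up, model), dat, flags) -
                  cpp_pred(psi_matrix(dn, model), dat, flags)) / (2 * h)
  }
  et_row <- fit$errtype[dat$obs_type + 1L]
  lg <- et_row == 3L
  if (any(lg)) { # exponential stream: linearize on the log scale
    dF[lg, ] <- dF[lg, ] / pmax(f0[lg], 1e-12)
    f0[lg] <- log(pmax(f0[lg], 1e-12))
  }
  g2 <- resid_var(ifelse(lg, exp(f0), f0), dat$obs_type, fit$error,
                  fit$errtype)

  nbeta <- length(model$betas)
  fix_names <- paste0("theta_", pn)
  bmap <- integer(0)
  for (j in seq_along(model$betas)) {
    fix_names <- c(fix_names,
                   paste0("beta[", relation_label(model$betas[[j]]), "]"))
    bmap <- c(bmap, match(model$betas[[j]]$target, pn))
  }
  nfix <- P + nbeta
  # per-observation fixed-effect design: column for mu_l is dF_l, for a
  # beta it is dF_target * covariate term
  Xb <- matrix(0, length(f0), nbeta)
  if (nbeta > 0) {
    for (j in seq_along(model$betas)) {
      Xl <- fit$design[[pn[bmap[j]]]]
      # find the column of this beta within its parameter's design
      pos <- 1L
      for (jj in seq_len(j)) if (bmap[jj] == bmap[j]) pos <- pos + 1L
      xcov <- Xl[, pos]
      Xb[, j] <- dF[, bmap[j]] * xcov[dat$obs_subj + 1L]
    }
  }
  err_idx <- c(if (fit$errtype[1] %in% c(0L, 2L)) 1L,
               if (fit$errtype[1] != 0L) 2L,
               if (fit$errtype[2] %in% c(0L, 2L)) 3L,
               if (fit$errtype[2] != 0L) 4L)
  err_names <- c("a1", "b1", "a2", "b2")[err_idx]
  nvar <- P + length(err_idx)
  Gfix <- matrix(0, nfix, nfix)
  Gvar <- matrix(0, nvar, nvar)
  ok <- TRUE
  for (i in seq_len(dat$ns)) {
    j <- (dat$obs_off[i] + 1L):dat$obs_off[i + 1L]
    if (dat$obs_off[i + 1L] <= dat$obs_off[i]) next
    Fi <- dF[j, , drop = FALSE]
    Vi <- Fi %*% (omega^2 * t(Fi))
    diag(Vi) <- diag(Vi) + g2[j]
    Vinv <- tryCatch(solve(Vi), error = function(e) NULL)
    if (is.null(Vinv)) { ok <- FALSE; next }
    Fth <- cbind(Fi, Xb[j, , drop = FALSE])
    Gfix <- Gfix + crossprod(Fth, Vinv %*% Fth)
    D <- vector("list", nvar)
    for (l in seq_len(P))
      D[[l]] <- (2 * omega[l]) * tcrossprod(Fi[, l])
    ot <- dat$obs_type[j]
    fj <- f0[j]
    for (kk in seq_along(err_idx)) {
      e <- err_idx[kk]
      dv <- numeric(length(j))
      if (e == 1L) dv[ot == 0L] <- 2 * fit$error[1]
      if (e == 2L) {
        if (fit$errtype[1] == 3L) dv[ot == 0L] <- 2 * fit$error[2]
        else dv[ot == 0L] <- 2 * fit$error[2] * fj[ot == 0L]^2
      }
      if (e == 3L) dv[ot == 1L] <- 2 * fit$error[3]
      if (e == 4L) {
        if (fit$errtype[2] == 3L) dv[ot == 1L] <- 2 * fit$error[4]
        else dv[ot == 1L] <- 2 * fit$error[4] * fj[ot == 1L]^2
      }
      D[[P + kk]] <- diag(dv, nrow = length(j))
    }
    VD <- lapply(D, function(d) Vinv %*% d)
    for (a in seq_len(nvar)) for (b in a:nvar) {
      tr <- sum(VD[[a]] * t(VD[[b]]))
      Gvar[a, b] <- Gvar[a, b] + 0.5 * tr
      Gvar[b, a] <- Gvar[a, b]
    }
  }
  inv_or_null <- function(M) tryCatch(solve(M), error = function(e) NULL)
  Vfix <- inv_or_null(Gfix)
  Vvar <- inv_or_null(Gvar)
  if (!ok || is.null(Vfix) || is.null(Vvar) ||
      any(!is.finite(diag(Vfix))) || any(!is.finite(diag(Vvar)))) {
    return(list(kappa = Inf, failed = "non-invertible information",
                se = NULL, rse = NULL))
  }
  se_fix <- sqrt(pmax(diag(Vfix), 0))
  se_var <- sqrt(pmax(diag(Vvar), 0))
  names(se_fix) <- fix_names
  names(se_var) <- c(paste0("omega_", pn), err_names)

  # relative standard errors on the reported (natural) scale
  tr <- param_transforms(model)
  theta <- model$theta
  rse_theta <- 100 * se_fix[seq_len(P)] *
    ifelse(tr == 1L, 1 - theta, 1)
  names(rse_theta) <- pn
  bvals <- vapply(model$betas, `[[`, 0, "value")
  rse_beta <- if (nbeta) 100 * se_fix[P + seq_len(nbeta)] / abs(bvals)
              else numeric(0)
  if (nbeta)
    names(rse_beta) <- fix_names[P + seq_len(nbeta)]
  rse_omega <- 100 * se_var[seq_len(P)] / omega
  names(rse_omega) <- paste0("omega_", pn)
  errv <- fit$error[err_idx]
  rse_err <- 100 * se_var[P + seq_along(err_idx)] / errv
  names(rse_err) <- err_names
  rse <- c(rse_theta, rse_beta, rse_omega, rse_err)

  # condition number from the correlation matrix of all estimates
  Vall <- matrix(0, nfix + nvar, nfix + nvar)
  Vall[seq_len(nfix), seq_len(nfix)] <- Vfix
  Vall[nfix + seq_len(nvar), nfix + seq_len(nvar)] <- Vvar
  Cm <- tryCatch(stats::cov2cor(Vall), warning = function(w) NULL,
                 error = function(e) NULL)
  kappa <- if (is.null(Cm) || any(!is.finite(Cm))) Inf else {
    ev <- eigen(Cm, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) <= 0) Inf else max(ev) / min(ev)
  }
  wald <- NULL
  if (nbeta) {
    se_b <- se_fix[P + seq_len(nbeta)]
    wald <- data.frame(
      relation = vapply(model$betas, relation_label, ""),
      estimate = bvals, se = unname(se_b),
      p = vapply(seq_len(nbeta),
                 function(j) wald_test(bvals[j], se_b[j]), 0))
  }
  list(se = c(se_fix, se_var), rse = rse, kappa = kappa, wald = wald,
       vcov_fixed = Vfix, vcov_random = Vvar)
}

#' Conditional-distribution shrinkage
#'
#' `100 * (1 - var(conditional mean eta) / omega^2)` per random effect,
#' the variance taken across subjects of the conditional-mean individual
#' deviations. Near 0 when individual data are rich (the conditional means
#' spread like the population distribution); near 100% when the individual
#' data carry no information and every conditional mean collapses to 0.
#'
#' @param fit A [saem_fit()].
#' @return Named vector of shrinkage percentages (`NA` where `omega = 0`).
#' @export
shrinkage <- function(fit) {
  omega <- fit$omega
  out <- setNames(rep(NA_real_, length(omega)), names(omega))
  for (l in seq_along(omega)) {
    if (omega[l] <= 0) next
    v <- var(fit$eta_mean[, l])
    out[l] <- 100 * (1 - v / omega[l]^2)
  }
  out
}

#' Wald test of a covariate coefficient
#'
#' Two-sided normal test of `beta = 0`.
#'
#' @param beta,se Estimate and standard error (`se > 0`).
#' @return The p-value.
#' @export
wald_test <- function(beta, se) {
  if (!(se > 0)) stop("se must be > 0", call. = FALSE)
  2 * pnorm(-abs(beta / se))
}

#' Shapiro-Wilk normality check
#'
#' Thin wrapper over the standard Shapiro-Wilk test used to check the
#' normality of random effects and residuals.
#'
#' @param values Numeric vector, `n >= 3`.
#' @return List with `statistic` and `p.value`.
#' @export
shapiro_wilk_check <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) < 3)
    stop("need at least 3 values", call. = FALSE)
  if (sd(values) == 0)
    stop("degenerate input: constant values", call. = FALSE)
  sw <- shapiro.test(values)
  list(statistic = unname(sw$statistic), p.value = sw$p.value)
}
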