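#' SAEM estimation settings
#'
#' Iteration schedule and sampler settings for [saem_fit()]. The defaults
#' follow common practice for stochastic approximation EM: an exploratory
#' phase with step size 1 and simulated annealing on the variance and
#' residual-error parameters, followed by a smoothing phase with step size
#' `1/(k - n_explore)`. The conditional sampler runs `n_chains` independent
#' MCMC chains per subject, each advanced by `n_transitions` transitions per
#' SAEM iteration (an independence kernel proposing from the conditional
#' prior, then a componentwise random walk with scales adapted towards
#' `rw_target` acceptance).
#'
#' @param n_explore,n_smooth Iterations in each phase.
#' @param n_chains Number of MCMC chains (5 mirrors the reference analysis).
#' @param n_transitions MCMC transitions per chain per SAEM iteration.
#' @param anneal Annealing factor in (0, 1] bounding the per-iteration
#'   shrinkage of variance/error parameters during exploration.
#' @param rw_init,rw_target Initial relative random-walk scale and target
#'   acceptance rate.
#' @param ll_draws Importance-sampling draws per subject for the marginal
#'   log-likelihood computed at the end of the fit.
#' @param cond_iter,cond_burn Iterations (and burn-in) of the final
#'   conditional sampling pass used for empirical-Bayes summaries.
#' @param compute_ll,compute_fim Toggle the post-fit likelihood and Fisher
#'   information steps.
#' @return A list of class `saem_control`.
#' @export
saem_control <- function(n_explore = 400, n_smooth = 200, n_chains = 5,
                         n_transitions = 2, anneal = 0.95, rw_init = 0.5,
                         rw_target = 0.3, ll_draws = 2000, cond_iter = 120,
                         cond_burn = 20, compute_ll = TRUE,
                         compute_fim = TRUE) {
  structure(list(n_explore = n_explore, n_smooth = n_smooth,
                 n_chains = n_chains, n_transitions = n_transitions,
                 anneal = anneal, rw_init = rw_init, rw_target = rw_target,
                 ll_draws = ll_draws, cond_iter = cond_iter,
                 cond_burn = cond_burn, compute_ll = compute_ll,
                 compute_fim = compute_fim),
            class = "saem_control")
}

# NCA-informed starting values: CL from dose/AUC, V1 from dose/Cmax.
init_from_data <- function(dataset, model) {
  s <- dataset$subjects; o <- dataset$observations; d <- dataset$doses
  cl <- v1 <- numeric(0)
  for (id in s$id) {
    oi <- o[o$id == id & o$kind == "plasma", ]
    di <- d[d$id == id, ]
    if (nrow(oi) < 2 || nrow(di) < 1) next
    dose <- sum(di$amount)
    tt <- c(0, oi$time); cc <- c(0, oi$value)
    auc <- sum(diff(tt) * (head(cc, -1) + tail(cc, -1)) / 2)
    n <- nrow(oi)
    lam <- NA
    if (n >= 3) {
      tl <- tail(oi$time, 3); clg <- tail(oi$value, 3)
      if (all(clg > 0)) lam <- -coef(lm(log(clg) ~ tl))[2]
    }
    if (is.finite(lam) && lam > 0) auc <- auc + tail(oi$value, 1) / lam
    if (auc > 0) cl <- c(cl, dose / auc)
    cmax <- max(oi$value)
    if (cmax > 0) v1 <- c(v1, dose / cmax)
  }
  cl0 <- if (length(cl)) median(cl) else 0.1
  v10 <- if (length(v1)) median(v1) else 10
  pn <- names(model$theta)
  th <- setNames(numeric(length(pn)), pn)
  th["CL"] <- cl0
  th["V1"] <- v10
  if ("Q" %in% pn) th["Q"] <- cl0
  if ("V2" %in% pn) th["V2"] <- v10
  if ("Q2" %in% pn) th["Q2"] <- cl0 / 2
  if ("V3" %in% pn) th["V3"] <- v10
  if ("CLB" %in% pn) th["CLB"] <- cl0 / 2
  if ("purine" %in% pn) th["purine"] <- 0.5
  list(theta = th,
       omega = setNames(rep(0.3, length(pn)), pn),
       error = c(a1 = 1, b1 = 0.3, a2 = 1, b2 = 0.5))
}

# Complete-data M-step for one residual-error stream.
err_update <- function(y, f, et, cur) {
  f <- pmax(f, 1e-10)
  r <- y - f
  if (et == 0L) return(c(sqrt(mean(r^2)), 0))
  if (et == 1L) return(c(0, sqrt(mean((r / f)^2))))
  if (et == 3L) {
    rl <- log(pmax(y, 1e-12)) - log(f)
    return(c(0, sqrt(mean(rl^2))))
  }
  nll <- function(p) {
    s2 <- exp(2 * p[1]) + exp(2 * p[2]) * f^2
    0.5 * sum(log(s2) + r^2 / s2)
  }
  o <- optim(log(pmax(cur, 1e-4)), nll, method = "Nelder-Mead",
             control = list(maxit = 120, reltol = 1e-10))
  exp(o$par)
}

#' Fit a population model by SAEM
#'
#' Maximum-likelihood estimation of the fixed effects, covariate
#' coefficients, between-subject variability and residual-error parameters
#' of a [population_model()] by stochastic approximation EM with MCMC
#' conditional sampling of the individual random effects. Individual
#' parameters are log-normal (logit-normal for the urinary excretion
#' fraction) around the covariate-adjusted population values.
#'
#' After the stochastic phase the fit is completed with a conditional
#' sampling pass (empirical-Bayes means, modes and samples), a linearized
#' Fisher information matrix (standard errors, relative standard errors,
#' condition number), an importance-sampling estimate of `-2 log L`, the
#' corrected BIC, and conditional-distribution shrinkage.
#'
#' @param dataset A [pk_dataset()].
#' @param model A [population_model()]; its parameter values are not used as
#'   starting values unless `init = "model"`.
#' @param control A [saem_control()].
#' @param seed Integer seed making the whole fit reproducible.
#' @param init `"nca"` (heuristic starting values from the data, default),
#'   `"model"` (start at the model's own values, e.g. for warm starts), or a
#'   list with elements `theta`, `omega`, `error`.
#' @return An object of class `saem_fit`.
#' @export
saem_fit <- function(dataset, model, control = saem_control(), seed = NULL,
                     init = c("nca", "model")) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(inherits(model, "population_model"))
  if (nrow(dataset$subjects) < 2)
    stop("need at least 2 subjects", call. = FALSE)
  dat <- prepare_data(dataset)
  panel <- derive_covariates(dataset)

  if (is.character(init)) {
    init <- match.arg(init)
    ini <- if (init == "nca") init_from_data(dataset, model)
           else list(theta = model$theta,
                     omega = pmax(model$omega, 0.05),
                     error = err_par_vector(model))
  } else ini <- init
  work <- model
  work$theta[] <- unlist(ini$theta)[names(work$theta)]
  work$omega[] <- pmax(unlist(ini$omega)[names(work$omega)], 0.05)
  errpar <- as.numeric(ini$error)
  if (any(!is.finite(c(work$theta, errpar))))
    stop("initial values must be finite", call. = FALSE)

  pn <- names(work$theta)
  P <- length(pn)
  ns <- dat$ns
  design <- build_design(work, panel)
  coefs <- model_coefs(work)
  # candidate covariate coefficients start at their provided values
  XtX <- lapply(design, crossprod)
  XtXi <- lapply(XtX, solve)
  omega <- unname(work$omega)
  trans <- param_transforms(work)
  slot0 <- unname(psi_slots[ifelse(pn == "purine", "purine", pn)]) - 1L
  base_psi <- c(0, 0, 0, 0, 0, 0, 0, 1)
  flags <- spec_flags(work$spec)
  errtype <- err_type_vector(work)
  ipl <- dat$obs_type == 0L
  iur <- dat$obs_type == 1L

  nch <- control$n_chains
  etas <- replicate(nch, matrix(0, ns, P), simplify = FALSE)
  rwsd <- rep(control$rw_init, P)
  K1 <- control$n_explore; K2 <- control$n_smooth
  Sx <- lapply(design, function(X) numeric(ncol(X)))
  S2 <- numeric(P)
  trace <- matrix(NA_real_, K1 + K2, P + length(work$betas) + P + 4)
  for (k in seq_len(K1 + K2)) {
    m <- m_matrix(design, coefs)
    st <- cpp_saem_step(etas, m, omega, trans, slot0, base_psi, flags, dat,
                        errpar, errtype, rwsd, control$n_transitions)
    etas <- st$etas
    if (k <= K1) {
      rate <- st$acc_rw / pmax(st$prop_rw, 1)
      rwsd <- pmin(pmax(rwsd * exp(0.4 * (rate - control$rw_target)),
                        0.05), 10)
    }
    gam <- if (k <= K1) 1 else 1 / (k - K1)
    phis <- lapply(etas, function(e) m + e)
    for (l in seq_len(P)) {
      cur <- Reduce(`+`, lapply(phis, function(ph)
        drop(crossprod(design[[l]], ph[, l])))) / nch
      cur2 <- mean(vapply(phis, function(ph) sum(ph[, l]^2), 0))
      Sx[[l]] <- (1 - gam) * Sx[[l]] + gam * cur
      S2[l] <- (1 - gam) * S2[l] + gam * cur2
      cf <- drop(XtXi[[l]] %*% Sx[[l]])
      o2 <- (S2[l] - 2 * sum(cf * Sx[[l]]) +
               drop(crossprod(cf, XtX[[l]] %*% cf))) / ns
      o2 <- max(o2, 1e-6)
      if (k <= K1) o2 <- max(o2, control$anneal * omega[l]^2)
      coefs[[pn[l]]] <- cf
      omega[l] <- sqrt(o2)
    }
    fbar <- st$pred
    if (any(ipl)) {
      ep <- err_update(dat$obs_y[ipl], fbar[ipl, , drop = FALSE],
                       errtype[1], errpar[1:2])
      errpar[1:2] <- if (k <= K1) pmax(ep, control$anneal * errpar[1:2])
                     else errpar[1:2] + gam * (ep - errpar[1:2])
    }
    if (any(iur)) {
      eu <- err_update(dat$obs_y[iur], fbar[iur, , drop = FALSE],
                       errtype[2], errpar[3:4])
      errpar[3:4] <- if (k <= K1) pmax(eu, control$anneal * errpar[3:4])
                     else errpar[3:4] + gam * (eu - errpar[3:4])
    }
    if (any(!is.finite(unlist(coefs))) || any(!is.finite(omega)))
      stop("estimation error: non-finite sufficient statistics at ",
           "iteration ", k, call. = FALSE)
    trace[k, ] <- c(vapply(seq_len(P), function(l) coefs[[pn[l]]][1], 0),
                    unlist(lapply(coefs, function(cf) cf[-1])),
                    omega, errpar)
  }

  final <- set_coefs(work, coefs, omega, errpar)
  m <- m_matrix(design, coefs)

  # conditional sampling pass at the final estimates
  keep <- vector("list", control$cond_iter - control$cond_burn)
  for (k in seq_len(control$cond_iter)) {
    st <- cpp_saem_step(etas, m, omega, trans, slot0, base_psi, flags, dat,
                        errpar, errtype, rwsd, control$n_transitions)
    etas <- st$etas
    if (k > control$cond_burn) keep[[k - control$cond_burn]] <- etas
  }
  nsamp <- length(keep) * nch
  cond <- array(NA_real_, c(ns, P, nsamp))
  idx <- 0L
  for (kk in keep) for (e in kk) {
    idx <- idx + 1L
    cond[, , idx] <- e
  }
  eta_mean <- apply(cond, c(1, 2), mean)

  # conditional modes (empirical-Bayes MAP estimates)
  eta_mode <- eta_mean
  act <- which(omega > 0)
  for (i in seq_len(ns)) {
    obj <- function(e) {
      eta <- numeric(P); eta[act] <- e
      phi <- m[i, ] + eta
      psi <- base_psi
      psi[slot0 + 1L] <- ifelse(trans == 1L, plogis(phi), exp(phi))
      ll <- cpp_ll_subject(psi, dat, flags, i, errpar, errtype)
      -(ll - 0.5 * sum((e / omega[act])^2))
    }
    o <- optim(eta_mean[i, act], obj, method = "Nelder-Mead",
               control = list(maxit = 300, reltol = 1e-9))
    eta_mode[i, act] <- o$par
  }

  fit <- structure(list(
    model = final, theta = final$theta, omega = setNames(omega, pn),
    betas = final$betas, error = errpar, errtype = errtype,
    coefs = coefs, design = design, panel = panel, dataset = dataset,
    dat = dat, m = m, eta_mean = eta_mean, eta_mode = eta_mode,
    cond_samples = cond, trace = trace, rwsd = rwsd,
    control = control, seed = seed,
    n_obs = length(dat$obs_y), n_subjects = ns), class = "saem_fit")

  fit$shrinkage <- shrinkage(fit)
  if (control$compute_fim)
    fit$fim <- tryCatch(fisher_information(fit),
                        error = function(e) list(kappa = Inf,
                                                 failed = conditionMessage(e)))
  if (control$compute_ll) {
    llo <- log_likelihood(fit, mc_size = control$ll_draws)
    fit$minus2ll <- llo$minus2ll
    fit$minus2ll_se <- llo$se
    fit$bicc <- compute_bicc(llo$minus2ll, final, dataset)
  }
  fit
}

#' @export
print.saem_fit <- function(x, ...) {
  cat("<saem_fit> ", x$n_subjects, " subjects, ", x$n_obs,
      " observations\n", sep = "")
  rse <- if (!is.null(x$fim) && is.null(x$fim$failed)) x$fim$rse else NULL
  pn <- names(x$theta)
  est <- c(x$theta,
           setNames(vapply(x$betas, `[[`, 0, "value"),
                    paste0("beta[", vapply(x$betas, relation_label, ""),
                           "]")),
           setNames(x$omega, paste0("omega_", pn)),
           a1 = x$error[1], b1 = x$error[2], a2 = x$error[3],
           b2 = x$error[4])
  est <- est[abs(est) > 0 | !grepl("^(a|b)[12]$", names(est))]
  tab <- data.frame(estimate = signif(est, 4))
  if (!is.null(rse)) {
    r <- rse[names(est)]
    tab$rse_pct <- signif(r, 3)
  }
  sh <- x$shrinkage
  print(tab)
  cat("shrinkage (%): ",
      paste(sprintf("%s=%.1f", names(sh), sh), collapse = ", "), "\n",
      sep = "")
  if (!is.null(x$minus2ll))
    cat("-2LL = ", round(x$minus2ll, 2), " (IS se ",
        round(x$minus2ll_se, 2), "), BICc = ", round(x$bicc, 2), "\n",
        sep = "")
  if (!is.null(x$fim$kappa))
    cat("condition number kappa = ", round(x$fim$kappa, 2), "\n", sep = "")
  invisible(x)
}
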