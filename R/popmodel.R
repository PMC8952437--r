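#' Covariate-parameter relation
#'
#' Describes how a covariate enters a structural parameter on the log scale:
#' `form = "linear"` adds `beta * x` to the log parameter (exponential
#' relation on the natural scale, covariate entered uncentered), and
#' `form = "power"` adds `beta * log(x / ref)` (a power relation normalized
#' at `ref`, e.g. 70 kg for body weight).
#'
#' @param target Structural parameter name (e.g. `"CL"`, `"V1"`).
#' @param covariate Column name of the covariate panel
#'   (see [derive_covariates()]).
#' @param form `"linear"` or `"power"`.
#' @param ref Normalization constant for the power form.
#' @param value Coefficient value (0 for a candidate to be estimated).
#' @return An object of class `covariate_relation`.
#' @export
covariate_relation <- function(target, covariate,
                               form = c("linear", "power"), ref = 70,
                               value = 0) {
  form <- match.arg(form)
  if (form == "power" && !(ref > 0)) stop("ref must be > 0", call. = FALSE)
  structure(list(target = target, covariate = covariate, form = form,
                 ref = ref, value = value),
            class = "covariate_relation")
}

relation_label <- function(b) {
  if (b$form == "power")
    sprintf("%s ~ log(%s/%g)", b$target, b$covariate, b$ref)
  else sprintf("%s ~ %s", b$target, b$covariate)
}

#' Population (nonlinear mixed-effects) model
#'
#' Fixed effects `theta` (natural scale), diagonal between-subject
#' variability `omega` (standard deviations of the random effects on the
#' transformed scale: log for all parameters, logit for the urinary
#' excretion fraction so individual fractions stay inside `[0, 1]`),
#' covariate relations, and residual-error models for the plasma and urine
#' observation streams.
#'
#' Error model types: `"additive"` (`sd = a`), `"proportional"`
#' (`sd = b f`), `"combined"` (`sd = sqrt(a^2 + b^2 f^2)`) and
#' `"exponential"` (additive with sd `b` on the log observation).
#'
#' @param spec A [structural_spec()].
#' @param theta Named vector of fixed effects covering
#'   `structural_param_names(spec)` (use `purine` for the urinary fraction).
#' @param omega Named vector of BSV standard deviations (missing names
#'   default to 0 = no random effect).
#' @param betas List of [covariate_relation()]s.
#' @param error_plasma,error_urine Lists `list(type =, a =, b =)`.
#' @return An object of class `population_model`.
#' @export
population_model <- function(spec, theta, omega = NULL, betas = list(),
                             error_plasma = list(type = "combined",
                                                 a = 0.5, b = 0.2),
                             error_urine = list(type = "proportional",
                                                b = 0.3)) {
  stopifnot(inherits(spec, "structural_spec"))
  if (!is_linear_spec(spec))
    stop("unsupported spec: the mixed-effects machinery covers linear ",
         "specs; saturable variants are simulation-only", call. = FALSE)
  pn <- structural_param_names(spec)
  theta <- unlist(theta)
  if (!all(pn %in% names(theta)))
    stop("theta must name: ", paste(pn, collapse = ", "), call. = FALSE)
  theta <- theta[pn]
  om <- setNames(rep(0, length(pn)), pn)
  if (!is.null(omega)) {
    omega <- unlist(omega)
    bad <- setdiff(names(omega), pn)
    if (length(bad)) stop("omega names not in spec: ",
                          paste(bad, collapse = ", "), call. = FALSE)
    om[names(omega)] <- omega
  }
  if (any(om < 0)) stop("omega must be >= 0", call. = FALSE)
  for (b in betas) {
    stopifnot(inherits(b, "covariate_relation"))
    if (!b$target %in% pn)
      stop("beta targets unknown parameter ", b$target, call. = FALSE)
  }
  chk_err <- function(e) {
    stopifnot(e$type %in% c("additive", "proportional", "combined",
                            "exponential"))
    if (e$type %in% c("additive", "combined") && !(e$a > 0))
      stop("error parameter a must be > 0", call. = FALSE)
    if (e$type != "additive" && !(e$b > 0))
      stop("error parameter b must be > 0", call. = FALSE)
    e
  }
  structure(list(spec = spec, theta = theta, omega = om, betas = betas,
                 error_plasma = chk_err(error_plasma),
                 error_urine = chk_err(error_urine)),
            class = "population_model")
}

#' @export
print.population_model <- function(x, ...) {
  cat("<population_model> ", x$spec$n_compartments, "-compartment",
      if (x$spec$elim_nonurinary == "first_order") " (dual elimination)",
      "\n", sep = "")
  tab <- data.frame(theta = signif(x$theta, 4), omega = signif(x$omega, 3))
  print(tab)
  for (b in x$betas)
    cat("  beta[", relation_label(b), "] = ", signif(b$value, 4), "\n",
        sep = "")
  cat("  error plasma: ", x$error_plasma$type, "; urine: ",
      x$error_urine$type, "\n", sep = "")
  invisible(x)
}

# Transform codes per parameter: 0 log, 1 logit (urinary fraction).
param_transforms <- function(model) {
  pn <- names(model$theta)
  ifelse(pn == "purine", 1L, 0L)
}

phi_of_theta <- function(model) {
  tr <- param_transforms(model)
  out <- log(model$theta)
  out[tr == 1L] <- qlogis(model$theta[tr == 1L])
  out
}

theta_of_phi <- function(mu, model) {
  tr <- param_transforms(model)
  setNames(ifelse(tr == 1L, plogis(mu), exp(mu)), names(model$theta))
}

# Per-parameter fixed-effect design matrices from the covariate panel:
# column 1 is the intercept (mu_l), remaining columns the covariate terms.
build_design <- function(model, panel) {
  pn <- names(model$theta)
  out <- list()
  for (l in pn) {
    X <- matrix(1, nrow(panel), 1)
    cn <- "(mu)"
    for (b in model$betas) {
      if (b$target != l) next
      v <- panel[[b$covariate]]
      if (is.null(v))
        stop("covariate ", b$covariate, " not in panel", call. = FALSE)
      x <- if (b$form == "power") log(v / b$ref) else v
      X <- cbind(X, x)
      cn <- c(cn, relation_label(b))
    }
    colnames(X) <- cn
    out[[l]] <- X
  }
  out
}

# Coefficient vectors (mu_l, beta_l...) aligned with build_design columns.
model_coefs <- function(model) {
  mu <- phi_of_theta(model)
  pn <- names(model$theta)
  out <- list()
  for (l in pn) {
    cf <- mu[[l]]
    for (b in model$betas) if (b$target == l) cf <- c(cf, b$value)
    out[[l]] <- cf
  }
  out
}

# Prior-mean matrix m (subjects x parameters) on the transformed scale.
m_matrix <- function(design, coefs) {
  do.call(cbind, lapply(names(design),
                        function(l) drop(design[[l]] %*% coefs[[l]])))
}

# Write coefficient vectors back into the model object.
set_coefs <- function(model, coefs, omega = NULL, error = NULL) {
  tr <- param_transforms(model)
  pn <- names(model$theta)
  for (i in seq_along(pn)) {
    mu <- coefs[[pn[i]]][1]
    model$theta[i] <- if (tr[i] == 1L) plogis(mu) else exp(mu)
  }
  k <- setNames(rep(1L, length(pn)), pn)
  for (j in seq_along(model$betas)) {
    l <- model$betas[[j]]$target
    k[l] <- k[l] + 1L
    model$betas[[j]]$value <- coefs[[l]][k[l]]
  }
  if (!is.null(omega)) model$omega[] <- omega
  if (!is.null(error)) {
    model$error_plasma[c("a", "b")] <- as.list(error[1:2])
    model$error_urine[c("a", "b")] <- as.list(error[3:4])
  }
  model
}

err_type_code <- function(e) {
  match(e$type, c("additive", "proportional", "combined",
                  "exponential")) - 1L
}

err_par_vector <- function(model) {
  gp <- function(e, nm) if (is.null(e[[nm]])) 0 else e[[nm]]
  c(gp(model$error_plasma, "a"), gp(model$error_plasma, "b"),
    gp(model$error_urine, "a"), gp(model$error_urine, "b"))
}

err_type_vector <- function(model) {
  c(err_type_code(model$error_plasma), err_type_code(model$error_urine))
}

n_error_pars <- function(model) {
  cnt <- function(e) if (e$type == "combined") 2L else 1L
  cnt(model$error_plasma) + cnt(model$error_urine)
}

# Flattened event arrays with CSR offsets, the layout consumed by C++.
prepare_data <- function(dataset) {
  validate_pk_dataset(dataset)
  s <- dataset$subjects
  o <- dataset$observations
  d <- dataset$doses
  idx <- match(o$id, s$id)
  ord <- order(idx, o$time)
  o <- o[ord, ]; idx <- idx[ord]
  didx <- match(d$id, s$id)
  dord <- order(didx, d$time)
  d <- d[dord, ]; didx <- didx[dord]
  ns <- nrow(s)
  off <- function(i, n) c(0L, cumsum(tabulate(i, nbins = n)))
  list(ns = ns,
       obs_subj = as.integer(idx - 1L),
       obs_time = as.numeric(o$time),
       obs_y = as.numeric(o$value),
       obs_type = as.integer(o$kind == "urine"),
       obs_ustart = ifelse(is.na(o$interval_start), 0,
                           as.numeric(o$interval_start)),
       obs_uvol = ifelse(is.na(o$urine_volume), 1,
                         as.numeric(o$urine_volume)),
       dose_subj = as.integer(didx - 1L),
       dose_time = as.numeric(d$time),
       dose_amt = as.numeric(d$amount),
       dose_tinf = as.numeric(d$tinf),
       obs_off = as.integer(off(idx, ns)),
       dose_off = as.integer(off(didx, ns)),
       obs_kind = o$kind,
       obs_id = o$id)
}

# Natural-scale psi matrix (subjects x 8 slots) from transformed phi.
psi_matrix <- function(phi, model) {
  ns <- nrow(phi)
  tr <- param_transforms(model)
  pn <- names(model$theta)
  psi <- matrix(rep(c(0, 0, 0, 0, 0, 0, 0, 1), each = ns), ns, 8)
  for (k in seq_along(pn)) {
    v <- if (tr[k] == 1L) plogis(phi[, k]) else exp(phi[, k])
    psi[, psi_slots[[if (pn[k] == "purine") "purine" else pn[k]]]] <- v
  }
  psi
}
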