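#' Candidate structural model specifications
#'
#' A structural spec selects the compartment count and elimination topology:
#' a urinary route from the central compartment (first order or saturable),
#' an optional non-urinary first-order route from the central compartment
#' (making the urinary excretion fraction `p_urine` an estimated parameter),
#' and an optional route from the first peripheral compartment. The selected
#' model for tranexamic acid in hemorrhagic caesarean delivery is the
#' two-compartment spec with double first-order elimination from the central
#' compartment.
#'
#' @param n_compartments 1, 2 or 3.
#' @param elim_urinary `"first_order"` or `"michaelis_menten"`; elimination
#'   into the urine compartment, always from the central compartment.
#' @param elim_nonurinary `"none"` or `"first_order"`; a second, non-urinary
#'   route from the central compartment.
#' @param elim_peripheral `"none"`, `"first_order"` or `"michaelis_menten"`;
#'   elimination from the first peripheral compartment (requires at least 2
#'   compartments).
#' @return An object of class `structural_spec`.
#' @export
structural_spec <- function(n_compartments = 2,
                            elim_urinary = c("first_order",
                                             "michaelis_menten"),
                            elim_nonurinary = c("none", "first_order"),
                            elim_peripheral = c("none", "first_order",
                                                "michaelis_menten")) {
  elim_urinary <- match.arg(elim_urinary)
  elim_nonurinary <- match.arg(elim_nonurinary)
  elim_peripheral <- match.arg(elim_peripheral)
  stopifnot(n_compartments %in% 1:3)
  if (elim_peripheral != "none" && n_compartments < 2)
    stop("peripheral elimination requires at least 2 compartments",
         call. = FALSE)
  if (elim_urinary == "michaelis_menten" && elim_nonurinary != "none")
    stop("saturable urinary elimination is not combined with a non-urinary ",
         "route", call. = FALSE)
  structure(list(n_compartments = as.integer(n_compartments),
                 elim_urinary = elim_urinary,
                 elim_nonurinary = elim_nonurinary,
                 elim_peripheral = elim_peripheral),
            class = "structural_spec")
}

#' @export
print.structural_spec <- function(x, ...) {
  cat("<structural_spec> ", x$n_compartments, "-compartment, urinary=",
      x$elim_urinary, ", non-urinary=", x$elim_nonurinary,
      ", peripheral=", x$elim_peripheral, "\n", sep = "")
  invisible(x)
}

is_linear_spec <- function(spec) {
  spec$elim_urinary == "first_order" && spec$elim_peripheral != "michaelis_menten"
}

spec_flags <- function(spec) {
  c(spec$n_compartments,
    as.integer(spec$elim_nonurinary == "first_order"),
    as.integer(spec$elim_peripheral != "none"))
}

#' The candidate base-model set
#'
#' The ten combinations of compartment count and elimination topology
#' screened during base-model building.
#'
#' @return A named list of [structural_spec()] objects.
#' @export
candidate_specs <- function() {
  list(
    `1cmt_urinary` = structural_spec(1),
    `1cmt_dual` = structural_spec(1, elim_nonurinary = "first_order"),
    `2cmt_mm` = structural_spec(2, elim_urinary = "michaelis_menten"),
    `2cmt_mm_periph` = structural_spec(2, elim_urinary = "michaelis_menten",
                                       elim_peripheral = "first_order"),
    `2cmt_mm_periph_mm` = structural_spec(
      2, elim_urinary = "michaelis_menten",
      elim_peripheral = "michaelis_menten"),
    `2cmt_urinary` = structural_spec(2),
    `2cmt_periph` = structural_spec(2, elim_peripheral = "first_order"),
    `2cmt_periph_mm` = structural_spec(
      2, elim_peripheral = "michaelis_menten"),
    `2cmt_dual` = structural_spec(2, elim_nonurinary = "first_order"),
    `3cmt_urinary` = structural_spec(3))
}

#' Names of the structural parameters of a spec
#'
#' The estimated parameter set implied by a [structural_spec()], in the
#' package's canonical order (`purine` appears only for dual-elimination
#' specs).
#'
#' @param spec A [structural_spec()].
#' @return Character vector of parameter names.
#' @export
structural_param_names <- function(spec) {
  nm <- if (spec$elim_urinary == "michaelis_menten") c("Vmax", "Km", "V1")
        else c("CL", "V1")
  if (spec$n_compartments >= 2) nm <- c(nm, "Q", "V2")
  if (spec$n_compartments >= 3) nm <- c(nm, "Q2", "V3")
  if (spec$elim_peripheral == "first_order") nm <- c(nm, "CLB")
  if (spec$elim_peripheral == "michaelis_menten") nm <- c(nm, "VmaxB", "KmB")
  if (spec$elim_nonurinary == "first_order") nm <- c(nm, "purine")
  nm
}

#' Structural parameter set
#'
#' Collects the parameters of a structural spec: total central elimination
#' clearance `CL` (L/min) split between urine and a non-urinary route by the
#' fraction `p_urine` (so that the urinary rate constant is
#' `p_urine * CL / V1`), volumes (L), diffusional clearances (L/min), and
#' for saturable routes `Vmax` (mg/min) and `Km` (mg/L).
#'
#' @param CL,V1,Q,V2,Q2,V3,CLB Clearances (L/min) and volumes (L).
#' @param p_urine Urinary excretion fraction in `[0, 1]`; 1 when the only
#'   central elimination is urinary.
#' @param Vmax,Km,VmaxB,KmB Saturable-route parameters.
#' @return A named list of class `structural_params`.
#' @export
structural_params <- function(CL = NULL, V1 = NULL, Q = NULL, V2 = NULL,
                              Q2 = NULL, V3 = NULL, CLB = NULL,
                              p_urine = 1, Vmax = NULL, Km = NULL,
                              VmaxB = NULL, KmB = NULL) {
  p <- list(CL = CL, V1 = V1, Q = Q, V2 = V2, Q2 = Q2, V3 = V3, CLB = CLB,
            p_urine = p_urine, Vmax = Vmax, Km = Km, VmaxB = VmaxB,
            KmB = KmB)
  num <- unlist(p[!vapply(p, is.null, TRUE)])
  if (any(!is.finite(num))) stop("non-finite parameter", call. = FALSE)
  pos <- setdiff(names(num), "p_urine")
  if (any(num[pos] <= 0))
    stop("volumes, clearances and saturable parameters must be > 0",
         call. = FALSE)
  if (p_urine < 0 || p_urine > 1)
    stop("p_urine must lie in [0, 1]", call. = FALSE)
  structure(p, class = "structural_params")
}

# 8-slot natural-scale layout consumed by the C++ evaluator.
psi_slots <- c(CL = 1L, V1 = 2L, Q = 3L, V2 = 4L, Q2 = 5L, V3 = 6L,
               CLB = 7L, purine = 8L)

params_to_psi8 <- function(params) {
  g <- function(nm, default = 0) {
    v <- params[[nm]]
    if (is.null(v)) default else v
  }
  c(g("CL"), g("V1"), g("Q"), g("V2"), g("Q2"), g("V3"), g("CLB"),
    g("p_urine", 1))
}

check_params_spec <- function(spec, params) {
  need <- structural_param_names(spec)
  need[need == "purine"] <- "p_urine"
  for (nm in need)
    if (is.null(params[[nm]]))
      stop("spec requires parameter ", nm, call. = FALSE)
  invisible(TRUE)
}

#' Predict a concentration and urinary-excretion profile
#'
#' Evaluates the plasma concentration `A1(t)/V1` and the cumulative amount
#' excreted in urine for a dosing schedule of zero-order infusions. Linear
#' specs are evaluated in closed form by superposition of the disposition
#' modes; saturable specs are integrated numerically (stiff-safe, `lsoda`).
#' The 1-minute bolus of the caesarean-delivery design is represented as a
#' 1-minute zero-order infusion.
#'
#' @param spec A [structural_spec()].
#' @param params A [structural_params()] (or named list).
#' @param doses data.frame with columns `time`, `amount`, `tinf` (minutes,
#'   mg, minutes).
#' @param times Sorted numeric vector of evaluation times (min).
#' @param method `"auto"` (closed form when linear), `"analytic"` or
#'   `"ode"`.
#' @param rtol,atol Integration tolerances for the ODE path.
#' @return A data.frame with columns `time`, `plasma` (mg/L) and
#'   `urine_cumulative` (mg).
#' @export
predict_profile <- function(spec, params, doses, times,
                            method = c("auto", "analytic", "ode"),
                            rtol = 1e-8, atol = 1e-10) {
  method <- match.arg(method)
  stopifnot(inherits(spec, "structural_spec"))
  check_params_spec(spec, params)
  if (is.unsorted(times)) stop("times must be sorted", call. = FALSE)
  doses <- as.data.frame(doses)
  if (nrow(doses) == 0 || all(doses$amount == 0)) {
    return(data.frame(time = times, plasma = 0,
                      urine_cumulative = 0))
  }
  if (method == "auto") method <- if (is_linear_spec(spec)) "analytic"
                                  else "ode"
  if (method == "analytic") {
    if (!is_linear_spec(spec))
      stop("closed-form evaluation requires a linear spec", call. = FALSE)
    dm <- as.matrix(doses[, c("time", "amount", "tinf")])
    pr <- cpp_profile(params_to_psi8(params), spec_flags(spec), dm,
                      as.numeric(times))
    return(data.frame(time = times, plasma = pr$conc,
                      urine_cumulative = pr$ucum))
  }
  ode_profile(spec, params, doses, times, rtol = rtol, atol = atol)
}

# Numerical integration path (reference oracle for linear specs, required
# for Michaelis-Menten routes).
ode_profile <- function(spec, params, doses, times, rtol = 1e-8,
                        atol = 1e-10) {
  n <- spec$n_compartments
  p <- params
  mm_u <- spec$elim_urinary == "michaelis_menten"
  mm_b <- spec$elim_peripheral == "michaelis_menten"
  fo_b <- spec$elim_peripheral == "first_order"
  rhs <- function(t, y, parms) {
    rate <- sum(doses$amount / doses$tinf *
                  (t >= doses$time & t < doses$time + doses$tinf))
    A1 <- y[1]
    C1 <- A1 / p$V1
    out_u <- if (mm_u) p$Vmax * C1 / (p$Km + C1)
             else p$p_urine * p$CL / p$V1 * A1
    out_nu <- if (mm_u) 0 else (1 - p$p_urine) * p$CL / p$V1 * A1
    d1 <- rate - out_u - out_nu
    dAu <- out_u
    d2 <- d3 <- 0
    if (n >= 2) {
      A2 <- y[2]
      d1 <- d1 - p$Q / p$V1 * A1 + p$Q / p$V2 * A2
      d2 <- p$Q / p$V1 * A1 - p$Q / p$V2 * A2
      if (fo_b) d2 <- d2 - p$CLB / p$V2 * A2
      if (mm_b) {
        C2 <- A2 / p$V2
        d2 <- d2 - p$VmaxB * C2 / (p$KmB + C2)
      }
    }
    if (n >= 3) {
      A3 <- y[3]
      d1 <- d1 - p$Q2 / p$V1 * A1 + p$Q2 / p$V3 * A3
      d3 <- p$Q2 / p$V1 * A1 - p$Q2 / p$V3 * A3
    }
    list(c(d1, if (n >= 2) d2, if (n >= 3) d3, dAu))
  }
  y0 <- c(rep(0, n), 0)
  tgrid <- sort(unique(c(0, times, doses$time, doses$time + doses$tinf)))
  ev <- sort(unique(c(doses$time, doses$time + doses$tinf)))
  sol <- deSolve::lsoda(y0, tgrid, rhs, parms = NULL, rtol = rtol,
                        atol = atol,
                        events = list(times = ev[ev > min(tgrid)]))
  if (attr(sol, "istate")[1] < 0)
    stop("integration error: solver failed; try looser tolerances",
         call. = FALSE)
  idx <- match(times, sol[, 1])
  data.frame(time = times, plasma = sol[idx, 2] / p$V1,
             urine_cumulative = sol[idx, n + 2])
}

# Disposition matrix of a linear spec (amount units, rates in 1/min).
disposition_matrix <- function(spec, params) {
  if (!is_linear_spec(spec))
    stop("unsupported spec: disposition matrix requires a linear spec",
         call. = FALSE)
  p <- params
  n <- spec$n_compartments
  k10 <- p$CL / p$V1
  A <- matrix(0, n, n)
  A[1, 1] <- -k10
  if (n >= 2) {
    k12 <- p$Q / p$V1; k21 <- p$Q / p$V2
    k20 <- if (spec$elim_peripheral == "first_order") p$CLB / p$V2 else 0
    A[1, 1] <- A[1, 1] - k12
    A[1, 2] <- k21
    A[2, 1] <- k12
    A[2, 2] <- -(k21 + k20)
  }
  if (n >= 3) {
    k13 <- p$Q2 / p$V1; k31 <- p$Q2 / p$V3
    A[1, 1] <- A[1, 1] - k13
    A[1, 3] <- k31
    A[3, 1] <- k13
    A[3, 3] <- -k31
  }
  A
}

#' Terminal half-life of a linear disposition system
#'
#' `ln(2) / lambda_z` where `lambda_z` is the slowest eigenvalue rate of
#' the disposition matrix among the modes that actually contribute to the
#' plasma response (modes whose bolus-response AUC share is below 1e-6 are
#' ignored, so that e.g. a vanishing diffusional clearance degenerates
#' cleanly to the one-compartment value).
#'
#' @inheritParams predict_profile
#' @return Half-life in minutes.
#' @export
terminal_half_life <- function(spec, params) {
  check_params_spec(spec, params)
  A <- disposition_matrix(spec, params)
  eg <- eigen(A)
  lam <- Re(eg$values)
  e1 <- c(1, rep(0, nrow(A) - 1))
  w <- Re(eg$vectors[1, ] * solve(eg$vectors, e1)) # modal bolus amplitudes
  auc <- -w / lam
  keep <- auc / sum(auc) > 1e-6
  lz <- min(abs(lam[keep]))
  log(2) / lz
}

#' Typical parameter values under a covariate model
#'
#' Applies the final covariate relations to reference covariate values:
#' `psi = theta * exp(beta * x)` for a linear-on-log relation and
#' `psi = theta * (x / ref)^beta` for a power relation.
#'
#' @param theta Named vector or list of fixed effects.
#' @param betas List of [covariate_relation()] objects (with `value` set).
#' @param covariates Named vector of reference covariate values; required
#'   for every relation.
#' @return A named numeric vector of typical parameter values.
#' @export
typical_value <- function(theta, betas = list(), covariates = numeric()) {
  out <- unlist(theta)
  for (b in betas) {
    if (!b$covariate %in% names(covariates))
      stop("configuration error: missing reference covariate ",
           b$covariate, call. = FALSE)
    x <- covariates[[b$covariate]]
    fac <- if (b$form == "power") (x / b$ref)^b$value else exp(b$value * x)
    out[b$target] <- out[b$target] * fac
  }
  out
}
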