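#' Derive the candidate covariate panel from raw anthropometrics
#'
#' Computes, for each subject, the body-size and renal-function measures
#' screened during covariate model building: BMI, ideal weight (IW, Devine,
#' female), adjusted body weight (ABW, correction factor 0.4), lean body
#' weight (LBW, Janmahasatian, female), body surface area (BSA, Du Bois),
#' Cockcroft-Gault estimated creatinine clearance (female), and CKD-EPI 2009
#' and MDRD-4 estimated glomerular filtration rates (female, de-indexed from
#' mL/min/1.73 m2 to absolute mL/min via BSA/1.73). Weight-dependent
#' measures are computed twice: with the pre-pregnancy weight (`_bef`
#' suffix) and with the weight at caesarean.
#'
#' All subjects are parturients, so female-specific constants are used
#' throughout. Serum creatinine is stored in mg/L and converted to mg/dL
#' inside the renal formulas.
#'
#' @param subjects A `pk_dataset` or its `subjects` data.frame.
#' @return A data.frame, one row per subject, with the raw fields (`age`,
#'   `height`, `bw_before`, `bw`) and the derived panel. Subjects with a
#'   missing weight or creatinine get `covariate_missing = TRUE` and `NA`
#'   derived values; they are retained for base-model fitting but excluded
#'   from covariate modelling.
#' @export
derive_covariates <- function(subjects) {
  if (inherits(subjects, "pk_dataset")) subjects <- subjects$subjects
  s <- as.data.frame(subjects)
  stopifnot(all(c("id", "age", "height", "bw_before", "bw", "scr")
                %in% names(s)))
  ok <- stats::complete.cases(s[, c("age", "height", "bw_before", "bw",
                                    "scr")])
  if (any(s$age[ok] <= 0) || any(s$height[ok] <= 0) ||
      any(s$bw[ok] <= 0) || any(s$bw_before[ok] <= 0) ||
      any(s$scr[ok] <= 0))
    stop("anthropometric fields must be positive", call. = FALSE)
  h <- s$height
  iw <- ideal_weight(h)
  panel <- data.frame(
    id = s$id, age = s$age, height = h,
    bw_before = s$bw_before, bw = s$bw, scr = s$scr,
    bmi_bef = body_mass_index(s$bw_before, h),
    bmi = body_mass_index(s$bw, h),
    iw = iw,
    abw_bef = iw + 0.4 * (s$bw_before - iw),
    abw = iw + 0.4 * (s$bw - iw),
    lbw_bef = lean_body_weight(s$bw_before, h),
    lbw = lean_body_weight(s$bw, h),
    bsa_bef = body_surface_area(s$bw_before, h),
    bsa = body_surface_area(s$bw, h),
    eclcr_cg_bef = eclcr_cockcroft_gault(s$age, s$bw_before, s$scr),
    eclcr_cg = eclcr_cockcroft_gault(s$age, s$bw, s$scr),
    stringsAsFactors = FALSE)
  panel$egfr_ckdepi_bef <- egfr_ckdepi(s$age, s$scr) * panel$bsa_bef / 1.73
  panel$egfr_ckdepi <- egfr_ckdepi(s$age, s$scr) * panel$bsa / 1.73
  panel$egfr_mdrd_bef <- egfr_mdrd(s$age, s$scr) * panel$bsa_bef / 1.73
  panel$egfr_mdrd <- egfr_mdrd(s$age, s$scr) * panel$bsa / 1.73
  panel$covariate_missing <- !ok
  rownames(panel) <- NULL
  panel
}

#' Body-size and renal-function formulas (female)
#'
#' Building blocks of [derive_covariates()], exposed for direct use.
#' `eclcr_cockcroft_gault()` takes serum creatinine in mg/L (the storage
#' convention) and converts internally to mg/dL; `egfr_ckdepi()` and
#' `egfr_mdrd()` return indexed values in mL/min/1.73 m2.
#'
#' @param age Years.
#' @param weight kg.
#' @param height cm.
#' @param scr Serum creatinine, mg/L.
#' @return Numeric vector.
#' @name anthropometrics
NULL

#' @rdname anthropometrics
#' @export
body_mass_index <- function(weight, height) weight / (height / 100)^2

#' @rdname anthropometrics
#' @export
ideal_weight <- function(height) 45.5 + 2.3 * (height / 2.54 - 60)

#' @rdname anthropometrics
#' @export
lean_body_weight <- function(weight, height) {
  9270 * weight / (8780 + 244 * body_mass_index(weight, height))
}

#' @rdname anthropometrics
#' @export
body_surface_area <- function(weight, height) {
  0.007184 * weight^0.425 * height^0.725
}

#' @rdname anthropometrics
#' @export
eclcr_cockcroft_gault <- function(age, weight, scr) {
  0.85 * (140 - age) * weight / (72 * scr / 10)
}

#' @rdname anthropometrics
#' @export
egfr_ckdepi <- function(age, scr) {
  s <- scr / 10 / 0.7
  141 * pmin(s, 1)^-0.329 * pmax(s, 1)^-1.209 * 0.993^age * 1.018
}

#' @rdname anthropometrics
#' @export
egfr_mdrd <- function(age, scr) {
  175 * (scr / 10)^-1.154 * age^-0.203 * 0.742
}
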