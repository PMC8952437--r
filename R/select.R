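#' Screen covariates against empirical-Bayes random effects
#'
#' Regresses the conditional-mean random effect of each target parameter on
#' every candidate covariate (raw form and log form) and ranks the
#' covariate-parameter pairs by p-value. A screening step only: retention
#' decisions are made by [forward_select()].
#'
#' @param fit A [saem_fit()].
#' @param targets Structural parameters to screen (default `CL`, `V1`, `Q`
#'   where present).
#' @param covariates Panel columns to test; defaults to the full derived
#'   panel of [derive_covariates()].
#' @return data.frame with `target`, `covariate`, `form`, `r2`, `p`,
#'   ranked by `p`.
#' @export
screen_covariates <- function(fit, targets = NULL, covariates = NULL) {
  stopifnot(inherits(fit, "saem_fit"))
  pn <- names(fit$theta)
  if (is.null(targets)) targets <- intersect(c("CL", "V1", "Q"), pn)
  panel <- fit$panel
  keep <- !panel$covariate_missing
  if (is.null(covariates))
    covariates <- setdiff(names(panel)[vapply(panel, is.numeric, TRUE)],
                          c("scr"))
  eta <- fit$eta_mean
  out <- list()
  for (l in targets) {
    li <- match(l, pn)
    y <- eta[keep, li]
    for (cv in covariates) {
      x <- panel[[cv]][keep]
      if (sd(x) == 0) next
      for (form in c("linear", "power")) {
        xx <- if (form == "power") log(x) else x
        fm <- summary(lm(y ~ xx))
        out[[length(out) + 1L]] <- data.frame(
          target = l, covariate = cv, form = form,
          r2 = fm$r.squared,
          p = fm$coefficients[2, 4], stringsAsFactors = FALSE)
      }
    }
  }
  res <- do.call(rbind, out)
  res[order(res$p), ]
}

#' Retention thresholds for covariate forward selection
#'
#' @param delta_bicc Minimum BICc drop to accept a candidate (3.84, the 5%
#'   chi-square point with 1 df).
#' @param kappa_max Maximum condition number (collinearity guard).
#' @param alpha Wald significance level for the candidate coefficient.
#' @return A list of thresholds.
#' @export
selection_rules <- function(delta_bicc = 3.84, kappa_max = 100,
                            alpha = 0.05) {
  list(delta_bicc = delta_bicc, kappa_max = kappa_max, alpha = alpha)
}

#' Forward selection of covariate relations
#'
#' One-at-a-time forward inclusion: each remaining candidate is added to
#' the current model and refitted; the best candidate of the round is
#' retained when it lowers the BICc by at least `delta_bicc` while keeping
#' the condition number below `kappa_max` and a Wald-significant
#' coefficient. Ties are broken by lower BICc, then lower condition number,
#' then label. Selection stops when no candidate qualifies. Candidate fits
#' that error are recorded as non-evaluable and selection continues.
#'
#' Subjects with missing covariates are excluded from the selection dataset
#' (they remain usable for base-model fitting).
#'
#' @param dataset A [pk_dataset()].
#' @param base_fit The fitted base model ([saem_fit()]); candidate fits are
#'   warm-started from its estimates.
#' @param candidates List of [covariate_relation()]s.
#' @param rules A [selection_rules()].
#' @param control [saem_control()] for the candidate refits (a shortened
#'   schedule is typical since fits are warm-started).
#' @param seed Integer; one deterministic sub-seed per candidate fit is
#'   derived from it.
#' @return List of class `forward_selection` with `ledger` (one row per
#'   candidate per round), `model` (final [population_model()]) and `fit`.
#' @export
forward_select <- function(dataset, base_fit, candidates,
                           rules = selection_rules(),
                           control = saem_control(n_explore = 150,
                                                  n_smooth = 75,
                                                  n_chains = 2,
                                                  ll_draws = 1000),
                           seed = 1) {
  stopifnot(inherits(base_fit, "saem_fit"))
  keep <- !base_fit$panel$covariate_missing
  if (!all(keep)) {
    ids <- base_fit$panel$id[keep]
    dataset <- subset_dataset(dataset, ids)
  }
  cur_fit <- base_fit
  cur_model <- base_fit$model
  cur_bicc <- base_fit$bicc
  ledger <- list()
  step <- 0L
  remaining <- candidates
  fid <- 0L
  repeat {
    step <- step + 1L
    evals <- vector("list", length(remaining))
    for (ci in seq_along(remaining)) {
      cand <- remaining[[ci]]
      fid <- fid + 1L
      cand_model <- cur_model
      cand_model$betas <- c(cand_model$betas, list(cand))
      res <- tryCatch({
        f <- saem_fit(dataset, cand_model, control = control,
                      seed = seed * 1000L + fid,
                      init = list(theta = cur_model$theta,
                                  omega = pmax(cur_fit$omega, 0.05),
                                  error = cur_fit$error))
        nb <- length(f$model$betas)
        wp <- if (!is.null(f$fim$wald)) f$fim$wald$p[nb] else NA_real_
        list(fit = f, bicc = f$bicc, m2ll = f$minus2ll,
             kappa = f$fim$kappa, wald_p = wp, error = NA_character_)
      }, error = function(e)
        list(fit = NULL, bicc = NA_real_, m2ll = NA_real_,
             kappa = NA_real_, wald_p = NA_real_,
             error = conditionMessage(e)))
      evals[[ci]] <- res
      ledger[[length(ledger) + 1L]] <- data.frame(
        step = step, candidate = relation_label(cand),
        minus2ll = res$m2ll, bicc = res$bicc, kappa = res$kappa,
        wald_p = res$wald_p, accepted = FALSE,
        reason = if (!is.na(res$error)) "fit failed" else "",
        stringsAsFactors = FALSE)
    }
    qual <- vapply(evals, function(r)
      !is.null(r$fit) && is.finite(r$bicc) &&
        r$bicc <= cur_bicc - rules$delta_bicc &&
        is.finite(r$kappa) && r$kappa < rules$kappa_max &&
        is.finite(r$wald_p) && r$wald_p <= rules$alpha, TRUE)
    # annotate rejection reasons for this round
    base_row <- length(ledger) - length(remaining)
    for (ci in seq_along(remaining)) {
      r <- evals[[ci]]
      if (qual[ci] || !is.na(ledger[[base_row + ci]]$reason) &&
          nzchar(ledger[[base_row + ci]]$reason)) next
      why <- c(
        if (!is.na(r$bicc) && r$bicc > cur_bicc - rules$delta_bicc)
          "dBICc < threshold",
        if (is.finite(r$kappa) && r$kappa >= rules$kappa_max)
          "over-parameterized (kappa)",
        if (is.finite(r$wald_p) && r$wald_p > rules$alpha)
          "Wald n.s.")
      ledger[[base_row + ci]]$reason <- paste(why, collapse = "; ")
    }
    if (!any(qual)) break
    bic <- vapply(evals, function(r) ifelse(is.finite(r$bicc), r$bicc,
                                            Inf), 0)
    kap <- vapply(evals, function(r) ifelse(is.finite(r$kappa), r$kappa,
                                            Inf), 0)
    lab <- vapply(remaining, relation_label, "")
    ord <- order(!qual, bic, kap, lab)
    best <- ord[1]
    ledger[[base_row + best]]$accepted <- TRUE
    ledger[[base_row + best]]$reason <- "accepted"
    cur_fit <- evals[[best]]$fit
    cur_model <- cur_fit$model
    cur_bicc <- evals[[best]]$bicc
    remaining <- remaining[-best]
    if (!length(remaining)) break
  }
  structure(list(ledger = do.call(rbind, ledger), model = cur_model,
                 fit = cur_fit, base_bicc = base_fit$bicc),
            class = "forward_selection")
}

#' @export
print.forward_selection <- function(x, ...) {
  cat("<forward_selection> base BICc = ", round(x$base_bicc, 2), "\n",
      sep = "")
  led <- x$ledger
  led$minus2ll <- round(led$minus2ll, 2)
  led$bicc <- round(led$bicc, 2)
  led$kappa <- round(led$kappa, 1)
  led$wald_p <- signif(led$wald_p, 3)
  print(led, row.names = FALSE)
  acc <- vapply(x$model$betas, relation_label, "")
  cat("retained: ", if (length(acc)) paste(acc, collapse = ", ")
      else "(none)", "\n", sep = "")
  invisible(x)
}

# Restrict a dataset to a subset of subjects.
subset_dataset <- function(dataset, ids) {
  pk_dataset(dataset$subjects[dataset$subjects$id %in% ids, ],
             dataset$doses[dataset$doses$id %in% ids, ],
             dataset$observations[dataset$observations$id %in% ids, ])
}
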