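# Simulate replicate observation vectors on the observed design (same
# subjects, doses, sampling times, covariates). Returns an n_obs x n_sim
# matrix of simulated measurements.
simulate_observations <- function(dataset, model, n_sim, seed = NULL,
                                  residual = TRUE) {
  if (!is.null(seed)) set.seed(seed)
  dat <- prepare_data(dataset)
  panel <- derive_covariates(dataset)
  design <- build_design(model, panel)
  m <- m_matrix(design, model_coefs(model))
  omega <- unname(model$omega)
  ns <- dat$ns
  P <- length(model$theta)
  flags <- spec_flags(model$spec)
  ipl <- dat$obs_type == 0L
  out <- matrix(NA_real_, length(dat$obs_y), n_sim)
  for (s in seq_len(n_sim)) {
    eta <- matrix(0, ns, P)
    for (l in seq_len(P))
      if (omega[l] > 0) eta[, l] <- rnorm(ns, 0, omega[l])
    f <- cpp_pred(psi_matrix(m + eta, model), dat, flags)
    y <- f
    if (residual) {
      addn <- function(f, e) {
        n <- length(f)
        switch(e$type,
               additive = f + rnorm(n, 0, e$a),
               proportional = f * (1 + rnorm(n, 0, e$b)),
               combined = f + sqrt(e$a^2 + e$b^2 * f^2) * rnorm(n),
               exponential = f * exp(rnorm(n, 0, e$b)))
      }
      y[ipl] <- addn(f[ipl], model$error_plasma)
      y[!ipl] <- addn(f[!ipl], model$error_urine)
    }
    out[, s] <- y
  }
  out
}

#' Visual predictive check
#'
#' Simulates `n_sim` replicate trials on the observed design and compares
#' the observed 10th/50th/90th concentration percentiles per time bin with
#' the simulation-based prediction interval of each percentile. Time bins
#' default to the nominal sampling times when every observation lies within
#' the design's sampling window of a nominal time; otherwise quantile bins
#' are used.
#'
#' @param dataset A [pk_dataset()].
#' @param model A fully specified [population_model()] (or the `model` of a
#'   fit).
#' @param n_sim Number of simulated replicates (at least 100 advised).
#' @param seed Seed.
#' @param kind Observation stream to check.
#' @param probs Percentiles summarized.
#' @param ci Level of the per-percentile prediction band.
#' @param bins Optional explicit bin centers.
#' @param window Half-width (min) of the nominal-time window.
#' @return An object of class `pk_vpc`: data.frames `observed` and `bands`.
#' @export
vpc <- function(dataset, model, n_sim = 500, seed = 1, kind = "plasma",
                probs = c(0.1, 0.5, 0.9), ci = 0.95, bins = NULL,
                window = 10) {
  if (n_sim < 100)
    warning("n_sim < 100 gives unstable prediction bands")
  if (inherits(model, "saem_fit")) model <- model$model
  o <- dataset$observations
  sel <- o$kind == kind
  times <- o$time[sel]
  if (is.null(bins)) {
    nom <- sort(unique(c(15, 30, 60, 120, 180, 360)))
    nearest <- nom[pmax(1, apply(abs(outer(times, nom, `-`)), 1,
                                 which.min))]
    if (all(abs(times - nearest) <= window)) bins <- nom
    else bins <- unique(quantile(times, probs = seq(0, 1, length.out = 7)))
  }
  centers <- bins
  bin_of <- apply(abs(outer(times, centers, `-`)), 1, which.min)
  sims <- simulate_observations(dataset, model, n_sim, seed)[sel, ,
                                                             drop = FALSE]
  obs_q <- t(sapply(seq_along(centers), function(b)
    quantile(o$value[sel][bin_of == b], probs, na.rm = TRUE)))
  sim_q <- array(NA_real_, c(length(centers), length(probs), n_sim))
  for (s in seq_len(n_sim))
    sim_q[, , s] <- t(sapply(seq_along(centers), function(b)
      quantile(sims[bin_of == b, s], probs, na.rm = TRUE)))
  alpha <- (1 - ci) / 2
  bands <- do.call(rbind, lapply(seq_along(probs), function(p)
    data.frame(bin = centers, percentile = 100 * probs[p],
               lo = apply(sim_q[, p, , drop = FALSE], 1, quantile, alpha),
               mid = apply(sim_q[, p, , drop = FALSE], 1, median),
               hi = apply(sim_q[, p, , drop = FALSE], 1, quantile,
                          1 - alpha))))
  observed <- data.frame(bin = centers, n = tabulate(bin_of,
                                                     length(centers)))
  observed <- cbind(observed, as.data.frame(obs_q))
  names(observed)[-(1:2)] <- paste0("p", 100 * probs)
  structure(list(observed = observed, bands = bands, n_sim = n_sim,
                 kind = kind), class = "pk_vpc")
}

#' @export
print.pk_vpc <- function(x, ...) {
  cat("<pk_vpc> ", x$kind, ", ", x$n_sim, " simulations\n", sep = "")
  print(x$observed, row.names = FALSE)
  invisible(x)
}

#' Fraction of observed percentiles inside their prediction bands
#'
#' Convenience summary of a [vpc()] result: the share of (bin, percentile)
#' cells whose observed percentile lies inside the simulated band.
#'
#' @param x A `pk_vpc`.
#' @return A fraction in `[0, 1]`.
#' @export
vpc_coverage <- function(x) {
  obs <- x$observed
  probs <- sort(unique(x$bands$percentile))
  inside <- 0L; total <- 0L
  for (p in probs) {
    b <- x$bands[x$bands$percentile == p, ]
    op <- obs[[paste0("p", p)]]
    keep <- is.finite(op)
    inside <- inside + sum(op[keep] >= b$lo[keep] & op[keep] <= b$hi[keep])
    total <- total + sum(keep)
  }
  inside / total
}

#' Normalized prediction distribution errors
#'
#' Simulates the model on the observed design, decorrelates each subject's
#' simulated and observed vectors with the Cholesky factor of the empirical
#' simulation covariance, and transforms the ranks of the decorrelated
#' observations through the standard-normal quantile function. Under a
#' correct model the NPDE are approximately N(0, 1). Results are reported
#' separately for the plasma and urine streams.
#'
#' @inheritParams vpc
#' @return An object of class `pk_npde` with the per-observation NPDE, and
#'   per-stream Shapiro-Wilk statistics, means, variances, and the fraction
#'   of values outside the central 90% normal interval.
#' @export
npde <- function(dataset, model, n_sim = 500, seed = 1) {
  if (inherits(model, "saem_fit")) model <- model$model
  dat <- prepare_data(dataset)
  sims <- simulate_observations(dataset, model, n_sim, seed)
  y <- dat$obs_y
  np <- rep(NA_real_, length(y))
  ridge_used <- FALSE
  for (i in seq_len(dat$ns)) {
    j <- (dat$obs_off[i] + 1L):dat$obs_off[i + 1L]
    if (dat$obs_off[i + 1L] <= dat$obs_off[i]) next
    Si <- sims[j, , drop = FALSE]
    mu <- rowMeans(Si)
    if (length(j) == 1L) {
      dec_s <- Si - mu
      dec_y <- y[j] - mu
    } else {
      V <- var(t(Si))
      L <- tryCatch(t(chol(V)), error = function(e) NULL)
      if (is.null(L)) {
        ridge_used <- TRUE
        V <- V + diag(1e-6 + 1e-4 * diag(V), nrow(V))
        L <- t(chol(V))
      }
      dec_s <- forwardsolve(L, Si - mu)
      dec_y <- forwardsolve(L, y[j] - mu)
    }
    for (r in seq_along(j)) {
      rk <- sum(dec_s[r, ] < dec_y[r])
      np[j[r]] <- qnorm((rk + 0.5) / (n_sim + 1))
    }
  }
  if (ridge_used)
    warning("singular simulation covariance: ridge-stabilized ",
            "decorrelation used")
  per_stream <- function(sel) {
    v <- np[sel]
    list(n = length(v), mean = mean(v), var = var(v),
         shapiro = if (length(v) >= 3 && sd(v) > 0)
           shapiro_wilk_check(v) else NULL,
         frac_outside90 = mean(abs(v) > qnorm(0.95)))
  }
  structure(list(npde = np,
                 plasma = per_stream(dat$obs_type == 0L),
                 urine = per_stream(dat$obs_type == 1L),
                 n_sim = n_sim), class = "pk_npde")
}

#' @export
print.pk_npde <- function(x, ...) {
  for (k in c("plasma", "urine")) {
    s <- x[[k]]
    if (s$n == 0) next
    cat(k, ": n=", s$n, " mean=", round(s$mean, 3), " var=",
        round(s$var, 3), " outside 90% interval=",
        round(100 * s$frac_outside90, 1), "%",
        if (!is.null(s$shapiro)) paste0(" SW p=",
                                        signif(s$shapiro$p.value, 3)),
        "\n", sep = "")
  }
  invisible(x)
}

#' Case bootstrap of a population fit
#'
#' Resamples subjects with replacement (stratified by dose arm, preserving
#' the arm sizes), refits each replicate warm-started from the reference
#' estimates, and summarizes every population parameter by its median and
#' quartiles over replicates. Replicates whose fit fails are excluded and
#' counted; more than 20% failures triggers a validity warning.
#'
#' @param dataset A [pk_dataset()].
#' @param model The final [population_model()] structure to refit.
#' @param fit The reference [saem_fit()] (provides warm-start values and
#'   the concordance check).
#' @param n_rep Number of bootstrap replicates (500 in a full run).
#' @param seed Seed; replicate seeds are derived deterministically.
#' @param control [saem_control()] for the replicate refits.
#' @return An object of class `pk_bootstrap` with a summary table
#'   (`estimate`, `median`, `q1`, `q3`, `within_iqr`) and the replicate
#'   draws.
#' @export
pk_bootstrap <- function(dataset, model, fit, n_rep = 500, seed = 1,
                         control = saem_control(n_explore = 120,
                                                n_smooth = 60,
                                                n_chains = 2,
                                                compute_ll = FALSE,
                                                compute_fim = FALSE)) {
  set.seed(seed)
  s <- dataset$subjects
  arms <- split(s$id, s$arm)
  par_vec <- function(f) {
    c(setNames(f$theta, names(f$theta)),
      setNames(vapply(f$betas, `[[`, 0, "value"),
               vapply(f$betas, relation_label, "")),
      setNames(f$omega, paste0("omega_", names(f$omega))),
      a1 = f$error[1], b1 = f$error[2], a2 = f$error[3], b2 = f$error[4])
  }
  ref <- par_vec(fit)
  draws <- matrix(NA_real_, n_rep, length(ref),
                  dimnames = list(NULL, names(ref)))
  fails <- 0L
  for (r in seq_len(n_rep)) {
    ids <- unlist(lapply(arms, function(a)
      sample(a, length(a), replace = TRUE)))
    bs <- s[match(ids, s$id), ]
    bs$id <- paste0("B", seq_along(ids), "_", bs$id)
    dl <- ol <- list()
    for (k in seq_along(ids)) {
      dd <- dataset$doses[dataset$doses$id == ids[k], ]
      oo <- dataset$observations[dataset$observations$id == ids[k], ]
      dd$id <- oo$id <- bs$id[k]
      dl[[k]] <- dd; ol[[k]] <- oo
    }
    bset <- pk_dataset(bs, do.call(rbind, dl), do.call(rbind, ol))
    res <- tryCatch(
      saem_fit(bset, model, control = control, seed = seed * 10000L + r,
               init = list(theta = fit$theta, omega = pmax(fit$omega, 0.05),
                           error = fit$error)),
      error = function(e) NULL)
    if (is.null(res)) fails <- fails + 1L
    else draws[r, ] <- par_vec(res)
  }
  if (fails > 0.2 * n_rep)
    warning("more than 20% of bootstrap replicates failed; summaries may ",
            "not be valid")
  ok <- stats::complete.cases(draws)
  qs <- apply(draws[ok, , drop = FALSE], 2, quantile,
              c(0.25, 0.5, 0.75))
  summary <- data.frame(parameter = names(ref), estimate = unname(ref),
                        median = qs[2, ], q1 = qs[1, ], q3 = qs[3, ],
                        within_iqr = ref >= qs[1, ] & ref <= qs[3, ],
                        row.names = NULL)
  structure(list(summary = summary, draws = draws[ok, , drop = FALSE],
                 n_rep = n_rep, n_failed = fails),
            class = "pk_bootstrap")
}

#' @export
print.pk_bootstrap <- function(x, ...) {
  cat("<pk_bootstrap> ", nrow(x$draws), "/", x$n_rep,
      " successful replicates\n", sep = "")
  s <- x$summary
  s[, 2:5] <- signif(s[, 2:5], 4)
  print(s, row.names = FALSE)
  invisible(x)
}

#' Plot a visual predictive check
#'
#' Percentile prediction bands with the observed percentiles overlaid.
#' Requires ggplot2.
#'
#' @param x A `pk_vpc`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
plot.pk_vpc <- function(x, ...) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("ggplot2 is required for plotting", call. = FALSE)
  obs <- x$observed
  long <- do.call(rbind, lapply(grep("^p[0-9]+$", names(obs), value = TRUE),
                                function(cn)
    data.frame(bin = obs$bin, percentile = as.numeric(sub("p", "", cn)),
               value = obs[[cn]])))
  ggplot2::ggplot(x$bands, ggplot2::aes(x = bin)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = lo, ymax = hi,
                                      group = percentile),
                         alpha = 0.25, fill = "steelblue") +
    ggplot2::geom_line(ggplot2::aes(y = mid, group = percentile),
                       linetype = 2, colour = "steelblue4") +
    ggplot2::geom_line(data = long,
                       ggplot2::aes(y = value, group = percentile),
                       colour = "firebrick") +
    ggplot2::geom_point(data = long, ggplot2::aes(y = value),
                        colour = "firebrick") +
    ggplot2::labs(x = "time (min)", y = paste(x$kind, "concentration"),
                  title = "Visual predictive check")
}

#' Plot normalized prediction distribution errors
#'
#' Histogram of the NPDE with the standard-normal density overlaid.
#' Requires ggplot2.
#'
#' @param x A `pk_npde`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
plot.pk_npde <- function(x, ...) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("ggplot2 is required for plotting", call. = FALSE)
  df <- data.frame(npde = x$npde)
  ggplot2::ggplot(df, ggplot2::aes(x = npde)) +
    ggplot2::geom_histogram(ggplot2::aes(y = ggplot2::after_stat(density)),
                            bins = 30, fill = "grey80", colour = "grey40") +
    ggplot2::stat_function(fun = dnorm, colour = "steelblue4",
                           linewidth = 1) +
    ggplot2::labs(x = "NPDE", y = "density",
                  title = "Normalized prediction distribution errors")
}
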