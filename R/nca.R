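# Linear-up/log-down trapezoid over one segment; log rule only on strictly
# declining positive segments.
.seg_auc <- function(t1, t2, c1, c2) {
  dt <- t2 - t1
  if (c1 > 0 && c2 > 0 && c2 < c1) {
    k <- log(c1 / c2)
    auc <- dt * (c1 - c2) / k
    # exact integral of t*C(t) with C log-linear on the segment
    lam <- k / dt
    aumc <- (t1 * c1 - t2 * c2) / lam + (c1 - c2) / lam^2
  } else {
    auc <- dt * (c1 + c2) / 2
    aumc <- dt * (t1 * c1 + t2 * c2) / 2
  }
  c(auc = auc, aumc = aumc)
}

# Interpolate concentration at time t0 inside a sampled span: log-linear on
# declining positive segments, linear otherwise.
.interp_conc <- function(times, conc, t0) {
  if (t0 <= times[1]) {
    # backward extrapolation from the first two points (log-linear when
    # declining)
    if (length(times) >= 2 && conc[1] > 0 && conc[2] > 0 &&
        conc[2] < conc[1]) {
      lam <- log(conc[1] / conc[2]) / (times[2] - times[1])
      return(conc[1] * exp(lam * (times[1] - t0)))
    }
    return(conc[1])
  }
  if (t0 >= tail(times, 1)) return(tail(conc, 1))
  i <- findInterval(t0, times)
  t1 <- times[i]; t2 <- times[i + 1]; c1 <- conc[i]; c2 <- conc[i + 1]
  if (c1 > 0 && c2 > 0 && c2 < c1) {
    lam <- log(c1 / c2) / (t2 - t1)
    c1 * exp(-lam * (t0 - t1))
  } else {
    c1 + (c2 - c1) * (t0 - t1) / (t2 - t1)
  }
}

.auc_between <- function(times, conc, a, b) {
  if (b <= a) return(0)
  ts <- c(a, times[times > a & times < b], b)
  cs <- vapply(ts, function(t0) .interp_conc(times, conc, t0), 0)
  tot <- 0
  for (i in seq_len(length(ts) - 1))
    tot <- tot + .seg_auc(ts[i], ts[i + 1], cs[i], cs[i + 1])[["auc"]]
  tot
}

#' Noncompartmental exposure metrics
#'
#' Model-free metrics from a single subject's plasma concentration-time
#' points after an intravenous dose: the end-of-infusion peak `c_t1`
#' (log-linear back-extrapolation of the earliest samples), interpolated
#' concentrations and partial areas to 30 and 60 min, the truncated mean
#' residence time over the observed span (AUMC/AUC), and the terminal
#' half-life from a log-linear regression on the last three declining
#' points. Areas use the linear-up/log-down trapezoid, with linear fallback
#' (and a note) on segments containing non-positive values.
#'
#' @param times Sorted sampling times (min).
#' @param conc Concentrations (mg/L).
#' @param dose Administered dose (mg), carried through for reference.
#' @param t_inf End of infusion (min), the anchor of `c_t1` and the partial
#'   areas.
#' @return A list of class `nca_metrics`.
#' @export
compute_nca <- function(times, conc, dose = NA, t_inf = 1) {
  stopifnot(length(times) == length(conc), length(times) >= 2)
  if (is.unsorted(times)) stop("times must be sorted", call. = FALSE)
  c_t1 <- .interp_conc(times, conc, t_inf)
  c_t30 <- .interp_conc(times, conc, 30)
  c_t60 <- .interp_conc(times, conc, 60)
  auc_t1_t30 <- .auc_between(times, conc, t_inf, 30)
  auc_t1_t60 <- .auc_between(times, conc, t_inf, 60)
  # truncated MRT over the observed span
  ts <- times; cs <- conc
  auc <- aumc <- 0
  for (i in seq_len(length(ts) - 1)) {
    sg <- .seg_auc(ts[i], ts[i + 1], cs[i], cs[i + 1])
    auc <- auc + sg[["auc"]]; aumc <- aumc + sg[["aumc"]]
  }
  mrt <- if (auc > 0) aumc / auc else NA_real_
  half_life <- NA_real_
  pos <- conc > 0
  if (sum(pos) >= 3) {
    idx <- tail(which(pos), 3)
    if (all(diff(conc[idx]) < 0)) {
      sl <- unname(coef(lm(log(conc[idx]) ~ times[idx]))[2])
      if (sl < 0) half_life <- log(2) / -sl
    }
  }
  structure(list(c_t1 = c_t1, c_t30 = c_t30, c_t60 = c_t60,
                 auc_t1_t30 = auc_t1_t30, auc_t1_t60 = auc_t1_t60,
                 auc_0_last = auc, mrt = mrt, half_life = half_life,
                 dose = dose),
            class = "nca_metrics")
}

#' @export
print.nca_metrics <- function(x, ...) {
  v <- unlist(x[c("c_t1", "c_t30", "c_t60", "auc_t1_t30", "auc_t1_t60",
                  "mrt", "half_life")])
  print(signif(v, 4))
  invisible(x)
}

#' Per-subject NCA over a dataset
#'
#' Applies [compute_nca()] to every subject's plasma observations.
#'
#' @param dataset A [pk_dataset()].
#' @param t_inf End of infusion (min).
#' @return data.frame of metrics, one row per subject with at least two
#'   plasma points.
#' @export
nca_table <- function(dataset, t_inf = 1) {
  o <- dataset$observations
  d <- dataset$doses
  rows <- list()
  for (id in dataset$subjects$id) {
    oi <- o[o$id == id & o$kind == "plasma", ]
    if (nrow(oi) < 2) next
    m <- compute_nca(oi$time, oi$value,
                     dose = sum(d$amount[d$id == id]), t_inf = t_inf)
    rows[[length(rows) + 1L]] <-
      cbind(data.frame(id = id), as.data.frame(unclass(m)))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Compare an NCA metric between bleeding-status groups
#'
#' Kruskal-Wallis comparison of a metric across patient groups (e.g. the
#' bleeding-status groups A/B/C(/D) assessed 30 or 60 min after dosing),
#' with per-group medians and interquartile ranges.
#'
#' @param values Numeric metric per subject.
#' @param groups Group label per subject.
#' @return List with `statistic`, `p.value`, `df` and a per-group summary
#'   data.frame.
#' @export
compare_groups <- function(values, groups) {
  keep <- is.finite(values) & !is.na(groups)
  values <- values[keep]; groups <- factor(groups[keep])
  if (nlevels(groups) < 2)
    stop("degenerate input: need at least 2 non-empty groups",
         call. = FALSE)
  kw <- kruskal.test(values, groups)
  smry <- do.call(rbind, lapply(levels(groups), function(g) {
    v <- values[groups == g]
    data.frame(group = g, n = length(v), median = median(v),
               q1 = quantile(v, 0.25), q3 = quantile(v, 0.75))
  }))
  rownames(smry) <- NULL
  list(statistic = unname(kw$statistic), p.value = kw$p.value,
       df = unname(kw$parameter), summary = smry)
}
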