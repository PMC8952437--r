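#' Assemble a population-PK event dataset
#'
#' Bundles subject records, dosing events and timed observations (plasma
#' concentrations and interval urine collections) into a validated dataset,
#' the container consumed by the estimation, diagnostic and NCA functions.
#'
#' Times are minutes from the first dose (T0). Serum creatinine is stored in
#' mg/L and converted internally where a formula expects mg/dL. Urine
#' observations are concentrations over the half-open collection interval
#' `(interval_start, time]` with the collected volume in litres.
#'
#' @param subjects data.frame with columns `id`, `age` (years), `height`
#'   (cm), `bw_before` (kg, pre-pregnancy), `bw` (kg, at caesarean), `scr`
#'   (serum creatinine, mg/L), `arm` (dose-group label) and
#'   `bleeding_volume` (mL). `age`, `height`, `scr` may be `NA` only where a
#'   subject is to be excluded from covariate modelling.
#' @param doses data.frame with columns `id`, `time` (min), `amount` (mg),
#'   `tinf` (infusion duration, min).
#' @param observations data.frame with columns `id`, `time` (min), `value`
#'   (mg/L), `kind` (`"plasma"` or `"urine"`), and for urine rows
#'   `interval_start` (min) and `urine_volume` (L).
#' @return An object of class `pk_dataset`.
#' @seealso [read_pk_dataset()], [derive_covariates()]
#' @export
pk_dataset <- function(subjects, doses, observations) {
  subjects <- as.data.frame(subjects)
  doses <- as.data.frame(doses)
  observations <- as.data.frame(observations)
  need <- function(df, cols, what) {
    miss <- setdiff(cols, names(df))
    if (length(miss))
      stop("schema error: ", what, " missing column(s): ",
           paste(miss, collapse = ", "), call. = FALSE)
  }
  need(subjects, c("id", "age", "height", "bw_before", "bw", "scr", "arm",
                   "bleeding_volume"), "subjects")
  need(doses, c("id", "time", "amount", "tinf"), "doses")
  need(observations, c("id", "time", "value", "kind"), "observations")
  if (!"interval_start" %in% names(observations))
    observations$interval_start <- NA_real_
  if (!"urine_volume" %in% names(observations))
    observations$urine_volume <- NA_real_
  subjects$id <- as.character(subjects$id)
  doses$id <- as.character(doses$id)
  observations$id <- as.character(observations$id)
  doses <- doses[order(match(doses$id, subjects$id), doses$time), ,
                 drop = FALSE]
  observations <- observations[
    order(match(observations$id, subjects$id), observations$time), ,
    drop = FALSE]
  rownames(subjects) <- rownames(doses) <- rownames(observations) <- NULL
  x <- structure(list(subjects = subjects, doses = doses,
                      observations = observations),
                 class = "pk_dataset")
  validate_pk_dataset(x)
}

#' Validate a population-PK dataset
#'
#' Checks referential integrity (every event references a known subject),
#' ordering, positivity, dose-before-observation, and the urine interval
#' conventions. Validation is idempotent: a valid dataset is returned
#' unchanged.
#'
#' @param x A `pk_dataset`.
#' @return `x`, invisibly unchanged, or an error describing the violation.
#' @export
validate_pk_dataset <- function(x) {
  stopifnot(inherits(x, "pk_dataset"))
  s <- x$subjects; d <- x$doses; o <- x$observations
  if (anyDuplicated(s$id))
    stop("validation error: duplicated subject id(s)", call. = FALSE)
  bad <- setdiff(unique(c(d$id, o$id)), s$id)
  if (length(bad))
    stop("validation error: events reference unknown subject(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  if (any(d$amount <= 0) || any(d$tinf <= 0))
    stop("validation error: dose amount and infusion duration must be > 0",
         call. = FALSE)
  if (any(!is.na(o$value) & o$value < 0))
    stop("validation error: negative observation value", call. = FALSE)
  if (!all(o$kind %in% c("plasma", "urine")))
    stop("validation error: observation kind must be 'plasma' or 'urine'",
         call. = FALSE)
  ur <- o$kind == "urine"
  if (any(ur)) {
    if (any(is.na(o$interval_start[ur])) || any(is.na(o$urine_volume[ur])))
      stop("validation error: urine rows need interval_start and urine_volume",
           call. = FALSE)
    if (any(o$interval_start[ur] >= o$time[ur]))
      stop("validation error: urine interval_start must precede time",
           call. = FALSE)
    if (any(o$urine_volume[ur] <= 0))
      stop("validation error: urine_volume must be > 0", call. = FALSE)
  }
  for (id in unique(o$id)) {
    first_dose <- suppressWarnings(min(d$time[d$id == id]))
    if (!is.finite(first_dose))
      stop("validation error: subject ", id, " has observations but no dose",
           call. = FALSE)
    if (any(o$time[o$id == id] < first_dose))
      stop("validation error: subject ", id,
           " has an observation before the first dose", call. = FALSE)
  }
  invisible(x)
}

#' @export
print.pk_dataset <- function(x, ...) {
  o <- x$observations
  cat("<pk_dataset> ", nrow(x$subjects), " subjects, ", nrow(x$doses),
      " doses, ", sum(o$kind == "plasma"), " plasma + ",
      sum(o$kind == "urine"), " urine observations\n", sep = "")
  if (length(unique(x$subjects$arm)) > 1)
    print(table(arm = x$subjects$arm))
  invisible(x)
}

# Event-record column order of the CSV dialect.
.pk_columns <- c("ID", "TIME", "DV", "DVID", "AMT", "TINF", "USTART", "UVOL",
                 "AGE", "HT", "BWBEF", "BW", "SCR", "ARM", "BLEED")

#' Read an event-record CSV into a `pk_dataset`
#'
#' The dialect is a single long-format file with one row per dose or
#' observation: columns `ID, TIME, DV, DVID (1 = plasma, 2 = urine), AMT,
#' TINF, USTART, UVOL, AGE, HT, BWBEF, BW, SCR, ARM, BLEED`. Rows with
#' `AMT > 0` are dosing events; rows with a non-missing `DV` are
#' observations. Subject covariates are taken from the subject's first row.
#'
#' @param path Path to the CSV file.
#' @return A validated [pk_dataset()].
#' @export
read_pk_dataset <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(.pk_columns, names(raw))
  if (length(miss))
    stop("schema error: missing required column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  raw$ID <- as.character(raw$ID)
  for (cc in setdiff(.pk_columns, c("ID", "ARM")))
    raw[[cc]] <- as.numeric(raw[[cc]])
  first <- raw[!duplicated(raw$ID), , drop = FALSE]
  subjects <- data.frame(
    id = first$ID, age = first$AGE, height = first$HT,
    bw_before = first$BWBEF, bw = first$BW, scr = first$SCR,
    arm = first$ARM, bleeding_volume = first$BLEED,
    stringsAsFactors = FALSE)
  isd <- !is.na(raw$AMT) & raw$AMT > 0
  doses <- data.frame(id = raw$ID[isd], time = raw$TIME[isd],
                      amount = raw$AMT[isd], tinf = raw$TINF[isd],
                      stringsAsFactors = FALSE)
  iso <- !is.na(raw$DV)
  observations <- data.frame(
    id = raw$ID[iso], time = raw$TIME[iso], value = raw$DV[iso],
    kind = ifelse(raw$DVID[iso] == 2, "urine", "plasma"),
    interval_start = raw$USTART[iso], urine_volume = raw$UVOL[iso],
    stringsAsFactors = FALSE)
  pk_dataset(subjects, doses, observations)
}

#' Write a `pk_dataset` as an event-record CSV
#'
#' Inverse of [read_pk_dataset()]: numeric fields are written with 17
#' significant digits so that a read/write round trip is bit-exact.
#'
#' @param x A `pk_dataset`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_pk_dataset <- function(x, path) {
  validate_pk_dataset(x)
  s <- x$subjects
  d <- x$doses; o <- x$observations
  id <- c(d$id, o$id)
  num <- rbind(
    cbind(d$time, NA, NA, d$amount, d$tinf, NA, NA),
    cbind(o$time, o$value, ifelse(o$kind == "urine", 2, 1), NA, NA,
          o$interval_start, o$urine_volume))
  ord <- order(match(id, s$id), num[, 1], !is.na(num[, 2]))
  id <- id[ord]; num <- num[ord, , drop = FALSE]
  cov <- s[match(id, s$id), c("age", "height", "bw_before", "bw", "scr",
                              "arm", "bleeding_volume")]
  fmt <- function(v) ifelse(is.na(v), "", sprintf("%.17g", v))
  out <- data.frame(
    ID = id, TIME = fmt(num[, 1]), DV = fmt(num[, 2]),
    DVID = ifelse(is.na(num[, 3]), "", as.character(num[, 3])),
    AMT = fmt(num[, 4]), TINF = fmt(num[, 5]), USTART = fmt(num[, 6]),
    UVOL = fmt(num[, 7]), AGE = fmt(cov$age), HT = fmt(cov$height),
    BWBEF = fmt(cov$bw_before), BW = fmt(cov$bw), SCR = fmt(cov$scr),
    ARM = as.character(cov$arm), BLEED = fmt(cov$bleeding_volume),
    stringsAsFactors = FALSE)
  write.table(out, path, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Compare a baseline variable between two dose groups
#'
#' Runs an F test of variance homogeneity; if homogeneity is not rejected
#' (p > alpha) an independent-samples t test with pooled variance is used,
#' otherwise a Kruskal-Wallis test.
#'
#' @param x,y Numeric vectors, the variable in each group.
#' @param alpha Significance level of the homogeneity screen (default 0.05).
#' @return A list with `test` (`"t"` or `"kruskal"`), `statistic`,
#'   `p.value` and `homogeneity_p`.
#' @export
compare_baseline <- function(x, y, alpha = 0.05) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) < 2 || length(y) < 2)
    stop("need at least 2 subjects per group", call. = FALSE)
  if (var(x) == 0 && var(y) == 0)
    stop("degenerate input: zero variance in both groups", call. = FALSE)
  hp <- var.test(x, y)$p.value
  if (is.na(hp) || hp > alpha) {
    tt <- t.test(x, y, var.equal = TRUE)
    list(test = "t", statistic = unname(tt$statistic),
         p.value = tt$p.value, homogeneity_p = hp)
  } else {
    kw <- kruskal.test(list(x, y))
    list(test = "kruskal", statistic = unname(kw$statistic),
         p.value = kw$p.value, homogeneity_p = hp)
  }
}
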