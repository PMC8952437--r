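test_that("event-record datasets assemble, validate and round-trip", {
  ds <- make_toy_dataset()
  expect_equal(nrow(ds$subjects), 3)
  expect_equal(nrow(ds$doses), 3)
  expect_equal(nrow(ds$observations), 24)

  # validation is idempotent
  expect_identical(validate_pk_dataset(ds), ds)

  # write/read round trip is bit-exact on every numeric field
  path <- tempfile(fileext = ".csv")
  write_pk_dataset(ds, path)
  ds2 <- read_pk_dataset(path)
  for (tab in c("subjects", "doses", "observations"))
    for (col in names(ds[[tab]]))
      expect_identical(ds2[[tab]][[col]], ds[[tab]][[col]],
                       label = paste(tab, col))
})

test_that("dataset validation rejects malformed records", {
  ds <- make_toy_dataset()
  # observation before the first dose, named subject
  bad <- ds$observations
  bad$time[1] <- -5
  expect_error(pk_dataset(ds$subjects, ds$doses, bad), "S1")
  # negative concentration
  bad <- ds$observations
  bad$value[2] <- -1
  expect_error(pk_dataset(ds$subjects, ds$doses, bad), "negative")
  # unknown subject
  bad <- ds$doses
  bad$id[1] <- "ghost"
  expect_error(pk_dataset(ds$subjects, bad, ds$observations), "ghost")
  # urine interval conventions
  bad <- ds$observations
  bad$interval_start[bad$kind == "urine"][1] <- 400
  expect_error(pk_dataset(ds$subjects, ds$doses, bad), "interval_start")
  # schema error from the reader
  path <- tempfile(fileext = ".csv")
  write.csv(data.frame(ID = 1, TIME = 0), path, row.names = FALSE)
  expect_error(read_pk_dataset(path), "schema")
})

test_that("derived covariate panel matches the standard female formulas", {
  s <- data.frame(id = "P1", age = 34, height = 166, bw_before = 73.2,
                  bw = 84.3, scr = 6.5, arm = "TXA1g",
                  bleeding_volume = 1000)
  p <- derive_covariates(s)
  # values computed independently from the closed-form definitions
  expect_equal(p$eclcr_cg_bef, 0.85 * 106 * 73.2 / (72 * 0.65),
               tolerance = 1e-12)
  expect_equal(p$eclcr_cg_bef, 140.9256, tolerance = 1e-4)
  expect_equal(p$iw, 57.81496, tolerance = 1e-4)
  expect_equal(p$bsa_bef, 1.81285, tolerance = 1e-4)
  expect_equal(p$lbw_bef, 44.46207, tolerance = 1e-4)
  expect_equal(p$abw_bef, 57.81496 + 0.4 * (73.2 - 57.81496),
               tolerance = 1e-6)
  expect_equal(p$bmi_bef, 73.2 / 1.66^2, tolerance = 1e-12)
  # CKD-EPI 2009 female at 0.65 mg/dL, de-indexed by BSA/1.73
  expect_equal(p$egfr_ckdepi_bef, 115.8324 * 1.81285 / 1.73,
               tolerance = 1e-4)
  expect_equal(p$egfr_mdrd_bef, 104.3397 * 1.81285 / 1.73,
               tolerance = 1e-4)
  # panel is a pure function of the record
  expect_identical(p, derive_covariates(s))

  # missing weight flags the subject instead of failing
  s2 <- rbind(s, within(s, {id <- "P2"; bw <- NA}))
  p2 <- derive_covariates(s2)
  expect_identical(p2$covariate_missing, c(FALSE, TRUE))
})

test_that("baseline comparison picks the test by variance homogeneity", {
  x <- c(1.2, 3.4, 2.2, 4.1, 0.7)
  same <- compare_baseline(x, x)
  expect_equal(same$test, "t")
  expect_equal(same$p.value, 1)
  expect_equal(same$statistic, 0)

  set.seed(1)
  a <- rnorm(50); b <- rnorm(50, 5)
  r <- compare_baseline(a, b)
  expect_equal(r$test, "t")
  expect_lt(r$p.value, 1e-3)

  set.seed(2)
  h <- compare_baseline(rnorm(40, 0, 1), rnorm(40, 0, 10))
  expect_equal(h$test, "kruskal")

  expect_error(compare_baseline(rep(1, 5), rep(2, 5)), "zero variance")
})
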