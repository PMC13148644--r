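make_audiogram_csv <- function(path, patients = 3, freqs = c(250, 500, 1000,
                                                             2000, 4000, 8000)) {
  df <- expand.grid(freq_hz = freqs, patient_id = paste0("P", seq_len(patients)))
  df$threshold_db_hl <- rep(c(10, 20, 30, 40, 50, 60),
                            length.out = nrow(df))
  df$age <- rep(10, nrow(df))
  write.csv(df[, c("patient_id", "freq_hz", "threshold_db_hl", "age")],
            path, row.names = FALSE)
  df
}

test_that("long-format audiogram CSVs are grouped, sorted and validated", {
  path <- withr::local_tempfile(fileext = ".csv")
  make_audiogram_csv(path, patients = 3, freqs = c(2000, 250, 500, 1000, 4000, 8000))
  auds <- read_audiograms(path)
  expect_length(auds, 3)
  expect_true(all(vapply(auds, function(a) length(a$freqs_hz) == 6, logical(1))))
  expect_true(all(vapply(auds, function(a) !is.unsorted(a$freqs_hz), logical(1))))
  expect_equal(auds[["P2"]]$meta$age, 10)

  empty <- withr::local_tempfile(fileext = ".csv")
  writeLines("patient_id,freq_hz,threshold_db_hl", empty)
  expect_length(read_audiograms(empty), 0)

  dup <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("patient_id,freq_hz,threshold_db_hl",
               "P1,1000,20", "P1,1000,30"), dup)
  expect_error(read_audiograms(dup), "duplicate")
})

test_that("severity grading uses the 4-frequency PTA and WHO bands", {
  freqs <- c(250, 500, 1000, 2000, 4000, 8000)
  expect_grade <- function(thr, pta, grade) {
    sg <- severity_grade(audiogram(freqs, rep(thr, 6)))
    expect_equal(sg$pta_db, pta)
    expect_equal(as.character(sg$grade), grade)
  }
  expect_grade(10, 10, "normal")
  expect_grade(85, 85, "profound")
  expect_grade(25, 25, "mild")
  expect_grade(40, 40, "moderate")
  expect_grade(55, 55, "moderately_severe")
  expect_grade(70, 70, "severe")
  expect_error(severity_grade(audiogram(c(125, 250), c(10, 10))), "cover")
})

test_that("severity is invariant to thresholds outside the PTA band", {
  a <- audiogram(c(250, 500, 1000, 2000, 4000, 8000),
                 c(90, 30, 30, 30, 30, 115))
  b <- audiogram(c(500, 1000, 2000, 4000), rep(30, 4))
  expect_equal(severity_grade(a)$pta_db, severity_grade(b)$pta_db)
})

test_that("performance factors follow the compressive dB-to-gain map", {
  map <- build_tonotopic_map(20)
  freqs <- c(250, 500, 1000, 2000, 4000, 8000)
  expect_equal(performance_profile(audiogram(freqs, rep(0, 6)), map)$factors,
               rep(1, 20))
  expect_equal(performance_profile(audiogram(freqs, rep(40, 6)), map)$factors,
               rep(0.1, 20))
  # interpolation stays between the adjacent measured factors
  a <- audiogram(c(1000, 2000), c(20, 60))
  p <- performance_profile(a, map)
  mid <- map$cf_hz > 1000 & map$cf_hz < 2000
  expect_true(all(p$factors[mid] <= 10^(-20 / 40) + 1e-12))
  expect_true(all(p$factors[mid] >= 10^(-60 / 40) - 1e-12))
})

test_that("raising any threshold never raises any performance factor", {
  map <- build_tonotopic_map(30)
  freqs <- c(250, 500, 1000, 2000, 4000, 8000)
  set.seed(8)
  for (k in 1:20) {
    thr <- runif(6, 0, 100)
    bump <- thr
    i <- sample(6, 1)
    bump[i] <- min(120, bump[i] + runif(1, 1, 20))
    f0 <- performance_profile(audiogram(freqs, thr), map)$factors
    f1 <- performance_profile(audiogram(freqs, bump), map)$factors
    expect_true(all(f1 <= f0 + 1e-12))
  }
})

test_that("synthetic cohorts are seeded, graded across all six bands", {
  cohort <- synthesize_cohort(224, seed = 7)
  expect_length(cohort, 224)
  expect_identical(cohort, synthesize_cohort(224, seed = 7))
  rep10k <- severity_report(synthesize_cohort(10000, seed = 1))
  expect_setequal(unique(rep10k$grade),
                  c("normal", "mild", "moderate", "moderately_severe",
                    "severe", "profound"))
  # thresholds stay clinical
  expect_true(all(vapply(cohort, function(a) {
    all(a$thresholds_db_hl >= -10 & a$thresholds_db_hl <= 120)
  }, logical(1))))
})

test_that("cohort demographics are independent of severity", {
  cohort <- synthesize_cohort(1000, seed = 13)
  rep <- severity_report(cohort)
  age <- vapply(cohort, function(a) a$meta$age, numeric(1))
  sex <- vapply(cohort, function(a) a$meta$sex == "female", logical(1))
  expect_lt(abs(cor(rep$pta_db, age)), 0.1)
  expect_lt(abs(cor(rep$pta_db, as.numeric(sex))), 0.1)
})

test_that("cohorts survive a CSV round trip", {
  cohort <- synthesize_cohort(5, seed = 2)
  path <- withr::local_tempfile(fileext = ".csv")
  write_audiograms(cohort, path)
  back <- read_audiograms(path)
  expect_length(back, 5)
  expect_equal(back[["P003"]]$thresholds_db_hl,
               cohort[["P003"]]$thresholds_db_hl, tolerance = 1e-12)
  expect_equal(back[["P002"]]$meta$age, cohort[["P002"]]$meta$age)
})
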