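test_that("smoking classification boundaries", {
  expect_identical(
    as.character(classify_smoking(c(0, 99, 100, 5000),
                                  answered = c(TRUE, TRUE, TRUE, TRUE))),
    c("never", "never", "ever", "ever"))
  expect_identical(as.character(classify_smoking(50, answered = FALSE)),
                   "excluded")
  expect_error(classify_smoking(-1), class = "arsmr_validation_error")
})

test_that("asthma categories follow the questionnaire logic", {
  expect_identical(as.character(classify_asthma(TRUE, TRUE, FALSE, FALSE)),
                   "past")
  expect_identical(as.character(classify_asthma(TRUE, TRUE, FALSE, TRUE)),
                   "current")
  expect_identical(as.character(classify_asthma(TRUE, TRUE, TRUE, FALSE)),
                   "current")
  expect_identical(as.character(classify_asthma(FALSE, NA, NA, NA)), "none")
  expect_identical(as.character(classify_asthma(NA, TRUE, TRUE, TRUE)),
                   "missing")
  # undiagnosed self-report: none by default, lifetime when broadened
  expect_identical(as.character(classify_asthma(TRUE, FALSE, FALSE, FALSE)),
                   "none")
  broad <- classify_asthma(TRUE, FALSE, FALSE, FALSE, broaden = TRUE)
  expect_true(as.character(broad) %in% c("past", "current"))
  expect_identical(as.character(broad), "past")
})

test_that("asthma categories always partition the cohort", {
  set.seed(31)
  for (i in 1:20) {
    n <- 200
    lace <- function(p = 0.15) {
      x <- runif(n) < 0.3
      x[runif(n) < p] <- NA
      x
    }
    cat <- classify_asthma(lace(), lace(), lace(), lace(),
                           broaden = i %% 2 == 0)
    expect_equal(sum(table(cat)), n)
    expect_false(anyNA(cat))
  }
})

test_that("medication correction scales exactly and preserves the ratio", {
  out <- correct_for_medication(2500, 3000, TRUE, mode = "scale")
  expect_equal(out$fvc_ml, 2640)
  expect_equal(out$fev1_ml, 2200)
  expect_equal(out$fev1_ml / out$fvc_ml, 2500 / 3000)

  unmed <- correct_for_medication(2500, 3000, FALSE, mode = "scale")
  expect_equal(unmed$fvc_ml, 3000)

  cov_mode <- correct_for_medication(2500, 3000, TRUE, mode = "covariate")
  expect_equal(cov_mode$fvc_ml, 3000)
  expect_true(cov_mode$med_covariate)

  excl <- correct_for_medication(2500, 3000, TRUE, mode = "exclude")
  expect_true(excl$excluded)
})

test_that("spirometry inclusion conjunction and strict mode", {
  expect_true(spirometry_inclusion(TRUE, "B"))
  expect_true(spirometry_inclusion(TRUE, "C"))
  expect_false(spirometry_inclusion(TRUE, "C", strict = TRUE))
  expect_false(spirometry_inclusion(FALSE, "A"))
  expect_false(spirometry_inclusion(TRUE, "D"))
  expect_error(spirometry_inclusion(TRUE, "Z"),
               class = "arsmr_validation_error")
})

ref_one <- function(location, scale, measure = "fvc") {
  data.frame(ethnic_background = "Cuban", sex = "F", age_band = "40-59",
             height_band = "160-172", measure = measure,
             location = location, scale = scale)
}
stratum_one <- data.frame(ethnic_background = "Cuban", sex = "F",
                          age_years = 45, height_cm = 165)

test_that("LLN is the 5th reference percentile", {
  expect_equal(lln_threshold(ref_one(100, 10), stratum_one, "fvc"), 83.551,
               tolerance = 1e-5)
  expect_equal(lln_threshold(ref_one(4000, 500), stratum_one, "fvc"),
               3177.573, tolerance = 1e-6)
  # degenerate scale limit: threshold collapses to the location
  expect_equal(lln_threshold(ref_one(4000, 1e-9), stratum_one, "fvc"), 4000,
               tolerance = 1e-6)
  expect_error(
    lln_threshold(ref_one(100, 10),
                  data.frame(ethnic_background = "Cuban", sex = "M",
                             age_years = 45, height_cm = 165), "fvc"),
    class = "arsmr_lookup_error")
})

test_that("below-LLN is strict; percent predicted is a plain ratio", {
  thr <- lln_threshold(ref_one(100, 10), stratum_one, "fvc")
  expect_false(classify_below_lln(thr, thr))
  expect_true(classify_below_lln(thr - 1e-9, thr))
  expect_equal(percent_predicted(100, 100), 100)
  expect_error(percent_predicted(1, -5), class = "arsmr_validation_error")
})

test_that("healthy reference draws fall below LLN at the nominal 5%", {
  set.seed(32)
  ref <- default_reference_model()
  n <- 4e4
  strat <- data.frame(ethnic_background = "Mexican", sex = "M",
                      age_years = rep(30, n), height_cm = 170)
  for (m in c("fev1", "fvc", "ratio", "pef")) {
    cell <- ref[ref$measure == m & ref$ethnic_background == "Mexican" &
                  ref$sex == "M" & ref$age_band == "18-39" &
                  ref$height_band == "160-172", ]
    vals <- rnorm(n, cell$location, cell$scale)
    rate <- mean(classify_below_lln(vals, lln_threshold(ref, strat, m)))
    expect_lt(abs(rate - 0.05), 3 * sqrt(0.05 * 0.95 / n))
  }
})

test_that("rice classification: exact top fifth on tie-free input", {
  set.seed(33)
  x <- runif(10000)
  rc <- classify_rice(x)
  expect_equal(sum(rc$label == "high"), 2000)
  expect_true(all(x[rc$label == "high"] > rc$cutoff))

  xm <- x; xm[c(5, 50)] <- NA
  expect_equal(sum(classify_rice(xm)$label == "excluded"), 2)
  expect_error(classify_rice(rep(NA_real_, 5)),
               class = "arsmr_degenerate_error")
  # permutation invariance of labels
  p <- sample.int(10000)
  expect_identical(classify_rice(x[p])$label, rc$label[p])
  expect_equal(classify_rice(x[p])$cutoff, rc$cutoff)
})

test_that("reference model survives a TSV round trip", {
  ref <- default_reference_model()
  path <- tempfile(fileext = ".tsv")
  write_reference_model(ref, path)
  back <- read_reference_model(path)
  expect_equal(back$location, ref$location)
  expect_equal(back$scale, ref$scale)
  expect_identical(back$measure, ref$measure)
})
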