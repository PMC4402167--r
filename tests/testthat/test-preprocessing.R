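test_that("mean arterial pressure follows DBP + (SBP - DBP)/3", {
  expect_equal(mean_arterial_pressure(120, 80), 80 + 40 / 3)
  expect_equal(mean_arterial_pressure(100, 100), 100)
  expect_equal(mean_arterial_pressure(150, 90), 110)
  expect_error(mean_arterial_pressure(80, 120), "sbp")
  expect_error(mean_arterial_pressure(80, 0), "dbp")
})

test_that("MAP is a convex combination of the two pressures", {
  set.seed(1)
  dbp <- runif(200, 50, 100)
  sbp <- dbp + runif(200, 0, 80)
  map <- mean_arterial_pressure(sbp, dbp)
  expect_true(all(map >= dbp & map <= sbp))
})

test_that("WHO BMI classes use left-closed half-open intervals", {
  expect_equal(as.character(classify_bmi(28.32)), "overweight")
  expect_equal(as.character(classify_bmi(25.0)), "overweight")
  expect_equal(as.character(classify_bmi(40.0)), "obese3")
  expect_equal(as.character(classify_bmi(18.49)), "underweight")
  expect_equal(as.character(classify_bmi(18.5)), "normal")
  expect_equal(as.character(classify_bmi(34.999)), "obese1")
  expect_error(classify_bmi(0), "positive")
})

test_that("BMI classification is monotone non-decreasing", {
  set.seed(2)
  bmi <- sort(runif(500, 12, 55))
  cls <- as.integer(classify_bmi(bmi))
  expect_true(all(diff(cls) >= 0))
})

test_that("Friedewald estimates LDL and VLDL and conserves mass", {
  fw <- friedewald(200, 50, 100)
  expect_equal(fw$ldl, 130)
  expect_equal(fw$vldl, 20)
  fw0 <- friedewald(100, 100, 0)
  expect_equal(fw0$ldl, 0)
  expect_equal(fw0$vldl, 0)
  fwp <- friedewald(190.71, 44.08, 130.08)
  expect_equal(fwp$ldl, 190.71 - 44.08 - 130.08 / 5)
  expect_equal(fwp$vldl, 130.08 / 5)
  set.seed(3)
  tc <- runif(50, 120, 300); hd <- runif(50, 25, 80); tg <- runif(50, 40, 390)
  fwr <- friedewald(tc, hd, tg)
  expect_equal(fwr$ldl + fwr$vldl + hd, tc)
  expect_error(friedewald(200, 50, 410), class = "friedewald_invalid")
})

test_that("Geary's ratio approaches sqrt(2/pi) under normality and detects skew", {
  set.seed(4)
  g <- geary_test(rnorm(1e5))
  expect_equal(g$ratio, sqrt(2 / pi), tolerance = 0.01)
  expect_lt(abs(g$z), 4)
  gexp <- geary_test(rexp(1e4))
  expect_lt(gexp$p, 0.01)
  expect_error(geary_test(rep(1, 20)), "variance")
  expect_error(geary_test(rnorm(5)), "n >= 8")
})

test_that("log transform targets only non-normal positive columns", {
  set.seed(5)
  tab <- data.frame(norm = rnorm(2000, 100, 10), lnorm = rlnorm(2000, 0, 0.8))
  res <- log_transform_if_nonnormal(tab, c("norm", "lnorm"), alpha = 0.05)
  expect_false(res$log$transformed[res$log$column == "norm"])
  expect_true(res$log$transformed[res$log$column == "lnorm"])
  expect_equal(res$table$norm, tab$norm)
  expect_equal(res$table$lnorm, log(tab$lnorm))
  expect_gt(res$log$p_after[res$log$column == "lnorm"], 0.05)
  bad <- data.frame(x = c(0, rlnorm(999, 0, 1)))
  expect_error(log_transform_if_nonnormal(bad, "x"), "'x'")
})

test_that("exclusion rules drop diabetics and missing-insulin subjects", {
  tab <- data.frame(insulin = c(NA, 1:9),
                    diabetes_flag = c(FALSE, TRUE, TRUE, rep(FALSE, 7)))
  tab$insulin_missing <- is.na(tab$insulin)
  res <- apply_exclusions(tab)
  expect_equal(nrow(res$table), 7)
  expect_equal(unname(res$excluded["insulin_missing"]), 1)
  expect_equal(unname(res$excluded["diabetes"]), 2)
  expect_equal(unname(res$excluded["total"]), 3)

  clean <- data.frame(insulin = 1:5)
  expect_equal(nrow(apply_exclusions(clean)$table), 5)

  both <- data.frame(insulin_missing = c(TRUE, FALSE),
                     diabetes_flag = c(TRUE, FALSE))
  resb <- apply_exclusions(both)
  expect_equal(unname(resb$excluded["total"]), 1)  # overlap counted once
  expect_equal(unname(resb$excluded["insulin_missing"]), 1)
  expect_equal(unname(resb$excluded["diabetes"]), 1)
})

test_that("preprocess_cohort appends derived indices consistently", {
  co <- generate_cohort(default_cohort_spec(n_total = 300), seed = 9)
  pp <- preprocess_cohort(co)
  tab <- pp$table
  expect_equal(tab$map, tab$dbp + (tab$sbp - tab$dbp) / 3)
  expect_equal(tab$non_hdl, tab$tchol - tab$hdl)
  ok <- !tab$friedewald_invalid
  expect_equal(tab$ldl[ok] + tab$vldl[ok] + tab$hdl[ok], tab$tchol[ok])
  expect_true(all(is.na(tab$ldl[!ok])))
  expect_true(all(levels(tab$bmi_class) == c("underweight", "normal", "overweight",
                                             "obese1", "obese2", "obese3")))
})
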