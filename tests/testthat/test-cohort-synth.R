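test_that("default spec carries the published per-phenotype parameters", {
  spec <- default_cohort_spec()
  ph <- setNames(spec$phenotypes,
                 vapply(spec$phenotypes, `[[`, character(1), "name"))
  expect_equal(ph$MHO$variables$wc_cm$location[["F"]], 104.40)
  expect_equal(ph$MHO$variables$wc_cm$scale[["F"]], 10.55)
  expect_equal(ph$HNW$variables$homa2ir$location[["M"]], 1.15)
  expect_equal(ph$HNW$variables$homa2ir$scale[["M"]], 0.44)
  expect_equal(ph$MONW$prevalence[["F"]], 28 / 992)
  for (g in c("F", "M")) {
    tot <- sum(vapply(spec$phenotypes, function(p) p$prevalence[[g]], numeric(1)))
    expect_equal(tot, 1, tolerance = 1e-9)
  }
})

test_that("cohort spec validation rejects inconsistent inputs", {
  spec <- default_cohort_spec()
  expect_error(cohort_spec(-5, 0.5, spec$phenotypes), "n_total")
  expect_error(cohort_spec(100, 1.5, spec$phenotypes), "gender_fraction")
  broken <- spec$phenotypes
  broken[[1]]$prevalence[["F"]] <- broken[[1]]$prevalence[["F"]] + 0.1
  expect_error(cohort_spec(100, 0.5, broken), "sum to")
})

test_that("generation is empty-safe and seed-deterministic", {
  spec0 <- default_cohort_spec(n_total = 0)
  expect_equal(nrow(generate_cohort(spec0, seed = 7)), 0)
  spec <- default_cohort_spec(n_total = 250)
  a <- generate_cohort(spec, seed = 7)
  b <- generate_cohort(spec, seed = 7)
  expect_identical(a, b)
  c <- generate_cohort(spec, seed = 8)
  expect_false(identical(a, c))
})

test_that("sample moments converge to the spec's targets", {
  spec <- default_cohort_spec(n_total = 20000)
  co <- generate_cohort(spec, seed = 13)
  ref <- mmsps_reference()
  for (phen in c("HNW", "MHO", "MDO")) {
    for (g in c("F", "M")) {
      sub <- co[co$true_phenotype == phen & co$gender == g, ]
      n <- nrow(sub)
      row <- ref$phenotype_params[ref$phenotype_params$variable == "wc_cm" &
                                  ref$phenotype_params$phenotype == phen, ]
      m <- row[[paste0("mean_", g)]]; s <- row[[paste0("sd_", g)]]
      expect_lt(abs(mean(sub$wc_cm) - m), 4 * s / sqrt(n))
      row <- ref$phenotype_params[ref$phenotype_params$variable == "homa2ir" &
                                  ref$phenotype_params$phenotype == phen, ]
      m <- row[[paste0("mean_", g)]]; s <- row[[paste0("sd_", g)]]
      expect_lt(abs(mean(sub$homa2ir) - m), 4 * s / sqrt(n))
    }
  }
})

test_that("phenotype frequencies stay within binomial 99% bounds", {
  spec <- default_cohort_spec(n_total = 20000)
  co <- generate_cohort(spec, seed = 21)
  for (p in spec$phenotypes) {
    for (g in c("F", "M")) {
      ng <- sum(co$gender == g)
      obs <- sum(co$true_phenotype == p$name & co$gender == g)
      prev <- p$prevalence[[g]]
      half <- qnorm(0.995) * sqrt(prev * (1 - prev) * ng)
      expect_lt(abs(obs - prev * ng), half + 1)
    }
  }
})

test_that("generated physiology is internally consistent", {
  co <- generate_cohort(default_cohort_spec(n_total = 500), seed = 3)
  expect_equal(co$homa2s, 100 / co$homa2ir)
  expect_true(all(co$sbp > co$dbp))
  expect_true(all(co$wc_cm > 40))
  # BMI bands match phenotype identity by construction
  cls <- classify_bmi(co$bmi)
  expect_true(all(cls[co$true_phenotype %in% c("HNW", "MONW")] == "normal"))
  expect_true(all(cls[co$true_phenotype %in% c("MHO", "MDO")] %in%
                    c("obese1", "obese2", "obese3")))
})

test_that("gaussian copula induces requested correlations without changing margins", {
  corr <- matrix(c(1, 0.6, 0.6, 1), 2,
                 dimnames = list(c("wc_cm", "homa2ir"), c("wc_cm", "homa2ir")))
  spec <- default_cohort_spec(n_total = 8000, correlation = corr)
  co <- generate_cohort(spec, seed = 17)
  hnw_f <- co[co$true_phenotype == "HNW" & co$gender == "F", ]
  expect_gt(cor(hnw_f$wc_cm, hnw_f$homa2ir, method = "spearman"), 0.4)
  expect_lt(abs(mean(hnw_f$wc_cm) - 79.27), 4 * 8.24 / sqrt(nrow(hnw_f)))
  ind <- generate_cohort(default_cohort_spec(n_total = 8000), seed = 17)
  hnw_i <- ind[ind$true_phenotype == "HNW" & ind$gender == "F", ]
  expect_lt(abs(cor(hnw_i$wc_cm, hnw_i$homa2ir)), 0.1)
})

test_that("cohort CSV and spec JSON round-trip", {
  co <- generate_cohort(default_cohort_spec(n_total = 50), seed = 5)
  f <- tempfile(fileext = ".csv")
  write_cohort_csv(co, f)
  back <- read_cohort_csv(f)
  expect_equal(back$id, co$id)
  expect_equal(back$wc_cm, co$wc_cm, tolerance = 1e-9)
  sf <- tempfile(fileext = ".json")
  spec <- default_cohort_spec(n_total = 123)
  write_cohort_spec(spec, sf)
  spec2 <- read_cohort_spec(sf)
  expect_equal(spec2$n_total, 123L)
  expect_identical(generate_cohort(spec2, seed = 2),
                   generate_cohort(spec, seed = 2))
  unlink(c(f, sf))
})
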