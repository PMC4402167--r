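test_that("scenario filters drop the intended phenotypes", {
  tab <- data.frame(id = 1:12,
                    phenotype = c("HNW", "MONW", "OW_HEALTHY", "OW_SICK",
                                  "MHO", "MDO", "HNW", "MONW", "OW_HEALTHY",
                                  "OW_SICK", "MHO", "MDO"))
  six <- scenario_filter(tab, "six_group")
  expect_equal(nrow(six$table), 12)
  expect_equal(sum(six$sick), 6)
  four <- scenario_filter(tab, "four_group")
  expect_false(any(four$table$phenotype %in% c("MONW", "MHO")))
  expect_equal(nrow(four$table), 8)
  two <- scenario_filter(tab, "two_group")
  expect_setequal(unique(two$table$phenotype), c("HNW", "MDO"))
  expect_equal(two$sick, two$table$phenotype == "MDO")
  only_h <- data.frame(phenotype = rep("HNW", 5))
  expect_error(scenario_filter(only_h, "two_group"), "empty outcome class")
})

test_that("ROC curve endpoints, monotonicity and perfect separation", {
  r <- build_roc(c(1, 2, 3, 4, 5, 6), c(0, 0, 0, 1, 1, 1))
  expect_equal(r$auc, 1)
  pts <- r$points
  expect_equal(pts$sensitivity[pts$threshold == -Inf], 1)
  expect_equal(pts$specificity[pts$threshold == -Inf], 0)
  expect_equal(pts$sensitivity[pts$threshold == Inf], 0)
  expect_equal(pts$specificity[pts$threshold == Inf], 1)
  expect_true(all(diff(pts$sensitivity[order(pts$threshold)]) <= 0))
  expect_error(build_roc(1:5, rep(1, 5)), "nonempty")
})

test_that("AUC equals the brute-force concordance count", {
  set.seed(41)
  for (i in 1:5) {
    v <- round(rnorm(30, 100, 10))   # rounding forces ties
    l <- rbinom(30, 1, 0.4)
    if (sum(l) == 0 || sum(l) == 30) next
    r <- build_roc(v, l)
    expect_equal(r$auc, auc_oracle(v, l), tolerance = 1e-12)
  }
})

test_that("AUC is near 1/2 when labels are independent of the marker", {
  set.seed(42)
  v <- rnorm(5000)
  l <- rbinom(5000, 1, 0.5)
  expect_lt(abs(build_roc(v, l)$auc - 0.5), 0.03)
})

test_that("cutpoint indices reproduce the published worked examples", {
  expect_equal(round_half_up(youden(0.733, 0.685), 2), 0.42)
  expect_equal(round_half_up(distance01(0.733, 0.685), 2), 0.41)
  expect_equal(round_half_up(youden(0.748, 0.697), 2), 0.45)
  expect_equal(round_half_up(distance01(0.748, 0.697), 2), 0.39)
  expect_equal(round_half_up(lr_plus(0.838, 0.823), 2), 4.73)
  expect_equal(round_half_up(lr_plus(0.960, 0.995), 2), 192.00)
  expect_equal(youden(1, 1), 1)
  expect_equal(distance01(1, 1), 0)
  expect_equal(lr_plus(1, 1), Inf)
  expect_error(youden(1.2, 0.5), "\\[0, 1\\]")
})

test_that("index identities hold exactly at every selected cutpoint", {
  set.seed(43)
  v <- c(rnorm(60, 1), rnorm(60))
  l <- rep(c(1, 0), each = 60)
  curve <- build_roc(v, l)
  for (policy in c("youden_sens", "youden", "distance")) {
    cp <- select_cutpoint(curve, policy = policy)
    sens <- cp$sens_pct / 100; spec <- cp$spec_pct / 100
    expect_equal(cp$youden, sens + spec - 1)
    expect_equal(cp$distance01, sqrt((1 - sens)^2 + (1 - spec)^2))
    if (spec < 1) expect_equal(cp$lr_plus, sens / (1 - spec))
  }
})

test_that("cutpoint selection matches an exhaustive scan", {
  set.seed(44)
  v <- round(c(rnorm(25, 2), rnorm(25)), 1)
  l <- rep(c(1, 0), each = 25)
  curve <- build_roc(v, l)
  cp <- select_cutpoint(curve, policy = "youden_sens", eps = 0.005)
  pts <- curve$points[is.finite(curve$points$threshold), ]
  J <- pts$sensitivity + pts$specificity - 1
  cand <- which(J >= max(J) - 0.005)
  cand <- cand[pts$sensitivity[cand] == max(pts$sensitivity[cand])]
  expect_equal(cp$cutpoint_cm, min(pts$threshold[cand]))

  cpj <- select_cutpoint(curve, policy = "youden")
  expect_equal(cpj$youden, max(J))
  cpd <- select_cutpoint(curve, policy = "distance")
  d <- sqrt((1 - pts$sensitivity)^2 + (1 - pts$specificity)^2)
  expect_equal(cpd$distance01, min(d))
})

test_that("near-tied Youden values resolve toward higher sensitivity", {
  # two thresholds with J within eps; the more sensitive one must win
  v <- c(1, 2, 3, 4, 5, 6, 7, 8)
  l <- c(0, 0, 0, 1, 0, 1, 1, 1)
  curve <- build_roc(v, l)
  cp <- select_cutpoint(curve, policy = "youden_sens", eps = 0.005)
  strict <- select_cutpoint(curve, policy = "youden")
  expect_gte(cp$sens_pct, strict$sens_pct)
  expect_lte(cp$cutpoint_cm, strict$cutpoint_cm)
})
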