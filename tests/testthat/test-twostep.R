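test_that("log-likelihood distance is symmetric, nonnegative, zero at identity", {
  pv <- c(1, 1)
  a <- list(n = 2, sum = c(2, 0), sumsq = c(2, 0))   # two points at (1,0)
  expect_equal(log_likelihood_distance(a, a, pv), 0)
  set.seed(11)
  for (i in 1:10) {
    b1 <- list(n = 3, sum = rnorm(2, 0, 3), sumsq = abs(rnorm(2, 5, 1)) + 3)
    b2 <- list(n = 5, sum = rnorm(2, 2, 3), sumsq = abs(rnorm(2, 9, 2)) + 6)
    d12 <- log_likelihood_distance(b1, b2, pv)
    expect_gte(d12, 0)
    expect_equal(d12, log_likelihood_distance(b2, b1, pv))
  }
  expect_error(log_likelihood_distance(list(n = 1, sum = 1, sumsq = 1),
                                       list(n = 1, sum = c(1, 2), sumsq = c(1, 4)),
                                       pv),
               "different predictor sets")
})

test_that("distance between singletons grows with separation", {
  pv <- 1
  d <- vapply(seq(0.5, 6, by = 0.5), function(sep) {
    log_likelihood_distance(list(n = 1, sum = 0, sumsq = 0),
                            list(n = 1, sum = sep, sumsq = sep^2), pv)
  }, numeric(1))
  expect_true(all(diff(d) > 0))
})

test_that("CF tree absorbs duplicates and preserves totals", {
  one <- build_cf_tree(matrix(c(1.5, 2.5), 1), pooled_var = c(1, 1))
  expect_equal(length(one$n), 1)
  expect_equal(one$n, 1)
  expect_equal(unname(one$sum[1, ]), c(1.5, 2.5))

  dup <- build_cf_tree(matrix(c(1, 1, 2, 2), 2, 2), pooled_var = c(1, 1))
  expect_equal(length(dup$n), 1)
  expect_equal(dup$n, 2)

  set.seed(12)
  x <- matrix(rnorm(400), 200, 2)
  tr <- build_cf_tree(x, seed = 1)
  expect_equal(sum(tr$n), 200)
  expect_equal(colSums(tr$sum), colSums(x))
  expect_true(all(tr$leaf_of >= 1 & tr$leaf_of <= length(tr$n)))
  expect_error(build_cf_tree(matrix(numeric(0), 3, 0)), "empty predictor")
})

test_that("CF leaves never mix well-separated components", {
  mix <- make_mixture(200, rbind(c(0, 0), c(10, 0)), seed = 31)
  z <- standardize_columns(as.matrix(mix$x))$x
  tr <- build_cf_tree(z, seed = 31)
  for (leaf in seq_along(tr$n)) {
    members <- mix$component[tr$leaf_of == leaf]
    expect_equal(length(unique(members)), 1)
  }
})

test_that("CF tree rebuild compresses past the leaf cap", {
  set.seed(13)
  x <- matrix(rnorm(1600), 800, 2)
  tr <- build_cf_tree(x, seed = 2, max_leaves = 256)
  expect_lte(length(tr$n), 256)
  expect_equal(sum(tr$n), 800)
  expect_gt(tr$threshold, 0)
})

test_that("agglomeration preserves counts and matches the closest-pair oracle", {
  set.seed(14)
  xs <- matrix(rnorm(16), 8, 2)
  pv <- colMeans(sweep(xs, 2, colMeans(xs))^2)
  pool <- cf_pool_from_rows(xs)
  agg <- agglomerate(pool, pv, k_max = 8)
  for (m in agg$models) expect_equal(sum(m$sizes), 8)

  # independent oracle: full re-scan greedy merge with the exported distance
  n <- pool$n; s <- pool$sum; ss <- pool$sumsq
  act <- rep(TRUE, 8)
  oracle <- NULL
  while (sum(act) > 1) {
    best <- NULL; bd <- Inf
    ia <- which(act)
    for (a in ia) for (b in ia) if (a < b) {
      d <- log_likelihood_distance(list(n = n[a], sum = s[a, ], sumsq = ss[a, ]),
                                   list(n = n[b], sum = s[b, ], sumsq = ss[b, ]), pv)
      if (d < bd - 1e-12) { bd <- d; best <- c(a, b) }
    }
    oracle <- rbind(oracle, c(best, bd))
    a <- best[1]; b <- best[2]
    n[a] <- n[a] + n[b]; s[a, ] <- s[a, ] + s[b, ]; ss[a, ] <- ss[a, ] + ss[b, ]
    act[b] <- FALSE
  }
  expect_equal(agg$merge_order$i, oracle[, 1])
  expect_equal(agg$merge_order$j, oracle[, 2])
  expect_equal(agg$merge_order$d, oracle[, 3], tolerance = 1e-9)
})

test_that("identity clustering at k = number of entries", {
  xs <- matrix(c(0, 0, 5, 0, 0, 5), 3, 2, byrow = TRUE)
  pool <- cf_pool_from_rows(xs)
  agg <- agglomerate(pool, c(1, 1), k_max = 3)
  m3 <- agg$models[[which(vapply(agg$models, `[[`, numeric(1), "k") == 3)]]
  expect_equal(sort(m3$assignment), 1:3)
  expect_equal(m3$sizes, c(1, 1, 1))
})

test_that("automatic k matches generating structure on separated mixtures", {
  k1 <- twostep_cluster(make_mixture(300, rbind(c(0, 0)), seed = 1)$x, seed = 1)$k
  expect_equal(k1, 1L)
  k2 <- twostep_cluster(make_mixture(300, rbind(c(0, 0), c(8, 0)), seed = 2)$x,
                        seed = 2)$k
  expect_equal(k2, 2L)
  k3 <- twostep_cluster(make_mixture(300, rbind(c(0, 0), c(8, 0),
                                                c(4, 8 * sqrt(3) / 2)),
                                     seed = 3)$x, seed = 3)$k
  expect_equal(k3, 3L)
})

test_that("well-separated two-component fit recovers means and members", {
  mix <- make_mixture(1000, rbind(c(0, 0), c(6, 0)), seed = 7)
  fit <- twostep_cluster(mix$x, seed = 7)
  expect_equal(fit$k, 2L)
  agree <- max(mean((fit$assignment == 1) == (mix$component == 1)),
               mean((fit$assignment == 2) == (mix$component == 1)))
  expect_gte(agree, 0.95)
  centers <- sort(fit$means[, "a"])
  expect_lt(abs(centers[1] - 0), 0.15)
  expect_lt(abs(centers[2] - 6), 0.15)
  expect_equal(sum(fit$sizes), 1000)
  # the noise dimension dilutes cohesion, so the bound is below the
  # 1D-separation ideal
  expect_gt(fit$silhouette, 0.4)
})

test_that("silhouette agrees with the brute-force oracle and its limits", {
  x2 <- matrix(c(0, 0, 10, 0), 2, 2, byrow = TRUE)
  s2 <- silhouette_coefficient(x2, c(1, 2))
  expect_equal(s2$coefficient, 1, tolerance = 1e-9)

  set.seed(15)
  x <- matrix(rnorm(100), 50, 2)
  lab <- sample(1:3, 50, replace = TRUE)
  ours <- silhouette_coefficient(x, lab)
  expect_equal(ours$coefficient, silhouette_oracle(x, lab), tolerance = 1e-12)
  expect_true(all(ours$widths >= -1 & ours$widths <= 1))

  set.seed(16)
  blob <- matrix(rnorm(4000), 2000, 2)
  rnd <- silhouette_coefficient(blob, sample(1:2, 2000, replace = TRUE))
  expect_lt(abs(rnd$coefficient), 0.1)

  expect_error(silhouette_coefficient(x, rep(1, 50)), "k = 1")
})

test_that("predictor importance ranks by between-cluster separation", {
  set.seed(17)
  lab <- rep(1:2, each = 100)
  x <- data.frame(strong = rnorm(200, ifelse(lab == 1, 0, 6)),
                  weak = rnorm(200, ifelse(lab == 1, 0, 1)),
                  flat = rnorm(200))
  imp <- predictor_importance(x, lab)
  expect_equal(names(imp)[1], "strong")
  expect_equal(unname(imp["strong"]), 1)
  expect_gt(imp["weak"], imp["flat"])

  const <- data.frame(a = x$strong, z = rep(1, 200))
  expect_warning(imp2 <- predictor_importance(const, lab), "zero variance")
  expect_equal(unname(imp2["z"]), 0)
  expect_error(predictor_importance(x, rep(1, 200)), "k = 1")
})

test_that("cluster model JSON serialization carries the summaries", {
  fit <- twostep_cluster(make_mixture(200, rbind(c(0, 0), c(8, 0)), seed = 4)$x,
                         seed = 4)
  f <- tempfile(fileext = ".json")
  write_cluster_model(fit, f)
  back <- jsonlite::read_json(f, simplifyVector = TRUE)
  expect_equal(back$k, fit$k)
  expect_equal(back$sizes, fit$sizes)
  expect_equal(back$silhouette, fit$silhouette, tolerance = 1e-12)
  unlink(f)
})
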