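#' Agglomerate CF entries by log-likelihood distance
#'
#' Second step of two-step clustering: greedy merging of the closest pair of
#' entries under [log_likelihood_distance()] until one cluster remains. Ties
#' in the closest pair are broken by lowest `(i, j)` lexicographic entry
#' index, making the merge order deterministic. For every candidate cluster
#' count `k <= k_max` the entry-to-cluster assignment, cluster summaries and
#' an information criterion are recorded:
#' \eqn{BIC(k) = -2 \sum_c \xi_c + 2 p k \log N}, with two parameters (mean,
#' variance) per predictor per cluster.
#'
#' @param pool CF entry pool (`n`, `sum`, `sumsq`), e.g. leaves of
#'   [build_cf_tree()].
#' @param pooled_var pooled per-predictor variances.
#' @param k_max largest cluster count to record (capped at the entry count).
#' @return list with `models` (per k: `k`, `sizes`, `means`, `variances`,
#'   `assignment` of entries to clusters, `xi_total`, `bic`), `merge_heights`
#'   (named numeric: the merge distance that reduces c clusters to c-1),
#'   `merge_order` (data.frame of merged entry-index pairs), and `n`.
#' @export
agglomerate <- function(pool, pooled_var, k_max = 15) {
  L <- length(pool$n)
  stopifnot(L >= 1, k_max >= 1)
  k_max <- min(k_max, L)
  p <- ncol(pool$sum)
  N <- sum(pool$n)

  n <- pool$n; s <- pool$sum; ss <- pool$sumsq
  active <- rep(TRUE, L)
  member <- seq_len(L)            # entry -> current (lowest-index) group
  xi <- cf_xi(pool, pooled_var)
  xi_total <- sum(xi)

  D <- matrix(Inf, L, L)
  if (L > 1) {
    for (i in seq_len(L - 1)) {
      js <- (i + 1):L
      D[i, js] <- .cf_dist_raw(n[i], s[i, ], ss[i, ], xi[i], n[js],
                               s[js, , drop = FALSE], ss[js, , drop = FALSE],
                               xi[js], rep(pooled_var, each = length(js)))
    }
  }

  snapshot <- function(cnt) {
    act <- which(active)
    lab <- match(member, act)      # clusters numbered by ascending group index
    mu <- s[act, , drop = FALSE] / n[act]
    v <- ss[act, , drop = FALSE] / n[act] - mu^2
    v[v < 0] <- 0
    list(k = cnt, sizes = n[act], means = mu, variances = v,
         assignment = lab, xi_total = xi_total,
         bic = -2 * xi_total + 2 * p * cnt * log(N))
  }

  models <- vector("list", k_max)
  if (L <= k_max) models[[L]] <- snapshot(L)
  merge_heights <- setNames(rep(NA_real_, max(L - 1, 0)),
                            if (L > 1) seq(L, 2) else character(0))
  merge_is <- integer(max(L - 1, 0)); merge_js <- integer(max(L - 1, 0))
  merge_ds <- numeric(max(L - 1, 0)); n_merges <- 0

  # row minima of the upper-triangle distance matrix (value and column),
  # so each step is O(L) instead of an O(L^2) rescan
  rmin <- rep(Inf, L); rmin_j <- rep(NA_integer_, L)
  refresh_row <- function(i) {
    row <- D[i, ]
    rmin[i] <<- min(row)
    rmin_j[i] <<- if (is.finite(rmin[i])) which.min(row) else NA_integer_
  }
  if (L > 1) for (i in seq_len(L - 1)) refresh_row(i)

  cnt <- L
  while (cnt > 1) {
    i <- which.min(rmin)                   # smallest i among ties
    j <- rmin_j[i]; m <- rmin[i]           # smallest j within the row
    merge_heights[[as.character(cnt)]] <- m
    n_merges <- n_merges + 1
    merge_is[n_merges] <- i; merge_js[n_merges] <- j; merge_ds[n_merges] <- m

    xi_total <- xi_total - xi[i] - xi[j]
    n[i] <- n[i] + n[j]
    s[i, ] <- s[i, ] + s[j, ]
    ss[i, ] <- ss[i, ] + ss[j, ]
    active[j] <- FALSE
    member[member == j] <- i
    D[j, ] <- Inf; D[, j] <- Inf
    mu <- s[i, ] / n[i]
    v <- ss[i, ] / n[i] - mu^2
    v[v < 0] <- 0
    xi[i] <- -n[i] * sum(0.5 * log(pooled_var + v))
    xi_total <- xi_total + xi[i]

    rmin[j] <- Inf; rmin_j[j] <- NA_integer_
    stale <- which(rmin_j == j)
    others <- which(active); others <- others[others != i]
    if (length(others) > 0) {
      d <- .cf_dist_raw(n[i], s[i, ], ss[i, ], xi[i], n[others],
                        s[others, , drop = FALSE], ss[others, , drop = FALSE],
                        xi[others], rep(pooled_var, each = length(others)))
      lo <- others < i
      D[others[lo], i] <- d[lo]
      D[i, others[!lo]] <- d[!lo]
      for (r in others[lo]) {
        if (D[r, i] < rmin[r]) { rmin[r] <- D[r, i]; rmin_j[r] <- i }
        else if (!is.na(rmin_j[r]) && rmin_j[r] == i) refresh_row(r)
      }
    }
    refresh_row(i)
    for (r in setdiff(stale, c(i, j))) refresh_row(r)

    cnt <- cnt - 1
    if (cnt <= k_max) models[[cnt]] <- snapshot(cnt)
  }

  list(models = models[!vapply(models, is.null, logical(1))],
       merge_heights = merge_heights,
       merge_order = data.frame(i = merge_is[seq_len(n_merges)],
                                j = merge_js[seq_len(n_merges)],
                                d = merge_ds[seq_len(n_merges)]),
       n = N)
}

#' Automatic cluster-number selection
#'
#' Deterministic rule: every candidate partition recorded by
#' [agglomerate()] is scored as a diagonal Gaussian mixture on the records
#' themselves, with variances shared across components. Component weights
#' and means start from the hard partition (plus, per predictor, from an
#' equal-quantile partition along that predictor, guarding against
#' wrong-axis local optima) and are refined by bounded EM; the best
#' log-likelihood \eqn{\ell(k)} is kept, with variances floored at
#' `var_floor` times the pooled variance. The selected k minimizes
#' \eqn{-2\,\ell(k) + (pk + p + k - 1)\, c_n}, by default with the
#' Hannan-Quinn weight \eqn{c_n = \max(2, 2\log\log n)}, ties to the
#' smaller k. Splitting a structureless Gaussian leaves its mixture density
#' almost unchanged, so the penalty keeps k = 1; genuinely separated
#' components improve \eqn{\ell} far beyond it.
#'
#' @param agg result of [agglomerate()].
#' @param x numeric matrix of the records that were preclustered (same
#'   scale as the pool, i.e. standardized).
#' @param var_floor variance floor as a fraction of the pooled variance
#'   (default 0.05).
#' @param em_iters EM refinement iterations per candidate (default 25).
#' @param penalty information-criterion weight per parameter: `"hq"`
#'   (Hannan-Quinn, default), `"aic"`, or `"bic"`. The lighter `"aic"`
#'   weight suits settings where an extra split is cheap and a missed split
#'   expensive, as in cluster-level health labelling.
#' @return selected integer k.
#' @export
select_k <- function(agg, x, var_floor = 0.05, em_iters = 25,
                     penalty = c("hq", "aic", "bic")) {
  penalty <- match.arg(penalty)
  x <- as.matrix(x)
  n <- nrow(x); p <- ncol(x)
  mu0 <- colMeans(x)
  pooled <- colMeans(sweep(x, 2, mu0)^2)
  pooled[pooled <= 0] <- 1e-12
  floorv <- var_floor * pooled

  cn <- switch(penalty, aic = 2, hq = max(2, 2 * log(log(n))), bic = log(n))
  score <- vapply(agg$models, function(model) {
    fit <- .fit_mixture_k(x, model, floorv, em_iters, cn = cn)
    -2 * fit$ll + fit$n_params * cn
  }, numeric(1))
  ks <- vapply(agg$models, `[[`, numeric(1), "k")
  as.integer(min(ks[score == min(score)]))
}

# Per-component log joint densities log(w_c) + log N(x; mu_c, diag(vv_c)).
# `vv` is a k x p matrix of per-component variances.
.mix_logdens <- function(x, w, mu, vv) {
  k <- length(w)
  ld <- matrix(NA_real_, nrow(x), k)
  for (c in seq_len(k)) {
    z2 <- sweep(sweep(x, 2, mu[c, ]), 2, sqrt(vv[c, ]), "/")^2
    ld[, c] <- log(w[c]) - 0.5 * sum(log(2 * pi * vv[c, ])) - 0.5 * rowSums(z2)
  }
  ld
}

# Soft-EM refinement of a diagonal Gaussian mixture. Two variance
# structures: "shared" (homoscedastic across components -- robust where
# per-component variance freedom would let a narrow-bulk/wide-tail solution
# out-fit a genuine two-component structure) and "free" (per-component
# diagonal variances -- needed where components genuinely differ in
# spread). Deterministic: fixed iteration cap with an absolute-tolerance
# early stop; variances floored at `floorv`.
.em_refine <- function(x, w, mu, vv, floorv, iters = 60,
                       variance = c("shared", "free")) {
  variance <- match.arg(variance)
  n <- nrow(x); k <- length(w)
  vmat <- if (variance == "shared") {
    matrix(rep(pmax(vv, floorv), each = k), k)
  } else {
    pmax(rbind(vv), rep(floorv, each = k))
  }
  ll <- -Inf
  for (it in seq_len(iters + 1)) {
    ld <- .mix_logdens(x, w, mu, vmat)
    mx <- apply(ld, 1, max)
    lse <- mx + log(rowSums(exp(ld - mx)))
    ll_new <- sum(lse)
    done <- it > iters || k == 1 || (is.finite(ll) && ll_new - ll < 1e-8)
    ll <- ll_new
    if (done) break
    r <- exp(ld - lse)
    nk <- colSums(r)
    if (any(nk < 1e-8)) break
    w <- nk / n
    mu <- crossprod(r, x) / nk
    if (variance == "shared") {
      resid2 <- vapply(seq_len(ncol(x)), function(j)
        sum(r * outer(x[, j], mu[, j], "-")^2), numeric(1))
      vmat <- matrix(rep(pmax(resid2 / n, floorv), each = k), k)
    } else {
      vmat <- pmax(crossprod(r, x^2) / nk - mu^2, rep(floorv, each = k))
    }
  }
  list(w = w, mu = mu, vv = vmat, ll = ll, variance = variance,
       n_params = if (variance == "shared") {
         ncol(x) * k + ncol(x) + k - 1
       } else {
         2 * ncol(x) * k + k - 1
       })
}

# Best mixture fit at the cluster count of `model`, over both variance
# structures and several deterministic starts: the agglomerative
# partition's parameters plus, per predictor, an equal-quantile partition
# along that predictor (rank-based, so groups are never empty). The
# alternative starts guard against wrong-axis local optima. Fits are
# compared by penalized likelihood (-2 ll + n_params * cn), so the freer
# variance structure must earn its extra parameters; ties keep the earlier,
# more constrained fit.
.fit_mixture_k <- function(x, model, floorv, iters = 60, cn = 2) {
  k <- model$k
  p <- ncol(x)
  w0 <- model$sizes / sum(model$sizes)
  starts <- list(list(w = w0, mu = rbind(model$means),
                      vv_shared = colSums(model$variances * w0),
                      vv_free = rbind(model$variances)))
  if (k > 1) {
    for (j in seq_len(p)) {
      lab <- as.integer(cut(rank(x[, j], ties.method = "first"), k,
                            labels = FALSE))
      sz <- tabulate(lab, k)
      mu <- rowsum(x, lab) / sz
      vfree <- rowsum(x^2, lab) / sz - mu^2
      starts[[length(starts) + 1]] <-
        list(w = sz / sum(sz), mu = mu,
             vv_shared = colSums(vfree * sz / sum(sz)), vv_free = vfree)
    }
  }
  best <- NULL; best_score <- Inf
  for (st in starts) {
    for (variance in c("shared", "free")) {
      fit <- .em_refine(x, st$w, st$mu,
                        if (variance == "shared") st$vv_shared else st$vv_free,
                        floorv, iters, variance = variance)
      score <- -2 * fit$ll + fit$n_params * cn
      if (score < best_score - 1e-9) { best <- fit; best_score <- score }
    }
  }
  best
}

#' Silhouette coefficient
#'
#' Mean over records of \eqn{(b - a) / \max(a, b)} with `a` the mean
#' distance to the other members of the record's own cluster (0 for a
#' singleton cluster) and `b` the lowest mean distance to the members of
#' another cluster. Euclidean distance; pass standardized predictors for
#' scale-free cohesion/separation. Values in \[-1, 1\]; 0.5-1 indicates good
#' clustering structure.
#'
#' @param x numeric matrix of predictor values.
#' @param assignment integer cluster labels, k >= 2, all clusters nonempty.
#' @return list with `coefficient` (mean silhouette) and `widths`
#'   (per-record values).
#' @export
silhouette_coefficient <- function(x, assignment) {
  x <- as.matrix(x)
  assignment <- as.integer(factor(assignment))
  k <- max(assignment)
  if (k < 2) stop("silhouette undefined for k = 1")
  n <- nrow(x)
  D <- as.matrix(dist(x))
  sizes <- tabulate(assignment, k)
  sumd <- t(rowsum(D, assignment))      # n x k: total distance to each cluster
  own <- cbind(seq_len(n), assignment)
  a <- ifelse(sizes[assignment] > 1, sumd[own] / (sizes[assignment] - 1), 0)
  meand <- sweep(sumd, 2, sizes, "/")
  meand[own] <- Inf
  b <- apply(meand, 1, min)
  s <- ifelse(pmax(a, b) > 0, (b - a) / pmax(a, b), 0)
  list(coefficient = mean(s), widths = s)
}

#' Predictor importance for a clustering
#'
#' Per-predictor one-way between-cluster F statistic, normalized by the
#' maximum so the strongest predictor scores 1.0. A predictor with zero
#' total variance scores 0 with a warning.
#'
#' @param x numeric matrix or data.frame of predictors.
#' @param assignment cluster labels, k >= 2.
#' @return named numeric scores in \[0, 1\], sorted decreasing.
#' @export
predictor_importance <- function(x, assignment) {
  x <- as.matrix(x)
  assignment <- as.integer(factor(assignment))
  k <- max(assignment)
  if (k < 2) stop("predictor importance undefined for k = 1")
  n <- nrow(x)
  f <- vapply(seq_len(ncol(x)), function(j) {
    v <- x[, j]
    if (var(v) == 0) {
      warning("predictor '", colnames(x)[j], "' has zero variance; score 0")
      return(0)
    }
    gm <- tapply(v, assignment, mean)
    gn <- tabulate(assignment, k)
    ssb <- sum(gn * (gm - mean(v))^2)
    ssw <- sum((v - gm[assignment])^2)
    if (ssw == 0) return(Inf)
    (ssb / (k - 1)) / (ssw / (n - k))
  }, numeric(1))
  names(f) <- colnames(x)
  top <- max(f)
  score <- if (top == 0) f else {
    if (is.infinite(top)) ifelse(is.infinite(f), 1, 0) else f / top
  }
  sort(score, decreasing = TRUE)
}

#' Two-step cluster analysis
#'
#' SPSS-style two-step clustering of continuous predictors: standardize,
#' precluster into CF-tree leaves ([build_cf_tree()]), agglomerate leaves by
#' log-likelihood distance ([agglomerate()]), and pick the cluster count
#' automatically ([select_k()]). Clusters are relabelled in decreasing size
#' order.
#'
#' @param x data.frame or matrix of continuous predictors (columns named).
#' @param k_max largest candidate cluster count (default 8).
#' @param seed seed for the CF-tree insertion shuffle.
#' @param standardize standardize predictors to zero mean / unit SD first
#'   (default TRUE; the predictors are on incommensurate scales).
#' @param max_leaves CF-tree leaf cap (default 512).
#' @param var_floor,k_penalty passed to [select_k()].
#' @return object of class `twostep_cluster`: `k`, `sizes`, `assignment`
#'   (per record), `means`/`variances` on the original scale, cluster
#'   sufficient statistics on the standardized scale (`stats_std`),
#'   `center`/`scale`/`pooled_var` of the standardization,
#'   `silhouette`, `importance`, `bic_trace`, `merge_heights`, `predictors`.
#' @export
#' @examples
#' set.seed(1)
#' x <- data.frame(a = c(rnorm(60), rnorm(60, 8)), b = rnorm(120))
#' fit <- twostep_cluster(x, seed = 1)
#' fit$k
twostep_cluster <- function(x, k_max = 8, seed = 1, standardize = TRUE,
                            max_leaves = 512, var_floor = 0.05,
                            k_penalty = "hq") {
  x <- as.data.frame(x)
  if (ncol(x) == 0) stop("empty predictor list")
  if (any(!vapply(x, is.numeric, logical(1))))
    stop("all predictors must be continuous")
  xm <- as.matrix(x)
  std <- if (standardize) standardize_columns(xm)
         else list(x = xm, center = rep(0, ncol(xm)), scale = rep(1, ncol(xm)))
  z <- std$x
  mu <- colMeans(z)
  pooled_var <- colMeans(sweep(z, 2, mu)^2)
  pooled_var[pooled_var <= 0] <- 1e-12

  tree <- build_cf_tree(z, pooled_var, max_leaves = max_leaves, seed = seed)
  pool <- cf_pool(tree$n, tree$sum, tree$sumsq)
  agg <- agglomerate(pool, pooled_var, k_max = k_max)
  k <- select_k(agg, z, var_floor = var_floor, penalty = k_penalty)
  model <- agg$models[[which(vapply(agg$models, `[[`, numeric(1), "k") == k)]]

  leaf_cluster <- model$assignment
  assignment <- leaf_cluster[tree$leaf_of]

  # Final membership pass: the selected partition's mixture parameters are
  # refined by the same shared-variance EM select_k scores (hierarchical
  # plus quantile-partition starts, best likelihood wins) and each case is
  # assigned to its maximum-posterior component. This detaches the boundary
  # from the precluster granularity and places it at the weighted
  # equal-posterior surface rather than the unweighted midpoint of a greedy
  # merge.
  mixture <- NULL
  if (k >= 2) {
    floorv <- var_floor * pooled_var
    cn <- switch(k_penalty, aic = 2, hq = max(2, 2 * log(log(nrow(z)))),
                 bic = log(nrow(z)))
    fit <- .fit_mixture_k(z, model, floorv, cn = cn)
    post <- .mix_logdens(z, fit$w, fit$mu, fit$vv)
    new_assignment <- max.col(post, ties.method = "first")
    if (!any(tabulate(new_assignment, k) == 0)) {
      assignment <- new_assignment
      mixture <- fit[c("w", "mu", "vv", "variance")]
    }
  }

  ord <- order(-tabulate(assignment, k), seq_len(k))
  relabel <- match(seq_len(k), ord)
  assignment <- relabel[assignment]
  if (!is.null(mixture)) {
    mixture$w <- mixture$w[ord]
    mixture$mu <- mixture$mu[ord, , drop = FALSE]
    mixture$vv <- mixture$vv[ord, , drop = FALSE]
  }

  sizes <- tabulate(assignment, k)
  means <- rowsum(xm, assignment) / sizes
  m2 <- rowsum(xm^2, assignment) / sizes
  variances <- pmax(m2 - means^2, 0)
  sum_std <- rowsum(z, assignment)
  sumsq_std <- rowsum(z^2, assignment)

  sil <- if (k >= 2) silhouette_coefficient(z, assignment) else NULL
  imp <- if (k >= 2) predictor_importance(xm, assignment) else NULL

  structure(list(
    k = k, n = nrow(xm), sizes = sizes, assignment = assignment,
    means = means, variances = variances, mixture = mixture,
    stats_std = cf_pool(sizes, sum_std, sumsq_std),
    center = std$center, scale = std$scale, pooled_var = pooled_var,
    silhouette = if (is.null(sil)) NA_real_ else sil$coefficient,
    importance = imp,
    bic_trace = setNames(vapply(agg$models, `[[`, numeric(1), "bic"),
                         vapply(agg$models, `[[`, numeric(1), "k")),
    merge_heights = agg$merge_heights,
    predictors = colnames(x), n_leaves = length(tree$n)
  ), class = "twostep_cluster")
}

#' @export
print.twostep_cluster <- function(x, ...) {
  cat("Two-step cluster model: k =", x$k, "on", x$n, "records (",
      length(x$predictors), "predictors,", x$n_leaves, "CF leaves )\n")
  cat("  sizes:", paste(x$sizes, collapse = ", "), "\n")
  if (!is.na(x$silhouette))
    cat("  silhouette:", sprintf("%.3f", x$silhouette), "\n")
  if (!is.null(x$importance))
    cat("  predictor importance:",
        paste(sprintf("%s=%.2f", names(x$importance), x$importance),
              collapse = ", "), "\n")
  invisible(x)
}

#' Serialize a cluster model to JSON
#'
#' @param model a [twostep_cluster()] fit.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_cluster_model <- function(model, path) {
  obj <- list(k = model$k, n = model$n, sizes = model$sizes,
              predictors = model$predictors,
              means = as.data.frame(model$means),
              variances = as.data.frame(model$variances),
              silhouette = model$silhouette,
              importance = as.list(model$importance),
              bic_trace = as.list(model$bic_trace))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
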