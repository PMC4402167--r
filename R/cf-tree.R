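# Clustering-feature (CF) sufficient statistics: a set of entries is held as
# parallel arrays -- counts `n` (length L), per-variable `sum` and `sumsq`
# (L x p matrices). Merging entries adds counts and sums exactly, so cluster
# means and variances derived from a pool are exact regardless of merge order.

cf_pool <- function(n, sum, sumsq) {
  sum <- rbind(sum); sumsq <- rbind(sumsq)
  stopifnot(length(n) == nrow(sum), all(dim(sum) == dim(sumsq)), all(n >= 1))
  list(n = n, sum = sum, sumsq = sumsq)
}

cf_pool_from_rows <- function(x) {
  x <- as.matrix(x)
  cf_pool(rep(1, nrow(x)), x, x^2)
}

# Within-entry MLE variances, clipped at 0 against roundoff.
cf_variances <- function(pool) {
  mu <- pool$sum / pool$n
  v <- pool$sumsq / pool$n - mu^2
  v[v < 0] <- 0
  v
}

# Log-likelihood term xi_v = -N_v * sum_j 0.5 * log(pooled_var_j + var_vj),
# vectorized over the entries of a pool.
cf_xi <- function(pool, pooled_var) {
  v <- cf_variances(pool)
  -pool$n * rowSums(0.5 * log(sweep(v, 2, pooled_var, "+")))
}

# Inline xi for raw arrays (no checks); n vector, s/ss matrices, pvr the
# pooled variances pre-expanded with rep(pv, each = nrow(s)).
.xi_raw <- function(n, s, ss, pvr) {
  v <- ss / n - (s / n)^2
  v[v < 0] <- 0
  -n * rowSums(0.5 * log(v + pvr))
}

# Distances from one entry (n0, s0, ss0, xi0) to L entries held in raw
# arrays. `pvr` as in .xi_raw for L rows.
.cf_dist_raw <- function(n0, s0, ss0, xi0, ln, ls, lss, lxi, pvr) {
  L <- length(ln)
  nm <- ln + n0
  sm <- ls + rep(s0, each = L)
  ssm <- lss + rep(ss0, each = L)
  vm <- ssm / nm - (sm / nm)^2
  vm[vm < 0] <- 0
  xim <- -nm * rowSums(0.5 * log(vm + pvr))
  d <- lxi + xi0 - xim
  d[d < 0] <- 0
  d
}

#' Log-likelihood merge distance between two CF entries
#'
#' The distance used throughout two-step clustering: the decrease in summed
#' entry log-likelihood caused by merging, \eqn{d(a,b) = \xi_a + \xi_b -
#' \xi_{a \cup b}} with \eqn{\xi_v = -N_v \sum_j \frac{1}{2}\log(\hat\sigma^2_j
#' + \hat\sigma^2_{v,j})}, where \eqn{\hat\sigma^2_j} is the pooled variance
#' of predictor j over the whole data set and \eqn{\hat\sigma^2_{v,j}} the
#' within-entry variance. Symmetric and nonnegative; zero for two identical
#' point masses at the same location.
#'
#' @param a,b entries: lists with `n` (count), `sum`, `sumsq` (numeric
#'   vectors over the same predictors).
#' @param pooled_var pooled per-predictor variances (> 0).
#' @return nonnegative scalar.
#' @export
#' @examples
#' a <- list(n = 1, sum = c(0, 0), sumsq = c(0, 0))
#' b <- list(n = 1, sum = c(3, 0), sumsq = c(9, 0))
#' log_likelihood_distance(a, b, pooled_var = c(1, 1))
log_likelihood_distance <- function(a, b, pooled_var) {
  if (length(a$sum) != length(b$sum))
    stop("entries are over different predictor sets")
  pvr <- rbind(pooled_var)
  xa <- .xi_raw(a$n, rbind(a$sum), rbind(a$sumsq), pvr)
  xb <- .xi_raw(b$n, rbind(b$sum), rbind(b$sumsq), pvr)
  xm <- .xi_raw(a$n + b$n, rbind(a$sum + b$sum), rbind(a$sumsq + b$sumsq), pvr)
  max(xa + xb - xm, 0)
}

#' Precluster records into CF-tree leaf entries
#'
#' First step of two-step clustering: records are absorbed sequentially into
#' leaf entries. A record joins its nearest leaf (by
#' [log_likelihood_distance()]) when that distance does not exceed the
#' current threshold, and starts a new leaf otherwise. The nearest leaf is
#' found by exact vectorised search over all leaves. When the leaf count
#' exceeds `max_leaves` the threshold is grown (to at least the median
#' nearest-neighbour distance among current leaves) and the leaves are
#' re-inserted under the larger threshold, BIRCH-style. Insertion order is
#' shuffled by `seed`; the algorithm is order-dependent, which the rebuild
#' schedule and threshold rule keep mild.
#'
#' @param x numeric matrix of (standardized) predictor values, n x p, p >= 1.
#' @param pooled_var pooled per-predictor variances; defaults to the MLE
#'   variances of `x`.
#' @param threshold initial absorption threshold (default 0: only exact
#'   duplicates merge until the first rebuild).
#' @param max_leaves leaf-count cap triggering a rebuild (default 512).
#' @param seed integer seed for the insertion-order shuffle; `NULL` keeps
#'   input order.
#' @return object of class `cf_tree`: the leaf pool (`n`, `sum`, `sumsq`),
#'   `leaf_of` (leaf index per input record), `threshold`, `pooled_var`.
#' @export
build_cf_tree <- function(x, pooled_var = NULL, threshold = 0,
                          max_leaves = 512, seed = NULL) {
  x <- as.matrix(x)
  if (ncol(x) == 0) stop("empty predictor list")
  if (nrow(x) == 0) stop("no records")
  n <- nrow(x); p <- ncol(x)
  if (is.null(pooled_var)) {
    mu <- colMeans(x)
    pooled_var <- colMeans(sweep(x, 2, mu)^2)
  }
  pooled_var[pooled_var <= 0] <- 1e-12
  ord <- if (is.null(seed)) seq_len(n) else {
    set.seed(substream_seed(seed, "cf_shuffle")); sample(n)
  }
  xi_singleton <- -sum(0.5 * log(pooled_var))

  cap <- min(n, max_leaves + 1)
  ln <- numeric(cap); ls <- matrix(0, cap, p); lss <- matrix(0, cap, p)
  lxi <- numeric(cap)
  L <- 0
  leaf_of <- integer(n)
  x2 <- x^2

  insert_one <- function(n0, s0, ss0, xi0) {
    if (L > 0) {
      sq <- seq_len(L)
      d <- .cf_dist_raw(n0, s0, ss0, xi0, ln[sq], ls[sq, , drop = FALSE],
                        lss[sq, , drop = FALSE], lxi[sq],
                        rep(pooled_var, each = L))
      jmin <- which.min(d)
      if (d[jmin] <= threshold) {
        ln[jmin] <<- ln[jmin] + n0
        ls[jmin, ] <<- ls[jmin, ] + s0
        lss[jmin, ] <<- lss[jmin, ] + ss0
        v <- lss[jmin, ] / ln[jmin] - (ls[jmin, ] / ln[jmin])^2
        v[v < 0] <- 0
        lxi[jmin] <<- -ln[jmin] * sum(0.5 * log(v + pooled_var))
        return(jmin)
      }
    }
    if (L + 1 > nrow(ls)) {
      grow <- min(n, 2 * nrow(ls))
      ls <<- rbind(ls, matrix(0, grow - nrow(ls), p))
      lss <<- rbind(lss, matrix(0, grow - nrow(lss), p))
      ln <<- c(ln, numeric(grow - length(ln)))
      lxi <<- c(lxi, numeric(grow - length(lxi)))
    }
    L <<- L + 1
    ln[L] <<- n0; ls[L, ] <<- s0; lss[L, ] <<- ss0; lxi[L] <<- xi0
    L
  }

  rebuild <- function() {
    sq <- seq_len(L)
    pvr <- rep(pooled_var, each = L)
    nn <- vapply(sq, function(i) {
      d <- .cf_dist_raw(ln[i], ls[i, ], lss[i, ], lxi[i], ln[sq],
                        ls[sq, , drop = FALSE], lss[sq, , drop = FALSE],
                        lxi[sq], pvr)
      min(d[-i])
    }, numeric(1))
    threshold <<- max(2 * threshold, stats::median(nn), 1e-8)
    old_n <- ln[sq]; old_s <- ls[sq, , drop = FALSE]
    old_ss <- lss[sq, , drop = FALSE]; old_xi <- lxi[sq]
    oldL <- L
    L <<- 0
    ln[] <<- 0; ls[] <<- 0; lss[] <<- 0; lxi[] <<- 0
    remap <- integer(oldL)
    for (i in seq_len(oldL))
      remap[i] <- insert_one(old_n[i], old_s[i, ], old_ss[i, ], old_xi[i])
    seen <- leaf_of > 0
    leaf_of[seen] <<- remap[leaf_of[seen]]
  }

  for (r in ord) {
    leaf_of[r] <- insert_one(1, x[r, ], x2[r, ], xi_singleton)
    while (L > max_leaves) rebuild()
  }

  sq <- seq_len(L)
  structure(list(n = ln[sq], sum = ls[sq, , drop = FALSE],
                 sumsq = lss[sq, , drop = FALSE],
                 leaf_of = leaf_of, threshold = threshold,
                 pooled_var = pooled_var),
            class = "cf_tree")
}
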