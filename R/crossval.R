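#' Split a cohort into training and validation halves
#'
#' Seeded, disjoint and exhaustive. With `stratified = TRUE` the split is
#' drawn within gender, keeping gender proportions equal across halves to
#' within one subject.
#'
#' @param cohort data.frame, n >= 2.
#' @param fraction training fraction in (0, 1); default 0.5.
#' @param seed integer seed.
#' @param stratified stratify the split by gender (default FALSE).
#' @return list with `train` and `test` data.frames and attribute
#'   `train_rows`.
#' @export
split_cohort <- function(cohort, fraction = 0.5, seed = 1, stratified = FALSE) {
  n <- nrow(cohort)
  if (n < 2) stop("need at least 2 records to split")
  if (fraction <= 0 || fraction >= 1) stop("fraction must lie in (0, 1)")
  set.seed(substream_seed(seed, "split"))
  if (stratified) {
    rows <- unlist(lapply(split(seq_len(n), cohort$gender), function(idx) {
      sample(idx, round(fraction * length(idx)))
    }), use.names = FALSE)
  } else {
    rows <- sample(n, round(fraction * n))
  }
  rows <- sort(rows)
  out <- list(train = cohort[rows, , drop = FALSE],
              test = cohort[-rows, , drop = FALSE])
  attr(out, "train_rows") <- rows
  out
}

#' Assign records to the clusters of a fitted model by centroid distance
#'
#' Each record (a singleton CF entry, standardized with the model's frozen
#' center/scale) is assigned to the cluster minimizing the log-likelihood
#' distance to that cluster's sufficient statistics, with the model's frozen
#' pooled variances. Ties go to the lowest-index cluster. Records with
#' missing predictor values are skipped (`NA` assignment) with a warning.
#'
#' @param model a [twostep_cluster()] fit.
#' @param newdata data.frame containing the model's predictor columns (on
#'   the same, possibly log-transformed, scale the model was fitted on).
#' @param weighting `"prior"` (default) assigns by maximum posterior under
#'   the model's frozen fitted mixture (the same rule that produced the
#'   model's own membership), falling back to prior-weighted log-likelihood
#'   distance when no mixture is stored; `"none"` uses the pure
#'   log-likelihood distance to the cluster summaries.
#' @return integer vector of cluster assignments (NA for skipped records).
#' @export
assign_by_centroids <- function(model, newdata, weighting = c("prior", "none")) {
  weighting <- match.arg(weighting)
  stopifnot(inherits(model, "twostep_cluster"))
  miss <- setdiff(model$predictors, names(newdata))
  if (length(miss) > 0) stop("missing predictors: ", paste(miss, collapse = ", "))
  xm <- as.matrix(newdata[, model$predictors, drop = FALSE])
  ok <- complete.cases(xm)
  if (any(!ok)) warning(sum(!ok), " record(s) with missing predictor values skipped")
  out <- rep(NA_integer_, nrow(xm))
  if (!any(ok)) return(out)
  z <- sweep(sweep(xm[ok, , drop = FALSE], 2, model$center), 2, model$scale, "/")
  if (weighting == "prior" && !is.null(model$mixture)) {
    mx <- model$mixture
    post <- .mix_logdens(z, mx$w, mx$mu, mx$vv)
    out[ok] <- max.col(post, ties.method = "first")
    return(out)
  }
  pv <- model$pooled_var
  st <- model$stats_std
  xi_c <- cf_xi(st, pv)
  xi0 <- -sum(0.5 * log(pv))
  m <- nrow(z)
  D <- matrix(NA_real_, m, model$k)
  for (c in seq_len(model$k)) {
    nm <- st$n[c] + 1
    sm <- sweep(z, 2, st$sum[c, ], "+")
    ssm <- sweep(z^2, 2, st$sumsq[c, ], "+")
    vm <- ssm / nm - (sm / nm)^2
    vm[vm < 0] <- 0
    xim <- -nm * rowSums(0.5 * log(sweep(vm, 2, pv, "+")))
    D[, c] <- xi_c[c] + xi0 - xim
    if (weighting == "prior") D[, c] <- D[, c] - log(st$n[c] / sum(st$n))
  }
  out[ok] <- max.col(-D, ties.method = "first")
  out
}

#' Align cluster labels of a confusion matrix
#'
#' Finds the column permutation maximizing the diagonal sum, by exhaustive
#' search over permutations in lexicographic order (exact for k <= 8, far
#' beyond the cluster counts that occur here); ties keep the
#' lexicographically first permutation.
#'
#' @param confusion square matrix of counts.
#' @return list with `perm` (new column order) and `aligned` (the permuted
#'   matrix).
#' @export
#' @examples
#' align_labels(matrix(c(0, 10, 9, 1), 2))
align_labels <- function(confusion) {
  confusion <- as.matrix(confusion)
  k <- nrow(confusion)
  stopifnot(k == ncol(confusion))
  if (k > 8) stop("exhaustive label alignment supports k <= 8")
  perms <- .permutations(k)
  best <- NULL; best_sum <- -Inf
  for (i in seq_len(nrow(perms))) {
    pm <- perms[i, ]
    s <- sum(confusion[cbind(seq_len(k), pm)])
    if (s > best_sum) { best_sum <- s; best <- pm }
  }
  list(perm = best, aligned = confusion[, best, drop = FALSE])
}

# All permutations of 1..k, rows in lexicographic order.
.permutations <- function(k) {
  if (k == 1) return(matrix(1L, 1, 1))
  sub <- .permutations(k - 1)
  out <- matrix(0L, 0, k)
  for (first in seq_len(k)) {
    rest <- setdiff(seq_len(k), first)
    out <- rbind(out, cbind(first, matrix(rest[sub], nrow(sub))))
  }
  unname(out)
}

#' Cohen's kappa for a confusion matrix
#'
#' Chance-corrected agreement \eqn{\kappa = (p_o - p_e)/(1 - p_e)} with
#' observed agreement \eqn{p_o} the diagonal fraction and expected agreement
#' \eqn{p_e = \sum_i r_i c_i / N^2}. The p-value uses the large-sample
#' variance of kappa under independence (Fleiss), a standard asymptotic
#' test.
#'
#' @param confusion square matrix of counts, grand total > 0.
#' @return list with `kappa`, `p_o`, `p_e`, `z`, `p`, `n`.
#' @export
#' @examples
#' m <- matrix(c(609, 0, 31, 0, 50, 0, 0, 14, 247), 3, byrow = TRUE)
#' cohens_kappa(m)$kappa   # 0.902
cohens_kappa <- function(confusion) {
  confusion <- as.matrix(confusion)
  stopifnot(nrow(confusion) == ncol(confusion))
  N <- sum(confusion)
  if (N <= 0) stop("empty confusion matrix")
  p_o <- sum(diag(confusion)) / N
  r <- rowSums(confusion) / N
  c_ <- colSums(confusion) / N
  p_e <- sum(r * c_)
  if (p_e >= 1) stop("kappa undefined: expected agreement is 1")
  kappa <- (p_o - p_e) / (1 - p_e)
  var0 <- (p_e + p_e^2 - sum(r * c_ * (r + c_))) / (N * (1 - p_e)^2)
  z <- if (var0 > 0) kappa / sqrt(var0) else NA_real_
  list(kappa = kappa, p_o = p_o, p_e = p_e, z = z,
       p = if (is.na(z)) NA_real_ else 2 * pnorm(-abs(z)), n = N)
}

# Pad a (possibly non-square) contingency table of counts to square, keeping
# dimnames 1..k.
.square_confusion <- function(a, b) {
  k <- max(max(a, na.rm = TRUE), max(b, na.rm = TRUE))
  tab <- table(factor(a, levels = seq_len(k)), factor(b, levels = seq_len(k)))
  matrix(tab, k, k)
}

#' Split-half cross-validation of the two-step clustering
#'
#' The cohort is split in halves. The training half is clustered
#' ([twostep_cluster()] on a common predictor set, with the cohort-level
#' log-transform decision replayed on both halves). The validation half is
#' then clustered twice: by the training model ([assign_by_centroids()],
#' with the training half's frozen transforms, scaling and mixture) and
#' independently from scratch. The two label sets are aligned
#' ([align_labels()]) and their agreement summarized by Cohen's kappa --
#' the published protocol's single pooled comparison of the testing half.
#'
#' @inheritParams cluster_strata
#' @param fraction training fraction (default 0.5; the published comparison
#'   used half the sample).
#' @param stratified stratify the split by gender.
#' @param predictors common clustering predictor columns (default HOMA2-IR,
#'   the one predictor every stratified analysis shares).
#' @return list with `kappa` (overall [cohens_kappa()] result), `k_train`,
#'   `k_test`, `confusion` (aligned confusion matrix of the validation
#'   half), the fitted `train_model` / `test_model`, and the `split`.
#' @export
crossval_clustering <- function(cohort, fraction = 0.5, seed = 1,
                                stratified = FALSE, k_max = 6, alpha = 0.05,
                                cutoff = 2.00,
                                predictors = "homa2ir") {
  stopifnot(all(predictors %in% names(cohort)))
  trans <- log_transform_if_nonnormal(cohort, predictors, alpha = alpha)
  halves <- split_cohort(trans$table, fraction = fraction, seed = seed,
                         stratified = stratified)
  m1 <- twostep_cluster(halves$train[, predictors, drop = FALSE],
                        k_max = k_max,
                        seed = substream_seed(seed, "cv_train"),
                        k_penalty = "bic")
  m2 <- twostep_cluster(halves$test[, predictors, drop = FALSE],
                        k_max = k_max,
                        seed = substream_seed(seed, "cv_test"),
                        k_penalty = "bic")
  a <- assign_by_centroids(m1, halves$test[, predictors, drop = FALSE])
  b <- m2$assignment
  keep <- !is.na(a)
  conf <- .square_confusion(a[keep], b[keep])
  al <- align_labels(conf)
  list(kappa = cohens_kappa(al$aligned), k_train = m1$k, k_test = m2$k,
       confusion = al$aligned, transform_log = trans$log,
       train_model = m1, test_model = m2, split = halves)
}
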