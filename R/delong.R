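# Placement values: V10_i = fraction of controls below case i (ties 0.5),
# V01_j = fraction of cases above control j. mean(V10) = mean(1 - V01) = AUC.
.placements <- function(pos, neg) {
  m <- length(pos); n <- length(neg)
  r_all <- rank(c(pos, neg))
  v10 <- (r_all[seq_len(m)] - rank(pos)) / n
  v01 <- 1 - (r_all[m + seq_len(n)] - rank(neg)) / m
  list(v10 = v10, v01 = v01, auc = mean(v10))
}

#' DeLong variance of a single empirical AUC
#'
#' Structural-components estimate `var(V10)/m + var(V01)/n` from the
#' placement values of the `m` cases and `n` controls.
#'
#' @param values numeric marker.
#' @param labels binary outcome (TRUE = case).
#' @return list with `auc` and `variance`.
#' @export
delong_auc_variance <- function(values, labels) {
  labels <- as.logical(labels)
  if (!any(labels) || all(labels)) stop("both outcome classes must be nonempty")
  pl <- .placements(values[labels], values[!labels])
  list(auc = pl$auc,
       variance = var(pl$v10) / length(pl$v10) + var(pl$v01) / length(pl$v01))
}

#' DeLong comparison of two AUCs of the same marker on two subject subsets
#'
#' Compares the AUC of `values` against `labels` on subset A with that on
#' subset B. When the subsets differ (the stepwise phenotype-exclusion
#' scenarios drop subjects, so they do), the unpaired two-sample form is
#' used: `var = varA + varB` from each curve's structural components. When
#' the two subsets are identical the curves coincide, and `z = 0`, `p = 1`
#' is returned directly.
#'
#' @param values numeric marker over all subjects.
#' @param labels binary outcome over all subjects.
#' @param subset_a,subset_b index vectors (integer or logical) into
#'   `values`/`labels` defining the two curves; default the full set.
#' @return list with `auc_a`, `auc_b`, `variance`, `z`, `p`.
#' @export
#' @examples
#' set.seed(1)
#' v <- c(rnorm(50, 1), rnorm(50))
#' l <- rep(c(TRUE, FALSE), each = 50)
#' delong_test(v, l)$p   # identical subsets: 1
delong_test <- function(values, labels, subset_a = seq_along(values),
                        subset_b = seq_along(values)) {
  labels <- as.logical(labels)
  ia <- seq_along(values)[subset_a]
  ib <- seq_along(values)[subset_b]
  a <- delong_auc_variance(values[ia], labels[ia])
  b <- delong_auc_variance(values[ib], labels[ib])
  if (length(ia) == length(ib) && all(sort(ia) == sort(ib)))
    return(list(auc_a = a$auc, auc_b = b$auc, variance = 0, z = 0, p = 1))
  v <- a$variance + b$variance
  if (!is.finite(v) || v <= 0) stop("degenerate DeLong variance")
  z <- (a$auc - b$auc) / sqrt(v)
  list(auc_a = a$auc, auc_b = b$auc, variance = v, z = z,
       p = 2 * pnorm(-abs(z)))
}

#' Stepwise phenotype-exclusion ROC report
#'
#' For each gender, builds the three scenario curves (all six phenotypes;
#' without MONW and MHO; HNW vs MDO only), selects a WC cutpoint on each
#' ([select_cutpoint()]), and compares every scenario pair with the unpaired
#' DeLong test.
#'
#' @param table phenotyped cohort (needs `gender`, `wc_cm`, `phenotype`).
#' @param policy,eps passed to [select_cutpoint()].
#' @return object of class `stepwise_report`: `reports` (one row per gender
#'   x scenario: n, AUC, cutpoint and indices), `delong` (pairwise
#'   comparisons per gender), `curves` (named list of [build_roc()]
#'   objects).
#' @export
stepwise_report <- function(table, policy = "youden_sens", eps = 0.005) {
  scenarios <- c("six_group", "four_group", "two_group")
  reports <- NULL; delong <- NULL; curves <- list()
  for (g in c("F", "M")) {
    sub <- table[table$gender == g, , drop = FALSE]
    if (nrow(sub) == 0) stop("empty gender subset: ", g)
    flt <- lapply(scenarios, function(sc) scenario_filter(sub, sc))
    names(flt) <- scenarios
    for (sc in scenarios) {
      f <- flt[[sc]]
      curve <- build_roc(f$table$wc_cm, f$sick)
      curves[[paste(g, sc, sep = "_")]] <- curve
      cp <- select_cutpoint(curve, policy = policy, eps = eps)
      reports <- rbind(reports,
                       cbind(data.frame(gender = g, scenario = sc,
                                        n = nrow(f$table), auc = curve$auc),
                             cp))
    }
    sick_all <- sub$phenotype %in% c("MONW", "OW_SICK", "MDO")
    idx_of <- lapply(flt, function(f) which(sub$id %in% f$table$id))
    pairs <- list(c("two_group", "four_group"), c("two_group", "six_group"),
                  c("four_group", "six_group"))
    for (pr in pairs) {
      dt <- delong_test(sub$wc_cm, sick_all, idx_of[[pr[1]]], idx_of[[pr[2]]])
      delong <- rbind(delong,
                      data.frame(gender = g, scenario_a = pr[1],
                                 scenario_b = pr[2], auc_a = dt$auc_a,
                                 auc_b = dt$auc_b, z = dt$z, p = dt$p))
    }
  }
  structure(list(reports = reports, delong = delong, curves = curves),
            class = "stepwise_report")
}

#' @export
print.stepwise_report <- function(x, ...) {
  cat("Stepwise WC cutpoint report\n")
  r <- x$reports
  for (i in seq_len(nrow(r))) {
    cat(sprintf("  %s %-10s n=%4d AUC %.3f  cutpoint %6.2f cm  sens %.1f%%  spec %.1f%%  J %.2f\n",
                r$gender[i], r$scenario[i], r$n[i], r$auc[i], r$cutpoint_cm[i],
                r$sens_pct[i], r$spec_pct[i], r$youden_2dp[i]))
  }
  invisible(x)
}
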