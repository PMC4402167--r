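#' Filter phenotyped records for a ROC scenario
#'
#' Stepwise phenotype exclusion: `six_group` keeps all six phenotypes;
#' `four_group` drops the atypical MONW and MHO (whose anomalous WC
#' behaviour acts as noise on the curve); `two_group` keeps only HNW and MDO
#' (the overweight "transition" groups removed as well). The binary outcome
#' is metabolically sick: MONW, OW_SICK or MDO among the retained
#' phenotypes.
#'
#' @param table data.frame with a `phenotype` column.
#' @param scenario `"six_group"`, `"four_group"` or `"two_group"`.
#' @return list with `table` (retained rows) and `sick` (logical outcome).
#' @export
scenario_filter <- function(table, scenario = c("six_group", "four_group",
                                                "two_group")) {
  scenario <- match.arg(scenario)
  keep_ph <- switch(scenario,
    six_group  = c("HNW", "MONW", "OW_HEALTHY", "OW_SICK", "MHO", "MDO"),
    four_group = c("HNW", "OW_HEALTHY", "OW_SICK", "MDO"),
    two_group  = c("HNW", "MDO"))
  out <- table[table$phenotype %in% keep_ph, , drop = FALSE]
  sick <- out$phenotype %in% c("MONW", "OW_SICK", "MDO")
  if (!any(sick) || all(sick))
    stop("scenario '", scenario, "' leaves an empty outcome class")
  list(table = out, sick = sick)
}

#' Build an empirical ROC curve
#'
#' Candidate thresholds are the midpoints between consecutive distinct
#' marker values plus -Inf/+Inf sentinels; a subject is called positive when
#' the marker is `>=` the threshold (higher WC indicates sick). The AUC is
#' the trapezoid area, cross-checked against the rank-statistic
#' (Mann-Whitney concordance) formulation to 1e-10.
#'
#' @param values numeric marker (WC, cm).
#' @param labels binary outcome (TRUE/1 = sick); both classes nonempty.
#' @return object of class `roc_curve`: data.frame `points` (`threshold`,
#'   `sensitivity`, `specificity`), `auc`, `n_pos`, `n_neg`.
#' @export
#' @examples
#' r <- build_roc(c(1, 2, 3, 4), c(0, 0, 1, 1))
#' r$auc   # 1
build_roc <- function(values, labels) {
  labels <- as.logical(labels)
  stopifnot(length(values) == length(labels))
  ok <- is.finite(values) & !is.na(labels)
  values <- values[ok]; labels <- labels[ok]
  if (!any(labels) || all(labels)) stop("both outcome classes must be nonempty")
  vp <- sort(values[labels]); vn <- sort(values[!labels])
  uniq <- sort(unique(values))
  thr <- c(-Inf, if (length(uniq) > 1) (head(uniq, -1) + uniq[-1]) / 2, Inf)
  sens <- (length(vp) - findInterval(thr, vp, left.open = TRUE)) / length(vp)
  spec <- findInterval(thr, vn, left.open = TRUE) / length(vn)
  pts <- data.frame(threshold = thr, sensitivity = sens, specificity = spec)

  x <- rev(1 - spec); y <- rev(sens)          # ascending in x
  auc <- sum(diff(x) * (head(y, -1) + y[-1]) / 2)
  r <- rank(c(values[labels], values[!labels]))
  auc_rank <- (sum(r[seq_len(length(vp))]) - length(vp) * (length(vp) + 1) / 2) /
    (as.numeric(length(vp)) * length(vn))
  if (abs(auc - auc_rank) > 1e-10)
    stop("internal error: trapezoid and concordance AUC disagree")
  structure(list(points = pts, auc = auc, n_pos = length(vp), n_neg = length(vn)),
            class = "roc_curve")
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("ROC curve: %d sick / %d healthy, AUC %.3f (%d thresholds)\n",
              x$n_pos, x$n_neg, x$auc, nrow(x$points)))
  invisible(x)
}

#' Cutpoint selection indices
#'
#' Youden index `J = sens + spec - 1`; distance to the perfect-classification
#' corner `d = sqrt((1-sens)^2 + (1-spec)^2)`; positive likelihood ratio
#' `LR+ = sens / (1 - spec)` (+Inf at spec = 1). Inputs are fractions in
#' \[0, 1\].
#'
#' @param sens sensitivity fraction.
#' @param spec specificity fraction.
#' @return numeric.
#' @export
#' @examples
#' youden(0.733, 0.685)      # 0.418
#' distance01(0.733, 0.685)  # 0.413
#' lr_plus(0.960, 0.995)     # 192
youden <- function(sens, spec) {
  .check_frac(sens, spec)
  sens + spec - 1
}

#' @rdname youden
#' @export
distance01 <- function(sens, spec) {
  .check_frac(sens, spec)
  sqrt((1 - sens)^2 + (1 - spec)^2)
}

#' @rdname youden
#' @export
lr_plus <- function(sens, spec) {
  .check_frac(sens, spec)
  ifelse(spec < 1, sens / (1 - spec), Inf)
}

.check_frac <- function(sens, spec) {
  if (any(sens < 0 | sens > 1 | spec < 0 | spec > 1, na.rm = TRUE))
    stop("sensitivity and specificity must lie in [0, 1]")
}

#' Select the operating cutpoint on a ROC curve
#'
#' Default policy `"youden_sens"` favours sensitivity: among finite
#' thresholds whose Youden index is within `eps` (default 0.005) of the
#' maximum, the one with the highest sensitivity wins; a remaining tie goes
#' to the lowest threshold. `"youden"` takes the strict Youden maximum and
#' `"distance"` the point closest to (0, 1); both break ties by lowest
#' threshold.
#'
#' @param curve a [build_roc()] result.
#' @param policy `"youden_sens"`, `"youden"` or `"distance"`.
#' @param eps Youden near-tie tolerance for `"youden_sens"`.
#' @return one-row data.frame: `cutpoint_cm`, `sens_pct`, `spec_pct`,
#'   `youden`, `distance01`, `lr_plus` (raw), and `youden_2dp`,
#'   `distance01_2dp`, `lr_plus_2dp` rounded half-up to two decimals.
#' @export
select_cutpoint <- function(curve, policy = c("youden_sens", "youden", "distance"),
                            eps = 0.005) {
  policy <- match.arg(policy)
  pts <- curve$points[is.finite(curve$points$threshold), , drop = FALSE]
  if (nrow(pts) == 0) stop("no finite thresholds on the curve")
  J <- pts$sensitivity + pts$specificity - 1
  d <- sqrt((1 - pts$sensitivity)^2 + (1 - pts$specificity)^2)
  pick <- switch(policy,
    youden_sens = {
      cand <- which(J >= max(J) - eps)
      cand <- cand[pts$sensitivity[cand] == max(pts$sensitivity[cand])]
      cand[which.min(pts$threshold[cand])]
    },
    youden = {
      cand <- which(J == max(J))
      cand[which.min(pts$threshold[cand])]
    },
    distance = {
      cand <- which(d == min(d))
      cand[which.min(pts$threshold[cand])]
    })
  sens <- pts$sensitivity[pick]; spec <- pts$specificity[pick]
  data.frame(cutpoint_cm = pts$threshold[pick],
             sens_pct = 100 * sens, spec_pct = 100 * spec,
             youden = youden(sens, spec),
             distance01 = distance01(sens, spec),
             lr_plus = lr_plus(sens, spec),
             youden_2dp = round_half_up(youden(sens, spec), 2),
             distance01_2dp = round_half_up(distance01(sens, spec), 2),
             lr_plus_2dp = round_half_up(lr_plus(sens, spec), 2))
}
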