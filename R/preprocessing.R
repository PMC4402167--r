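#' Mean arterial pressure
#'
#' Standard estimate `DBP + (SBP - DBP) / 3`, in mmHg. MAP is a convex
#' combination of the two pressures, so `dbp <= map <= sbp` always.
#'
#' @param sbp systolic pressure, mmHg.
#' @param dbp diastolic pressure, mmHg; must satisfy `sbp >= dbp > 0`.
#' @return MAP in mmHg.
#' @export
#' @examples
#' mean_arterial_pressure(120, 80)   # 93.33
mean_arterial_pressure <- function(sbp, dbp) {
  if (any(dbp <= 0)) stop("dbp must be positive")
  if (any(sbp < dbp)) stop("sbp must be >= dbp")
  dbp + (sbp - dbp) / 3
}

#' WHO BMI classification
#'
#' Half-open, left-closed intervals: underweight < 18.5; normal
#' \[18.5, 25); overweight \[25, 30); obese class I \[30, 35); class II
#' \[35, 40); class III >= 40.
#'
#' @param bmi body mass index in kg/m2, positive.
#' @return factor with levels `underweight`, `normal`, `overweight`,
#'   `obese1`, `obese2`, `obese3`.
#' @export
#' @examples
#' classify_bmi(c(17, 22, 28.32, 25, 40))
classify_bmi <- function(bmi) {
  if (any(bmi <= 0, na.rm = TRUE)) stop("bmi must be positive")
  cut(bmi, breaks = c(0, 18.5, 25, 30, 35, 40, Inf), right = FALSE,
      labels = c("underweight", "normal", "overweight", "obese1", "obese2", "obese3"))
}

#' Friedewald estimation of LDL and VLDL cholesterol
#'
#' `VLDL = TAG / 5` and `LDL = TC - HDL - VLDL` (mg/dL), valid for
#' TAG <= 400 mg/dL; above that the estimate breaks down and an error of
#' class `friedewald_invalid` is raised (the original study measured such
#' samples by lipoprotein electrophoresis instead). Mass is conserved:
#' `ldl + vldl + hdl == tchol` exactly.
#'
#' @param tchol total cholesterol, mg/dL.
#' @param hdl HDL cholesterol, mg/dL.
#' @param tag triglycerides, mg/dL.
#' @return data.frame with columns `ldl` and `vldl`.
#' @export
#' @examples
#' friedewald(200, 50, 100)   # ldl 130, vldl 20
friedewald <- function(tchol, hdl, tag) {
  if (any(tag > 400, na.rm = TRUE)) {
    stop(structure(class = c("friedewald_invalid", "error", "condition"),
                   list(message = "Friedewald formula invalid for TAG > 400 mg/dL",
                        call = sys.call())))
  }
  vldl <- tag / 5
  data.frame(ldl = tchol - hdl - vldl, vldl = vldl)
}

#' Geary's test of normality
#'
#' Ratio `a` of the mean absolute deviation to the population standard
#' deviation; under normality `a` converges to `sqrt(2/pi) ~ 0.7979` with
#' asymptotic null standard deviation `0.2123 / sqrt(n)`. Returns the ratio,
#' the standardized statistic and a two-sided normal p-value.
#'
#' @param values numeric sample, n >= 8, nonzero variance.
#' @return list with `ratio`, `z`, `p`, `n`.
#' @export
#' @examples
#' geary_test(rnorm(500))
geary_test <- function(values) {
  values <- values[is.finite(values)]
  n <- length(values)
  if (n < 8) stop("geary_test requires n >= 8")
  mu <- mean(values)
  s_pop <- sqrt(mean((values - mu)^2))
  if (s_pop == 0) stop("geary_test undefined for zero variance")
  a <- mean(abs(values - mu)) / s_pop
  z <- (a - sqrt(2 / pi)) / (0.2123 / sqrt(n))
  list(ratio = a, z = z, p = 2 * pnorm(-abs(z)), n = n)
}

#' Log-transform columns that fail a normality test
#'
#' Applies [geary_test()] to each named column; columns significant at
#' `alpha` are replaced by their natural logarithm and re-tested, mirroring
#' the analysis convention of transforming skewed biochemical variables and
#' corroborating normality afterwards. The corroboration has teeth: when the
#' log transform does not move the Geary statistic closer to its normal
#' value (as for a left-truncated but otherwise symmetric variable), the
#' column is reverted and recorded as untransformed.
#'
#' @param table data.frame.
#' @param columns character vector of column names to consider.
#' @param alpha significance level for the normality test (default 0.05).
#' @return list with `table` (transformed data) and `log` (data.frame per
#'   column: `transformed`, pre- and post-transform p-values).
#' @export
log_transform_if_nonnormal <- function(table, columns, alpha = 0.05) {
  stopifnot(all(columns %in% names(table)))
  rec <- data.frame(column = columns, transformed = FALSE,
                    p_before = NA_real_, p_after = NA_real_,
                    stringsAsFactors = FALSE)
  for (i in seq_along(columns)) {
    col <- columns[i]
    g <- geary_test(table[[col]])
    rec$p_before[i] <- g$p
    if (g$p < alpha) {
      if (any(table[[col]] <= 0, na.rm = TRUE))
        stop("column '", col, "' selected for log transform has nonpositive values")
      g2 <- geary_test(log(table[[col]]))
      if (abs(g2$z) < abs(g$z)) {
        table[[col]] <- log(table[[col]])
        rec$transformed[i] <- TRUE
        rec$p_after[i] <- g2$p
      }
    }
  }
  list(table = table, log = rec)
}

#' Apply the study's exclusion rules
#'
#' Removes subjects with missing insulin determination or a diabetes
#' diagnosis (whose treatment would distort the metabolic variables). Flags
#' are read from `insulin_missing` / `diabetes_flag` columns when present,
#' otherwise derived as `is.na(insulin)` and `FALSE`. A subject with both
#' flags is removed once; the per-reason counts may overlap.
#'
#' @param table cohort data.frame.
#' @return list with `table` (retained rows) and `excluded` (named counts:
#'   `insulin_missing`, `diabetes`, `total`).
#' @export
apply_exclusions <- function(table) {
  ins <- if ("insulin_missing" %in% names(table)) as.logical(table$insulin_missing)
         else if ("insulin" %in% names(table)) is.na(table$insulin)
         else rep(FALSE, nrow(table))
  dia <- if ("diabetes_flag" %in% names(table)) as.logical(table$diabetes_flag)
         else rep(FALSE, nrow(table))
  ins[is.na(ins)] <- FALSE
  dia[is.na(dia)] <- FALSE
  drop <- ins | dia
  list(table = table[!drop, , drop = FALSE],
       excluded = c(insulin_missing = sum(ins), diabetes = sum(dia),
                    total = sum(drop)))
}

#' Preprocess a cohort table
#'
#' Applies exclusions, then appends the derived indices every downstream
#' stage relies on: MAP, WHO BMI class, Friedewald LDL/VLDL (rows with
#' TAG > 400 mg/dL are flagged in `friedewald_invalid` and left `NA` rather
#' than estimated), non-HDL cholesterol and the TAG/HDL ratio.
#'
#' @param cohort data.frame with at least `sbp`, `dbp`, `bmi`, `tchol`,
#'   `hdl`, `tag`.
#' @return list with `table` (augmented data.frame) and `excluded` counts.
#' @export
#' @examples
#' cohort <- generate_cohort(default_cohort_spec(n_total = 100), seed = 1)
#' head(preprocess_cohort(cohort)$table)
preprocess_cohort <- function(cohort) {
  excl <- apply_exclusions(cohort)
  tab <- excl$table
  tab$map <- mean_arterial_pressure(tab$sbp, tab$dbp)
  tab$bmi_class <- classify_bmi(tab$bmi)
  tab$friedewald_invalid <- !is.na(tab$tag) & tab$tag > 400
  tab$ldl <- NA_real_
  tab$vldl <- NA_real_
  ok <- !tab$friedewald_invalid
  if (any(ok)) {
    fw <- friedewald(tab$tchol[ok], tab$hdl[ok], tab$tag[ok])
    tab$ldl[ok] <- fw$ldl
    tab$vldl[ok] <- fw$vldl
  }
  tab$non_hdl <- tab$tchol - tab$hdl
  tab$tag_hdl_ratio <- tab$tag / tab$hdl
  list(table = tab, excluded = excl$excluded)
}
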