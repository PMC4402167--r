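#' Per-stratum cluster predictors
#'
#' Predictor sets selected for each gender x BMI stratum: HOMA2-IR and
#' HOMA2-%B for normal-weight and overweight women; those plus TAG for
#' normal-weight and overweight men; HOMA2-IR alone for obese subjects of
#' either gender. Waist circumference is never a predictor, because it is
#' the dependent variable the downstream ROC analysis assesses.
#'
#' @param gender `"F"` or `"M"`.
#' @param bmi_stratum `"normal"`, `"overweight"` or `"obese"` (obese WHO
#'   sub-classes all use the obese set).
#' @return character vector of cohort column names.
#' @export
#' @examples
#' stratum_predictors("F", "normal")
#' stratum_predictors("M", "overweight")
stratum_predictors <- function(gender, bmi_stratum) {
  gender <- match.arg(gender, c("F", "M"))
  bmi_stratum <- match.arg(bmi_stratum, c("normal", "overweight", "obese"))
  if (bmi_stratum == "obese") return("homa2ir")
  if (gender == "F") c("homa2ir", "homa2b") else c("homa2ir", "homa2b", "tag")
}

#' Label clusters metabolically healthy or sick
#'
#' A cluster is healthy iff its mean HOMA2-IR (on the original scale) is
#' strictly below the population cutpoint (default 2.00); a mean exactly at
#' the cutpoint is sick.
#'
#' @param homa2ir_means numeric cluster means of HOMA2-IR.
#' @param cutoff insulin-resistance cutpoint (default 2.00).
#' @return character vector `"healthy"` / `"sick"`.
#' @export
#' @examples
#' label_clusters(c(1.47, 3.56, 2.00))
label_clusters <- function(homa2ir_means, cutoff = 2.00) {
  if (any(is.na(homa2ir_means))) stop("missing HOMA2-IR cluster means")
  ifelse(homa2ir_means < cutoff, "healthy", "sick")
}

# Collapse WHO sub-classes to the stratum group used for predictor choice.
.stratum_group <- function(bmi_class) {
  ifelse(bmi_class %in% c("obese1", "obese2", "obese3"), "obese",
         as.character(bmi_class))
}

#' Cluster every gender x BMI stratum
#'
#' Runs [twostep_cluster()] independently within each gender x BMI stratum
#' (normal, overweight, and the pooled obese group -- the WHO obese
#' sub-classes behave alike and were analysed as one obesity group), after
#' log-transforming predictors that fail Geary's normality test at the
#' cohort level ([log_transform_if_nonnormal()]). Each cluster is then
#' labelled healthy or sick from its raw-scale HOMA2-IR mean
#' ([label_clusters()]). Underweight subjects (BMI < 18.5) are not
#' clustered; no phenotype is defined for them.
#'
#' @param cohort preprocessed cohort (needs `gender`, `bmi_class`, and the
#'   predictor columns); [preprocess_cohort()] output works directly.
#' @param k_max largest candidate cluster count per stratum (default 6).
#' @param seed master seed; each stratum gets a named substream.
#' @param alpha significance level for the normality pre-test (default 0.05).
#' @param cutoff HOMA2-IR health cutpoint (default 2.00).
#' @return object of class `stratum_clustering`: a list of per-stratum
#'   results (`gender`, `bmi_class`, `group`, `predictors`, `model`,
#'   `homa2ir_means`, `health`, `rows`, `transform_log`) plus attributes
#'   `n_underweight` and `n`.
#' @export
cluster_strata <- function(cohort, k_max = 6, seed = 1, alpha = 0.05,
                           cutoff = 2.00) {
  if (!"bmi_class" %in% names(cohort)) cohort$bmi_class <- classify_bmi(cohort$bmi)
  # the normality test and log transform are a cohort-level decision, so
  # every stratum (and both cross-validation halves of a stratum) works on
  # the same scale
  all_preds <- unique(c(stratum_predictors("F", "normal"),
                        stratum_predictors("M", "normal"),
                        stratum_predictors("F", "obese")))
  all_preds <- intersect(all_preds, names(cohort))
  trans <- if (nrow(cohort) >= 8) {
    log_transform_if_nonnormal(cohort, all_preds, alpha = alpha)
  } else {
    list(table = cohort, log = NULL)
  }
  out <- list()
  groups <- list(normal = "normal", overweight = "overweight",
                 obese = c("obese1", "obese2", "obese3"))
  for (g in c("F", "M")) {
    for (group in names(groups)) {
      rows <- which(cohort$gender == g & cohort$bmi_class %in% groups[[group]])
      if (length(rows) == 0) next
      preds <- stratum_predictors(g, group)
      dat <- trans$table[rows, preds, drop = FALSE]
      tl <- if (is.null(trans$log)) NULL else
        trans$log[trans$log$column %in% preds, , drop = FALSE]
      fit <- twostep_cluster(dat, k_max = min(k_max, nrow(dat)),
                             seed = substream_seed(seed, paste0("stratum_", g, "_", group)))
      ir_means <- as.numeric(tapply(cohort$homa2ir[rows], fit$assignment, mean))
      out[[paste(g, group, sep = "_")]] <- list(
        gender = g, bmi_class = group, group = group, predictors = preds,
        model = fit, homa2ir_means = ir_means,
        health = label_clusters(ir_means, cutoff = cutoff),
        rows = rows, transform_log = tl)
    }
  }
  structure(out,
            n_underweight = sum(cohort$bmi_class == "underweight", na.rm = TRUE),
            n = nrow(cohort), class = "stratum_clustering")
}

#' @export
print.stratum_clustering <- function(x, ...) {
  cat("Stratified two-step clustering over", length(x), "strata\n")
  for (s in x) {
    cat(sprintf("  %s %-10s n=%4d k=%d healthy clusters: %d/%d silhouette %.2f\n",
                s$gender, s$bmi_class, length(s$rows), s$model$k,
                sum(s$health == "healthy"), s$model$k, s$model$silhouette))
  }
  nuw <- attr(x, "n_underweight")
  if (nuw > 0) cat("  (", nuw, "underweight subjects not phenotyped )\n")
  invisible(x)
}

#' Assign six metabolic phenotypes
#'
#' Combines each subject's BMI stratum with the health label of their
#' cluster: normal weight maps to HNW (healthy) or MONW (sick); overweight
#' to OW_HEALTHY / OW_SICK; any obese sub-class to MHO (healthy) or MDO
#' (sick) -- the obese sub-classes are clustered separately but collapsed in
#' the phenotype. Every non-underweight subject receives exactly one
#' phenotype; the underweight count is carried in the `n_underweight`
#' attribute.
#'
#' @param cohort the cohort passed to [cluster_strata()].
#' @param strata a [cluster_strata()] result for that cohort.
#' @return data.frame `id`, `gender`, `bmi_class`, `health`, `phenotype`,
#'   with attribute `n_underweight`.
#' @export
assign_phenotypes <- function(cohort, strata) {
  n <- nrow(cohort)
  health <- rep(NA_character_, n)
  for (s in strata) health[s$rows] <- s$health[s$model$assignment]
  if (!"bmi_class" %in% names(cohort)) cohort$bmi_class <- classify_bmi(cohort$bmi)
  group <- .stratum_group(cohort$bmi_class)
  phenotype <- rep(NA_character_, n)
  keep <- !is.na(health)
  phenotype[keep] <- ifelse(group[keep] == "normal",
                            ifelse(health[keep] == "healthy", "HNW", "MONW"),
                     ifelse(group[keep] == "overweight",
                            ifelse(health[keep] == "healthy", "OW_HEALTHY", "OW_SICK"),
                            ifelse(health[keep] == "healthy", "MHO", "MDO")))
  out <- data.frame(id = cohort$id, gender = cohort$gender,
                    bmi_class = cohort$bmi_class, health = health,
                    phenotype = phenotype, stringsAsFactors = FALSE)
  out <- out[keep, , drop = FALSE]
  attr(out, "n_underweight") <- attr(strata, "n_underweight")
  out
}

#' Cluster strata and append phenotypes to the cohort
#'
#' Convenience wrapper: [cluster_strata()] then [assign_phenotypes()],
#' returning the cohort restricted to phenotyped subjects with a `phenotype`
#' column appended.
#'
#' @inheritParams cluster_strata
#' @return list with `cohort` (phenotyped rows, `phenotype` and `health`
#'   columns appended), `strata`, and `assignments`.
#' @export
phenotype_cohort <- function(cohort, k_max = 6, seed = 1, alpha = 0.05,
                             cutoff = 2.00) {
  if (!"bmi_class" %in% names(cohort)) cohort$bmi_class <- classify_bmi(cohort$bmi)
  strata <- cluster_strata(cohort, k_max = k_max, seed = seed, alpha = alpha,
                           cutoff = cutoff)
  asg <- assign_phenotypes(cohort, strata)
  merged <- cohort[match(asg$id, cohort$id), , drop = FALSE]
  merged$health <- asg$health
  merged$phenotype <- asg$phenotype
  list(cohort = merged, strata = strata, assignments = asg)
}
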