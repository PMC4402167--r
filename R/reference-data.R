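#' Published summary statistics of the Maracaibo cohort
#'
#' The Maracaibo City Metabolic Syndrome Prevalence Study (MMSPS) cohort used
#' to derive the original waist-circumference cutoffs was never deposited;
#' only summary tables were published. This function returns those published
#' summaries, which parameterise the synthetic cohort generator
#' ([default_cohort_spec()]) and serve as desk-check inputs (the published
#' cross-validation confusion matrix, the published ROC index rows).
#'
#' @return A list with components:
#' \describe{
#'   \item{phenotype_counts}{data.frame of healthy/sick counts per gender and
#'     BMI class (normal, overweight, obese I--III).}
#'   \item{phenotype_params}{data.frame of per-phenotype, per-gender mean/SD
#'     for WC (cm), HOMA2-IR, TAG (mg/dL), HDL-C (mg/dL) and MAP (mmHg).}
#'   \item{pooled_params}{data.frame of per-gender pooled mean/SD for
#'     variables not reported per phenotype (age, fasting glucose, insulin,
#'     HOMA2-%B, total cholesterol, SBP, DBP).}
#'   \item{crossval_confusion}{published 3x3 cross-validation confusion
#'     matrix (centroid-based assignment vs. independent re-clustering of the
#'     test half, n = 951).}
#'   \item{roc_index_rows}{published candidate-cutpoint rows: WC threshold,
#'     sensitivity and specificity (percent) per gender and scenario.}
#'   \item{n_total}{cohort size after exclusions (1902).}
#'   \item{gender_fraction_female}{fraction of women (0.5215).}
#' }
#' @export
#' @examples
#' ref <- mmsps_reference()
#' subset(ref$phenotype_params, variable == "wc_cm" & phenotype == "MHO")
mmsps_reference <- function() {
  counts <- data.frame(
    gender  = rep(c("F", "M"), each = 5),
    bmi_class = rep(c("normal", "overweight", "obese1", "obese2", "obese3"), 2),
    healthy = c(336, 240, 59, 28, 14, 202, 294, 79, 28, 5),
    sick    = c(28, 76, 129, 54, 28, 36, 66, 119, 47, 34),
    stringsAsFactors = FALSE
  )

  ph <- c("HNW", "MONW", "OW_HEALTHY", "OW_SICK", "MHO", "MDO")
  params <- rbind(
    data.frame(variable = "wc_cm", phenotype = ph,
               mean_F = c(79.27, 77.20, 89.69, 90.27, 104.40, 105.50),
               sd_F   = c(8.24, 7.07, 6.88, 7.59, 10.55, 10.07),
               mean_M = c(81.54, 86.98, 94.82, 97.76, 109.17, 116.04),
               sd_M   = c(6.87, 7.62, 6.59, 6.10, 11.94, 15.32)),
    data.frame(variable = "homa2ir", phenotype = ph,
               mean_F = c(1.47, 3.56, 1.45, 3.12, 1.24, 3.14),
               sd_F   = c(0.48, 1.36, 0.51, 1.14, 0.37, 1.54),
               mean_M = c(1.15, 2.54, 1.49, 3.57, 1.40, 3.39),
               sd_M   = c(0.44, 1.47, 0.58, 1.41, 0.41, 1.42)),
    data.frame(variable = "tag", phenotype = ph,
               mean_F = c(86.49, 120.61, 112.97, 131.32, 120.12, 144.57),
               sd_F   = c(52.06, 155.70, 68.92, 93.03, 73.96, 95.54),
               mean_M = c(84.65, 180.99, 131.01, 173.92, 143.08, 184.60),
               sd_M   = c(38.44, 124.76, 80.97, 106.29, 118.27, 121.59)),
    data.frame(variable = "hdl", phenotype = ph,
               mean_F = c(49.29, 51.61, 48.17, 44.43, 45.57, 44.13),
               sd_F   = c(11.81, 11.54, 11.65, 10.84, 13.01, 11.45),
               mean_M = c(46.00, 39.50, 41.91, 38.45, 40.15, 36.71),
               sd_M   = c(11.16, 11.84, 12.88, 8.39, 9.91, 8.48)),
    data.frame(variable = "map", phenotype = ph,
               mean_F = c(83.80, 87.00, 89.20, 88.85, 95.78, 95.10),
               sd_F   = c(9.60, 13.17, 11.33, 10.46, 13.91, 12.07),
               mean_M = c(87.28, 88.28, 93.44, 91.45, 96.38, 98.01),
               sd_M   = c(9.92, 10.54, 11.77, 10.39, 13.17, 12.47))
  )

  pooled <- data.frame(
    variable = c("age_y", "glucose", "insulin", "homa2b", "tchol"),
    mean_F = c(40.11, 98.20, 14.57, 136.97, 193.77),
    sd_F   = c(15.29, 31.01, 9.34, 58.67, 44.41),
    mean_M = c(37.17, 99.09, 14.83, 137.25, 187.32),
    sd_M   = c(14.54, 32.73, 9.83, 65.83, 47.33),
    stringsAsFactors = FALSE
  )

  confusion <- matrix(c(609, 0, 31,
                        0, 50, 0,
                        0, 14, 247),
                      nrow = 3, byrow = TRUE,
                      dimnames = list(paste0("centroid", 1:3),
                                      paste0("recluster", 1:3)))

  roc_rows <- data.frame(
    gender   = rep(rep(c("F", "M"), each = 3), 3),
    scenario = rep(c("six_group", "four_group", "two_group"), each = 6),
    wc_cm = c(90.75, 91.25, 91.75, 97.75, 98.15, 98.40,
              90.75, 91.50, 92.25, 97.50, 98.15, 98.40,
              90.75, 91.50, 92.50, 97.00, 98.15, 98.65),
    sens_pct = c(75.2, 73.3, 73.3, 76.5, 74.8, 74.5,
                 82.2, 80.1, 78.4, 85.7, 83.8, 83.5,
                 94.3, 93.4, 92.9, 96.0, 96.0, 95.5),
    spec_pct = c(65.3, 68.5, 68.4, 67.8, 69.7, 69.7,
                 75.9, 79.3, 83.0, 80.2, 82.3, 82.3,
                 92.6, 93.7, 94.6, 98.5, 99.5, 99.5),
    selected = c(FALSE, TRUE, FALSE, FALSE, TRUE, FALSE,
                 FALSE, TRUE, FALSE, FALSE, TRUE, FALSE,
                 FALSE, TRUE, FALSE, FALSE, TRUE, FALSE),
    stringsAsFactors = FALSE
  )

  list(phenotype_counts = counts,
       phenotype_params = params,
       pooled_params = pooled,
       crossval_confusion = confusion,
       roc_index_rows = roc_rows,
       n_total = 1902L,
       gender_fraction_female = 0.5215)
}
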