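#' Construct a phenotype specification
#'
#' One entry of a cohort specification: a metabolic phenotype, its per-gender
#' prevalence, the per-variable sampling distributions, and the BMI bands the
#' phenotype occupies. Variables carry a distribution family tag: `"normal"`
#' (optionally truncated below at a physiologic floor) or `"lognormal"`
#' (parameters solved from the target mean/SD by moment matching, see
#' [lognormal_params()]).
#'
#' @param name phenotype label, one of `"HNW"`, `"MONW"`, `"OW_HEALTHY"`,
#'   `"OW_SICK"`, `"MHO"`, `"MDO"`.
#' @param prevalence named numeric, fraction per gender (`F`, `M`), each in
#'   \[0, 1\].
#' @param variables named list; each element a list with `family`
#'   (`"normal"`/`"lognormal"`), `location` and `scale` (named per gender),
#'   and optional `lower` truncation bound.
#' @param bmi_bands named list per gender of data.frames with columns
#'   `lower`, `upper`, `weight`; BMI is drawn uniformly within a band chosen
#'   by weight.
#' @return an object of class `phenotype_spec`.
#' @export
phenotype_spec <- function(name, prevalence, variables, bmi_bands) {
  name <- match.arg(name, c("HNW", "MONW", "OW_HEALTHY", "OW_SICK", "MHO", "MDO"))
  stopifnot(all(c("F", "M") %in% names(prevalence)),
            all(prevalence >= 0), all(prevalence <= 1))
  for (v in variables) {
    stopifnot(v$family %in% c("normal", "lognormal"),
              all(v$scale > 0))
  }
  structure(list(name = name, prevalence = prevalence,
                 variables = variables, bmi_bands = bmi_bands),
            class = "phenotype_spec")
}

#' Construct a cohort specification
#'
#' Bundle of everything [generate_cohort()] needs: the cohort size, the
#' gender split, the list of [phenotype_spec()] entries, and an optional
#' within-phenotype correlation matrix applied through a Gaussian copula
#' (default `NULL`, i.e. variables drawn independently within phenotype).
#'
#' @param n_total number of subjects (>= 0).
#' @param gender_fraction_female fraction of women in \[0, 1\].
#' @param phenotypes list of [phenotype_spec()] objects; per-gender
#'   prevalences must sum to 1 within 1e-9.
#' @param correlation optional correlation matrix with dimnames naming a
#'   subset of the phenotype variables.
#' @return an object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_total, gender_fraction_female, phenotypes,
                        correlation = NULL) {
  if (n_total < 0) stop("n_total must be >= 0")
  if (gender_fraction_female < 0 || gender_fraction_female > 1)
    stop("gender_fraction_female must lie in [0, 1]")
  for (g in c("F", "M")) {
    tot <- sum(vapply(phenotypes, function(p) p$prevalence[[g]], numeric(1)))
    if (abs(tot - 1) > 1e-9)
      stop("prevalences for gender ", g, " sum to ", format(tot), ", not 1")
  }
  if (!is.null(correlation)) {
    stopifnot(isSymmetric(unname(correlation)),
              !is.null(rownames(correlation)))
  }
  structure(list(n_total = as.integer(n_total),
                 gender_fraction_female = gender_fraction_female,
                 phenotypes = phenotypes,
                 correlation = correlation),
            class = "cohort_spec")
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat("Cohort specification:", x$n_total, "subjects,",
      sprintf("%.2f%%", 100 * x$gender_fraction_female), "women\n")
  for (p in x$phenotypes) {
    cat(sprintf("  %-10s prevalence F %.4f / M %.4f, %d variables\n",
                p$name, p$prevalence[["F"]], p$prevalence[["M"]],
                length(p$variables)))
  }
  invisible(x)
}

# WHO BMI bands each phenotype occupies; obese phenotypes are split across
# classes I-III with weights taken from the published per-class counts.
.bmi_bands_for <- function(name, counts, healthy) {
  col <- if (healthy) "healthy" else "sick"
  band <- function(lower, upper, weight) data.frame(lower = lower, upper = upper,
                                                    weight = weight)
  one_gender <- function(g) {
    cg <- counts[counts$gender == g, ]
    switch(name,
      HNW = , MONW = band(18.5, 24.99, 1),
      OW_HEALTHY = , OW_SICK = band(25, 29.99, 1),
      MHO = , MDO = {
        w <- cg[[col]][match(c("obese1", "obese2", "obese3"), cg$bmi_class)]
        rbind(band(30, 34.99, w[1]), band(35, 39.99, w[2]), band(40, 49.99, w[3]))
      })
  }
  list(F = one_gender("F"), M = one_gender("M"))
}

#' Default cohort specification from the published Maracaibo summaries
#'
#' Builds a [cohort_spec()] whose per-phenotype means/SDs for WC, HOMA2-IR,
#' TAG, HDL-C and MAP equal the published per-phenotype values, whose
#' per-gender prevalences equal the published healthy/sick counts divided by
#' gender totals, and whose BMI is drawn uniformly within each phenotype's
#' WHO band (obese phenotypes split across classes I-III by the published
#' per-class counts). Fasting glucose, HOMA2-%B, age, insulin and total
#' cholesterol were not published per phenotype; they use the pooled
#' per-gender values and are therefore non-informative across phenotypes.
#'
#' @param n_total cohort size; default 1902, the published analysis sample.
#' @param gender_fraction_female default 0.5215 as published.
#' @param correlation optional correlation matrix passed to [cohort_spec()].
#' @return a `cohort_spec`.
#' @export
#' @examples
#' spec <- default_cohort_spec()
#' spec
default_cohort_spec <- function(n_total = 1902,
                                gender_fraction_female = 0.5215,
                                correlation = NULL) {
  ref <- mmsps_reference()
  counts <- ref$phenotype_counts
  totals <- c(F = sum(counts$healthy[counts$gender == "F"]) +
                  sum(counts$sick[counts$gender == "F"]),
              M = sum(counts$healthy[counts$gender == "M"]) +
                  sum(counts$sick[counts$gender == "M"]))

  prev_for <- function(name) {
    pick <- function(g) {
      cg <- counts[counts$gender == g, ]
      n <- switch(name,
        HNW        = cg$healthy[cg$bmi_class == "normal"],
        MONW       = cg$sick[cg$bmi_class == "normal"],
        OW_HEALTHY = cg$healthy[cg$bmi_class == "overweight"],
        OW_SICK    = cg$sick[cg$bmi_class == "overweight"],
        MHO        = sum(cg$healthy[cg$bmi_class %in% c("obese1", "obese2", "obese3")]),
        MDO        = sum(cg$sick[cg$bmi_class %in% c("obese1", "obese2", "obese3")]))
      n / totals[[g]]
    }
    c(F = pick("F"), M = pick("M"))
  }

  floors <- c(wc_cm = 40, homa2ir = NA, tag = NA, hdl = 5, map = 40,
              glucose = 40, homa2b = 1, age_y = 18, insulin = NA, tchol = 50)
  families <- c(wc_cm = "normal", homa2ir = "lognormal", tag = "lognormal",
                hdl = "normal", map = "normal", glucose = "normal",
                homa2b = "normal", age_y = "normal", insulin = "lognormal",
                tchol = "normal")

  var_entry <- function(variable, mF, sF, mM, sM) {
    e <- list(family = unname(families[[variable]]),
              location = c(F = mF, M = mM),
              scale = c(F = sF, M = sM))
    if (!is.na(floors[[variable]])) e$lower <- unname(floors[[variable]])
    e
  }

  phenotypes <- lapply(c("HNW", "MONW", "OW_HEALTHY", "OW_SICK", "MHO", "MDO"),
    function(name) {
      vars <- list()
      pp <- ref$phenotype_params
      for (v in unique(pp$variable)) {
        row <- pp[pp$variable == v & pp$phenotype == name, ]
        vars[[v]] <- var_entry(v, row$mean_F, row$sd_F, row$mean_M, row$sd_M)
      }
      for (i in seq_len(nrow(ref$pooled_params))) {
        row <- ref$pooled_params[i, ]
        vars[[row$variable]] <- var_entry(row$variable, row$mean_F, row$sd_F,
                                          row$mean_M, row$sd_M)
      }
      phenotype_spec(name, prev_for(name), vars,
                     .bmi_bands_for(name, counts,
                                    healthy = name %in% c("HNW", "OW_HEALTHY", "MHO")))
    })

  cohort_spec(n_total, gender_fraction_female, phenotypes, correlation)
}

#' Write / read a cohort specification as JSON
#'
#' @param spec a [cohort_spec()].
#' @param path file path.
#' @return `write_cohort_spec` returns `path` invisibly; `read_cohort_spec`
#'   returns a `cohort_spec`.
#' @export
write_cohort_spec <- function(spec, path) {
  obj <- unclass(spec)
  # jsonlite drops names on atomic vectors; lists keep them
  obj$phenotypes <- lapply(obj$phenotypes, function(p) {
    p <- unclass(p)
    p$prevalence <- as.list(p$prevalence)
    p$variables <- lapply(p$variables, function(v) {
      v$location <- as.list(v$location)
      v$scale <- as.list(v$scale)
      v
    })
    p
  })
  if (!is.null(obj$correlation)) {
    obj$correlation <- list(variables = rownames(obj$correlation),
                            values = unname(apply(obj$correlation, 1,
                                                  as.list, simplify = FALSE)))
  }
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}

#' @rdname write_cohort_spec
#' @export
read_cohort_spec <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  phenotypes <- lapply(raw$phenotypes, function(p) {
    vars <- lapply(p$variables, function(v) {
      out <- list(family = v$family,
                  location = unlist(v$location), scale = unlist(v$scale))
      if (!is.null(v$lower)) out$lower <- v$lower
      out
    })
    bands <- lapply(p$bmi_bands, function(b)
      data.frame(lower = unlist(b$lower), upper = unlist(b$upper),
                 weight = unlist(b$weight)))
    phenotype_spec(p$name, unlist(p$prevalence), vars, bands)
  })
  corr <- NULL
  if (length(raw$correlation) > 0) {
    nm <- unlist(raw$correlation$variables)
    corr <- do.call(rbind, lapply(raw$correlation$values,
                                  function(row) as.numeric(unlist(row))))
    dimnames(corr) <- list(nm, nm)
  }
  cohort_spec(raw$n_total, raw$gender_fraction_female, phenotypes, corr)
}
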