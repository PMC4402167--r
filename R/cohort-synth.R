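#' Generate a synthetic cohort
#'
#' Draws `spec$n_total` subjects. Gender and phenotype are sampled from the
#' spec's gender fraction and per-gender prevalences; each variable is drawn
#' from its tagged family (truncated normal, or moment-matched log-normal for
#' the right-skewed HOMA2-IR, TAG and insulin) within phenotype and gender.
#' BMI is drawn uniformly within the phenotype's WHO band, so BMI
#' stratification is consistent with phenotype identity by construction.
#' HOMA2-S is the definitional reciprocal `100 / HOMA2-IR`; systolic and
#' diastolic pressures are reconstructed from the drawn mean arterial
#' pressure and an independent pulse pressure so that
#' `MAP = DBP + (SBP - DBP)/3` holds exactly.
#'
#' When `spec$correlation` is set, the named variables are coupled within
#' phenotype through a Gaussian copula with that correlation matrix; the
#' marginals are unchanged.
#'
#' @param spec a [cohort_spec()].
#' @param seed integer seed; equal seeds yield identical cohorts.
#' @return data.frame with columns `id`, `gender`, `age_y`, `bmi`, `wc_cm`,
#'   `sbp`, `dbp`, `glucose`, `insulin`, `homa2ir`, `homa2b`, `homa2s`,
#'   `tchol`, `tag`, `hdl`, `true_phenotype`.
#' @export
#' @examples
#' cohort <- generate_cohort(default_cohort_spec(n_total = 200), seed = 1)
#' table(cohort$true_phenotype)
generate_cohort <- function(spec, seed = 1) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- spec$n_total
  cols <- c("id", "gender", "age_y", "bmi", "wc_cm", "sbp", "dbp", "glucose",
            "insulin", "homa2ir", "homa2b", "homa2s", "tchol", "tag", "hdl",
            "true_phenotype")
  if (n == 0) {
    out <- as.data.frame(setNames(rep(list(character(0)), 2), cols[1:2]))
    for (v in cols[3:15]) out[[v]] <- numeric(0)
    out$true_phenotype <- character(0)
    return(out)
  }
  set.seed(substream_seed(seed, "synth"))

  gender <- ifelse(runif(n) < spec$gender_fraction_female, "F", "M")
  ph_names <- vapply(spec$phenotypes, `[[`, character(1), "name")
  phenotype <- character(n)
  for (g in c("F", "M")) {
    idx <- which(gender == g)
    prev <- vapply(spec$phenotypes, function(p) p$prevalence[[g]], numeric(1))
    phenotype[idx] <- sample(ph_names, length(idx), replace = TRUE, prob = prev)
  }

  out <- data.frame(id = sprintf("S%06d", seq_len(n)), gender = gender,
                    stringsAsFactors = FALSE)
  for (v in c(cols[3:15], "map")) out[[v]] <- NA_real_
  out$true_phenotype <- phenotype

  for (p in spec$phenotypes) {
    for (g in c("F", "M")) {
      idx <- which(phenotype == p$name & gender == g)
      m <- length(idx)
      if (m == 0) next
      draws <- .draw_variables(p, g, m, spec$correlation)
      for (v in names(draws)) out[[v]][idx] <- draws[[v]]
      out$bmi[idx] <- .draw_bmi(p$bmi_bands[[g]], m)
    }
  }
  out$homa2s <- 100 / out$homa2ir
  pp <- rnorm_trunc(n, 42, 8, lower = 20)      # pulse pressure, mmHg
  map <- out$map
  out$dbp <- map - pp / 3
  out$sbp <- out$dbp + pp
  out$map <- NULL
  out[, cols]
}

# Draw all spec variables for one phenotype x gender group. Independent
# draws by default; Gaussian copula over the named subset when `corr` given.
.draw_variables <- function(p, g, m, corr = NULL) {
  vars <- p$variables
  qdraw <- function(v, u) {
    loc <- v$location[[g]]; sc <- v$scale[[g]]
    if (v$family == "lognormal") {
      lp <- lognormal_params(loc, sc)
      qlnorm(u, lp$meanlog, lp$sdlog)
    } else {
      qnorm_trunc(u, loc, sc, lower = if (is.null(v$lower)) -Inf else v$lower)
    }
  }
  rdraw <- function(v) {
    loc <- v$location[[g]]; sc <- v$scale[[g]]
    if (v$family == "lognormal") {
      lp <- lognormal_params(loc, sc)
      rlnorm(m, lp$meanlog, lp$sdlog)
    } else {
      rnorm_trunc(m, loc, sc, lower = if (is.null(v$lower)) -Inf else v$lower)
    }
  }
  out <- list()
  coupled <- if (is.null(corr)) character(0) else intersect(rownames(corr), names(vars))
  if (length(coupled) >= 2) {
    R <- corr[coupled, coupled, drop = FALSE]
    z <- matrix(rnorm(m * length(coupled)), m) %*% chol(R)
    u <- pnorm(z)
    for (j in seq_along(coupled))
      out[[coupled[j]]] <- qdraw(vars[[coupled[j]]], u[, j])
  } else {
    coupled <- character(0)
  }
  for (v in setdiff(names(vars), coupled)) out[[v]] <- rdraw(vars[[v]])
  out
}

.draw_bmi <- function(bands, m) {
  band <- sample(nrow(bands), m, replace = TRUE, prob = bands$weight)
  runif(m, bands$lower[band], bands$upper[band])
}

#' Write / read the cohort CSV
#'
#' Plain UTF-8 CSV with header and `.` decimal separator, the dialect shared
#' by every stage of the pipeline.
#'
#' @param cohort data.frame as returned by [generate_cohort()].
#' @param path file path.
#' @return `write_cohort_csv` returns `path` invisibly; `read_cohort_csv`
#'   returns the data.frame.
#' @export
write_cohort_csv <- function(cohort, path) {
  write.csv(cohort, path, row.names = FALSE, quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
}
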