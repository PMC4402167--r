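#' Round half away from zero
#'
#' Commercial ("half-up") rounding, as used when formatting diagnostic indices
#' to two decimals. Base [round()] uses round-half-even, which maps 0.445 to
#' 0.44; reported tables in this field round 0.445 to 0.45.
#'
#' @param x numeric vector.
#' @param digits integer number of decimal places.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  # the eps guard keeps binary-representation shortfalls (0.445 stored as
  # 0.44499...) from flipping a half-up decision
  sign(x) * floor(abs(x) * m + 0.5 + sqrt(.Machine$double.eps)) / m
}

# Deterministic sub-seed for a named random substream. Keeps all derived seeds
# strictly below 2^31 - 1.
substream_seed <- function(seed, stream) {
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  as.integer((as.numeric(seed) * 48271 + h * 9973) %% (2^31 - 1))
}

# Truncated-normal draw by rejection; `lower` is a hard physiologic floor so
# the acceptance probability is always near 1 for realistic parameters.
rnorm_trunc <- function(n, mean, sd, lower = -Inf) {
  if (n == 0) return(numeric(0))
  x <- rnorm(n, mean, sd)
  bad <- which(x <= lower)
  while (length(bad) > 0) {
    x[bad] <- rnorm(length(bad), mean, sd)
    bad <- bad[x[bad] <= lower]
  }
  x
}

# Truncated-normal quantile (lower truncation only), for copula sampling.
qnorm_trunc <- function(p, mean, sd, lower = -Inf) {
  if (!is.finite(lower)) return(qnorm(p, mean, sd))
  plo <- pnorm(lower, mean, sd)
  qnorm(plo + p * (1 - plo), mean, sd)
}

#' Log-normal parameters matching a target mean and SD
#'
#' Moment matching: for a target arithmetic mean \eqn{m} and standard
#' deviation \eqn{s}, returns \eqn{\sigma^2 = \log(1 + s^2/m^2)} and
#' \eqn{\mu = \log m - \sigma^2/2}, so that the log-normal sample mean and SD
#' converge to \eqn{(m, s)}.
#'
#' @param m target arithmetic mean (> 0).
#' @param s target arithmetic SD (> 0).
#' @return list with `meanlog` and `sdlog`.
#' @export
lognormal_params <- function(m, s) {
  stopifnot(m > 0, s > 0)
  s2 <- log(1 + (s / m)^2)
  list(meanlog = log(m) - s2 / 2, sdlog = sqrt(s2))
}

# Column-wise standardization; returns scaled matrix plus center/scale used.
standardize_columns <- function(x, center = NULL, scale = NULL) {
  x <- as.matrix(x)
  if (is.null(center)) center <- colMeans(x)
  if (is.null(scale)) {
    scale <- apply(x, 2, sd)
    scale[scale == 0 | !is.finite(scale)] <- 1
  }
  list(x = sweep(sweep(x, 2, center), 2, scale, "/"),
       center = center, scale = scale)
}
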