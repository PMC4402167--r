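# Shared fixture builders; everything is generated in code at test time.

# Well-separated Gaussian mixture in 2D; `centers` is a k x 2 matrix.
make_mixture <- function(n, centers, seed, sd = 1, prob = NULL) {
  set.seed(seed)
  k <- nrow(centers)
  g <- sample(seq_len(k), n, replace = TRUE, prob = prob)
  list(x = data.frame(a = rnorm(n, centers[g, 1], sd),
                      b = rnorm(n, centers[g, 2], sd)),
       component = g)
}

# Small hand-held cohort with the columns the pipeline needs.
make_mini_cohort <- function(n = 60, seed = 42) {
  set.seed(seed)
  data.frame(
    id = sprintf("X%03d", seq_len(n)),
    gender = rep(c("F", "M"), length.out = n),
    age_y = runif(n, 20, 70),
    bmi = runif(n, 19, 42),
    wc_cm = runif(n, 65, 130),
    sbp = runif(n, 100, 160),
    dbp = runif(n, 60, 95),
    glucose = runif(n, 70, 160),
    insulin = runif(n, 3, 30),
    homa2ir = exp(rnorm(n, 0.5, 0.5)),
    homa2b = runif(n, 60, 250),
    homa2s = runif(n, 30, 150),
    tchol = runif(n, 120, 280),
    tag = runif(n, 40, 350),
    hdl = runif(n, 25, 75),
    stringsAsFactors = FALSE
  )
}

# Brute-force O(n^2) silhouette, written independently of the package path.
silhouette_oracle <- function(x, lab) {
  x <- as.matrix(x)
  n <- nrow(x)
  s <- numeric(n)
  for (i in seq_len(n)) {
    d <- sqrt(colSums((t(x) - x[i, ])^2))
    own <- lab == lab[i]
    a <- if (sum(own) > 1) sum(d[own]) / (sum(own) - 1) else 0
    b <- min(vapply(setdiff(unique(lab), lab[i]),
                    function(cl) mean(d[lab == cl]), numeric(1)))
    s[i] <- if (max(a, b) > 0) (b - a) / max(a, b) else 0
  }
  mean(s)
}

# Brute-force pairwise concordance AUC (ties count 1/2).
auc_oracle <- function(values, labels) {
  pos <- values[as.logical(labels)]
  neg <- values[!as.logical(labels)]
  tot <- 0
  for (p in pos) tot <- tot + sum(p > neg) + 0.5 * sum(p == neg)
  tot / (length(pos) * length(neg))
}
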