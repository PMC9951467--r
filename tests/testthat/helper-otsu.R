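# independent brute-force Otsu oracle: explicit scan over every internal
# bin edge, class statistics computed by partitioning the binned values
otsu_oracle <- function(v, n_bins = 256L) {
  v <- as.numeric(v)
  rng <- range(v)
  w <- diff(rng) / n_bins
  idx <- pmin(floor((v - rng[1]) / w) + 1, n_bins)
  mids <- rng[1] + (seq_len(n_bins) - 0.5) * w
  binned <- mids[idx]
  n <- length(v)
  best_k <- NA_integer_
  best_var <- -Inf
  for (k in seq_len(n_bins - 1)) {
    lower <- idx <= k
    n0 <- sum(lower)
    if (n0 == 0 || n0 == n) {
      var_b <- 0
    } else {
      mu0 <- mean(binned[lower])
      mu1 <- mean(binned[!lower])
      var_b <- (n0 / n) * ((n - n0) / n) * (mu0 - mu1)^2
    }
    if (var_b > best_var) {
      best_var <- var_b
      best_k <- k
    }
  }
  rng[1] + best_k * w
}

random_test_image <- function(seed) {
  withr::with_seed(seed, {
    side <- sample(c(8, 16, 32, 64, 128, 256), 2, replace = TRUE)
    kind <- sample(c("uniform", "bimodal", "integers", "skewed"), 1)
    n <- prod(side)
    v <- switch(kind,
      uniform = runif(n),
      bimodal = c(rnorm(ceiling(n * 0.7), 0.2, 0.05),
                  rnorm(floor(n * 0.3), 0.8, 0.1))[seq_len(n)],
      integers = sample(0:255, n, replace = TRUE) / 255,
      skewed = rexp(n, 5))
    matrix(v, side[1], side[2])
  })
}
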