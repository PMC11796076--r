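# Independent oracles, deliberately written by brute force so they share no
# code path with the implementation they check.

# Two-way ANOVA ICC(2,1) via explicit double loops over cells.
icc_oracle <- function(m) {
  n <- nrow(m); k <- ncol(m)
  g <- mean(m)
  ssr <- 0
  for (i in seq_len(n)) ssr <- ssr + k * (mean(m[i, ]) - g)^2
  ssc <- 0
  for (j in seq_len(k)) ssc <- ssc + n * (mean(m[, j]) - g)^2
  sst <- 0
  for (i in seq_len(n)) for (j in seq_len(k)) sst <- sst + (m[i, j] - g)^2
  sse <- sst - ssr - ssc
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))
}

# O(N^2) direct-sum DFT periodogram with the same one-sided PSD convention.
psd_oracle <- function(x, fs) {
  n <- length(x)
  x <- x - mean(x)
  half <- seq_len(floor(n / 2) + 1)
  f <- (half - 1) * fs / n
  s <- numeric(length(half))
  for (ki in seq_along(half)) {
    k <- half[ki] - 1
    re <- 0; im <- 0
    for (j in seq_len(n)) {
      ang <- -2 * pi * k * (j - 1) / n
      re <- re + x[j] * cos(ang)
      im <- im + x[j] * sin(ang)
    }
    s[ki] <- (re^2 + im^2) / (n * fs)
  }
  scale2 <- rep(2, length(half))
  scale2[1] <- 1
  if (n %% 2 == 0) scale2[length(half)] <- 1
  data.frame(f = f, s = s * scale2)
}

# Benjamini-Hochberg step-up by explicit sorting and cumulative minima.
bh_oracle <- function(p) {
  n <- length(p)
  o <- order(p)
  q <- numeric(n)
  prev <- 1
  for (i in rev(seq_len(n))) {
    val <- min(prev, p[o[i]] * n / i)
    q[o[i]] <- val
    prev <- val
  }
  q
}

# CCC through the algebraically distinct mean-squared-deviation route:
# CCC = 1 - E[(X - Y)^2] / (sx^2 + sy^2 + (mx - my)^2), population moments.
ccc_oracle <- function(x, y) {
  n <- length(x)
  mx <- mean(x); my <- mean(y)
  vx <- sum((x - mx)^2) / n
  vy <- sum((y - my)^2) / n
  msd <- sum((x - y)^2) / n
  1 - msd / (vx + vy + (mx - my)^2)
}

# Wide subject x trial matrix for one biomarker column.
ratings_matrix <- function(panel, biomarker) {
  w <- tidyr::pivot_wider(panel[, c("subject_id", "trial_id", biomarker)],
                          names_from = "trial_id",
                          values_from = dplyr::all_of(biomarker))
  m <- as.matrix(w[, -1])
  dimnames(m) <- NULL
  m
}
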