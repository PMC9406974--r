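# Independent statistical oracles, deliberately written scalar/naive so
# they share no code path with the package implementations.

# ICC(2,1) from the raw sums-of-squares definitions.
icc21_oracle <- function(x, y) {
  n <- length(x)
  k <- 2
  grand <- (sum(x) + sum(y)) / (n * k)
  msr <- 0
  for (i in seq_len(n)) msr <- msr + ((x[i] + y[i]) / 2 - grand)^2
  msr <- msr * k / (n - 1)
  msc <- n * ((mean(x) - grand)^2 + (mean(y) - grand)^2) / (k - 1)
  sse <- 0
  for (i in seq_len(n)) {
    ri <- (x[i] + y[i]) / 2
    for (v in c(x[i] - ri - (mean(x) - grand), y[i] - ri - (mean(y) - grand)))
      sse <- sse + v^2
  }
  mse <- sse / ((n - 1) * (k - 1))
  (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
}

# Exact two-sided Wilcoxon signed-rank p by full 2^n sign enumeration.
wilcoxon_enum_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  w <- sum(r[d > 0])
  ws <- vapply(0:(2^n - 1), function(m) {
    signs <- bitwAnd(m, 2^(0:(n - 1))) > 0
    sum(r[signs])
  }, numeric(1))
  min(1, 2 * min(mean(ws <= w), mean(ws >= w)))
}
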