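# Independent oracles. These deliberately take a different computational
# path from the package implementation: the changepoint oracle
# parameterizes the continuous piecewise-linear model by its four knot
# values (not hinge terms) and solves the normal equations directly; the
# SD oracle is a literal two-pass formula.

# continuous 3-segment least squares at fixed knots, knot-value basis
oracle_pw_fit <- function(days, values, d1, d2) {
  kx <- c(days[1], d1, d2, days[length(days)])
  A <- vapply(1:4, function(j) {
    y <- numeric(4); y[j] <- 1
    stats::approx(kx, y, xout = days)$y
  }, numeric(length(days)))
  beta <- qr.solve(crossprod(A), crossprod(A, values))
  sum((values - A %*% beta)^2)
}

# naive exhaustive enumeration over all admissible changepoint pairs,
# same tie rule as the spec (first lexicographic pair on ties)
oracle_detect_transitions <- function(days, values, min_seg = 2L) {
  n <- length(days)
  best <- NULL
  for (i1 in seq_len(n)) {
    for (i2 in seq_len(n)) {
      if (i1 < min_seg || i2 - i1 < min_seg || n - i2 < min_seg) next
      sse <- oracle_pw_fit(days, values, days[i1], days[i2])
      if (is.null(best) || sse < best$sse * (1 - 1e-9) - 1e-12)
        best <- list(days = c(days[i1], days[i2]), sse = sse)
    }
  }
  best
}

# two-pass sample SD
oracle_sd <- function(x) {
  m <- sum(x) / length(x)
  sqrt(sum((x - m)^2) / (length(x) - 1))
}

# independent accumulation mean
oracle_mean <- function(x) {
  acc <- 0
  for (v in x) acc <- acc + v
  acc / length(x)
}
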