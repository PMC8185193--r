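# Independent oracles, kept deliberately naive and separate from the
# implementations they check.

# Survival summation: explicit per-bin loop over midpoints.
oracleDvhSurvival <- function(edges, volumes) {
  tot <- 0
  for (i in seq_along(volumes)) {
    mid <- (edges[i] + edges[i + 1]) / 2
    tot <- tot + 10^(2 - 0.15 * mid) * volumes[i]
  }
  tot / sum(volumes)
}

# Two-sided sign-test p by exhaustive enumeration of all 2^m equally likely
# sign patterns: the proportion at least as extreme (in |#pos - m/2|) as k.
oracleSignP <- function(m, k) {
  if (m == 0) return(1)
  extreme <- 0L
  for (code in 0:(2^m - 1)) {
    j <- sum(bitwAnd(code, bitwShiftL(1L, 0:(m - 1))) != 0L)
    if (abs(j - m / 2) >= abs(k - m / 2)) extreme <- extreme + 1L
  }
  extreme / 2^m
}

# Follicle-count inversion by bisection (no closed form).
oracleReproductiveAge <- function(n, lo = 0, hi = 200, iters = 200) {
  f <- function(a) 10^(-0.00019 * a^2.452 + 5.717) - n
  for (i in seq_len(iters)) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

# Weighted least squares straight from the normal equations.
oracleWls <- function(X, y, w = rep(1, length(y))) {
  XtWX <- t(X) %*% (X * w)
  XtWy <- t(X) %*% (y * w)
  beta <- solve(XtWX, XtWy)
  res <- (y - X %*% beta) * sqrt(w)
  s2 <- sum(res^2) / (nrow(X) - ncol(X))
  se <- sqrt(diag(s2 * solve(XtWX)))
  list(beta = as.numeric(beta), se = as.numeric(se))
}

# Random valid differential DVH on an irregular grid.
randomDvh <- function(maxBins = 12, maxDose = 40) {
  b <- sample(2:maxBins, 1)
  edges <- sort(runif(b + 1, 0, maxDose))
  while (any(diff(edges) < 1e-6)) edges <- sort(runif(b + 1, 0, maxDose))
  v <- runif(b)
  DifferentialDVH("ovaries", edges, v)
}
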