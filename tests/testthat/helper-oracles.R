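# Independent brute-force oracles, deliberately written as plain
# per-sample / per-assignment loops so they share no code path with the
# package implementations they check.

pli_oracle <- function(phi_i, phi_j) {
  s <- 0
  n <- length(phi_i)
  for (t in seq_len(n)) {
    d <- phi_i[t] - phi_j[t]
    while (d <= -pi) d <- d + 2 * pi
    while (d > pi) d <- d - 2 * pi
    s <- s + sign(d)
  }
  abs(s / n)
}

# population-variance Pearson correlation via explicit loops
cor_oracle <- function(x, y) {
  n <- length(x)
  mx <- sum(x) / n
  my <- sum(y) / n
  sxy <- sxx <- syy <- 0
  for (t in seq_len(n)) {
    sxy <- sxy + (x[t] - mx) * (y[t] - my)
    sxx <- sxx + (x[t] - mx)^2
    syy <- syy + (y[t] - my)^2
  }
  (sxy / n) / sqrt((sxx / n) * (syy / n))
}

fisher_oracle <- function(X, labels) {
  classes <- unique(labels)
  mu <- colMeans(X)
  vapply(seq_len(ncol(X)), function(j) {
    num <- den <- 0
    for (cl in classes) {
      v <- X[labels == cl, j]
      nk <- length(v)
      muk <- mean(v)
      sigk2 <- sum((v - muk)^2) / nk
      num <- num + nk * (muk - mu[j])^2
      den <- den + nk * sigk2
    }
    if (den == 0) { if (num == 0) 0 else Inf } else num / den
  }, numeric(1L))
}

# exact two-sided signed-rank p by enumerating every sign vector
wilcoxon_oracle <- function(a, b) {
  d <- (b - a)
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) return(1)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  w_all <- as.vector(signs %*% r)
  p_le <- mean(w_all <= w_obs + 1e-9)
  p_ge <- mean(w_all >= w_obs - 1e-9)
  min(1, 2 * min(p_le, p_ge))
}
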