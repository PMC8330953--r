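# brute-force reference implementations, deliberately written in the most
# direct way possible and kept independent of the package's vectorized code

oracle_bray_curtis <- function(x, y) {
  num <- 0; den <- 0
  for (k in seq_along(x)) {
    num <- num + abs(x[k] - y[k])
    den <- den + x[k] + y[k]
  }
  num / den
}

oracle_hoeffding_d <- function(x, y) {
  n <- length(x)
  R <- rank(x); S <- rank(y)
  Q <- numeric(n)
  for (i in 1:n) {
    q <- 0
    for (j in 1:n) {
      if (j == i) next
      q <- q +
        (x[j] < x[i]) * (y[j] < y[i]) +
        0.5 * (x[j] == x[i]) * (y[j] < y[i]) +
        0.5 * (x[j] < x[i]) * (y[j] == y[i]) +
        0.25 * (x[j] == x[i]) * (y[j] == y[i])
    }
    Q[i] <- q
  }
  A <- sum((R - 1) * (R - 2) * (S - 1) * (S - 2))
  B <- sum((R - 2) * (S - 2) * Q)
  CC <- sum(Q * (Q - 1))
  30 * (A - 2 * (n - 2) * B + (n - 2) * (n - 3) * CC) /
    (n * (n - 1) * (n - 2) * (n - 3) * (n - 4))
}

oracle_bh <- function(p) {
  m <- length(p)
  out <- numeric(m)
  for (i in seq_len(m)) {
    ranks <- rank(p, ties.method = "first")
    cand <- 1
    for (j in seq_len(m)) {
      if (ranks[j] >= ranks[i]) {
        cand <- min(cand, min(1, p[j] * m / ranks[j]))
      }
    }
    out[i] <- cand
  }
  out
}

# two-sample JZS Bayes factor by brute-force double integration of the
# noncentral-t likelihood over (effect, normal-mixture variance)
oracle_jzs_two_group <- function(y1, y2, r = 0.5) {
  n1 <- length(y1); n2 <- length(y2)
  nu <- n1 + n2 - 2
  sp2 <- (sum((y1 - mean(y1))^2) + sum((y2 - mean(y2))^2)) / nu
  tt <- (mean(y1) - mean(y2)) / sqrt(sp2 * (1 / n1 + 1 / n2))
  neff <- n1 * n2 / (n1 + n2)
  s <- sqrt(2) * r
  uv <- seq(-25, 25, length.out = 601)
  vv <- exp(uv)
  dv <- uv[2] - uv[1]
  lpv <- 0.5 * log(s^2 / 2) - lgamma(0.5) - 1.5 * log(vv) -
    s^2 / (2 * vv) + uv
  dd <- seq(-60, 60, length.out = 1601)
  ddx <- dd[2] - dd[1]
  num <- 0
  for (i in seq_along(vv)) {
    fd <- dnorm(dd, 0, sqrt(vv[i])) *
      suppressWarnings(dt(tt, nu, ncp = dd * sqrt(neff)))
    num <- num + exp(lpv[i]) * dv * ddx *
      (sum(fd) - (fd[1] + fd[length(fd)]) / 2)
  }
  num / dt(tt, nu)
}
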