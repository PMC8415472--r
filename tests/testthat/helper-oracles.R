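# Independent brute-force oracles: each evaluates the defining formula of a
# measure directly (loops, no shared code with the package internals).

oracle_sumdiff <- function(a, b) {
  s <- 0
  for (i in seq_along(a)) s <- s + abs(a[i] - b[i])
  s
}

oracle_autocorrelation <- function(x, m) {
  n <- length(x)
  xb <- sum(x) / n
  num <- 0
  for (t in seq_len(n - m)) num <- num + (x[t] - xb) * (x[t + m] - xb)
  den <- 0
  for (t in seq_len(n)) den <- den + (x[t] - xb)^2
  num / den
}

oracle_pearson <- function(x, y) {
  n <- length(x)
  xb <- sum(x) / n; yb <- sum(y) / n
  num <- sum((x - xb) * (y - yb))
  num / sqrt(sum((x - xb)^2) * sum((y - yb)^2))
}

# MI as the Kullback-Leibler form sum p(a,b) log(p(a,b)/(p(a)p(b))) —
# a different identity from the entropy-sum route used by the package.
oracle_mi <- function(x, y, base = exp(1)) {
  n <- length(x)
  mi <- 0
  for (a in unique(x)) {
    for (b in unique(y)) {
      pxy <- sum(x == a & y == b) / n
      if (pxy > 0) {
        pa <- sum(x == a) / n
        pb <- sum(y == b) / n
        mi <- mi + pxy * log(pxy / (pa * pb)) / log(base)
      }
    }
  }
  mi
}

# Box occupancy via cut(): [lo, b2), ..., [b10, hi] half-open with the last
# bin closed, matching the stated grid convention through a different code
# path.
oracle_boxdim <- function(x, y) {
  lo <- min(x, y); hi <- max(x, y)
  if (hi == lo) return(0)
  br <- seq(lo, hi, length.out = 11)
  ix <- cut(x, br, right = FALSE, include.lowest = TRUE, labels = FALSE)
  iy <- cut(y, br, right = FALSE, include.lowest = TRUE, labels = FALSE)
  log(length(unique(paste(ix, iy)))) / log(10)
}

# Plain Shannon entropy (nats) of an empirical symbol distribution.
oracle_entropy <- function(x) {
  p <- as.vector(table(x)) / length(x)
  -sum(p * log(p))
}

# Direct time-domain Morlet convolution at a single scale (unit spacing),
# evaluated on the zero-padded, periodized series that the FFT route
# implicitly uses (frequency sampling periodizes the wavelet).
oracle_morlet_point <- function(x, s, t0, omega0 = 6) {
  n <- length(x)
  npad <- 2^ceiling(log2(n))
  xp <- c(x - mean(x), rep(0, npad - n))
  m <- seq_len(npad)
  psi <- 0
  for (shift in c(-npad, 0, npad)) {
    u <- (m - t0 + shift) / s
    psi <- psi + pi^(-0.25) * exp(1i * omega0 * u) * exp(-u^2 / 2)
  }
  sum(xp * Conj(psi)) / sqrt(s)
}
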