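# Independent brute-force oracles. These deliberately mirror the printed
# definitions with naive loops/enumeration and share no code with the
# package implementations they check.

oracleAcf <- function(x, nLags) {
  n <- length(x)
  mu <- mean(x)
  d <- x - mu
  denom <- sum(d^2)
  vapply(0:(nLags - 1L), function(k)
    sum(d[1:(n - k)] * d[(1 + k):n]) / denom, numeric(1L))
}

oraclePearson <- function(a, b) {
  ca <- a - mean(a); cb <- b - mean(b)
  sum(ca * cb) / sqrt(sum(ca^2) * sum(cb^2))
}

# ApEn: N-m+1 templates, self-matches included, Chebyshev distance.
oracleApEn <- function(u, m, r) {
  if (r <= 0) return(0)
  phi <- function(mm) {
    n <- length(u) - mm + 1L
    tpl <- sapply(seq_len(n), function(i) u[i:(i + mm - 1L)])
    C <- vapply(seq_len(n), function(i) {
      d <- apply(abs(tpl - tpl[, i]), 2L, max)
      sum(d <= r) / n
    }, numeric(1L))
    mean(log(C))
  }
  phi(m) - phi(m + 1L)
}

# SampEn: templates i = 1..N-m, self-matches excluded, -log(A/B).
oracleSampEn <- function(u, m, r) {
  if (r <= 0) {
    if (all(u == u[1L])) return(0) else return(Inf)
  }
  n <- length(u) - m
  B <- 0L; A <- 0L
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    if (max(abs(u[i:(i + m - 1L)] - u[j:(j + m - 1L)])) <= r) {
      B <- B + 1L
      if (abs(u[i + m] - u[j + m]) <= r) A <- A + 1L
    }
  }
  if (B == 0L || A == 0L) return(Inf)
  -log(A / B)
}

oracleShannonHist <- function(x, nBins) {
  r <- range(x)
  if (diff(r) == 0) return(0)
  edges <- seq(r[1L], r[2L], length.out = nBins + 1L)
  counts <- integer(nBins)
  for (v in x) {
    b <- max(1L, min(nBins, findInterval(v, edges, rightmost.closed = TRUE)))
    counts[b] <- counts[b] + 1L
  }
  p <- counts[counts > 0] / length(x)
  -sum(p * log(p))
}

oracleSpEn <- function(x) {
  n <- length(x)
  P <- Mod(fft(x))^2
  P <- P[1:(n %/% 2L + 1L)]
  if (sum(P) == 0) return(0)
  p <- P / sum(P)
  p <- p[p > 0]
  -sum(p * log(p)) / log(n %/% 2L + 1L)
}

oracleAttEn <- function(x) {
  key <- integer(0)
  for (i in 2:(length(x) - 1L)) {
    if ((x[i] > x[i - 1L] && x[i] > x[i + 1L]) ||
        (x[i] < x[i - 1L] && x[i] < x[i + 1L])) key <- c(key, i)
  }
  if (length(key) < 2L) return(0)
  iv <- diff(key)
  tab <- table(iv)
  p <- as.numeric(tab) / sum(tab)
  -sum(p * log(p))
}

oracleCre <- function(x) {
  xs <- sort(x)
  n <- length(xs)
  if (n < 2L) return(0)
  total <- 0
  for (i in seq_len(n - 1L)) {
    p <- sum(x > xs[i]) / n
    if (p > 0) total <- total + (xs[i + 1L] - xs[i]) * (-p * log(p))
  }
  total
}

# AUC by explicit trapezoidal integration of the empirical ROC.
oracleAucTrapezoid <- function(scores, labels) {
  pts <- rocPoints(scores, labels)
  pts <- pts[order(pts$fpr, pts$tpr), ]
  fpr <- c(0, pts$fpr, 1); tpr <- c(0, pts$tpr, 1)
  sum(diff(fpr) * (head(tpr, -1) + tail(tpr, -1)) / 2)
}
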