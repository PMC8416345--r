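# Independent brute-force oracles, deliberately written with none of the
# package's internals: plain loops and textbook formulas only.

# queue-based flood fill, 8-connectivity; returns an integer label matrix
oracleFloodFill <- function(mask) {
  H <- nrow(mask); W <- ncol(mask)
  lab <- matrix(0L, H, W)
  nxt <- 0L
  for (j in seq_len(W)) {
    for (i in seq_len(H)) {
      if (mask[i, j] == 0 || lab[i, j] != 0L) next
      nxt <- nxt + 1L
      queue <- list(c(i, j))
      lab[i, j] <- nxt
      while (length(queue)) {
        p <- queue[[1]]; queue <- queue[-1]
        for (di in -1:1) for (dj in -1:1) {
          qi <- p[1] + di; qj <- p[2] + dj
          if (qi < 1 || qi > H || qj < 1 || qj > W) next
          if (mask[qi, qj] != 0 && lab[qi, qj] == 0L) {
            lab[qi, qj] <- nxt
            queue[[length(queue) + 1]] <- c(qi, qj)
          }
        }
      }
    }
  }
  lab
}

# partition of a label matrix as a canonical set-of-pixel-sets signature
partitionSignature <- function(lab) {
  comps <- lapply(split(which(lab > 0), lab[lab > 0]), sort)
  unname(comps[order(vapply(comps, min, numeric(1)))])
}

oracleDice <- function(a, b) {
  inter <- 0; na <- 0; nb <- 0
  for (i in seq_along(a)) {
    if (a[i] != 0) na <- na + 1
    if (b[i] != 0) nb <- nb + 1
    if (a[i] != 0 && b[i] != 0) inter <- inter + 1
  }
  if (na + nb == 0) return(1)
  2 * inter / (na + nb)
}

oraclePearson <- function(x, y) {
  n <- length(x)
  mx <- sum(x) / n; my <- sum(y) / n
  sxy <- 0; sxx <- 0; syy <- 0
  for (i in seq_len(n)) {
    sxy <- sxy + (x[i] - mx) * (y[i] - my)
    sxx <- sxx + (x[i] - mx)^2
    syy <- syy + (y[i] - my)^2
  }
  r <- sxy / sqrt(sxx * syy)
  tt <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, p = 2 * stats::pt(-abs(tt), n - 2))
}

# ICC(2,1) from explicitly accumulated two-way ANOVA sums of squares
oracleICC21 <- function(x, y) {
  n <- length(x); k <- 2
  Y <- cbind(x, y)
  grand <- sum(Y) / (n * k)
  SSR <- 0; SSC <- 0; SST <- 0
  rowm <- numeric(n); colm <- numeric(k)
  for (i in seq_len(n)) rowm[i] <- sum(Y[i, ]) / k
  for (j in seq_len(k)) colm[j] <- sum(Y[, j]) / n
  for (i in seq_len(n)) SSR <- SSR + k * (rowm[i] - grand)^2
  for (j in seq_len(k)) SSC <- SSC + n * (colm[j] - grand)^2
  for (i in seq_len(n)) for (j in seq_len(k)) SST <- SST + (Y[i, j] - grand)^2
  SSE <- SST - SSR - SSC
  MSR <- SSR / (n - 1); MSC <- SSC / (k - 1); MSE <- SSE / ((n - 1) * (k - 1))
  unname((MSR - MSE) / (MSR + (k - 1) * MSE + k * (MSC - MSE) / n))
}

oracleBlandAltman <- function(x, y) {
  d <- x - y
  n <- length(d)
  m <- sum(d) / n
  s <- sqrt(sum((d - m)^2) / (n - 1))
  c(meanDiff = m, lo = m - 1.96 * s, hi = m + 1.96 * s)
}

# small desk-scale phantom used across tests
testPhantomSpec <- function(seed = 1L, ...) {
  PhantomSpec(shape = c(4L, 256L, 256L), seed = as.integer(seed), ...)
}
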