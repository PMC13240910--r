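# Independent brute-force oracles, deliberately naive O(n^2) / exhaustive
# implementations kept separate from the package's fast paths.

bruteU <- function(x, y) {
  u <- 0
  for (xi in x) for (yj in y) {
    u <- u + (xi > yj) + 0.5 * (xi == yj)
  }
  u
}

bruteDelta <- function(x, y) {
  s <- 0
  for (xi in x) for (yj in y) s <- s + sign(xi - yj)
  s / (length(x) * length(y))
}

bruteAUC <- function(values, labels, positive = "soluble") {
  pos <- values[labels == positive]
  neg <- values[labels != positive]
  s <- 0
  for (p in pos) for (q in neg) s <- s + (p > q) + 0.5 * (p == q)
  s / (length(pos) * length(neg))
}

bruteHL <- function(x, y) median(as.numeric(outer(x, y, "-")))

bruteYouden <- function(values, labels, positive = "soluble") {
  pos <- values[labels == positive]
  neg <- values[labels != positive]
  best <- -Inf; bestT <- Inf
  for (t in sort(unique(values))) {
    for (orient in c("ge", "le")) {
      if (orient == "ge") {
        j <- mean(pos >= t) + mean(neg < t) - 1
      } else {
        j <- mean(pos <= t) + mean(neg > t) - 1
      }
      if (j > best + 1e-12) {
        best <- j; bestT <- t
      } else if (abs(j - best) <= 1e-12 && t < bestT) {
        bestT <- t
      }
    }
  }
  list(J = max(0, best), threshold = bestT)
}

# exact two-sided Mann-Whitney p by exhaustive label reassignment
bruteExactP <- function(x, y) {
  n1 <- length(x)
  v <- c(x, y)
  n <- length(v)
  mu <- n1 * (n - n1) / 2
  obs <- abs(bruteU(x, y) - mu)
  idx <- utils::combn(n, n1)
  hits <- 0
  for (j in seq_len(ncol(idx))) {
    u <- bruteU(v[idx[, j]], v[-idx[, j]])
    if (abs(u - mu) >= obs - 1e-9) hits <- hits + 1
  }
  hits / ncol(idx)
}

# random two-group instance with ties, sizes 2..nmax
randomInstance <- function(nmax = 60, tie = TRUE) {
  n1 <- sample(2:floor(nmax / 2), 1)
  n2 <- sample(2:(nmax - n1), 1)
  if (tie) {
    pool <- sample(1:12, n1 + n2, replace = TRUE) / 2
  } else {
    pool <- rnorm(n1 + n2)
  }
  list(x = pool[seq_len(n1)], y = pool[n1 + seq_len(n2)])
}

# small labeled ProteinSet reused by several suites
makeTinySet <- function() {
  ProteinSet(
    c(s1 = "MKKLVEEDDE", s2 = "ACDEFGHIKLMNPQRSTVWY", s3 = "GGGGSSSSTT",
      i1 = "AVILAVILAVIL", i2 = "CCWWFFYYMM", i3 = "RRRRHHHHKKKK"),
    labels = c("soluble", "soluble", "soluble",
               "insoluble", "insoluble", "insoluble"))
}
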