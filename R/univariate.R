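#' Mann-Whitney U statistic and two-sided p-value
#'
#' `U` counts between-group pairs with `x_i > y_j` plus half the ties,
#' computed from midranks in O(n log n). The p-value uses the exact
#' permutation distribution of U given the observed midranks (a
#' generating-function dynamic program that is valid under ties) when
#' `n1 + n2 <= 50`, and the tie-corrected normal approximation with
#' continuity correction otherwise. When all values are identical across
#' both groups the variance is zero and `p = 1` by convention.
#'
#' @param x Numeric values of the first group (soluble).
#' @param y Numeric values of the second group (insoluble).
#' @return A list with elements `U` and `p.value`.
#' @examples
#' mannWhitneyU(c(1, 2, 3), c(4, 5, 6))  # U = 0, p = 0.1
#' @export
mannWhitneyU <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  stopifnot(n1 >= 1L, n2 >= 1L)
  r <- rank(c(x, y))
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  n <- n1 + n2
  if (n <= 50L) {
    p <- .exactMannWhitneyP(r, n1, U)
  } else {
    ties <- table(r)
    tieTerm <- sum(ties^3 - ties)
    sigma2 <- (n1 * n2 / 12) * ((n + 1) - tieTerm / (n * (n - 1)))
    if (sigma2 <= 0) {
      p <- 1
    } else {
      mu <- n1 * n2 / 2
      z <- (U - mu - sign(U - mu) * 0.5) / sqrt(sigma2)
      p <- min(1, 2 * stats::pnorm(-abs(z)))
    }
  }
  list(U = U, p.value = p)
}

# Exact permutation distribution of U given midranks, via DP over items.
# Scores are 2*midrank (integers); counts stay exact in doubles up to
# choose(50, 25) < 2^53.
.exactMannWhitneyP <- function(r, n1, U) {
  n <- length(r)
  s <- as.integer(round(2 * r))
  maxSum <- sum(sort(s, decreasing = TRUE)[seq_len(n1)])
  # f[k+1, t+1] = number of size-k subsets with score sum t
  f <- matrix(0, nrow = n1 + 1L, ncol = maxSum + 1L)
  f[1L, 1L] <- 1
  for (item in s) {
    kmax <- n1
    for (k in seq(kmax, 1L)) {
      src <- f[k, ]
      if (item > 0L) {
        shifted <- c(rep(0, item), src[seq_len(length(src) - item)])
      } else {
        shifted <- src
      }
      f[k + 1L, ] <- f[k + 1L, ] + shifted
    }
  }
  counts <- f[n1 + 1L, ]
  total <- sum(counts)
  sums <- seq_along(counts) - 1L           # score sums of x-subset
  uVals <- (sums - n1 * (n1 + 1)) / 2      # U = R1 - n1(n1+1)/2, R1 = sums/2
  mu <- n1 * (n - n1) / 2
  keep <- counts > 0
  obs <- abs(U - mu)
  sum(counts[keep][abs(uVals[keep] - mu) >= obs - 1e-9]) / total
}

#' Cliff's delta effect size
#'
#' `delta = P(x > y) - P(x < y)`, computed from midranks in O(n log n);
#' algebraically `2U/(n1 n2) - 1`.
#'
#' @inheritParams mannWhitneyU
#' @return Numeric in `[-1, 1]`.
#' @examples
#' cliffsDelta(c(1, 2), c(1, 3))  # -0.25
#' @export
cliffsDelta <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  stopifnot(n1 >= 1L, n2 >= 1L)
  r <- rank(c(x, y))
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  2 * U / (n1 * n2) - 1
}

#' Percentile-bootstrap confidence interval for Cliff's delta
#'
#' Draws `B` independent within-group resamples with replacement and returns
#' the 2.5/97.5 percentile interval (for `ciLevel = 0.95`). Deterministic
#' given `seed`.
#'
#' @inheritParams mannWhitneyU
#' @param B Number of bootstrap resamples (>= 100).
#' @param seed Integer seed for the resampling stream.
#' @param ciLevel Confidence level.
#' @return Numeric `c(low, high)`.
#' @export
bootstrapDeltaCI <- function(x, y, B = 2000L, seed = 1L, ciLevel = 0.95) {
  stopifnot(B >= 100L)
  n1 <- length(x); n2 <- length(y)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed))
  d <- vapply(seq_len(B), function(b) {
    cliffsDelta(x[sample.int(n1, n1, replace = TRUE)],
                y[sample.int(n2, n2, replace = TRUE)])
  }, numeric(1))
  alpha <- (1 - ciLevel) / 2
  stats::quantile(d, c(alpha, 1 - alpha), names = FALSE)
}

# count of pairs x_i - y_j <= t, for sorted ys; O(n log n)
.countDiffLE <- function(t, xs, ys) {
  sum(length(ys) - findInterval(xs - t, ys, left.open = TRUE))
}

# largest realized difference x_i - y_j that is <= t (or -Inf)
.maxDiffLE <- function(t, xs, ys) {
  j <- findInterval(xs - t, ys, left.open = TRUE) + 1L  # first y >= x - t
  ok <- j <= length(ys)
  if (!any(ok)) return(-Inf)
  max(xs[ok] - ys[j[ok]])
}

# k-th smallest of the n1*n2 pairwise differences x_i - y_j, without
# materializing the pairs: bisection over the value range with rank
# counting, then snap to the largest realized difference below the bound.
.kthPairDiff <- function(xs, ys, k) {
  lo <- xs[1L] - ys[length(ys)]
  hi <- xs[length(xs)] - ys[1L]
  if (k <= 1L && .countDiffLE(lo, xs, ys) >= 1L) return(lo)
  eps <- 1e-12 * max(1, abs(lo), abs(hi))
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (.countDiffLE(mid, xs, ys) >= k) hi <- mid else lo <- mid
    if ((hi - lo) <= eps) break
  }
  .maxDiffLE(hi, xs, ys)
}

#' Hodges-Lehmann shift estimate with distribution-free CI
#'
#' The shift is the median of all `n1 * n2` pairwise differences
#' `x_i - y_j`, computed by k-th order-statistic selection (binary search
#' over the value range with rank counting) rather than materializing the
#' pairs, so it runs in O(n log n log range). The confidence interval is
#' the classical inversion of the rank-sum statistic: the `k`-th and
#' `(n1 n2 + 1 - k)`-th pairwise differences with
#' `k = floor(n1 n2 / 2 - z_(1-alpha/2) sqrt(n1 n2 (n1+n2+1)/12))`.
#'
#' @inheritParams mannWhitneyU
#' @param ciLevel Confidence level for the interval.
#' @return Numeric `c(shift, low, high)`.
#' @examples
#' hodgesLehmann(c(1, 2, 3), c(0, 1, 2))[1]  # 1
#' @export
hodgesLehmann <- function(x, y, ciLevel = 0.95) {
  n1 <- length(x); n2 <- length(y)
  stopifnot(n1 >= 1L, n2 >= 1L)
  xs <- sort(x); ys <- sort(y)
  m <- as.double(n1) * n2
  shift <- if (m %% 2 == 1) {
    .kthPairDiff(xs, ys, (m + 1) / 2)
  } else {
    (.kthPairDiff(xs, ys, m / 2) + .kthPairDiff(xs, ys, m / 2 + 1)) / 2
  }
  z <- stats::qnorm((1 + ciLevel) / 2)
  k <- floor(m / 2 - z * sqrt(n1 * n2 * (n1 + n2 + 1) / 12))
  k <- max(1, min(k, floor(m / 2)))
  low <- .kthPairDiff(xs, ys, k)
  high <- .kthPairDiff(xs, ys, m + 1 - k)
  c(shift = shift, low = low, high = high)
}

#' Tie-aware ROC AUC
#'
#' `AUC = P(value_pos > value_neg) + 0.5 P(value_pos = value_neg)` computed
#' from midranks. Not orientation-corrected: a feature whose positive class
#' takes smaller values reports AUC < 0.5 as-is.
#'
#' @param values Numeric feature or score values.
#' @param labels Class labels parallel to `values`.
#' @param positive Label treated as the positive class.
#' @return Numeric in `[0, 1]`.
#' @export
rocAUC <- function(values, labels, positive = "soluble") {
  pos <- labels == positive
  nP <- sum(pos); nN <- sum(!pos)
  stopifnot(nP >= 1L, nN >= 1L)
  r <- rank(values)
  (sum(r[pos]) - nP * (nP + 1) / 2) / (as.double(nP) * nN)
}

#' Youden's J and its optimal threshold
#'
#' Scans every distinct observed value as a candidate threshold in both
#' decision orientations (predict positive if `value >= T` and if
#' `value <= T`) and returns the maximum of `sensitivity + specificity - 1`
#' together with the smallest threshold achieving it.
#'
#' @inheritParams rocAUC
#' @return A list with elements `J` and `threshold`.
#' @export
youdenThreshold <- function(values, labels, positive = "soluble") {
  pos <- labels == positive
  nP <- sum(pos); nN <- sum(!pos)
  stopifnot(nP >= 1L, nN >= 1L)
  ord <- order(values)
  vs <- values[ord]
  lp <- pos[ord]
  starts <- which(!duplicated(vs))
  ends <- c(starts[-1L] - 1L, length(vs))
  u <- vs[starts]
  cumP <- cumsum(lp); cumN <- cumsum(!lp)
  posLT <- c(0, cumP)[starts]          # positives strictly below u_k
  negLT <- c(0, cumN)[starts]
  posLE <- cumP[ends]
  negLE <- cumN[ends]
  jGE <- (nP - posLT) / nP + negLT / nN - 1     # positive if value >= T
  jLE <- posLE / nP + (nN - negLE) / nN - 1     # positive if value <= T
  jAll <- c(jGE, jLE)
  tAll <- c(u, u)
  jMax <- max(jAll)
  hit <- which(jAll >= jMax - 1e-12)
  list(J = max(0, jMax), threshold = min(tAll[hit]))
}

#' Benjamini-Hochberg adjusted q-values
#'
#' Step-up FDR adjustment (delegates to [stats::p.adjust()]), preserving
#' input order.
#'
#' @param p Numeric vector of p-values.
#' @return q-values in `[0, 1]`, same order as `p`.
#' @export
bhAdjust <- function(p) stats::p.adjust(p, method = "BH")

# deterministic per-feature substream seed, tied to the canonical feature
# identity so results are independent of analysis order
.featureSeed <- function(seed, feature) {
  idx <- match(feature, solubilityFeatureNames())
  if (is.na(idx)) idx <- 0L
  (as.integer(seed) %% 1000003L) * 1009L + 7919L * idx
}

#' Full univariate analysis of one feature
#'
#' Produces the complete per-feature report row: per-class medians and
#' quartiles (linear-interpolation sample quantiles), Hodges-Lehmann shift
#' with rank-inversion CI, Cliff's delta with percentile-bootstrap CI,
#' Mann-Whitney p, tie-aware AUC, Youden's J and optimal threshold. The
#' `q_value` column is filled by [analyzeFeatures()] across features.
#'
#' @param sf A [SolubilityFeatures-class] with both classes present.
#' @param feature Canonical feature name.
#' @param bootstrapB Bootstrap resamples for the delta CI; `0` skips the
#'   bootstrap (CI columns become `NA`).
#' @param seed Base seed; each feature uses an independent substream.
#' @param ciLevel Confidence level for both intervals.
#' @return One-row `data.frame`.
#' @export
analyzeFeature <- function(sf, feature, bootstrapB = 2000L, seed = 1L,
                           ciLevel = 0.95) {
  if (!feature %in% rownames(sf)) {
    stop("unknown feature: ", feature, call. = FALSE)
  }
  v <- featureValues(sf)[feature, ]
  lab <- solubilityLabels(sf)
  x <- v[lab == "soluble"]; y <- v[lab == "insoluble"]
  if (length(x) < 1L || length(y) < 1L) {
    stop("both classes must be present", call. = FALSE)
  }
  qx <- stats::quantile(x, c(0.5, 0.25, 0.75), names = FALSE, type = 7)
  qy <- stats::quantile(y, c(0.5, 0.25, 0.75), names = FALSE, type = 7)
  hl <- hodgesLehmann(x, y, ciLevel = ciLevel)
  mw <- mannWhitneyU(x, y)
  delta <- cliffsDelta(x, y)
  if (bootstrapB > 0L) {
    ci <- bootstrapDeltaCI(x, y, B = bootstrapB,
                           seed = .featureSeed(seed, feature),
                           ciLevel = ciLevel)
  } else {
    ci <- c(NA_real_, NA_real_)
  }
  auc <- rocAUC(v, lab)
  yj <- youdenThreshold(v, lab)
  data.frame(
    feature_name = feature, n_soluble = length(x), n_insoluble = length(y),
    soluble_median = qx[1], soluble_q1 = qx[2], soluble_q3 = qx[3],
    insoluble_median = qy[1], insoluble_q1 = qy[2], insoluble_q3 = qy[3],
    hl_shift = hl[["shift"]], hl_ci_low = hl[["low"]],
    hl_ci_high = hl[["high"]],
    delta = delta, delta_ci_low = ci[1], delta_ci_high = ci[2],
    p_value = mw$p.value, q_value = NA_real_,
    auc = auc, youden_j = yj$J, threshold = yj$threshold,
    stringsAsFactors = FALSE, row.names = NULL)
}

#' Univariate analysis of all features with joint FDR adjustment
#'
#' Runs [analyzeFeature()] for every requested feature and applies
#' Benjamini-Hochberg adjustment jointly across their p-values. Results are
#' deterministic given `seed` and independent of row or feature order.
#'
#' @inheritParams analyzeFeature
#' @param features Features to analyze (default: all 36).
#' @return `data.frame` with one row per feature.
#' @export
analyzeFeatures <- function(sf, features = solubilityFeatureNames(),
                            bootstrapB = 2000L, seed = 1L, ciLevel = 0.95) {
  rows <- lapply(features, analyzeFeature, sf = sf, bootstrapB = bootstrapB,
                 seed = seed, ciLevel = ciLevel)
  out <- do.call(rbind, rows)
  out$q_value <- bhAdjust(out$p_value)
  out
}
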