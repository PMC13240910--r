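#' @title Composite-delta solubility index
#'
#' @description `CompositeModel` is the untrained linear solubility score
#' `S = sum_j delta_j * (x_j - median_j) / IQR_j` over the
#' redundancy-filtered features: each retained feature is robust-scaled by
#' its pooled median and interquartile range and weighted by its Cliff's
#' delta. `S > 0` classifies soluble, `S <= 0` insoluble. There is no
#' fitting or optimization of any kind -- every constant is an empirical
#' summary of the data.
#'
#' @slot features Ordered retained feature names.
#' @slot weights Cliff's delta per feature, in `[-1, 1]`.
#' @slot medians Pooled per-feature medians (feature units).
#' @slot iqrs Pooled per-feature IQRs (feature units, > 0).
#' @name CompositeModel-class
#' @exportClass CompositeModel
setClass("CompositeModel",
  representation(features = "character", weights = "numeric",
                 medians = "numeric", iqrs = "numeric"))

setValidity("CompositeModel", function(object) {
  msgs <- character(0)
  k <- length(object@features)
  if (length(object@weights) != k || length(object@medians) != k ||
      length(object@iqrs) != k) {
    msgs <- c(msgs, "features, weights, medians, iqrs must have equal length")
  }
  if (any(object@iqrs <= 0)) msgs <- c(msgs, "every IQR must be > 0")
  if (any(abs(object@weights) > 1 + 1e-12)) {
    msgs <- c(msgs, "weights (Cliff's delta) must lie in [-1, 1]")
  }
  if (length(msgs) > 0L) msgs else TRUE
})

#' Construct a CompositeModel directly from constants
#'
#' @param features Feature names.
#' @param weights Delta weights.
#' @param medians Robust-scaling medians.
#' @param iqrs Robust-scaling IQRs (> 0).
#' @return A validated [CompositeModel-class].
#' @examples
#' # the reduced two-feature formulation
#' m <- CompositeModel(c("length", "neg_ratio"), c(-0.215, 0.150),
#'                     c(236, 0.126531), c(231, 0.039934))
#' compositeScore(m, c(length = 236, neg_ratio = 0.126531))  # 0
#' @export
CompositeModel <- function(features, weights, medians, iqrs) {
  new("CompositeModel", features = features,
      weights = stats::setNames(as.numeric(weights), features),
      medians = stats::setNames(as.numeric(medians), features),
      iqrs = stats::setNames(as.numeric(iqrs), features))
}

setMethod("show", "CompositeModel", function(object) {
  cat("CompositeModel (untrained composite-delta index)\n")
  for (f in object@features) {
    cat(sprintf("  %+.4f * (%s - %g) / %g\n", object@weights[[f]], f,
                object@medians[[f]], object@iqrs[[f]]))
  }
})

#' Robust scaling
#'
#' `(x - median) / IQR` with `IQR = Q3 - Q1`; the centering and scale
#' constants are supplied, not estimated here.
#'
#' @param x Numeric values.
#' @param center Median.
#' @param iqr Interquartile range, must be > 0.
#' @return Scaled values.
#' @export
robustScale <- function(x, center, iqr) {
  if (!is.finite(iqr) || iqr <= 0) {
    stop("degenerate feature: IQR must be > 0", call. = FALSE)
  }
  (x - center) / iqr
}

#' Fit the composite-delta model
#'
#' Medians and IQRs are computed on the pooled dataset (both classes
#' together, linear-interpolation quantiles); weights are the retained
#' features' Cliff's delta values taken from a univariate `results` table.
#' No optimization is performed.
#'
#' @param sf A [SolubilityFeatures-class].
#' @param results Output of [analyzeFeatures()].
#' @param retained Features to include.
#' @return A [CompositeModel-class].
#' @export
fitComposite <- function(sf, results, retained) {
  missing <- setdiff(retained, results$feature_name)
  if (length(missing) > 0L) {
    stop("retained feature(s) missing from results: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  vals <- featureValues(sf)
  med <- numeric(0); iqr <- numeric(0)
  for (f in retained) {
    q <- stats::quantile(vals[f, ], c(0.25, 0.5, 0.75), names = FALSE,
                         type = 7)
    if (q[3] - q[1] <= 0) {
      stop("degenerate feature (zero pooled IQR): ", f, call. = FALSE)
    }
    med <- c(med, q[2]); iqr <- c(iqr, q[3] - q[1])
  }
  w <- results$delta[match(retained, results$feature_name)]
  CompositeModel(retained, w, med, iqr)
}

#' Composite-delta score
#'
#' `S = sum_j delta_j * (x_j - median_j) / IQR_j`.
#'
#' @param model A [CompositeModel-class].
#' @param x A named numeric vector of raw feature values, a matrix /
#'   data.frame with the model's features as columns, or a
#'   [SolubilityFeatures-class].
#' @return Numeric score(s), dimensionless.
#' @export
compositeScore <- function(model, x) {
  if (is(x, "SolubilityFeatures")) {
    x <- t(featureValues(x)[model@features, , drop = FALSE])
  } else if (is.null(dim(x))) {
    x <- matrix(x[model@features], nrow = 1,
                dimnames = list(NULL, model@features))
  } else {
    x <- as.matrix(x)[, model@features, drop = FALSE]
  }
  scaled <- sweep(sweep(x, 2, model@medians[model@features], "-"),
                  2, model@iqrs[model@features], "/")
  as.numeric(scaled %*% model@weights[model@features])
}

#' Classify composite scores
#'
#' `S > 0` is soluble; `S <= 0` (including the boundary) is insoluble.
#'
#' @param S Numeric scores.
#' @return Factor with levels soluble/insoluble.
#' @export
classifyScore <- function(S) {
  factor(ifelse(S > 0, "soluble", "insoluble"),
         levels = c("soluble", "insoluble"))
}

#' Descriptive classification metrics
#'
#' Confusion-matrix metrics of the rule "soluble iff `score > threshold`"
#' with soluble as the positive class, plus the tie-aware AUC of the scores.
#' MCC uses the convention 0 when any denominator factor is zero; F1 is 0
#' when its denominator is zero.
#'
#' @param scores Numeric scores.
#' @param labels Labels parallel to `scores` (soluble/insoluble).
#' @param threshold Decision threshold (default 0, the sign rule).
#' @return One-row `data.frame`: threshold, auc, accuracy, f1, mcc,
#'   precision, sensitivity, specificity.
#' @export
evaluateScores <- function(scores, labels, threshold = 0) {
  lab <- as.character(labels)
  keep <- lab %in% c("soluble", "insoluble")
  scores <- scores[keep]; lab <- lab[keep]
  pred <- scores > threshold
  actual <- lab == "soluble"
  tp <- sum(pred & actual); fp <- sum(pred & !actual)
  fn <- sum(!pred & actual); tn <- sum(!pred & !actual)
  acc <- (tp + tn) / length(lab)
  prec <- if (tp + fp > 0) tp / (tp + fp) else 0
  sens <- if (tp + fn > 0) tp / (tp + fn) else 0
  spec <- if (tn + fp > 0) tn / (tn + fp) else 0
  f1den <- 2 * tp + fp + fn
  f1 <- if (f1den > 0) 2 * tp / f1den else 0
  mccden <- as.double(tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  mcc <- if (mccden > 0) {
    (as.double(tp) * tn - as.double(fp) * fn) / sqrt(mccden)
  } else 0
  auc <- rocAUC(scores, lab, positive = "soluble")
  data.frame(threshold = threshold, auc = auc, accuracy = acc, f1 = f1,
             mcc = mcc, precision = prec, sensitivity = sens,
             specificity = spec)
}

#' Serialize / deserialize a CompositeModel as JSON
#'
#' @param model A [CompositeModel-class].
#' @param path JSON file path.
#' @return `writeCompositeModel` returns `path` invisibly;
#'   `readCompositeModel` returns the model.
#' @export
writeCompositeModel <- function(model, path) {
  jsonlite::write_json(
    list(features = model@features,
         weights = unname(model@weights),
         medians = unname(model@medians),
         iqrs = unname(model@iqrs)),
    path, digits = NA, auto_unbox = FALSE)
  invisible(path)
}

#' @rdname writeCompositeModel
#' @export
readCompositeModel <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  CompositeModel(obj$features, obj$weights, obj$medians, obj$iqrs)
}
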