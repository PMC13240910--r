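#' @title Redundancy report
#'
#' @description Result of the Spearman redundancy stage: the tie-aware rank
#' correlation matrix over the analyzed features, the partition of features
#' into redundancy clusters (connected components of the graph with edges
#' `|rho| >= threshold`), and the single retained representative per
#' cluster.
#'
#' @slot featureNames Features analyzed, in input order.
#' @slot rho Symmetric Spearman correlation matrix, unit diagonal.
#' @slot clusters List of character vectors partitioning `featureNames`.
#' @slot retained One representative feature per cluster.
#' @slot threshold The `|rho|` cutoff used.
#' @name RedundancyReport-class
#' @exportClass RedundancyReport
setClass("RedundancyReport",
  representation(featureNames = "character", rho = "matrix",
                 clusters = "list", retained = "character",
                 threshold = "numeric"))

setValidity("RedundancyReport", function(object) {
  msgs <- character(0)
  if (!isTRUE(all.equal(object@rho, t(object@rho), tolerance = 1e-12))) {
    msgs <- c(msgs, "rho must be symmetric")
  }
  if (any(abs(object@rho) > 1 + 1e-12)) msgs <- c(msgs, "|rho| must be <= 1")
  part <- sort(unlist(object@clusters))
  if (!identical(part, sort(object@featureNames))) {
    msgs <- c(msgs, "clusters must partition the feature set")
  }
  if (length(object@retained) != length(object@clusters)) {
    msgs <- c(msgs, "exactly one retained feature per cluster")
  }
  if (length(msgs) > 0L) msgs else TRUE
})

setMethod("show", "RedundancyReport", function(object) {
  cat(sprintf(
    "RedundancyReport: %d feature(s), %d cluster(s) at |rho| >= %g\n",
    length(object@featureNames), length(object@clusters), object@threshold))
  cat("  retained:", paste(object@retained, collapse = ", "), "\n")
})

#' Spearman correlation matrix over features
#'
#' Tie-aware (average-rank) Spearman correlation between every pair of the
#' requested features, diagonal exactly 1.
#'
#' @param sf A [SolubilityFeatures-class].
#' @param features Feature subset (default all 36).
#' @return Symmetric numeric matrix.
#' @export
spearmanMatrix <- function(sf, features = solubilityFeatureNames()) {
  v <- t(featureValues(sf)[features, , drop = FALSE])
  rho <- stats::cor(v, method = "spearman")
  diag(rho) <- 1
  rho
}

#' Cluster features by redundancy
#'
#' Connected components of the graph whose edges join feature pairs with
#' `|rho_ij| >= threshold`. Components (rather than cliques) make the
#' clustering deterministic and parameter-free; a chain of pairwise-strong
#' correlations is treated as one latent axis.
#'
#' @param rho Correlation matrix with dimnames.
#' @param threshold Redundancy cutoff on `|rho|` (default 0.85).
#' @return List of character vectors (clusters), ordered by first member's
#'   position in `rho`'s column order.
#' @export
clusterRedundant <- function(rho, threshold = 0.85) {
  stopifnot(!is.null(colnames(rho)))
  adj <- abs(rho) >= threshold
  diag(adj) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(g)$membership
  clusters <- split(colnames(rho), comp)
  ord <- order(vapply(clusters, function(cl)
    min(match(cl, colnames(rho))), numeric(1)))
  unname(clusters[ord])
}

#' Select one representative feature per cluster
#'
#' Per cluster: the first `preference`-listed feature that is present
#' (default preference is `length`, the directly interpretable size
#' descriptor); otherwise the member with the largest `|delta|`, ties broken
#' deterministically by alphabetical feature name.
#'
#' @param clusters List of feature-name clusters.
#' @param delta Named numeric of Cliff's delta per feature.
#' @param preference Character vector of preferred representatives.
#' @return Character vector, one feature per cluster.
#' @export
selectRepresentatives <- function(clusters, delta,
                                  preference = "length") {
  vapply(clusters, function(cl) {
    pref <- preference[preference %in% cl]
    if (length(pref) > 0L) return(pref[1L])
    d <- abs(delta[cl])
    d[is.na(d)] <- 0
    cand <- cl[d >= max(d) - 1e-15]
    sort(cand)[1L]
  }, character(1))
}

#' Full redundancy analysis
#'
#' Computes the Spearman matrix, clusters at `|rho| >= threshold`, and picks
#' representatives, returning a [RedundancyReport-class].
#'
#' @inheritParams spearmanMatrix
#' @inheritParams clusterRedundant
#' @inheritParams selectRepresentatives
#' @return A [RedundancyReport-class].
#' @export
redundancyReport <- function(sf, features, delta, threshold = 0.85,
                             preference = "length") {
  rho <- spearmanMatrix(sf, features)
  clusters <- clusterRedundant(rho, threshold)
  retained <- selectRepresentatives(clusters, delta, preference)
  new("RedundancyReport", featureNames = features, rho = rho,
      clusters = clusters, retained = retained, threshold = threshold)
}
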