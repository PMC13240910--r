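#' @title Feature matrix container
#'
#' @description `SolubilityFeatures` extends `SummarizedExperiment`: rows are
#' the 36 canonical descriptors (in [solubilityFeatureNames()] order),
#' columns are proteins, the single assay `"features"` holds the values and
#' `colData(x)$label` the solubility labels.
#'
#' @name SolubilityFeatures-class
#' @exportClass SolubilityFeatures
setClass("SolubilityFeatures", contains = "SummarizedExperiment")

setValidity("SolubilityFeatures", function(object) {
  msgs <- character(0)
  if (!"features" %in% SummarizedExperiment::assayNames(object)) {
    msgs <- c(msgs, "assay 'features' is required")
  } else {
    a <- SummarizedExperiment::assay(object, "features")
    if (!identical(rownames(a), solubilityFeatureNames())) {
      msgs <- c(msgs, "rows must be the 36 canonical features in order")
    }
    if (anyNA(a)) msgs <- c(msgs, "feature values must not contain NA")
  }
  if (!"label" %in% names(SummarizedExperiment::colData(object))) {
    msgs <- c(msgs, "colData must contain a 'label' column")
  }
  if (length(msgs) > 0L) msgs else TRUE
})

#' Construct a SolubilityFeatures object
#'
#' @param values Numeric matrix, proteins x 36 features (canonical names as
#'   columns) or 36 x proteins (canonical names as rows).
#' @param labels Solubility labels (recycled scalar allowed).
#' @param ids Protein identifiers.
#' @return A validated [SolubilityFeatures-class].
#' @export
SolubilityFeatures <- function(values, labels = "unlabeled", ids = NULL) {
  featNames <- solubilityFeatureNames()
  if (!is.null(colnames(values)) && all(featNames %in% colnames(values))) {
    values <- t(values[, featNames, drop = FALSE])
  }
  values <- values[featNames, , drop = FALSE]
  if (is.null(ids)) ids <- colnames(values)
  if (is.null(ids)) ids <- sprintf("protein_%d", seq_len(ncol(values)))
  colnames(values) <- ids
  if (length(labels) == 1L) labels <- rep(labels, ncol(values))
  labels <- factor(as.character(labels), levels = SOLUBILITY_LEVELS)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(features = values),
    colData = S4Vectors::DataFrame(label = labels, row.names = ids))
  new("SolubilityFeatures", se)
}

#' @describeIn SolubilityFeatures-class the 36 x n value matrix
#' @param x A `SolubilityFeatures` object.
#' @export
featureValues <- function(x) SummarizedExperiment::assay(x, "features")

#' @describeIn SolubilityFeatures-class the label factor
#' @export
solubilityLabels <- function(x) SummarizedExperiment::colData(x)$label

setMethod("show", "SolubilityFeatures", function(object) {
  tab <- table(solubilityLabels(object))
  cat(sprintf("SolubilityFeatures: %d feature(s) x %d protein(s) (%s)\n",
              nrow(object), ncol(object),
              paste(sprintf("%d %s", tab, names(tab)), collapse = ", ")))
})

.splitResidues <- function(seq) {
  strsplit(toupper(gsub("\\s", "", seq)), "", fixed = TRUE)[[1]]
}

.canonicalResidues <- function(seq) {
  r <- .splitResidues(seq)
  r[r %in% AA20]
}

#' Effective (canonical) sequence length
#'
#' Number of canonical residues; ambiguity codes (`X`, `B`, `Z`, `U`, `O`)
#' are excluded from this count, which is the denominator of every
#' composition feature.
#'
#' @param seq Amino-acid sequence (character scalar).
#' @return Integer length `L >= 1`.
#' @examples
#' effectiveLength("AXA")  # 2
#' @export
effectiveLength <- function(seq) {
  r <- .canonicalResidues(seq)
  if (length(r) == 0L) {
    stop("degenerate record: no canonical residues", call. = FALSE)
  }
  length(r)
}

#' Residue frequencies f_a = n_a / L
#'
#' @param seq Amino-acid sequence.
#' @param tables A [ResidueTables-class] (unused for frequencies themselves,
#'   kept for interface symmetry).
#' @return Named numeric vector over the 20 canonical residues, summing to 1.
#' @export
aaFrequencies <- function(seq, tables = defaultResidueTables()) {
  r <- .canonicalResidues(seq)
  if (length(r) == 0L) stop("degenerate record: no canonical residues",
                            call. = FALSE)
  cnt <- table(factor(r, levels = AA20))
  f <- as.numeric(cnt) / length(r)
  names(f) <- AA20
  f
}

#' Physicochemical group ratios r_G
#'
#' @inheritParams aaFrequencies
#' @return Named numeric: `pos_ratio`, `neg_ratio`, `polar_ratio`,
#'   `hydrophobic_ratio`, `tiny_ratio`, `sulfur_ratio`.
#' @export
groupRatios <- function(seq, tables = defaultResidueTables()) {
  f <- aaFrequencies(seq, tables)
  g <- residueGroups(tables)
  c(pos_ratio = sum(f[g$positive]), neg_ratio = sum(f[g$negative]),
    polar_ratio = sum(f[g$polar]), hydrophobic_ratio = sum(f[g$hydrophobic]),
    tiny_ratio = sum(f[g$tiny]), sulfur_ratio = sum(f[g$sulfur]))
}

#' Molecular weight in Da
#'
#' Sum of average residue masses over canonical residues plus one water.
#'
#' @inheritParams aaFrequencies
#' @export
molecularWeight <- function(seq, tables = defaultResidueTables()) {
  r <- .canonicalResidues(seq)
  if (length(r) == 0L) stop("degenerate record: no canonical residues",
                            call. = FALSE)
  sum(residueMasses(tables)[r]) + tables@waterMass
}

.chargeFromCounts <- function(counts, pH, pka) {
  # counts: named vector over D,E,C,Y,H,K,R (one protein) or matrix n x 7
  basic <- c("K", "R", "H")
  acidic <- c("D", "E", "C", "Y")
  if (is.matrix(counts)) {
    pos <- rep(1 / (1 + 10^(pH - pka[["Nterm"]])), nrow(counts))
    neg <- rep(1 / (1 + 10^(pka[["Cterm"]] - pH)), nrow(counts))
    for (a in basic) pos <- pos + counts[, a] / (1 + 10^(pH - pka[[a]]))
    for (a in acidic) neg <- neg + counts[, a] / (1 + 10^(pka[[a]] - pH))
  } else {
    pos <- 1 / (1 + 10^(pH - pka[["Nterm"]])) +
      sum(counts[basic] / (1 + 10^(pH - pka[basic])))
    neg <- 1 / (1 + 10^(pka[["Cterm"]] - pH)) +
      sum(counts[acidic] / (1 + 10^(pka[acidic] - pH)))
  }
  pos - neg
}

.ionizableCounts <- function(seq) {
  r <- .canonicalResidues(seq)
  if (length(r) == 0L) stop("degenerate record: no canonical residues",
                            call. = FALSE)
  vapply(c("D", "E", "C", "Y", "H", "K", "R"),
         function(a) sum(r == a), numeric(1))
}

#' Henderson-Hasselbalch net charge at a given pH
#'
#' `Q(pH) = sum_basic 1/(1+10^(pH-pKa)) - sum_acidic 1/(1+10^(pKa-pH))`
#' with basic groups = N-terminus, K, R, H and acidic groups = C-terminus,
#' D, E, C, Y. Strictly decreasing in pH.
#'
#' @inheritParams aaFrequencies
#' @param pH pH in `[0, 14]`.
#' @return Net charge in elementary charges.
#' @export
netCharge <- function(seq, pH = 7, tables = defaultResidueTables()) {
  stopifnot(pH >= 0, pH <= 14)
  .chargeFromCounts(.ionizableCounts(seq), pH, pkaSet(tables))
}

#' Isoelectric point by bisection
#'
#' The unique root of [netCharge()] on `[0, 14]`, found by bisection to a
#' pH tolerance of 1e-6 (well inside the documented 1e-4 contract). The
#' termini guarantee at least one ionizable group of each sign, so the root
#' exists and is unique (the charge curve is strictly decreasing).
#'
#' @inheritParams aaFrequencies
#' @return pI in pH units, in `(0, 14)`.
#' @export
isoelectricPoint <- function(seq, tables = defaultResidueTables()) {
  counts <- .ionizableCounts(seq)
  pka <- pkaSet(tables)
  lo <- 0; hi <- 14
  for (i in 1:60) {
    mid <- (lo + hi) / 2
    if (.chargeFromCounts(counts, mid, pka) > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Mean Kyte-Doolittle hydropathy (GRAVY)
#'
#' @inheritParams aaFrequencies
#' @export
meanHydropathy <- function(seq, tables = defaultResidueTables()) {
  r <- .canonicalResidues(seq)
  if (length(r) == 0L) stop("degenerate record: no canonical residues",
                            call. = FALSE)
  mean(hydropathyScale(tables)[r])
}

#' Mean Chou-Fasman propensity for a structure class
#'
#' @inheritParams aaFrequencies
#' @param structureClass `"helix"`, `"sheet"` or `"turn"`.
#' @export
propensityMean <- function(seq, structureClass = c("helix", "sheet", "turn"),
                           tables = defaultResidueTables()) {
  structureClass <- match.arg(structureClass)
  r <- .canonicalResidues(seq)
  if (length(r) == 0L) stop("degenerate record: no canonical residues",
                            call. = FALSE)
  mean(propensityScale(tables, structureClass)[r])
}

#' Disorder ratio
#'
#' Fraction of canonical residues whose disorder propensity `d(a)` strictly
#' exceeds the threshold `tau` of `tables`.
#'
#' @inheritParams aaFrequencies
#' @export
disorderRatio <- function(seq, tables = defaultResidueTables()) {
  r <- .canonicalResidues(seq)
  if (length(r) == 0L) stop("degenerate record: no canonical residues",
                            call. = FALSE)
  mean(disorderScale(tables)[r] > disorderThreshold(tables))
}

.maxHydrophobicRun <- function(chars, hydrophobicSet) {
  pat <- sprintf("[%s]+", paste(hydrophobicSet, collapse = ""))
  m <- gregexpr(pat, chars)
  vapply(m, function(mm) {
    if (mm[1L] == -1L) 0L else max(attr(mm, "match.length"))
  }, integer(1))
}

#' Aggregation ratio
#'
#' Length of the longest contiguous run of hydrophobic residues divided by
#' the effective (canonical) length. An ambiguous residue interrupts a run.
#'
#' @inheritParams aaFrequencies
#' @examples
#' aggregationRatio("AAADAA")  # 0.5
#' @export
aggregationRatio <- function(seq, tables = defaultResidueTables()) {
  L <- effectiveLength(seq)
  run <- .maxHydrophobicRun(toupper(gsub("\\s", "", seq)),
                            residueGroups(tables)$hydrophobic)
  run / L
}

#' Extract the 36 canonical descriptors for every record
#'
#' Vectorized over the whole [ProteinSet-class]; deterministic and
#' order-preserving. Ambiguous residues (`X, B, Z, U, O`) are excluded from
#' every computation (counts, masses, hydropathy, propensities, runs) and
#' from the length denominator, and they interrupt hydrophobic runs.
#'
#' @param proteins A [ProteinSet-class].
#' @param tables A [ResidueTables-class].
#' @return A [SolubilityFeatures-class] with one column per record.
#' @examples
#' ps <- ProteinSet(c(a = "ACDEFGHIKLMNPQRSTVWY"), labels = "soluble")
#' featureValues(extractFeatures(ps))["freq_A", ]  # 0.05
#' @export
extractFeatures <- function(proteins, tables = defaultResidueTables()) {
  stopifnot(is(proteins, "ProteinSet"))
  seqs <- proteinSequences(proteins)
  cnt <- Biostrings::letterFrequency(seqs, letters = AA20)
  colnames(cnt) <- AA20
  L <- rowSums(cnt)
  if (any(L == 0)) {
    stop("degenerate record(s) with no canonical residues: ",
         paste(utils::head(proteinIDs(proteins)[L == 0], 5), collapse = ", "),
         call. = FALSE)
  }
  freq <- cnt / L
  g <- residueGroups(tables)
  grpRatio <- function(set) rowSums(freq[, set, drop = FALSE])

  mw <- as.numeric(cnt %*% residueMasses(tables)[AA20]) + tables@waterMass
  hyd <- as.numeric(freq %*% hydropathyScale(tables)[AA20])
  propMean <- function(s)
    as.numeric(freq %*% propensityScale(tables, s)[AA20])
  disInd <- as.numeric(disorderScale(tables)[AA20] >
                       disorderThreshold(tables))
  dis <- as.numeric(freq %*% disInd)

  pka <- pkaSet(tables)
  ion <- cnt[, c("D", "E", "C", "Y", "H", "K", "R"), drop = FALSE]
  qc <- .chargeFromCounts(ion, 7, pka)
  lo <- rep(0, length(L)); hi <- rep(14, length(L))
  basic <- c("K", "R", "H"); acidic <- c("D", "E", "C", "Y")
  for (i in 1:60) {
    # vectorized charge at per-protein bisection midpoints
    mid <- (lo + hi) / 2
    q <- 1 / (1 + 10^(mid - pka[["Nterm"]])) -
         1 / (1 + 10^(pka[["Cterm"]] - mid))
    for (a in basic)  q <- q + ion[, a] / (1 + 10^(mid - pka[[a]]))
    for (a in acidic) q <- q - ion[, a] / (1 + 10^(pka[[a]] - mid))
    up <- q > 0
    lo[up] <- mid[up]; hi[!up] <- mid[!up]
  }
  pI <- (lo + hi) / 2

  runs <- .maxHydrophobicRun(as.character(seqs), g$hydrophobic)

  vals <- rbind(
    length = L, molecular_weight = mw, isoelectric_point = pI,
    net_charge_pH7 = qc, mean_hydropathy = hyd,
    pos_ratio = grpRatio(g$positive), neg_ratio = grpRatio(g$negative),
    polar_ratio = grpRatio(g$polar),
    hydrophobic_ratio = grpRatio(g$hydrophobic),
    tiny_ratio = grpRatio(g$tiny), sulfur_ratio = grpRatio(g$sulfur),
    helix_prop_mean = propMean("helix"), sheet_prop_mean = propMean("sheet"),
    turn_prop_mean = propMean("turn"), disorder_ratio = dis,
    aggregation_ratio = runs / L,
    t(freq)[, , drop = FALSE])
  rownames(vals) <- solubilityFeatureNames()
  SolubilityFeatures(vals, labels = proteinLabels(proteins),
                     ids = proteinIDs(proteins))
}
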