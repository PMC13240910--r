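#' @title Labeled protein sequence set
#'
#' @description `ProteinSet` holds an ordered collection of identified,
#' labeled amino-acid sequences. Sequences are stored as a
#' [Biostrings::AAStringSet] (uppercase, no gaps); labels are a factor with
#' levels `soluble`, `insoluble`, `unlabeled`; `provenance` records source
#' files and the label-assignment rule.
#'
#' @slot sequences An `AAStringSet`, names are the unique record ids.
#' @slot labels Factor parallel to `sequences`.
#' @slot provenance Character vector describing origin.
#'
#' @name ProteinSet-class
#' @exportClass ProteinSet
setClass("ProteinSet",
  representation(sequences = "AAStringSet", labels = "factor",
                 provenance = "character"))

setValidity("ProteinSet", function(object) {
  msgs <- character(0)
  ids <- names(object@sequences)
  if (is.null(ids) || anyNA(ids) || any(ids == "")) {
    msgs <- c(msgs, "every record must have a non-empty id")
  } else if (anyDuplicated(ids)) {
    msgs <- c(msgs, sprintf("duplicate record id(s): %s",
      paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  }
  if (length(object@labels) != length(object@sequences)) {
    msgs <- c(msgs, "labels must be parallel to sequences")
  }
  if (!all(levels(object@labels) %in% SOLUBILITY_LEVELS)) {
    msgs <- c(msgs, "labels must use levels soluble/insoluble/unlabeled")
  }
  if (any(Biostrings::width(object@sequences) == 0L)) {
    msgs <- c(msgs, "empty sequence(s) present")
  }
  if (length(msgs) > 0L) msgs else TRUE
})

#' Construct a ProteinSet
#'
#' @param sequences Character vector or `AAStringSet` of amino-acid
#'   sequences (uppercased on input).
#' @param ids Record identifiers; defaults to `names(sequences)`.
#' @param labels Character/factor of `soluble`/`insoluble`/`unlabeled`;
#'   recycled scalar allowed.
#' @param provenance Free-text origin description.
#' @return A validated [ProteinSet-class].
#' @examples
#' ps <- ProteinSet(c(p1 = "MKLV", p2 = "ACDE"), labels = "soluble")
#' proteinLabels(ps)
#' @export
ProteinSet <- function(sequences, ids = names(sequences),
                       labels = "unlabeled", provenance = "in-memory") {
  if (is.character(sequences)) {
    sequences <- Biostrings::AAStringSet(toupper(gsub("\\s", "", sequences)))
  }
  names(sequences) <- ids
  if (length(labels) == 1L) labels <- rep(labels, length(sequences))
  labels <- factor(as.character(labels), levels = SOLUBILITY_LEVELS)
  if (anyNA(labels)) stop("labels must be soluble/insoluble/unlabeled",
                          call. = FALSE)
  new("ProteinSet", sequences = sequences, labels = labels,
      provenance = provenance)
}

#' @describeIn ProteinSet-class record ids
#' @param x A `ProteinSet`.
#' @export
proteinIDs <- function(x) names(x@sequences)

#' @describeIn ProteinSet-class sequences as `AAStringSet`
#' @export
proteinSequences <- function(x) x@sequences

#' @describeIn ProteinSet-class label factor
#' @export
proteinLabels <- function(x) x@labels

setMethod("show", "ProteinSet", function(object) {
  n <- length(object@sequences)
  tab <- table(object@labels)
  cat(sprintf("ProteinSet with %d record(s): %s\n", n,
              paste(sprintf("%d %s", tab, names(tab)), collapse = ", ")))
  cat("  provenance:", paste(object@provenance, collapse = "; "), "\n")
})

setMethod("length", "ProteinSet", function(x) length(x@sequences))

#' Label-assignment rules for FASTA ingestion
#'
#' The benchmark FASTA dialect is not standardized, so the label of each
#' record is assigned by a pluggable rule: a fixed label for a whole file, a
#' case-insensitive keyword/regex match on the full header line, or a
#' two-column (`id,label`) sidecar CSV.
#'
#' @param label Fixed label for every record.
#' @param insolublePattern,solublePattern Regular expressions tried in that
#'   order against the header (insoluble first, because the English word
#'   "insoluble" contains "soluble").
#' @param unmatched Label used when neither pattern matches.
#' @param path Sidecar CSV path with columns `id` and `label`.
#' @return A label rule object for [readProteinFasta()].
#' @name labelRules
NULL

#' @rdname labelRules
#' @export
fixedLabelRule <- function(label = "unlabeled") {
  label <- match.arg(label, SOLUBILITY_LEVELS)
  structure(list(type = "fixed", label = label), class = "deltasol_label_rule")
}

#' @rdname labelRules
#' @export
headerLabelRule <- function(insolublePattern = "insoluble",
                            solublePattern = "soluble",
                            unmatched = "unlabeled") {
  unmatched <- match.arg(unmatched, SOLUBILITY_LEVELS)
  structure(list(type = "header", insoluble = insolublePattern,
                 soluble = solublePattern, unmatched = unmatched),
            class = "deltasol_label_rule")
}

#' @rdname labelRules
#' @export
sidecarLabelRule <- function(path) {
  structure(list(type = "sidecar", path = path),
            class = "deltasol_label_rule")
}

.applyLabelRule <- function(rule, ids, headers) {
  switch(rule$type,
    fixed = rep(rule$label, length(ids)),
    header = {
      lab <- rep(rule$unmatched, length(ids))
      lab[grepl(rule$soluble, headers, ignore.case = TRUE)] <- "soluble"
      lab[grepl(rule$insoluble, headers, ignore.case = TRUE)] <- "insoluble"
      lab
    },
    sidecar = {
      side <- utils::read.csv(rule$path, stringsAsFactors = FALSE)
      if (!all(c("id", "label") %in% names(side))) {
        stop("sidecar table must have columns id,label", call. = FALSE)
      }
      orphan <- setdiff(side$id, ids)
      if (length(orphan) > 0L) {
        stop("sidecar id(s) without sequence: ",
             paste(utils::head(orphan, 5), collapse = ", "), call. = FALSE)
      }
      lab <- rep("unlabeled", length(ids))
      hit <- match(ids, side$id)
      lab[!is.na(hit)] <- side$label[hit[!is.na(hit)]]
      lab
    },
    stop("unknown label rule", call. = FALSE))
}

#' Read labeled protein sequences from FASTA
#'
#' Reads a FASTA file (wrapped or unwrapped sequence lines), assigns labels
#' by `labelRule`, and validates the alphabet. The 20 canonical residues
#' plus the ambiguity codes `X, B, Z, U, O` are accepted; ambiguous residues
#' are preserved verbatim in the record (they are excluded later, at feature
#' extraction). No filtering of any kind is applied.
#'
#' @param path FASTA file path.
#' @param labelRule A rule from [fixedLabelRule()], [headerLabelRule()] or
#'   [sidecarLabelRule()].
#' @param invalidPolicy `"reject"` (default) errors on characters outside
#'   the canonical + ambiguity alphabet, naming the offending record;
#'   `"ambiguous"` replaces them with `X`.
#' @return A [ProteinSet-class] in file order.
#' @export
readProteinFasta <- function(path, labelRule = headerLabelRule(),
                             invalidPolicy = c("reject", "ambiguous")) {
  invalidPolicy <- match.arg(invalidPolicy)
  stopifnot(inherits(labelRule, "deltasol_label_rule"))
  raw <- Biostrings::readBStringSet(path)
  if (length(raw) == 0L) stop("empty FASTA file: ", path, call. = FALSE)
  headers <- names(raw)
  ids <- sub("\\s.*$", "", headers)
  if (anyDuplicated(ids)) {
    stop("duplicate FASTA id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  seqs <- toupper(gsub("[ \t\r]", "", as.character(raw)))
  allowed <- paste0(c(AA20, AA_AMBIGUOUS), collapse = "")
  bad <- grepl(sprintf("[^%s]", allowed), seqs)
  if (any(bad)) {
    if (invalidPolicy == "reject") {
      stop("invalid residue character(s) in record(s): ",
           paste(utils::head(ids[bad], 5), collapse = ", "), call. = FALSE)
    }
    seqs[bad] <- gsub(sprintf("[^%s]", allowed), "X", seqs[bad])
  }
  labels <- .applyLabelRule(labelRule, ids, headers)
  ProteinSet(seqs, ids = ids, labels = labels,
             provenance = sprintf("fasta:%s rule:%s", path, labelRule$type))
}

#' Write a ProteinSet to FASTA
#'
#' Headers are `id label` so the set round-trips through
#' [readProteinFasta()] with the default header rule.
#'
#' @param x A [ProteinSet-class].
#' @param path Output path.
#' @param width Line-wrap width.
#' @return `path`, invisibly.
#' @export
writeProteinFasta <- function(x, path, width = 60L) {
  out <- x@sequences
  names(out) <- paste(proteinIDs(x), as.character(proteinLabels(x)))
  Biostrings::writeXStringSet(out, path, width = width)
  invisible(path)
}

#' Merge several ProteinSets into one
#'
#' Concatenates record collections preserving part order; label counts are
#' additive. Ids must be unique across parts.
#'
#' @param parts A list of [ProteinSet-class] objects.
#' @return A merged [ProteinSet-class].
#' @export
mergeProteinSets <- function(parts) {
  stopifnot(length(parts) >= 1L,
            all(vapply(parts, is, logical(1), "ProteinSet")))
  ids <- unlist(lapply(parts, proteinIDs))
  if (anyDuplicated(ids)) {
    stop("id collision across parts: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  seqs <- do.call(c, lapply(parts, proteinSequences))
  labels <- factor(unlist(lapply(parts, function(p)
    as.character(proteinLabels(p)))), levels = SOLUBILITY_LEVELS)
  new("ProteinSet", sequences = seqs, labels = labels,
      provenance = unlist(lapply(parts, function(p) p@provenance)))
}

# Full-precision numeric formatting so feature CSVs round-trip
# bit-identically.
.fmtNum <- function(x) {
  out <- sprintf("%.17g", x)
  out[is.na(x)] <- "NA"
  out
}

#' Write a feature matrix to CSV
#'
#' Columns are `id,label` followed by the 36 canonical features in
#' [solubilityFeatureNames()] order. Values are serialized with 17
#' significant digits so that [readFeatureCSV()] reproduces them
#' bit-identically.
#'
#' @param sf A [SolubilityFeatures-class] object.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
writeFeatureCSV <- function(sf, path) {
  vals <- featureValues(sf)
  df <- data.frame(id = colnames(sf), label = as.character(solubilityLabels(sf)),
                   stringsAsFactors = FALSE)
  for (nm in solubilityFeatureNames()) df[[nm]] <- .fmtNum(vals[nm, ])
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a feature matrix from CSV
#'
#' Accepts the table written by [writeFeatureCSV()] (or the equivalent
#' benchmark export): an `id` column, an optional `label` column (absent
#' labels default to `unlabeled`), and exactly the 36 canonical feature
#' columns. Unknown or missing feature columns are an error.
#'
#' @param path CSV path.
#' @return A [SolubilityFeatures-class] object.
#' @export
readFeatureCSV <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!"id" %in% names(df)) stop("feature CSV must have an id column",
                                 call. = FALSE)
  labels <- if ("label" %in% names(df)) df$label else "unlabeled"
  featNames <- solubilityFeatureNames()
  missing <- setdiff(featNames, names(df))
  if (length(missing) > 0L) {
    stop("feature CSV is missing feature column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  unknown <- setdiff(names(df), c("id", "label", featNames))
  if (length(unknown) > 0L) {
    stop("unknown column(s) in feature CSV: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  vals <- as.matrix(df[featNames])
  storage.mode(vals) <- "double"
  SolubilityFeatures(vals, labels = labels, ids = df$id)
}
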