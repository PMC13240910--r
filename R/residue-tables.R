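#' @title Per-residue property tables
#'
#' @description `ResidueTables` is the single source of truth for every
#' per-residue constant used by feature extraction: average residue masses,
#' Kyte-Doolittle hydropathy, Chou-Fasman helix/sheet/turn propensities, a
#' residue-level disorder propensity scale with its threshold `tau`,
#' side-chain and terminal pKa values, and the six physicochemical residue
#' groups. Every scale carries a provenance string so pipeline reports can
#' state which published scale was used.
#'
#' @slot masses Named numeric, average residue (not free amino acid) masses
#'   in Da for the 20 canonical residues.
#' @slot waterMass Numeric(1), mass of one water in Da added per peptide.
#' @slot hydropathy Named numeric, Kyte-Doolittle indices.
#' @slot propensities List with elements `helix`, `sheet`, `turn`, each a
#'   named numeric over the 20 canonical residues.
#' @slot disorderScale Named numeric disorder propensities `d(a)`.
#' @slot disorderThreshold Numeric(1) threshold `tau`; a residue counts as
#'   disorder-promoting when `d(a) > tau` (strict).
#' @slot pka Named numeric over `D,E,C,Y,H,K,R,Nterm,Cterm`.
#' @slot groups List of residue sets: `positive`, `negative`, `polar`,
#'   `hydrophobic`, `tiny`, `sulfur`.
#' @slot provenance Named character, literature source per scale.
#'
#' @seealso [defaultResidueTables()], [readResidueTables()],
#'   [writeResidueTables()]
#' @name ResidueTables-class
#' @exportClass ResidueTables
setClass("ResidueTables",
  representation(
    masses            = "numeric",
    waterMass         = "numeric",
    hydropathy        = "numeric",
    propensities      = "list",
    disorderScale     = "numeric",
    disorderThreshold = "numeric",
    pka               = "numeric",
    groups            = "list",
    provenance        = "character"
  )
)

.checkResidueCoverage <- function(x, what) {
  missing <- setdiff(AA20, names(x))
  if (length(missing) > 0L) {
    return(sprintf("%s is missing residue(s): %s",
                   what, paste(missing, collapse = ", ")))
  }
  extra <- setdiff(names(x), AA20)
  if (length(extra) > 0L) {
    return(sprintf("%s has unknown residue(s): %s",
                   what, paste(extra, collapse = ", ")))
  }
  if (anyNA(x) || !is.numeric(x)) {
    return(sprintf("%s contains missing or non-numeric entries", what))
  }
  NULL
}

setValidity("ResidueTables", function(object) {
  msgs <- character(0)
  for (nm in c("masses", "hydropathy", "disorderScale")) {
    m <- .checkResidueCoverage(slot(object, nm), nm)
    if (!is.null(m)) msgs <- c(msgs, m)
  }
  if (!setequal(names(object@propensities), c("helix", "sheet", "turn"))) {
    msgs <- c(msgs, "propensities must have elements helix, sheet, turn")
  } else {
    for (s in c("helix", "sheet", "turn")) {
      m <- .checkResidueCoverage(object@propensities[[s]],
                                 paste0("propensities$", s))
      if (!is.null(m)) msgs <- c(msgs, m)
    }
  }
  pkaNames <- c("D", "E", "C", "Y", "H", "K", "R", "Nterm", "Cterm")
  if (!setequal(names(object@pka), pkaNames)) {
    msgs <- c(msgs, sprintf(
      "pka must cover exactly {%s}", paste(pkaNames, collapse = ",")))
  }
  groupNames <- c("positive", "negative", "polar", "hydrophobic",
                  "tiny", "sulfur")
  if (!all(groupNames %in% names(object@groups))) {
    msgs <- c(msgs, "groups must define positive, negative, polar, hydrophobic, tiny, sulfur")
  } else {
    bad <- vapply(object@groups, function(g) !all(g %in% AA20), logical(1))
    if (any(bad)) {
      msgs <- c(msgs, sprintf("group(s) %s contain non-canonical residues",
                              paste(names(object@groups)[bad], collapse = ", ")))
    }
  }
  if (any(object@masses <= 0)) msgs <- c(msgs, "all masses must be > 0")
  if (length(object@waterMass) != 1L || object@waterMass <= 0) {
    msgs <- c(msgs, "waterMass must be a single positive number")
  }
  if (length(object@disorderThreshold) != 1L ||
      !is.finite(object@disorderThreshold)) {
    msgs <- c(msgs, "disorderThreshold must be a single finite number")
  }
  if (length(msgs) > 0L) msgs else TRUE
})

#' Default residue property tables
#'
#' Returns the package defaults: average residue masses (+ one water per
#' chain), the Kyte-Doolittle hydropathy scale, classical Chou-Fasman
#' helix/sheet/turn propensities, the TOP-IDP disorder propensity scale with
#' threshold `tau = 0`, EMBOSS-style pKa values (side chains D, E, C, Y, H,
#' K, R plus termini), and the six physicochemical residue groups
#' (`positive = {K,R,H}`, `negative = {D,E}`, `polar = {S,T,N,Q}`,
#' `hydrophobic = {A,V,I,L,M,F,W,Y}`, `tiny = {A,G,S,T}`,
#' `sulfur = {C,M}`). Each scale's literature identity is recorded in the
#' `provenance` slot. Any entry can be overridden from a YAML file with
#' [readResidueTables()], e.g. to substitute a different disorder scale.
#'
#' @return A validated [ResidueTables-class] object.
#' @examples
#' tab <- defaultResidueTables()
#' hydropathyScale(tab)[["I"]]  # 4.5
#' residueGroups(tab)$negative  # D, E
#' @export
defaultResidueTables <- function() {
  masses <- c(
    A = 71.0788,  C = 103.1388, D = 115.0886, E = 129.1155, F = 147.1766,
    G = 57.0519,  H = 137.1411, I = 113.1594, K = 128.1741, L = 113.1594,
    M = 131.1926, N = 114.1038, P = 97.1167,  Q = 128.1307, R = 156.1875,
    S = 87.0782,  T = 101.1051, V = 99.1326,  W = 186.2132, Y = 163.1760)
  hydropathy <- c(
    A = 1.8,  C = 2.5,  D = -3.5, E = -3.5, F = 2.8,
    G = -0.4, H = -3.2, I = 4.5,  K = -3.9, L = 3.8,
    M = 1.9,  N = -3.5, P = -1.6, Q = -3.5, R = -4.5,
    S = -0.8, T = -0.7, V = 4.2,  W = -0.9, Y = -1.3)
  helix <- c(
    A = 1.42, C = 0.70, D = 1.01, E = 1.51, F = 1.13,
    G = 0.57, H = 1.00, I = 1.08, K = 1.16, L = 1.21,
    M = 1.45, N = 0.67, P = 0.57, Q = 1.11, R = 0.98,
    S = 0.77, T = 0.83, V = 1.06, W = 1.08, Y = 0.69)
  sheet <- c(
    A = 0.83, C = 1.19, D = 0.54, E = 0.37, F = 1.38,
    G = 0.75, H = 0.87, I = 1.60, K = 0.74, L = 1.30,
    M = 1.05, N = 0.89, P = 0.55, Q = 1.10, R = 0.93,
    S = 0.75, T = 1.19, V = 1.70, W = 1.37, Y = 1.47)
  turn <- c(
    A = 0.66, C = 1.19, D = 1.46, E = 0.74, F = 0.60,
    G = 1.56, H = 0.95, I = 0.47, K = 1.01, L = 0.59,
    M = 0.60, N = 1.56, P = 1.52, Q = 0.98, R = 0.95,
    S = 1.43, T = 0.96, V = 0.50, W = 0.96, Y = 1.14)
  # TOP-IDP disorder propensities (disorder-promoting > 0)
  disorder <- c(
    A = 0.060,  C = 0.020,  D = 0.192,  E = 0.736,  F = -0.697,
    G = 0.166,  H = 0.303,  I = -0.486, K = 0.586,  L = -0.326,
    M = -0.397, N = 0.007,  P = 0.987,  Q = 0.318,  R = 0.180,
    S = 0.341,  T = 0.059,  V = -0.121, W = -0.884, Y = -0.510)
  pka <- c(D = 3.9, E = 4.1, C = 8.5, Y = 10.1, H = 6.5, K = 10.8,
           R = 12.5, Nterm = 8.6, Cterm = 3.6)
  groups <- list(
    positive    = c("K", "R", "H"),
    negative    = c("D", "E"),
    polar       = c("S", "T", "N", "Q"),
    hydrophobic = c("A", "V", "I", "L", "M", "F", "W", "Y"),
    tiny        = c("A", "G", "S", "T"),
    sulfur      = c("C", "M"))
  provenance <- c(
    masses       = "average residue masses (IUPAC standard atomic weights)",
    hydropathy   = "Kyte & Doolittle (1982) hydropathy index",
    propensities = "Chou & Fasman (1978) conformational parameters",
    disorder     = "TOP-IDP scale, Campen et al. (2008); threshold tau = 0",
    pka          = "EMBOSS pKa set (side chains D,E,C,Y,H,K,R; termini 8.6/3.6)")
  new("ResidueTables",
      masses = masses[AA20], waterMass = 18.01524,
      hydropathy = hydropathy[AA20],
      propensities = list(helix = helix[AA20], sheet = sheet[AA20],
                          turn = turn[AA20]),
      disorderScale = disorder[AA20], disorderThreshold = 0,
      pka = pka, groups = groups, provenance = provenance)
}

#' @describeIn ResidueTables-class residue masses accessor
#' @param tables A `ResidueTables` object.
#' @export
residueMasses <- function(tables) tables@masses

#' @describeIn ResidueTables-class hydropathy scale accessor
#' @export
hydropathyScale <- function(tables) tables@hydropathy

#' @describeIn ResidueTables-class propensity scale accessor
#' @param structureClass One of `"helix"`, `"sheet"`, `"turn"`.
#' @export
propensityScale <- function(tables, structureClass) {
  structureClass <- match.arg(structureClass, c("helix", "sheet", "turn"))
  tables@propensities[[structureClass]]
}

#' @describeIn ResidueTables-class disorder scale accessor
#' @export
disorderScale <- function(tables) tables@disorderScale

#' @describeIn ResidueTables-class disorder threshold accessor
#' @export
disorderThreshold <- function(tables) tables@disorderThreshold

#' @describeIn ResidueTables-class pKa set accessor
#' @export
pkaSet <- function(tables) tables@pka

#' @describeIn ResidueTables-class residue group accessor
#' @export
residueGroups <- function(tables) tables@groups

#' @describeIn ResidueTables-class provenance strings accessor
#' @export
tableProvenance <- function(tables) tables@provenance

setMethod("show", "ResidueTables", function(object) {
  cat("ResidueTables (20 canonical residues)\n")
  cat("  disorder threshold tau:", object@disorderThreshold, "\n")
  cat("  groups:", paste(sprintf("%s{%s}", names(object@groups),
      vapply(object@groups, function(g) paste(g, collapse = ""), "")),
      collapse = " "), "\n")
  cat("  provenance:\n")
  for (nm in names(object@provenance)) {
    cat("   ", nm, ":", object@provenance[[nm]], "\n")
  }
})

.tablesToList <- function(tables) {
  list(
    masses = as.list(tables@masses),
    water_mass = tables@waterMass,
    hydropathy = as.list(tables@hydropathy),
    propensities = lapply(tables@propensities, as.list),
    disorder = list(scale = as.list(tables@disorderScale),
                    threshold = tables@disorderThreshold),
    pka = as.list(tables@pka),
    groups = lapply(tables@groups, as.list),
    provenance = as.list(tables@provenance))
}

#' Write residue property tables to a YAML config file
#'
#' The written file round-trips through [readResidueTables()] to identical
#' values, and is the documented template for overriding individual scales.
#'
#' @param tables A [ResidueTables-class] object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
writeResidueTables <- function(tables, path) {
  stopifnot(is(tables, "ResidueTables"))
  yaml::write_yaml(.tablesToList(tables), path, precision = 15L)
  invisible(path)
}

.coerceScale <- function(x, what) {
  v <- unlist(x)
  if (!is.numeric(v)) {
    stop(sprintf("non-numeric entry in %s: %s", what,
                 paste(utils::head(v[!grepl("^-?[0-9.eE+]+$", v)], 3),
                       collapse = ", ")), call. = FALSE)
  }
  v
}

#' Read residue property tables from a YAML config file
#'
#' Any section present in the file (`masses`, `water_mass`, `hydropathy`,
#' `propensities`, `disorder` with `scale`/`threshold`, `pka`, `groups`)
#' overrides the corresponding default; unspecified sections fall back to
#' [defaultResidueTables()]. A supplied scale must cover all 20 canonical
#' residues -- a partial scale is rejected with an error naming the missing
#' residue rather than silently merged, so a config file always states a
#' complete, auditable scale.
#'
#' @param path Path to a YAML config file. An empty file yields the defaults.
#' @param base Tables supplying defaults for unspecified sections.
#' @return A validated [ResidueTables-class] object.
#' @export
readResidueTables <- function(path, base = defaultResidueTables()) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg)) cfg <- list()
  tab <- base
  fullScale <- function(x, what) {
    v <- .coerceScale(x, what)
    m <- .checkResidueCoverage(v, what)
    if (!is.null(m)) stop(m, call. = FALSE)
    v[AA20]
  }
  if (!is.null(cfg$masses)) tab@masses <- fullScale(cfg$masses, "masses")
  if (!is.null(cfg$water_mass)) tab@waterMass <- as.numeric(cfg$water_mass)
  if (!is.null(cfg$hydropathy)) {
    tab@hydropathy <- fullScale(cfg$hydropathy, "hydropathy")
  }
  if (!is.null(cfg$propensities)) {
    for (s in names(cfg$propensities)) {
      if (!s %in% c("helix", "sheet", "turn")) {
        stop("unknown propensity class in config: ", s, call. = FALSE)
      }
      tab@propensities[[s]] <- fullScale(cfg$propensities[[s]],
                                         paste0("propensities$", s))
    }
  }
  if (!is.null(cfg$disorder)) {
    if (!is.null(cfg$disorder$scale)) {
      tab@disorderScale <- fullScale(cfg$disorder$scale, "disorder scale")
    }
    if (!is.null(cfg$disorder$threshold)) {
      tab@disorderThreshold <- as.numeric(cfg$disorder$threshold)
    }
  }
  if (!is.null(cfg$pka)) {
    v <- .coerceScale(cfg$pka, "pka")
    tab@pka[names(v)] <- v
  }
  if (!is.null(cfg$groups)) {
    for (g in names(cfg$groups)) {
      tab@groups[[g]] <- as.character(unlist(cfg$groups[[g]]))
    }
  }
  if (!is.null(cfg$provenance)) {
    prov <- unlist(cfg$provenance)
    tab@provenance[names(prov)] <- prov
  }
  validObject(tab)
  tab
}
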