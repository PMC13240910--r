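#' Pipeline configuration
#'
#' Bundles the thresholds and seed of an end-to-end run.
#'
#' @param outDir Directory for report artifacts (created if absent).
#' @param fdrAlpha Significance gate on BH-adjusted q-values (default 0.05).
#' @param bootstrapB Bootstrap resamples for delta CIs (default 2000; 0
#'   disables the bootstrap).
#' @param rhoThreshold Spearman redundancy cutoff (default 0.85).
#' @param deltaFloor Minimum `|delta|` for a significant feature to enter
#'   the redundancy/composite stage (default 0.1, i.e. only features with a
#'   non-negligible effect are integrated).
#' @param preference Preferred cluster representatives (default `length`).
#' @param seed Pipeline seed; per-feature substreams derive from it.
#' @return A `deltasol_pipeline_config` list.
#' @export
pipelineConfig <- function(outDir, fdrAlpha = 0.05, bootstrapB = 2000L,
                           rhoThreshold = 0.85, deltaFloor = 0.1,
                           preference = "length", seed = 1L) {
  stopifnot(fdrAlpha > 0, fdrAlpha < 1,
            bootstrapB == 0L || bootstrapB >= 100L,
            rhoThreshold > 0, rhoThreshold <= 1.01)
  structure(list(outDir = outDir, fdrAlpha = fdrAlpha,
                 bootstrapB = as.integer(bootstrapB),
                 rhoThreshold = rhoThreshold, deltaFloor = deltaFloor,
                 preference = preference, seed = as.integer(seed)),
            class = "deltasol_pipeline_config")
}

# small polynomial rolling hash so the run log can state a config
# fingerprint without external digest dependencies
.configHash <- function(txt) {
  h <- 0
  for (b in utf8ToInt(txt)) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", h)
}

.writeResultsCSV <- function(results, path) {
  df <- results
  num <- vapply(df, is.numeric, logical(1))
  for (nm in names(df)[num]) df[[nm]] <- .fmtNum(df[[nm]])
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
}

#' Run the full analysis pipeline
#'
#' Feature extraction, univariate statistics with joint BH adjustment,
#' Spearman redundancy filtering of the significant high-effect features,
#' composite-delta construction and evaluation. Writes `features.csv`,
#' `results.csv`, `results.json`, `rho.csv`, `clusters.json`,
#' `composite_model.json`, `metrics.csv` and `run_log.txt` into
#' `config$outDir`. Outputs are byte-identical across reruns with the same
#' inputs and config.
#'
#' Features enter the redundancy/composite stage when `q < fdrAlpha` and
#' `|delta| >= deltaFloor`; non-significant features still appear in
#' `results.csv`. `metrics.csv` reports the sign rule `S > 0` in both score
#' orientations (as-is and sign-flipped).
#'
#' @param proteins A [ProteinSet-class] with both classes present.
#' @param config A [pipelineConfig()] list.
#' @param tables A [ResidueTables-class].
#' @return Invisibly, a list with `features`, `results`, `redundancy`,
#'   `model`, `metrics`.
#' @export
runPipeline <- function(proteins, config,
                        tables = defaultResidueTables()) {
  stopifnot(inherits(config, "deltasol_pipeline_config"))
  dir.create(config$outDir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(config$outDir, f)

  sf <- tryCatch(extractFeatures(proteins, tables),
                 error = function(e) stop("stage features: ",
                                          conditionMessage(e), call. = FALSE))
  writeFeatureCSV(sf, out("features.csv"))

  results <- tryCatch(
    analyzeFeatures(sf, bootstrapB = config$bootstrapB, seed = config$seed),
    error = function(e) stop("stage univariate: ", conditionMessage(e),
                             call. = FALSE))
  .writeResultsCSV(results, out("results.csv"))
  jsonlite::write_json(results, out("results.json"), digits = NA,
                       dataframe = "rows")

  sig <- results$q_value < config$fdrAlpha &
    abs(results$delta) >= config$deltaFloor
  candidates <- results$feature_name[sig]

  model <- NULL; metrics <- NULL; red <- NULL
  if (length(candidates) >= 1L) {
    delta <- stats::setNames(results$delta, results$feature_name)
    red <- redundancyReport(sf, candidates, delta,
                            threshold = config$rhoThreshold,
                            preference = config$preference)
    rhoOut <- data.frame(feature = rownames(red@rho),
                         apply(red@rho, 2, .fmtNum),
                         check.names = FALSE)
    utils::write.csv(rhoOut, out("rho.csv"), row.names = FALSE, quote = FALSE)
    jsonlite::write_json(list(threshold = config$rhoThreshold,
                              clusters = red@clusters,
                              retained = red@retained),
                         out("clusters.json"), digits = NA,
                         auto_unbox = TRUE)
    model <- fitComposite(sf, results, red@retained)
    writeCompositeModel(model, out("composite_model.json"))
    scores <- compositeScore(model, sf)
    metrics <- rbind(
      cbind(orientation = "as-is",
            evaluateScores(scores, solubilityLabels(sf))),
      cbind(orientation = "sign-flipped",
            evaluateScores(-scores, solubilityLabels(sf))))
    .writeResultsCSV(metrics, out("metrics.csv"))
  }

  # the fingerprint covers the analysis parameters, not the output path
  cfgTxt <- paste(vapply(config[setdiff(names(config), "outDir")],
                         function(v) paste(format(v), collapse = ","),
                         character(1)),
                  collapse = "|")
  log <- c(
    sprintf("DeltaSol %s", as.character(utils::packageVersion("DeltaSol"))),
    sprintf("seed: %d", config$seed),
    sprintf("config: %s", cfgTxt),
    sprintf("config_hash: %s", .configHash(cfgTxt)),
    sprintf("records: %d", length(proteins)),
    sprintf("label counts: %s",
            paste(sprintf("%s=%d", names(table(proteinLabels(proteins))),
                          table(proteinLabels(proteins))), collapse = " ")),
    sprintf("significant features (q<%g, |delta|>=%g): %d",
            config$fdrAlpha, config$deltaFloor, length(candidates)),
    if (!is.null(red)) sprintf("retained: %s",
                               paste(red@retained, collapse = ", ")),
    "residue table provenance:",
    sprintf("  %s: %s", names(tableProvenance(tables)),
            tableProvenance(tables)))
  writeLines(log, out("run_log.txt"))

  invisible(list(features = sf, results = results, redundancy = red,
                 model = model, metrics = metrics))
}
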