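## End-to-end pipeline: synthesis -> extraction -> classification ->
## redundancy, from one config and one seed.

#' Pipeline run configuration
#'
#' Bundles every tunable of the four stages. All stage seeds are derived
#' from the single global seed by a counter scheme, so each stage is
#' independently reproducible.
#'
#' @param population a \code{\link{populationSpec}}.
#' @param bout a \code{\link{boutSpec}}.
#' @param bouts_per_individual bouts per individual to synthesize.
#' @param snr_db rendering SNR, dB.
#' @param sample_rate rendering rate, Hz.
#' @param extraction a \code{\link{featureConfig}}.
#' @param n_repeats CV repeats per scheme.
#' @param n_trees trees per forest.
#' @param redundancy_types whoop types used for the redundancy stage.
#' @param min_age_months adult filter threshold.
#' @param seed global seed.
#' @return a \code{RunConfig} (named list, classed).
#' @export
runConfig <- function(population = populationSpec(), bout = boutSpec(),
                      bouts_per_individual = 4, snr_db = 15,
                      sample_rate = 32000,
                      extraction = featureConfig(),
                      n_repeats = 100, n_trees = 500,
                      redundancy_types = c("A", "S"),
                      min_age_months = 24, seed = 1L) {
  structure(list(population = population, bout = bout,
                 bouts_per_individual = bouts_per_individual,
                 snr_db = snr_db, sample_rate = sample_rate,
                 extraction = extraction, n_repeats = n_repeats,
                 n_trees = n_trees, redundancy_types = redundancy_types,
                 min_age_months = min_age_months,
                 seed = as.integer(seed)),
            class = "RunConfig")
}

#' Read a pipeline configuration from YAML
#'
#' Keys mirror the arguments of \code{\link{runConfig}}; the
#' \code{population}, \code{bout} and \code{extraction} sections are
#' passed to their constructors, so partial configs inherit defaults.
#'
#' @param path YAML file path.
#' @return a \code{RunConfig}.
#' @export
readRunConfig <- function(path) {
  y <- yaml::read_yaml(path)
  args <- list()
  if (!is.null(y$population))
    args$population <- do.call(populationSpec, y$population)
  if (!is.null(y$bout)) args$bout <- do.call(boutSpec, y$bout)
  if (!is.null(y$extraction))
    args$extraction <- do.call(featureConfig, y$extraction)
  for (k in c("bouts_per_individual", "snr_db", "sample_rate",
              "n_repeats", "n_trees", "redundancy_types",
              "min_age_months", "seed"))
    if (!is.null(y[[k]])) args[[k]] <- y[[k]]
  do.call(runConfig, args)
}

#' Run the full analysis pipeline
#'
#' Synthesizes (or ingests) a dataset, extracts the sixteen acoustic
#' features, runs the clan- and individual-signature tests, and the
#' serial-redundancy analysis on the configured whoop types. Outputs and
#' a reproducibility manifest are written under \code{out_dir} when
#' given; rerunning with the same config produces identical results.
#'
#' @param config a \code{\link{runConfig}} (or path of a YAML config).
#' @param out_dir optional output directory for CSV/JSON artefacts.
#' @param metadata optional pre-recorded metadata table (with
#'   \code{wav_path}); when supplied the synthesis stage is skipped and
#'   WAVs are read from \code{wav_dir}.
#' @param wav_dir base directory for \code{metadata$wav_path}.
#' @return list: \code{manifest}, \code{features} (FeatureTable),
#'   \code{clan} and \code{individual} (\linkS4class{CVSummary}),
#'   \code{redundancy} (\linkS4class{PrefixCurve} or NULL if the accuracy
#'   gate refused), \code{importance} (data.frame).
#' @export
runPipeline <- function(config = runConfig(), out_dir = NULL,
                        metadata = NULL, wav_dir = ".") {
  if (is.character(config)) config <- readRunConfig(config)
  seed <- config$seed
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  warnings_log <- character(0)

  if (is.null(metadata)) {
    ds <- stage("synth", synthesizeDataset(
      config$population, config$bout, config$bouts_per_individual,
      snr_db = config$snr_db, sample_rate = config$sample_rate,
      seed = deriveSeed(seed, 101L)))
    records <- ds$records
    md <- ds$metadata
  } else {
    md <- stage("ingest", readMetadata(metadata))
    records <- stage("ingest", lapply(file.path(wav_dir, md$wav_path),
                                      readWhoopWav))
    ds <- NULL
  }

  features <- stage("extract",
                    extractFeatureTable(records, md, config = config$extraction))
  n_failed <- sum(features$failed)

  adults <- filterAdults(features, config$min_age_months)
  clan_cv <- stage("classify", runRepeats(
    adults, splitSpec("clan", config$n_repeats, config$n_trees,
                      seed = deriveSeed(seed, 201L))))
  indiv_tab <- stage("classify", prepareIndividualDataset(adults))
  indiv_cv <- stage("classify", runRepeats(
    indiv_tab, splitSpec("individual", config$n_repeats, config$n_trees,
                         seed = deriveSeed(seed, 202L))))
  importance <- stage("classify", featureImportance(
    indiv_tab, splitSpec("individual", max(10L, config$n_repeats %/% 4L),
                         config$n_trees, seed = deriveSeed(seed, 203L))))

  red_tab <- subsetTypes(indiv_tab, config$redundancy_types)
  red <- tryCatch(
    prefixAccuracyCurve(
      prepareIndividualDataset(red_tab),
      splitSpec("individual", config$n_repeats, config$n_trees,
                seed = deriveSeed(seed, 204L))),
    error = function(e) {
      warnings_log <<- c(warnings_log, conditionMessage(e))
      NULL
    })

  manifest <- list(
    package_version = as.character(utils::packageVersion("whoopsig")),
    config_hash = configHash(config),
    seed = seed,
    counts = list(whoops = nrow(features),
                  extraction_failures = n_failed,
                  adults = nrow(adults),
                  individual_rows = nrow(indiv_tab),
                  redundancy_rows = nrow(red_tab)),
    warnings = warnings_log)

  out <- list(manifest = manifest, features = features, clan = clan_cv,
              individual = indiv_cv, redundancy = red,
              importance = importance)
  if (!is.null(out_dir)) writePipelineOutputs(out, out_dir)
  out
}

writePipelineOutputs <- function(out, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  prov <- paste0("# whoopsig config ", out$manifest$config_hash)
  writeTable <- function(df, name) {
    path <- file.path(out_dir, name)
    con <- file(path, "w")
    writeLines(prov, con)
    write.csv(df, con, row.names = FALSE)
    close(con)
  }
  writeTable(out$features, "features.csv")
  writeTable(cvRepeats(out$clan), "clan_repeats.csv")
  writeTable(cvRepeats(out$individual), "individual_repeats.csv")
  writeTable(as.data.frame(pooledConfusion(out$individual)),
             "individual_confusion.csv")
  writeTable(out$importance, "importance.csv")
  if (!is.null(out$redundancy))
    writeTable(prefixCurveTable(out$redundancy), "redundancy_curve.csv")
  summary <- list(
    manifest = out$manifest,
    clan = list(mean = meanAccuracy(out$clan), sd = sdAccuracy(out$clan),
                chance = meanWE(out$clan)),
    individual = list(mean = meanAccuracy(out$individual),
                      sd = sdAccuracy(out$individual),
                      chance = meanWE(out$individual)))
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}
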