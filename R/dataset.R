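## Dataset synthesis, on-disk layout, and metadata validation.

metadataColumns <- c("whoop_id", "bout_id", "caller_id", "clan_id",
                     "position_in_bout", "whoop_type", "age_months", "sex",
                     "recording_method", "wav_path")

#' Synthesize a full study dataset in memory
#'
#' Samples a population, draws \code{bouts_per_individual} bouts for every
#' individual, and renders every whoop. Fully deterministic given
#' \code{seed}. This is the in-memory counterpart of
#' \code{\link{writeDataset}} and the input to
#' \code{\link{extractFeatureTable}}.
#'
#' @param spec a \code{\link{populationSpec}}.
#' @param bout a \code{\link{boutSpec}}.
#' @param bouts_per_individual bouts to draw per individual.
#' @param snr_db rendering signal-to-noise ratio, dB (\code{Inf} noiseless).
#' @param sample_rate rendering rate, Hz.
#' @param seed integer seed (fans out internally per bout).
#' @param render if \code{FALSE}, skip waveform rendering and return
#'   parameters and metadata only.
#' @return list with \code{population} (data.frame), \code{records}
#'   (list of \linkS4class{WhoopRecord}, NULL if \code{render = FALSE}),
#'   \code{params} (list of \code{SynthWhoopParams}), \code{metadata}
#'   (data.frame, one row per whoop), \code{truth} (data.frame from
#'   \code{\link{trueWhoopFeatures}}).
#' @export
synthesizeDataset <- function(spec = populationSpec(), bout = boutSpec(),
                              bouts_per_individual = 4, snr_db = 15,
                              sample_rate = 32000, seed = spec$seed,
                              render = TRUE) {
  pop <- samplePopulation(spec)
  old <- .Random.seed.save()
  on.exit(.Random.seed.restore(old))
  params <- list(); meta <- list(); truth <- list()
  bout_counter <- 0L
  for (i in seq_len(nrow(pop))) {
    sig <- as.list(pop[i, ])
    for (b in seq_len(bouts_per_individual)) {
      bout_counter <- bout_counter + 1L
      set.seed(deriveSeed(seed, 1000L + bout_counter))
      ps <- generateBout(sig, bout, spec, snr_db = snr_db)
      bid <- sprintf("%s_b%03d", sig$individual_id, b)
      for (j in seq_along(ps)) {
        params[[length(params) + 1L]] <- ps[[j]]
        meta[[length(meta) + 1L]] <- data.frame(
          whoop_id = sprintf("%s_w%02d", bid, j),
          bout_id = bid,
          caller_id = sig$individual_id,
          clan_id = sig$clan_id,
          position_in_bout = j,
          whoop_type = ps[[j]]$type,
          age_months = sig$age_months,
          sex = sig$sex,
          recording_method = "synthetic",
          wav_path = NA_character_,
          stringsAsFactors = FALSE)
        truth[[length(truth) + 1L]] <- trueWhoopFeatures(ps[[j]])
      }
    }
  }
  metadata <- do.call(rbind, meta)
  truth <- cbind(whoop_id = metadata$whoop_id, do.call(rbind, truth))
  records <- NULL
  if (render) {
    records <- vector("list", length(params))
    for (k in seq_along(params)) {
      set.seed(deriveSeed(seed, 2000000L + k))
      records[[k]] <- renderWhoop(params[[k]], sample_rate,
                                  metadata = as.list(metadata[k, ]))
    }
  }
  list(population = pop, records = records, params = params,
       metadata = metadata, truth = truth)
}

#' Write a synthetic dataset to disk
#'
#' One mono PCM16 WAV per whoop plus \code{metadata.csv} (schema:
#' \code{whoop_id, bout_id, caller_id, clan_id, position_in_bout,
#' whoop_type, age_months, sex, recording_method, wav_path}) and
#' \code{truth.csv} mirroring the ground-truth synthesis parameters.
#'
#' @param dataset result of \code{\link{synthesizeDataset}} (with
#'   \code{render = TRUE}).
#' @param out_dir output directory (created if missing).
#' @return the metadata data.frame (with populated \code{wav_path}),
#'   invisibly.
#' @export
writeDataset <- function(dataset, out_dir) {
  if (is.null(dataset$records) || !length(dataset$records))
    stop("writeDataset: dataset has no rendered records")
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
    stop("writeDataset: cannot create directory ", out_dir)
  md <- dataset$metadata
  scale <- max(vapply(dataset$records,
                      function(r) max(abs(waveform(r))), numeric(1)))
  for (k in seq_along(dataset$records)) {
    rel <- file.path("wav", paste0(md$whoop_id[k], ".wav"))
    dir.create(file.path(out_dir, "wav"), showWarnings = FALSE)
    r <- dataset$records[[k]]
    writeWhoopWav(waveform(r) / scale * 0.95, sampleRate(r),
                  file.path(out_dir, rel))
    md$wav_path[k] <- rel
  }
  write.csv(md, file.path(out_dir, "metadata.csv"), row.names = FALSE)
  write.csv(dataset$truth, file.path(out_dir, "truth.csv"),
            row.names = FALSE)
  invisible(md)
}

#' Read and validate a whoop metadata table
#'
#' Schema-validates a metadata CSV (or data.frame): all required columns
#' present, \code{whoop_id} unique, and every bout mapped to exactly one
#' caller. Errors name the offending column, id, or bout.
#'
#' @param path CSV path, or a data.frame to validate in place.
#' @return the validated data.frame.
#' @export
readMetadata <- function(path) {
  md <- if (is.data.frame(path)) path else {
    if (!file.exists(path)) stop("readMetadata: no such file: ", path)
    read.csv(path, stringsAsFactors = FALSE)
  }
  if (!nrow(md)) stop("readMetadata: metadata table is empty")
  missing_cols <- setdiff(metadataColumns, names(md))
  if (length(missing_cols))
    stop("readMetadata: missing column(s): ",
         paste(missing_cols, collapse = ", "))
  dup <- md$whoop_id[duplicated(md$whoop_id)]
  if (length(dup))
    stop("readMetadata: duplicate whoop_id: ", dup[1])
  callers_per_bout <- tapply(md$caller_id, md$bout_id,
                             function(v) length(unique(v)))
  bad <- names(callers_per_bout)[callers_per_bout > 1]
  if (length(bad))
    stop("readMetadata: bout mapped to multiple callers: ", bad[1])
  md
}
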