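## S4 classes for the central data objects.

#' WhoopRecord: one call as waveform plus metadata
#'
#' A single call: the sampled waveform, its sample rate, and the metadata
#' that downstream analyses key on (caller, clan, bout, position in bout,
#' whoop type, age, sex, recording method).
#'
#' @slot waveform numeric vector of samples.
#' @slot sampleRate sampling rate in Hz.
#' @slot metadata named list; recognised fields are \code{whoop_id},
#'   \code{bout_id}, \code{caller_id}, \code{clan_id},
#'   \code{position_in_bout}, \code{whoop_type}, \code{age_months},
#'   \code{sex}, \code{recording_method}.
#'
#' @export
setClass("WhoopRecord",
  representation(waveform = "numeric", sampleRate = "numeric",
                 metadata = "list"),
  validity = function(object) {
    msg <- NULL
    if (length(object@sampleRate) != 1L || !is.finite(object@sampleRate) ||
        object@sampleRate <= 0)
      msg <- c(msg, "sampleRate must be a single positive number")
    if (length(object@waveform) < 1L || anyNA(object@waveform))
      msg <- c(msg, "waveform must be non-empty and free of NA")
    if (is.null(msg)) TRUE else msg
  })

#' Construct a WhoopRecord
#'
#' @param waveform numeric vector of samples.
#' @param sampleRate sampling rate in Hz.
#' @param metadata named list of call metadata.
#' @return a \linkS4class{WhoopRecord}.
#' @export
whoopRecord <- function(waveform, sampleRate, metadata = list()) {
  new("WhoopRecord", waveform = as.numeric(waveform),
      sampleRate = as.numeric(sampleRate), metadata = metadata)
}

#' @describeIn WhoopRecord-class waveform accessor
#' @param x a \code{WhoopRecord}.
#' @export
waveform <- function(x) x@waveform

#' @describeIn WhoopRecord-class sample-rate accessor
#' @export
sampleRate <- function(x) x@sampleRate

#' @describeIn WhoopRecord-class duration in seconds
#' @export
recordDuration <- function(x) length(x@waveform) / x@sampleRate

setMethod("show", "WhoopRecord", function(object) {
  md <- object@metadata
  cat(sprintf("WhoopRecord: %.3f s at %g Hz", recordDuration(object),
              object@sampleRate))
  if (!is.null(md$caller_id))
    cat(sprintf(" | caller %s", md$caller_id))
  if (!is.null(md$whoop_type))
    cat(sprintf(" (type %s)", md$whoop_type))
  cat("\n")
})

#' FundamentalContour: a traced fundamental-frequency track
#'
#' Time-ordered (time, frequency) trace of the fundamental of one call, on
#' a regular frame grid (frames dropped below the energy threshold are
#' simply absent).
#'
#' @slot times frame centre times in seconds, strictly increasing.
#' @slot freqs fundamental frequency per frame in Hz, all positive.
#' @slot frameHop frame hop in seconds.
#'
#' @export
setClass("FundamentalContour",
  representation(times = "numeric", freqs = "numeric", frameHop = "numeric"),
  validity = function(object) {
    msg <- NULL
    if (length(object@times) != length(object@freqs))
      msg <- c(msg, "times and freqs must have equal length")
    if (length(object@times) > 1L && any(diff(object@times) <= 0))
      msg <- c(msg, "times must be strictly increasing")
    if (any(object@freqs <= 0) || anyNA(object@freqs))
      msg <- c(msg, "freqs must be positive and free of NA")
    if (length(object@frameHop) != 1L || object@frameHop <= 0)
      msg <- c(msg, "frameHop must be a single positive number")
    if (is.null(msg)) TRUE else msg
  })

#' Construct a FundamentalContour
#'
#' @param times frame times (s), strictly increasing.
#' @param freqs frequencies (Hz), positive.
#' @param frameHop frame hop (s).
#' @return a \linkS4class{FundamentalContour}.
#' @export
fundamentalContour <- function(times, freqs, frameHop) {
  new("FundamentalContour", times = as.numeric(times),
      freqs = as.numeric(freqs), frameHop = as.numeric(frameHop))
}

#' @describeIn FundamentalContour-class frame times accessor
#' @param x a \code{FundamentalContour}.
#' @export
contourTimes <- function(x) x@times

#' @describeIn FundamentalContour-class frequencies accessor
#' @export
contourFreqs <- function(x) x@freqs

#' @describeIn FundamentalContour-class frame hop accessor
#' @export
contourHop <- function(x) x@frameHop

setMethod("show", "FundamentalContour", function(object) {
  cat(sprintf(
    "FundamentalContour: %d frames, %.3f-%.3f s, %.0f-%.0f Hz (hop %.1f ms)\n",
    length(object@times), min(object@times), max(object@times),
    min(object@freqs), max(object@freqs), 1000 * object@frameHop))
})

#' CVSummary: repeated cross-validation summary
#'
#' Summary of repeated split-train-test runs of one classification scheme:
#' accuracy mean and s.d. across repeats, the mean weighted expectation
#' (composition-weighted chance level), the pooled confusion matrix and
#' per-class accuracies, plus the per-repeat table.
#'
#' @slot scheme \code{"clan"} or \code{"individual"}.
#' @slot meanAccuracy mean test accuracy across repeats.
#' @slot sdAccuracy s.d. of test accuracy across repeats (NA for one repeat).
#' @slot meanWE mean weighted expectation across repeats.
#' @slot repeats data.frame with one row per repeat
#'   (\code{repeat_index}, \code{accuracy}, \code{we}, \code{n_test}).
#' @slot confusion pooled class-by-class count matrix
#'   (rows = true, columns = predicted).
#' @slot perClass data.frame of per-class mean accuracy.
#'
#' @export
setClass("CVSummary",
  representation(scheme = "character", meanAccuracy = "numeric",
                 sdAccuracy = "numeric", meanWE = "numeric",
                 repeats = "data.frame", confusion = "matrix",
                 perClass = "data.frame"),
  validity = function(object) {
    msg <- NULL
    if (!object@scheme %in% c("clan", "individual"))
      msg <- c(msg, "scheme must be 'clan' or 'individual'")
    acc <- object@repeats$accuracy
    if (any(acc < 0 | acc > 1))
      msg <- c(msg, "accuracies must lie in [0, 1]")
    we <- object@repeats$we
    if (any(we < 0 | we > 1))
      msg <- c(msg, "weighted expectations must lie in [0, 1]")
    if (is.null(msg)) TRUE else msg
  })

setMethod("show", "CVSummary", function(object) {
  cat(sprintf("CVSummary (%s scheme, %d repeats)\n", object@scheme,
              nrow(object@repeats)))
  cat(sprintf("  accuracy mean: %.3f, s.d.: %.3f, chance (mean WE): %.3f\n",
              object@meanAccuracy,
              if (is.na(object@sdAccuracy)) NA_real_ else object@sdAccuracy,
              object@meanWE))
})

#' @describeIn CVSummary-class mean accuracy accessor
#' @param x a \code{CVSummary}.
#' @export
meanAccuracy <- function(x) x@meanAccuracy

#' @describeIn CVSummary-class accuracy s.d. accessor
#' @export
sdAccuracy <- function(x) x@sdAccuracy

#' @describeIn CVSummary-class mean weighted expectation accessor
#' @export
meanWE <- function(x) x@meanWE

#' @describeIn CVSummary-class per-repeat results accessor
#' @export
cvRepeats <- function(x) x@repeats

#' @describeIn CVSummary-class pooled confusion matrix accessor
#' @export
pooledConfusion <- function(x) x@confusion

#' PrefixCurve: bout-prefix accuracy curve with baselines
#'
#' How the probability of identifying the true caller accumulates over the
#' first k whoops of a bout, with the flat chance baseline and the
#' equal-informativeness baseline.
#'
#' @slot curve data.frame with columns \code{k}, \code{mean_prob}
#'   (mean vote mass on the true caller), \code{accuracy} (fraction of
#'   bout-prefixes whose aggregated top class is the true caller, ties
#'   fractional), \code{n_bouts}.
#' @slot chance flat chance level (mean WE).
#' @slot equalInformative equal-informativeness baseline values per k.
#' @slot p single-whoop accuracy used for the baseline.
#' @slot nClasses number of classes.
#'
#' @export
setClass("PrefixCurve",
  representation(curve = "data.frame", chance = "numeric",
                 equalInformative = "numeric", p = "numeric",
                 nClasses = "numeric"),
  validity = function(object) {
    v <- c(object@curve$mean_prob, object@curve$accuracy)
    if (any(v < -1e-9 | v > 1 + 1e-9))
      return("curve values must lie in [0, 1]")
    TRUE
  })

setMethod("show", "PrefixCurve", function(object) {
  cat(sprintf("PrefixCurve: k = 1..%d, single-whoop accuracy %.3f, chance %.3f\n",
              max(object@curve$k), object@p, object@chance))
  print(object@curve, row.names = FALSE)
})

#' @describeIn PrefixCurve-class curve table accessor
#' @param x a \code{PrefixCurve}.
#' @export
prefixCurveTable <- function(x) {
  out <- x@curve
  out$chance <- rep(x@chance, nrow(out))
  out$equal_informative <- x@equalInformative[out$k]
  out
}
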