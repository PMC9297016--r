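## Extraction configuration and provenance hashing.

#' Feature-extraction configuration
#'
#' All tunable analysis parameters in one validated object. Defaults:
#' 32 kHz working rate; fundamental tracing on 1024-sample Hann frames
#' with 75\% overlap restricted to 0.2-2 kHz; entropy and cepstral peak
#' prominence on the signal resampled to 8 kHz in 4 ms blocks with 3.5 ms
#' overlap; 99\% energy criterion for call duration.
#'
#' The CPP quefrency search range is derived from \code{cpp_band}; it must
#' fit inside the one-sided cepstrum of a padded block, which at the
#' default 4 ms / 64-point settings caps the low edge of the band at
#' 250 Hz. An infeasible range errors here, at configuration time.
#'
#' @param sample_rate working rate for tracing/spectral features, Hz.
#' @param entropy_rate rate for entropy/CPP analysis, Hz.
#' @param block_ms analysis block length for entropy/CPP, ms.
#' @param block_hop_ms block hop (block length minus overlap), ms.
#' @param cpp_pad FFT length for padded entropy/CPP blocks (CPP only;
#'   entropy uses the unpadded block so its white-noise calibration is
#'   analytic).
#' @param cpp_band fundamental search band for the cepstral peak, Hz.
#' @param trace_nfft,trace_hop STFT frame length and hop (samples at
#'   \code{sample_rate}) for fundamental tracing.
#' @param trace_band fundamental search band, Hz.
#' @param trace_threshold_db frames whose in-band energy is more than this
#'   many dB below the strongest frame are dropped.
#' @param trace_max_jump maximum relative inter-frame fundamental jump.
#' @param energy_fraction energy fraction defining call duration.
#' @param n_harmonics harmonics summed in the subharmonic comparison.
#' @param harmonic_halfwidth band half-width around each (sub)harmonic as a
#'   fraction of the fundamental.
#' @param ratio_cap_db cap for harmonic-to-subharmonic dB ratios.
#' @return a validated \code{FeatureConfig} (named list, classed).
#' @export
featureConfig <- function(sample_rate = 32000, entropy_rate = 8000,
                          block_ms = 4, block_hop_ms = 0.5, cpp_pad = 64,
                          cpp_band = c(250, 1200),
                          trace_nfft = 1024, trace_hop = 256,
                          trace_band = c(200, 2000),
                          trace_threshold_db = 20, trace_max_jump = 0.2,
                          energy_fraction = 0.99, n_harmonics = 6,
                          harmonic_halfwidth = 0.2, ratio_cap_db = 60) {
  cfg <- list(sample_rate = sample_rate, entropy_rate = entropy_rate,
              block_ms = block_ms, block_hop_ms = block_hop_ms,
              cpp_pad = as.integer(cpp_pad), cpp_band = cpp_band,
              trace_nfft = as.integer(trace_nfft),
              trace_hop = as.integer(trace_hop), trace_band = trace_band,
              trace_threshold_db = trace_threshold_db,
              trace_max_jump = trace_max_jump,
              energy_fraction = energy_fraction,
              n_harmonics = as.integer(n_harmonics),
              harmonic_halfwidth = harmonic_halfwidth,
              ratio_cap_db = ratio_cap_db)
  cfg$block_n <- as.integer(round(block_ms / 1000 * entropy_rate))
  cfg$block_hop <- max(1L, as.integer(round(block_hop_ms / 1000 *
                                              entropy_rate)))
  if (cfg$block_n < 2L) stop("featureConfig: block shorter than 2 samples")
  if (cfg$cpp_pad < cfg$block_n)
    stop("featureConfig: cpp_pad must be >= the block length in samples")
  qmax <- (cfg$cpp_pad / 2) / entropy_rate
  if (1 / cpp_band[1] > qmax + 1e-12)
    stop("featureConfig: CPP quefrency range empty at this block size: ",
         "1/", cpp_band[1], " s exceeds the one-sided cepstrum span ",
         signif(qmax, 3), " s; raise cpp_band[1] or cpp_pad")
  if (trace_band[2] > sample_rate / 2)
    stop("featureConfig: trace_band exceeds Nyquist")
  if (!(energy_fraction > 0 && energy_fraction < 1))
    stop("featureConfig: energy_fraction must lie in (0, 1)")
  class(cfg) <- "FeatureConfig"
  cfg
}

## FNV-1a over the serialized config: a stable provenance fingerprint
## without external dependencies.
configHash <- function(cfg) {
  raw <- serialize(cfg, NULL, version = 2)
  h <- 2166136261
  for (b in as.integer(raw)) {
    h <- bitwXor(as.integer(h %% 2^31), b)
    h <- (h * 16777619) %% 2^31
  }
  sprintf("%08x", as.integer(h))
}

featureNames <- c("dur", "dur.cf", "dur.upsweep", "dur.subharm",
                  "endtime.cf", "endtime.upsweep", "freq.centroid",
                  "freq.peak", "freq.min", "freq.max", "freq.mean.cf",
                  "harmonic.ratio.total", "harmonic.ratio.cf",
                  "mean.entropy", "cpp.mean", "cpp.sd")

#' The sixteen acoustic feature names
#'
#' Column names of the acoustic features produced by
#' \code{\link{extractFeatures}}, in canonical order.
#' @return character vector of length 16.
#' @export
whoopFeatureNames <- function() featureNames
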