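## Acoustic feature extraction: the sixteen per-call features.

asWave <- function(x) {
  if (is(x, "WhoopRecord")) list(x = x@waveform, fs = x@sampleRate)
  else stop("expected a WhoopRecord")
}

#' Resample a call to a target rate
#'
#' Anti-aliased polyphase resampling (via \code{signal::resample}) at the
#' rational approximation of the rate ratio. Duration is preserved to
#' within one output sample.
#'
#' @param record a \linkS4class{WhoopRecord}.
#' @param target_rate target rate, Hz.
#' @return a resampled \linkS4class{WhoopRecord}.
#' @export
resampleAudio <- function(record, target_rate) {
  if (length(target_rate) != 1L || target_rate <= 0)
    stop("resampleAudio: target_rate must be a single positive number")
  fs <- sampleRate(record)
  if (abs(fs - target_rate) < 1e-9) return(record)
  frac <- ratApprox(target_rate / fs)
  y <- signal::resample(waveform(record), frac[1], frac[2])
  n_expect <- round(length(waveform(record)) * target_rate / fs)
  if (length(y) > n_expect + 1L) y <- y[seq_len(n_expect)]
  whoopRecord(y, target_rate, record@metadata)
}

## continued-fraction rational approximation p/q of a positive ratio
ratApprox <- function(r, tol = 1e-9, qmax = 10000) {
  p0 <- 0; q0 <- 1; p1 <- 1; q1 <- 0; x <- r
  repeat {
    a <- floor(x)
    p <- a * p1 + p0; q <- a * q1 + q0
    if (q > qmax || abs(p / q - r) < tol) return(c(as.integer(p),
                                                   as.integer(q)))
    p0 <- p1; q0 <- q1; p1 <- p; q1 <- q
    x <- 1 / (x - a)
  }
}

#' Energy-criterion call window
#'
#' The call window holding \code{fraction} of total squared-sample energy
#' with symmetric tail trimming: cumulative energy crosses
#' \code{(1 - fraction)/2} at the start and \code{1 - (1 - fraction)/2} at
#' the end. Call duration is the window length.
#'
#' @param record a \linkS4class{WhoopRecord}.
#' @param fraction energy fraction, default 0.99.
#' @return list: \code{t_start}, \code{t_end}, \code{dur} (seconds) and
#'   sample indices \code{i_start}, \code{i_end}.
#' @export
energyWindow <- function(record, fraction = 0.99) {
  w <- asWave(record)
  e <- cumsum(w$x^2)
  tot <- e[length(e)]
  if (tot <= 0) stop("energyWindow: silent input")
  lo <- (1 - fraction) / 2
  i1 <- which(e >= lo * tot)[1]
  i2 <- which(e >= (1 - lo) * tot)[1]
  list(t_start = (i1 - 1) / w$fs, t_end = i2 / w$fs,
       dur = (i2 - i1 + 1) / w$fs, i_start = i1, i_end = i2)
}

windowSamples <- function(record, window) {
  if (is.null(window)) return(record)
  whoopRecord(waveform(record)[window$i_start:window$i_end],
              sampleRate(record), record@metadata)
}

#' Peak and centroid frequency
#'
#' Power spectrum of the (windowed) call: \code{freq.peak} is the argmax
#' frequency, \code{freq.centroid} the power-weighted mean frequency, both
#' in kHz. DC is excluded.
#'
#' @param record a \linkS4class{WhoopRecord}.
#' @param window optional \code{\link{energyWindow}} result restricting
#'   the analysis.
#' @return list: \code{freq.peak}, \code{freq.centroid} (kHz).
#' @export
spectrumSummary <- function(record, window = NULL) {
  w <- asWave(windowSamples(record, window))
  if (length(w$x) < 2L) stop("spectrumSummary: empty window")
  n <- stats::nextn(length(w$x), c(2, 3, 5))   # fast mixed-radix length
  P <- (Mod(fft(c(w$x, numeric(n - length(w$x)))))^2)[
    seq_len(floor(n / 2) + 1)]
  freqs <- (seq_along(P) - 1) * w$fs / n
  P[1] <- 0
  list(freq.peak = freqs[which.max(P)] / 1000,
       freq.centroid = sum(freqs * P) / sum(P) / 1000)
}

## Hann-windowed power STFT. Returns power matrix (freq bins x frames),
## bin frequencies, and frame-centre times.
powerSTFT <- function(x, fs, nfft, hop) {
  if (length(x) < nfft) {
    x <- c(x, numeric(nfft - length(x)))
  }
  w <- 0.5 - 0.5 * cos(2 * pi * (0:(nfft - 1)) / (nfft - 1))
  starts <- seq(1, length(x) - nfft + 1, by = hop)
  idx <- outer(0:(nfft - 1), starts, "+")
  M <- matrix(x[idx], nrow = nfft) * w
  S <- Mod(stats::mvfft(M))^2
  list(P = S[seq_len(nfft / 2 + 1), , drop = FALSE],
       freqs = (0:(nfft / 2)) * fs / nfft,
       times = (starts - 1 + nfft / 2) / fs)
}

#' Trace the fundamental-frequency contour
#'
#' Ridge tracking on the call spectrogram within the configured band:
#' tracking is seeded at the most energetic frame and extended in both
#' directions under a continuity constraint (maximum relative jump
#' \code{trace_max_jump} per frame), with parabolic interpolation of the
#' ridge for sub-bin accuracy. Frames whose in-band energy falls more than
#' \code{trace_threshold_db} below the strongest frame are dropped. If an
#' \code{anchor} contour is supplied (e.g. a hand-traced contour), it is
#' resampled onto the frame grid and returned instead.
#'
#' @param record a \linkS4class{WhoopRecord} at the working rate.
#' @param config a \code{\link{featureConfig}}.
#' @param anchor optional anchor contour: a
#'   \linkS4class{FundamentalContour} or a data.frame with columns
#'   \code{time_s}, \code{freq_hz}.
#' @return a \linkS4class{FundamentalContour} (times relative to the start
#'   of \code{record}).
#' @export
traceFundamental <- function(record, config = featureConfig(),
                             anchor = NULL) {
  w <- asWave(record)
  st <- powerSTFT(w$x, w$fs, config$trace_nfft, config$trace_hop)
  hop_s <- config$trace_hop / w$fs
  if (!is.null(anchor)) {
    if (is(anchor, "FundamentalContour"))
      anchor <- data.frame(time_s = contourTimes(anchor),
                           freq_hz = contourFreqs(anchor))
    keep <- st$times >= min(anchor$time_s) & st$times <= max(anchor$time_s)
    if (!any(keep)) stop("traceFundamental: anchor does not overlap call")
    f <- approx(anchor$time_s, anchor$freq_hz, xout = st$times[keep])$y
    return(fundamentalContour(st$times[keep], f, hop_s))
  }
  band <- config$trace_band
  bi <- which(st$freqs >= band[1] & st$freqs <= band[2])
  P <- st$P[bi, , drop = FALSE]
  fen <- colSums(P)
  if (max(fen) <= 1e-20)
    stop("traceFundamental: no voiced frames (no in-band energy)")
  keep_e <- fen >= max(fen) * 10^(-config$trace_threshold_db / 10)
  if (!any(keep_e)) stop("traceFundamental: no voiced frames")
  nfft <- config$trace_nfft
  pickPeak <- function(j, fmin, fmax) {
    ii <- which(st$freqs[bi] >= fmin & st$freqs[bi] <= fmax)
    if (!length(ii)) return(NA_real_)
    i <- ii[which.max(P[ii, j])]
    gi <- bi[i]
    if (gi > 1 && gi < nrow(st$P)) {
      a <- log(st$P[gi - 1, j] + 1e-300)
      b <- log(st$P[gi, j] + 1e-300)
      cc <- log(st$P[gi + 1, j] + 1e-300)
      d <- 0.5 * (a - cc) / (a - 2 * b + cc)
      if (!is.finite(d) || abs(d) > 0.5) d <- 0
      (gi - 1 + d) * w$fs / nfft
    } else st$freqs[gi]
  }
  nf <- ncol(P)
  f0 <- rep(NA_real_, nf)
  j0 <- which.max(fen)
  f0[j0] <- pickPeak(j0, band[1], band[2])
  mj <- config$trace_max_jump
  if (j0 < nf) for (j in (j0 + 1):nf) {
    prev <- f0[j - 1]
    if (is.na(prev)) break
    f0[j] <- pickPeak(j, prev * (1 - mj), prev * (1 + mj))
  }
  if (j0 > 1) for (j in (j0 - 1):1) {
    prev <- f0[j + 1]
    if (is.na(prev)) break
    f0[j] <- pickPeak(j, prev * (1 - mj), prev * (1 + mj))
  }
  ok <- keep_e & !is.na(f0) & f0 > 0
  if (!any(ok)) stop("traceFundamental: no voiced frames")
  fundamentalContour(st$times[ok], f0[ok], hop_s)
}

## Shared CF segmentation rule, applied to any sampled contour:
## m = median frequency strictly before the (earliest) peak frame; CF = the
## longest contiguous run of frames within [0.9 m, 1.1 m] ending no later
## than the peak frame; ties broken by earliest start.
runSegmentation <- function(times, freqs) {
  step <- if (length(times) > 1) median(diff(times)) else 0
  pk <- which.max(freqs)
  out <- list(peak_time = times[pk], dur_cf = 0, cf_start = NA_real_,
              cf_end = NA_real_, freq_mean_cf = NA_real_, flagged = TRUE)
  if (pk < 2L) return(out)
  m <- median(freqs[seq_len(pk - 1L)])
  inband <- freqs[seq_len(pk)] >= 0.9 * m & freqs[seq_len(pk)] <= 1.1 * m
  r <- rle(inband)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- which(r$values)
  if (!length(runs)) return(out)
  best <- runs[which.max(r$lengths[runs])]
  i1 <- starts[best]; i2 <- ends[best]
  list(peak_time = times[pk], dur_cf = (i2 - i1 + 1L) * step,
       cf_start = times[i1], cf_end = times[i2],
       freq_mean_cf = mean(freqs[i1:i2]), flagged = FALSE)
}

#' Segment the constant-frequency portion of a call
#'
#' The CF portion is the longest contiguous run of contour frames within
#' +-10\% of the median contour frequency prior to the (earliest) peak
#' frame, ending no later than the peak. If the peak falls on the first
#' frame the CF is undefined: \code{dur.cf = 0}, flagged.
#'
#' @param contour a \linkS4class{FundamentalContour}.
#' @param call_dur call duration (s) used for the relative end time;
#'   defaults to the contour span.
#' @param call_start time origin of the call (s), default 0.
#' @return list: \code{cf_start}, \code{cf_end}, \code{dur.cf},
#'   \code{endtime.cf}, \code{freq.mean.cf} (Hz), \code{peak_time},
#'   \code{flagged}.
#' @export
segmentCF <- function(contour, call_dur = NULL, call_start = 0) {
  tt <- contourTimes(contour)
  if (length(tt) < 3L) stop("segmentCF: need at least 3 contour frames")
  if (is.null(call_dur)) call_dur <- max(tt) - call_start
  s <- runSegmentation(tt, contourFreqs(contour))
  endt <- if (s$flagged) 0 else
    min(max((s$cf_end - call_start) / call_dur, 0), 1)
  list(cf_start = s$cf_start, cf_end = s$cf_end, dur.cf = s$dur_cf,
       endtime.cf = endt, freq.mean.cf = s$freq_mean_cf,
       peak_time = s$peak_time, flagged = s$flagged)
}

#' Segment the upsweep portion of a call
#'
#' The upsweep runs from the end of the CF portion to the contour peak.
#'
#' @param contour a \linkS4class{FundamentalContour}.
#' @param cf_end CF end time (s); use the peak time itself for flat calls
#'   whose CF extends to the peak.
#' @param call_dur,call_start as in \code{\link{segmentCF}}.
#' @return list: \code{dur.upsweep}, \code{endtime.upsweep},
#'   \code{peak_time}.
#' @export
segmentUpsweep <- function(contour, cf_end, call_dur = NULL,
                           call_start = 0) {
  tt <- contourTimes(contour)
  if (is.null(call_dur)) call_dur <- max(tt) - call_start
  pk <- tt[which.max(contourFreqs(contour))]
  if (pk < cf_end - 1e-9)
    stop("segmentUpsweep: peak precedes cf_end (inconsistent marks)")
  list(dur.upsweep = max(pk - cf_end, 0),
       endtime.upsweep = min(max((pk - call_start) / call_dur, 0), 1),
       peak_time = pk)
}

#' Detect subharmonic-dominated periods
#'
#' Per STFT frame, harmonic energy is summed in bands around integer
#' multiples of the traced fundamental and subharmonic energy in bands
#' around half-integer multiples (band half-width a configured fraction of
#' the fundamental). A frame is subharmonic-dominated iff subharmonic
#' energy strictly exceeds harmonic energy; maximal runs of such frames
#' form the subharmonic intervals. Energy ratios are floored so the dB
#' ratio is capped at +-\code{ratio_cap_db}.
#'
#' @param record a \linkS4class{WhoopRecord} at the working rate.
#' @param contour the traced \linkS4class{FundamentalContour}.
#' @param config a \code{\link{featureConfig}}.
#' @param cf_interval optional \code{c(start, end)} of the CF portion for
#'   the CF-restricted ratio.
#' @return list: \code{intervals} (two-column matrix of start/end times),
#'   \code{dur.subharm}, \code{harmonic.ratio.total},
#'   \code{harmonic.ratio.cf} (dB; falls back to the total ratio, flagged
#'   \code{NA}-free, when no CF interval is supplied).
#' @export
detectSubharmonics <- function(record, contour, config = featureConfig(),
                               cf_interval = NULL) {
  if (missing(contour) || is.null(contour))
    stop("detectSubharmonics: contour missing")
  w <- asWave(record)
  st <- powerSTFT(w$x, w$fs, config$trace_nfft, config$trace_hop)
  hop_s <- config$trace_hop / w$fs
  tt <- contourTimes(contour)
  use <- st$times >= min(tt) - hop_s / 2 & st$times <= max(tt) + hop_s / 2
  jj <- which(use)
  f0 <- approx(tt, contourFreqs(contour), xout = st$times[jj],
               rule = 2)$y
  hw <- config$harmonic_halfwidth
  nyq <- w$fs / 2
  bandEnergy <- function(j, centres, f) {
    tot <- 0
    for (cf in centres) {
      if (cf - hw * f > nyq) next
      ii <- which(st$freqs >= cf - hw * f & st$freqs <= min(cf + hw * f, nyq))
      if (length(ii)) tot <- tot + sum(st$P[ii, j])
    }
    tot
  }
  Eh <- numeric(length(jj)); Es <- numeric(length(jj))
  for (m in seq_along(jj)) {
    k <- seq_len(config$n_harmonics)
    Eh[m] <- bandEnergy(jj[m], k * f0[m], f0[m])
    Es[m] <- bandEnergy(jj[m], (k - 0.5) * f0[m], f0[m])
  }
  dom <- Es > Eh
  r <- rle(dom)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  runs <- which(r$values)
  intervals <- if (length(runs))
    cbind(start = st$times[jj[starts[runs]]] - hop_s / 2,
          end = st$times[jj[ends[runs]]] + hop_s / 2)
  else matrix(numeric(0), ncol = 2,
              dimnames = list(NULL, c("start", "end")))
  capRatio <- function(eh, es) {
    eps <- (eh + es) * 10^(-config$ratio_cap_db / 10)
    if (eh + es <= 0) return(0)
    10 * log10((eh + eps) / (es + eps))
  }
  inCF <- if (!is.null(cf_interval))
    st$times[jj] >= cf_interval[1] & st$times[jj] <= cf_interval[2]
  else rep(TRUE, length(jj))
  list(intervals = intervals, dur.subharm = sum(dom) * hop_s,
       harmonic.ratio.total = capRatio(sum(Eh), sum(Es)),
       harmonic.ratio.cf = capRatio(sum(Eh[inCF]), sum(Es[inCF])))
}

blockSpectra <- function(x, n, hop, pad = NULL) {
  if (length(x) < n) stop("window shorter than one analysis block")
  starts <- seq(1, length(x) - n + 1, by = hop)
  idx <- outer(0:(n - 1), starts, "+")
  M <- matrix(x[idx], nrow = n)
  if (!is.null(pad) && pad > n) M <- rbind(M, matrix(0, pad - n, ncol(M)))
  stats::mvfft(M)
}

## analytic expected normalized entropy of white noise for N independent
## one-sided bins (Dirichlet(1,...,1) weights): (psi(N+1) - psi(2)) / ln N
whiteNoiseEntropy <- function(n_bins) {
  (digamma(n_bins + 1) - digamma(2)) / log(n_bins)
}

#' Mean normalized spectral entropy
#'
#' The signal is resampled to \code{entropy_rate} and cut into
#' \code{block_ms} blocks at \code{block_hop_ms} hop. Per block, the
#' Shannon entropy of the normalized one-sided power spectrum is divided
#' by \code{log(N_bins)}. With \code{calibrate = TRUE} (default) each
#' block's value is further divided by the analytic expected entropy of
#' white noise for that bin count and clamped to [0, 1], anchoring the
#' scale at its printed endpoints (0 = pure tone, 1 = white noise); the
#' raw normalized entropy is returned with \code{calibrate = FALSE}. The
#' mean is taken over blocks inside the energy window.
#'
#' @param record a \linkS4class{WhoopRecord} (any rate; resampled
#'   internally).
#' @param window optional \code{\link{energyWindow}} result (in
#'   \code{record} time) restricting the blocks.
#' @param config a \code{\link{featureConfig}}.
#' @param calibrate logical; calibrate to the white-noise expectation.
#' @return mean entropy in [0, 1].
#' @export
spectralEntropyMean <- function(record, window = NULL,
                                config = featureConfig(),
                                calibrate = TRUE) {
  rec8 <- resampleAudio(record, config$entropy_rate)
  x <- waveform(rec8)
  if (!is.null(window)) {
    i1 <- max(1L, floor(window$t_start * config$entropy_rate) + 1L)
    i2 <- min(length(x), ceiling(window$t_end * config$entropy_rate))
    x <- x[i1:i2]
  }
  S <- blockSpectra(x, config$block_n, config$block_hop)
  nb <- floor(config$block_n / 2) + 1L
  P <- Mod(S[seq_len(nb), , drop = FALSE])^2
  cs <- colSums(P)
  ok <- cs > 0
  if (!any(ok)) stop("spectralEntropyMean: silent window")
  p <- sweep(P[, ok, drop = FALSE], 2, cs[ok], "/")
  plogp <- p * log(p)
  plogp[!is.finite(plogp)] <- 0
  H <- -colSums(plogp) / log(nb)
  if (calibrate) H <- pmin(H / whiteNoiseEntropy(nb), 1)
  mean(H)
}

#' Cepstral peak prominence statistics
#'
#' Per block (at \code{entropy_rate}), the real cepstrum of the dB
#' magnitude spectrum (block zero-padded to \code{cpp_pad}) is regressed
#' on quefrency over the search range corresponding to \code{cpp_band};
#' CPP is the height of the cepstral maximum above the regression line.
#' Amplitude scaling shifts the whole log spectrum and cancels in the
#' prominence.
#'
#' @inheritParams spectralEntropyMean
#' @return list: \code{cpp.mean}, \code{cpp.sd} (dB; \code{cpp.sd} is 0
#'   for a single block).
#' @export
cppStats <- function(record, window = NULL, config = featureConfig()) {
  rec8 <- resampleAudio(record, config$entropy_rate)
  x <- waveform(rec8)
  if (!is.null(window)) {
    i1 <- max(1L, floor(window$t_start * config$entropy_rate) + 1L)
    i2 <- min(length(x), ceiling(window$t_end * config$entropy_rate))
    x <- x[i1:i2]
  }
  pad <- config$cpp_pad
  S <- blockSpectra(x, config$block_n, config$block_hop, pad = pad)
  A <- Mod(S)
  floorv <- pmax(apply(A, 2, max), .Machine$double.xmin) * 1e-8
  A <- pmax(A, rep(floorv, each = nrow(A)))
  logmag <- 20 * log10(A)
  C <- Re(stats::mvfft(logmag, inverse = TRUE)) / pad
  q <- (0:(pad - 1)) / config$entropy_rate
  idx <- which(q >= 1 / config$cpp_band[2] & q <= 1 / config$cpp_band[1])
  X <- cbind(1, q[idx])
  proj <- X %*% solve(crossprod(X), t(X))
  resid <- C[idx, , drop = FALSE] - proj %*% C[idx, , drop = FALSE]
  cpp <- apply(resid, 2, max)
  list(cpp.mean = mean(cpp),
       cpp.sd = if (length(cpp) > 1) sd(cpp) else 0)
}

#' Extract the sixteen acoustic features from one call
#'
#' Orchestrates the full per-call pipeline: resample to the working rate,
#' 99\%-energy call window, spectral peak/centroid, fundamental tracing,
#' CF and upsweep segmentation, subharmonic detection, spectral entropy
#' and cepstral peak prominence (at 8 kHz). A call whose contour cannot be
#' traced is returned with \code{failed = TRUE} and NA features, never
#' dropped. Degenerate CF (peak on the first frame) yields
#' \code{dur.cf = 0} and is noted in \code{flags}.
#'
#' @param record a \linkS4class{WhoopRecord}.
#' @param config a \code{\link{featureConfig}}.
#' @param anchor optional anchor contour passed to
#'   \code{\link{traceFundamental}}.
#' @return one-row data.frame: the 16 features (frequencies in kHz,
#'   durations in s, ratios in dB), plus \code{failed}, \code{flags}, and
#'   a \code{config_hash} provenance column.
#' @export
extractFeatures <- function(record, config = featureConfig(),
                            anchor = NULL) {
  out <- as.data.frame(setNames(as.list(rep(NA_real_,
                                            length(featureNames))),
                                featureNames), check.names = FALSE)
  out$failed <- FALSE
  out$flags <- ""
  out$config_hash <- configHash(config)
  res <- try({
    rec <- resampleAudio(record, config$sample_rate)
    win <- energyWindow(rec, config$energy_fraction)
    seg <- windowSamples(rec, win)
    ss <- spectrumSummary(rec, win)
    contour <- traceFundamental(seg, config, anchor = anchor)
    cf <- segmentCF(contour, call_dur = win$dur, call_start = 0)
    flags <- character(0)
    cf_end_eff <- if (cf$flagged) {
      flags <- c(flags, "cf_undefined")
      cf$peak_time
    } else cf$cf_end
    up <- segmentUpsweep(contour, cf_end_eff, call_dur = win$dur,
                         call_start = 0)
    sh <- detectSubharmonics(seg, contour, config,
                             cf_interval = if (!cf$flagged)
                               c(cf$cf_start, cf$cf_end) else NULL)
    seg8 <- resampleAudio(seg, config$entropy_rate)
    ent <- spectralEntropyMean(seg8, NULL, config)
    cpp <- cppStats(seg8, NULL, config)
    fr <- contourFreqs(contour)
    out$dur <- win$dur
    out$dur.cf <- min(cf$dur.cf, win$dur)
    out$dur.upsweep <- min(up$dur.upsweep, win$dur)
    out$dur.subharm <- min(sh$dur.subharm, win$dur)
    out$endtime.cf <- if (cf$flagged) up$endtime.upsweep else cf$endtime.cf
    out$endtime.upsweep <- up$endtime.upsweep
    out$freq.centroid <- ss$freq.centroid
    out$freq.peak <- ss$freq.peak
    out$freq.min <- min(fr) / 1000
    out$freq.max <- max(fr) / 1000
    out$freq.mean.cf <- if (cf$flagged) max(fr) / 1000 else
      cf$freq.mean.cf / 1000
    out$harmonic.ratio.total <- sh$harmonic.ratio.total
    out$harmonic.ratio.cf <- sh$harmonic.ratio.cf
    out$mean.entropy <- ent
    out$cpp.mean <- cpp$cpp.mean
    out$cpp.sd <- cpp$cpp.sd
    out$flags <- paste(flags, collapse = ";")
    stopifnot(out$endtime.cf <= out$endtime.upsweep + 1e-9,
              out$freq.min <= out$freq.mean.cf + 1e-9,
              out$freq.mean.cf <= out$freq.max + 1e-9,
              out$mean.entropy >= 0, out$mean.entropy <= 1)
    NULL
  }, silent = TRUE)
  if (inherits(res, "try-error")) {
    out$failed <- TRUE
    out$flags <- conditionMessage(attr(res, "condition"))
  }
  out
}

#' Extract features for a whole dataset
#'
#' Batch \code{\link{extractFeatures}} over a list of records (e.g. from
#' \code{\link{synthesizeDataset}}) or a metadata CSV plus WAV directory.
#' Exactly one row is emitted per input call; failures are flagged, not
#' dropped.
#'
#' @param records list of \linkS4class{WhoopRecord}, or the path of a
#'   metadata CSV (schema of \code{\link{readMetadata}}).
#' @param metadata metadata data.frame aligned with \code{records}
#'   (ignored when \code{records} is a CSV path).
#' @param wav_dir base directory for \code{wav_path} entries when reading
#'   from disk.
#' @param config a \code{\link{featureConfig}}.
#' @param contours optional named list of anchor contours keyed by
#'   \code{whoop_id} (each a data.frame \code{time_s}, \code{freq_hz}).
#' @return a FeatureTable: metadata columns + 16 features + \code{failed}
#'   + \code{flags} + \code{config_hash}.
#' @export
extractFeatureTable <- function(records, metadata = NULL, wav_dir = ".",
                                config = featureConfig(),
                                contours = NULL) {
  if (is.character(records)) {
    metadata <- readMetadata(records)
    records <- lapply(file.path(wav_dir, metadata$wav_path), readWhoopWav)
  }
  if (is.null(metadata))
    metadata <- data.frame(whoop_id = sprintf("w%04d",
                                              seq_along(records)))
  stopifnot(length(records) == nrow(metadata))
  rows <- vector("list", length(records))
  for (k in seq_along(records)) {
    anc <- if (!is.null(contours)) contours[[metadata$whoop_id[k]]]
    rows[[k]] <- extractFeatures(records[[k]], config, anchor = anc)
  }
  cbind(metadata, do.call(rbind, rows))
}
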