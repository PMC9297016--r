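toneRecord <- function(freq, dur = 1, fs = 32000, amp = 1) {
  whoopRecord(amp * sin(2 * pi * freq * (0:(dur * fs - 1)) / fs), fs)
}

test_that("resampling preserves tones and durations", {
  r <- toneRecord(700)
  r8 <- resampleAudio(r, 8000)
  expect_equal(length(waveform(r8)), 8000)
  s <- spectrumSummary(r8)
  expect_lt(abs(s$freq.peak - 0.7), 0.002)   # within 2 bins (kHz)
  expect_identical(resampleAudio(r, 32000), r)
  expect_error(resampleAudio(r, -1), "target_rate")
})

test_that("the energy window matches a brute-force cumulative scan", {
  fs <- 8000
  # tone occupying the middle half of the file
  x <- numeric(2 * fs)
  mid <- (fs / 2):(3 * fs / 2)
  x[mid] <- sin(2 * pi * 500 * mid / fs)
  w <- energyWindow(whoopRecord(x, fs))
  expect_lt(abs(w$t_start - 0.5), 0.01 * 1)
  expect_lt(abs(w$t_end - 1.5), 0.01 * 1)
  # unit impulse: zero-width window at the impulse
  xi <- numeric(fs); xi[1234] <- 1
  wi <- energyWindow(whoopRecord(xi, fs))
  expect_equal(wi$i_start, 1234)
  expect_equal(wi$i_end, 1234)
  # linear-ramp envelope: oracle = direct cumulative-energy loop
  set.seed(3)
  xr <- seq(0, 1, length.out = fs) * sin(2 * pi * 300 * (0:(fs - 1)) / fs)
  wr <- energyWindow(whoopRecord(xr, fs), fraction = 0.99)
  e <- xr^2; tot <- sum(e); cum <- 0; i1 <- NA; i2 <- NA
  for (i in seq_along(e)) {
    cum <- cum + e[i]
    if (is.na(i1) && cum >= 0.005 * tot) i1 <- i
    if (cum >= 0.995 * tot) { i2 <- i; break }
  }
  expect_equal(wr$i_start, i1)
  expect_equal(wr$i_end, i2)
  expect_error(energyWindow(whoopRecord(numeric(100) + 0, fs)), "silent")
})

test_that("spectral peak and centroid follow closed forms", {
  r <- toneRecord(800)
  s <- spectrumSummary(r)
  expect_lt(abs(s$freq.peak - 0.8), 0.002)
  expect_lt(abs(s$freq.centroid - 0.8), 0.002)
  # two equal-power tones: centroid at the midpoint
  fs <- 32000
  x2 <- sin(2 * pi * 600 * (0:(fs - 1)) / fs) +
    sin(2 * pi * 1000 * (0:(fs - 1)) / fs)
  s2 <- spectrumSummary(whoopRecord(x2, fs))
  expect_lt(abs(s2$freq.centroid - 0.8), 0.002)
  # 1:3 power ratio at 600/1000 Hz: centroid = 0.25*600 + 0.75*1000
  x3 <- sin(2 * pi * 600 * (0:(fs - 1)) / fs) +
    sqrt(3) * sin(2 * pi * 1000 * (0:(fs - 1)) / fs)
  s3 <- spectrumSummary(whoopRecord(x3, fs))
  expect_lt(abs(s3$freq.centroid - 0.9), 0.002)
})

test_that("tracing recovers a flat tone and honours anchors", {
  r <- toneRecord(700, dur = 2)
  ct <- traceFundamental(r)
  expect_true(all(abs(contourFreqs(ct) - 700) < 32000 / 1024))
  # anchor pass-through: returned contour equals the anchor on its grid
  anc <- data.frame(time_s = seq(0.2, 1.8, by = 0.01),
                    freq_hz = 500 + 100 * seq(0.2, 1.8, by = 0.01))
  ct2 <- traceFundamental(r, anchor = anc)
  expect_equal(contourFreqs(ct2),
               approx(anc$time_s, anc$freq_hz,
                      xout = contourTimes(ct2))$y)
  expect_error(traceFundamental(whoopRecord(rep(1e-30, 32000), 32000),
                                featureConfig()), "voiced|silent")
})

test_that("tracing a noisy synthetic whoop stays within 2% of truth", {
  p <- structure(list(type = "A", f0_cf = 720, f0_max = 1010, dur = 2.8,
                      cf_start = 0.17, cf_end = 1.7, upsweep_end = 2.5,
                      n_harmonics = 6, amplitude_rolloff = 6,
                      subharmonic = NULL, snr = 20),
                 class = "SynthWhoopParams")
  set.seed(12)
  rec <- renderWhoop(p, 32000)
  ct <- traceFundamental(rec)
  truth <- whoopsig:::f0Curve(contourTimes(ct), p)
  expect_lt(median(abs(contourFreqs(ct) - truth) / truth), 0.02)
})

test_that("CF segmentation matches its closed-form cases", {
  # 1 s flat at 700 Hz then a steep rise to 1000 Hz: the +-10% band
  # admits at most one rising frame, so CF is the flat second
  hop <- 0.008
  tt <- seq(hop, 1.6, by = hop)
  fr <- ifelse(tt <= 1, 700, pmin(700 + 300 * (tt - 1) / 0.02, 1000))
  ct <- fundamentalContour(tt, fr, hop)
  seg <- segmentCF(ct, call_dur = 1.6)
  expect_lt(abs(seg$dur.cf - 1.0), 2 * hop)
  expect_equal(seg$freq.mean.cf, 700, tolerance = 1 / 700)
  expect_false(seg$flagged)
  # contour entirely within +-10% of its pre-peak median: CF reaches peak
  fr2 <- 700 + 20 * sin(tt * 3)
  seg2 <- segmentCF(fundamentalContour(tt, fr2, hop), call_dur = 1.6)
  expect_equal(seg2$cf_end, tt[which.max(fr2)])
  expect_equal(seg2$dur.cf, which.max(fr2) * hop)
})

test_that("CF segmentation equals exhaustive run enumeration", {
  # independent oracle: enumerate every contiguous run ending at or before
  # the earliest peak and inside the band, pick the longest (earliest tie)
  oracleCF <- function(fr) {
    pk <- which.max(fr)
    if (pk < 2) return(NULL)
    m <- median(fr[1:(pk - 1)])
    best <- NULL
    for (i in seq_len(pk)) for (j in i:pk) {
      if (all(fr[i:j] >= 0.9 * m & fr[i:j] <= 1.1 * m)) {
        if (is.null(best) || (j - i) > (best[2] - best[1]))
          best <- c(i, j)
      }
    }
    best
  }
  set.seed(99)
  hop <- 0.01
  for (case in 1:400) {
    n <- sample(5:40, 1)
    fr <- 700 * exp(cumsum(rnorm(n, sd = 0.05)))
    tt <- seq_len(n) * hop
    seg <- segmentCF(fundamentalContour(tt, fr, hop), call_dur = n * hop)
    oc <- oracleCF(fr)
    if (is.null(oc)) {
      expect_true(seg$flagged || seg$dur.cf == 0)
    } else {
      expect_equal(seg$cf_start, tt[oc[1]])
      expect_equal(seg$cf_end, tt[oc[2]])
    }
  }
})

test_that("upsweep segmentation measures plateau-to-peak time", {
  hop <- 0.01
  tt <- seq(hop, 2, by = hop)
  fr <- ifelse(tt <= 1, 700, pmin(700 + 750 * (tt - 1), 1000))
  ct <- fundamentalContour(tt, fr, hop)
  # plateau ends at 1.0 s, peak at 1.4 s
  up <- segmentUpsweep(ct, 1.0, call_dur = 2)
  expect_lt(abs(up$dur.upsweep - 0.4), 2 * hop)
  expect_lt(abs(up$endtime.upsweep - 1.4 / 2), 2 * hop)
  # flat call whose CF extends to the peak: zero upsweep
  frf <- rep(700, length(tt)) + c(seq(0, 1, length.out = length(tt)))
  ctf <- fundamentalContour(tt, frf, hop)
  upf <- segmentUpsweep(ctf, max(tt), call_dur = 2)
  expect_equal(upf$dur.upsweep, 0)
  expect_error(segmentUpsweep(ct, 1.9), "peak precedes")
})

test_that("subharmonic detection finds injected intervals and caps ratios", {
  base <- list(type = "A", f0_cf = 700, f0_max = 1000, dur = 3,
               cf_start = 0.15, cf_end = 1.9, upsweep_end = 2.6,
               n_harmonics = 6, amplitude_rolloff = 6,
               subharmonic = NULL, snr = Inf)
  # pure harmonic stack: no subharmonic time, ratio at the +60 dB cap
  rec <- renderWhoop(structure(base, class = "SynthWhoopParams"), 32000)
  ct <- traceFundamental(rec)
  d0 <- detectSubharmonics(rec, ct)
  expect_equal(d0$dur.subharm, 0)
  # at or just under the +60 dB cap: STFT sidelobe leakage leaves a few
  # parts-per-million of energy in the half-integer bands
  expect_gte(d0$harmonic.ratio.total, 45)
  expect_lte(d0$harmonic.ratio.total, 60)
  # +6 dB subharmonic on [1.0, 1.5] s: detected interval overlaps with
  # Jaccard >= 0.8
  base$subharmonic <- list(start = 1.0, end = 1.5, level_db = 6)
  rec1 <- renderWhoop(structure(base, class = "SynthWhoopParams"), 32000)
  ct1 <- traceFundamental(rec1)
  d1 <- detectSubharmonics(rec1, ct1,
                           cf_interval = c(base$cf_start, base$cf_end))
  expect_gt(nrow(d1$intervals), 0)
  lo <- max(d1$intervals[1, "start"], 1.0)
  hi <- min(d1$intervals[nrow(d1$intervals), "end"], 1.5)
  union <- max(d1$intervals[nrow(d1$intervals), "end"], 1.5) -
    min(d1$intervals[1, "start"], 1.0)
  expect_gte((hi - lo) / union, 0.8)
  expect_lt(d1$harmonic.ratio.cf, d0$harmonic.ratio.total)
  # a weak (-20 dB) subharmonic never strictly dominates
  base$subharmonic$level_db <- -20
  rec2 <- renderWhoop(structure(base, class = "SynthWhoopParams"), 32000)
  d2 <- detectSubharmonics(rec2, traceFundamental(rec2))
  expect_equal(d2$dur.subharm, 0)
  expect_error(detectSubharmonics(rec, NULL), "contour")
})

test_that("raw spectral entropy matches the two-atom closed form", {
  fs <- 8000
  tt <- (0:(fs - 1)) / fs
  # two equal tones on exact 250 Hz bins of the 32-sample rectangular block
  x <- sin(2 * pi * 750 * tt) + sin(2 * pi * 1500 * tt)
  h <- spectralEntropyMean(whoopRecord(x, fs), calibrate = FALSE)
  expect_lt(abs(h - log(2) / log(17)), 0.005)
  # entropy is always within [0, 1], calibrated or not
  set.seed(5)
  hn <- spectralEntropyMean(whoopRecord(rnorm(fs), fs))
  expect_gte(hn, 0); expect_lte(hn, 1)
})

test_that("CPP separates periodic pulse trains from noise", {
  fs <- 8000
  pulse <- numeric(2 * fs); pulse[seq(1, 2 * fs, by = 10)] <- 1  # 800 Hz
  set.seed(21)
  noise <- rnorm(2 * fs)
  cp <- cppStats(whoopRecord(pulse, fs))
  cn <- cppStats(whoopRecord(noise, fs))
  # paired periodic-vs-noise margin derived for 4 ms blocks
  expect_gt(cp$cpp.mean - cn$cpp.mean, 2)
  # amplitude scaling cancels in the prominence
  cp10 <- cppStats(whoopRecord(10 * pulse, fs))
  expect_equal(cp10$cpp.mean, cp$cpp.mean, tolerance = 1e-8)
  # near-stationary signal: dispersion below the mean level
  expect_lt(cp$cpp.sd, cp$cpp.mean)
  expect_error(featureConfig(cpp_band = c(100, 1200)), "quefrency")
})

test_that("full extraction recovers noiseless ground truth", {
  p <- structure(list(type = "S", f0_cf = 750, f0_max = 1080, dur = 2.6,
                      cf_start = 0.16, cf_end = 0.9, upsweep_end = 1.5,
                      n_harmonics = 6, amplitude_rolloff = 6,
                      subharmonic = NULL, snr = Inf),
                 class = "SynthWhoopParams")
  f <- extractFeatures(renderWhoop(p, 32000))
  expect_false(f$failed)
  expect_lt(abs(f$dur - p$dur) / p$dur, 0.05)
  expect_lt(abs(f$freq.max * 1000 - p$f0_max) / p$f0_max, 0.02)
  expect_lte(f$endtime.cf, f$endtime.upsweep)
  expect_lte(f$freq.min, f$freq.mean.cf)
  expect_lte(f$freq.mean.cf, f$freq.max)
})

test_that("flat terminal whoops have coincident CF and upsweep ends", {
  p <- structure(list(type = "T", f0_cf = 650, f0_max = 650, dur = 2,
                      cf_start = 0.12, cf_end = 1.8, upsweep_end = 1.8,
                      n_harmonics = 6, amplitude_rolloff = 6,
                      subharmonic = NULL, snr = Inf),
                 class = "SynthWhoopParams")
  f <- extractFeatures(renderWhoop(p, 32000))
  expect_false(f$failed)
  expect_lt(f$dur.upsweep, 0.25)
  expect_lt(abs(f$endtime.cf - f$endtime.upsweep), 0.15)
})

test_that("batch extraction emits one flagged row per input", {
  p <- structure(list(type = "S", f0_cf = 700, f0_max = 1000, dur = 1.5,
                      cf_start = 0.1, cf_end = 0.6, upsweep_end = 0.9,
                      n_harmonics = 6, amplitude_rolloff = 6,
                      subharmonic = NULL, snr = Inf),
                 class = "SynthWhoopParams")
  good <- renderWhoop(p, 32000)
  silent <- whoopRecord(numeric(8000), 32000)
  ft <- extractFeatureTable(list(good, silent, good))
  expect_equal(nrow(ft), 3L)
  expect_equal(ft$failed, c(FALSE, TRUE, FALSE))
  expect_match(ft$flags[2], "silent")
})

test_that("features are invariant to constant amplitude scaling", {
  p <- structure(list(type = "A", f0_cf = 700, f0_max = 980, dur = 2.2,
                      cf_start = 0.14, cf_end = 1.4, upsweep_end = 2.0,
                      n_harmonics = 6, amplitude_rolloff = 6,
                      subharmonic = NULL, snr = Inf),
                 class = "SynthWhoopParams")
  rec <- renderWhoop(p, 32000)
  rec3 <- whoopRecord(3 * waveform(rec), 32000)
  f1 <- extractFeatures(rec)
  f3 <- extractFeatures(rec3)
  for (nm in whoopFeatureNames())
    expect_equal(f3[[nm]], f1[[nm]], tolerance = 1e-6, label = nm)
})
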