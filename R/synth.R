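## Synthetic whoop-bout generator: population -> bouts -> rendered calls.

rtruncnorm1 <- function(n, sd, trunc = 2.5) {
  if (sd == 0) return(rep(0, n))
  x <- rnorm(n, sd = sd)
  pmin(pmax(x, -trunc * sd), trunc * sd)
}

## lognormal jitter with coefficient of variation cv, truncated at 3 sdlog
jitterFactor <- function(n, cv, trunc = 3) {
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  z <- pmin(pmax(rnorm(n), -trunc), trunc)
  exp(z * sdlog - sdlog^2 / 2)
}

#' Sample a population of individual vocal signatures
#'
#' Draws per-clan and per-individual multiplicative offsets for the base
#' call parameters. Each individual parameter mean equals
#' \code{base * (1 + clan offset + individual offset)}, with offsets drawn
#' from zero-mean normals with s.d. \code{clan_effect_scale} and
#' \code{individual_effect_scale} (truncated at 2.5 s.d.). A single
#' frequency offset is shared by \code{f0_cf} and \code{f0_max}.
#' Deterministic given \code{spec$seed}.
#'
#' @param spec a \code{\link{populationSpec}}.
#' @return data.frame with one row per individual: \code{individual_id},
#'   \code{clan_id}, \code{sex}, \code{age_months}, \code{f0_cf_mean},
#'   \code{f0_max_mean}, \code{dur_mean}, \code{cf_fraction_mean},
#'   \code{subharmonic_propensity}, \code{amplitude_rolloff},
#'   \code{n_harmonics}.
#' @export
samplePopulation <- function(spec) {
  validatePopulationSpec(spec)
  nC <- spec$n_clans
  nI <- spec$individuals_per_clan
  n <- nC * nI
  old <- .Random.seed.save()
  on.exit(.Random.seed.restore(old), add = TRUE)
  set.seed(deriveSeed(spec$seed, 1L))

  eff <- function(name, scale_clan, scale_ind) {
    on <- name %in% spec$signature_params
    clan_off <- if (on) rtruncnorm1(nC, scale_clan) else rep(0, nC)
    ind_off <- if (on) rtruncnorm1(n, scale_ind) else rep(0, n)
    1 + rep(clan_off, each = nI) + ind_off
  }
  f0_mult <- eff("f0", spec$clan_effect_scale, spec$individual_effect_scale)
  dur_mult <- eff("dur", spec$clan_effect_scale, spec$individual_effect_scale)
  cf_mult <- eff("cf_fraction", spec$clan_effect_scale,
                 spec$individual_effect_scale)

  clan_id <- rep(sprintf("clan%02d", seq_len(nC)), each = nI)
  data.frame(
    individual_id = sprintf("ind%03d", seq_len(n)),
    clan_id = clan_id,
    sex = rep_len(c("f", "m"), n),
    age_months = sample(25:120, n, replace = TRUE),
    f0_cf_mean = spec$f0_cf_base * f0_mult,
    f0_max_mean = spec$f0_max_base * f0_mult,
    dur_mean = spec$dur_base * dur_mult,
    cf_fraction_mean = pmin(pmax(spec$cf_fraction_base * cf_mult, 0.05), 0.9),
    subharmonic_propensity = spec$subharmonic_propensity,
    amplitude_rolloff = spec$amplitude_rolloff,
    n_harmonics = spec$n_harmonics,
    stringsAsFactors = FALSE)
}

.Random.seed.save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}
.Random.seed.restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

whoopParams <- function(type, sig, spec, bout_f0, bout_dur, snr_db) {
  f0j <- jitterFactor(1, spec$within_individual_cv)
  dj <- jitterFactor(1, spec$within_individual_cv)
  cj <- jitterFactor(1, spec$within_individual_cv)
  f0_cf <- sig$f0_cf_mean * bout_f0 * f0j
  f0_max <- sig$f0_max_mean * bout_f0 * f0j
  # physiological cap: per-call pitch within +-30% of the population base
  # (also keeps 4 * n_harmonics * f0_max under the default 32 kHz rate)
  cap <- 1.30 * spec$f0_max_base
  if (f0_max > cap) {
    sc <- cap / f0_max
    f0_max <- cap
    f0_cf <- f0_cf * sc
  }
  dur <- sig$dur_mean * bout_dur * dj
  cf_fraction <- pmin(pmax(sig$cf_fraction_mean * cj, 0.05), 0.9)

  if (type == "P") dur <- dur * 0.35          # preliminary whoops are short
  if (type == "T") dur <- dur * 0.7
  cf_start <- 0.06 * dur
  if (type == "A") {                          # long CF, late peak
    upsweep_end <- 0.92 * dur
    cf_end <- cf_start + pmin(cf_fraction * 1.35, 0.85) *
      (upsweep_end - cf_start)
  } else if (type == "T") {                   # flat, low contour
    f0_max <- f0_cf
    cf_end <- 0.9 * dur
    upsweep_end <- cf_end
  } else {                                    # S and P: peak near centre
    upsweep_end <- 0.58 * dur
    cf_end <- cf_start + (cf_fraction * 0.55) * (upsweep_end - cf_start)
  }

  sub <- NULL
  if (type %in% c("A", "S") &&
      runif(1) < sig$subharmonic_propensity && cf_end - cf_start > 0.3) {
    s0 <- cf_start + 0.2 * (cf_end - cf_start)
    sub <- list(start = s0, end = s0 + 0.5 * (cf_end - cf_start),
                level_db = spec$subharmonic_level_db)
  }
  p <- list(type = type, f0_cf = f0_cf, f0_max = f0_max, dur = dur,
            cf_start = cf_start, cf_end = cf_end, upsweep_end = upsweep_end,
            n_harmonics = sig$n_harmonics,
            amplitude_rolloff = sig$amplitude_rolloff,
            subharmonic = sub, snr = snr_db)
  class(p) <- "SynthWhoopParams"
  stopifnot(0 <= p$cf_start, p$cf_start < p$cf_end,
            p$cf_end <= p$upsweep_end, p$upsweep_end <= p$dur,
            p$f0_max >= p$f0_cf)
  p
}

#' Generate ground-truth parameters for one whoop bout
#'
#' Bout length is uniform on \code{[length_min, length_max]}. The type
#' sequence follows the template (optional leading P, A/S body, optional
#' trailing T). Every whoop shares a bout-level lognormal jitter
#' (\code{bout_effect_cv}) on frequency and duration, on top of
#' per-call jitter with CV \code{within_individual_cv}. P whoops are
#' rendered short (duration multiplier 0.35) and T whoops flat
#' (\code{f0_max = f0_cf}). Uses the current RNG stream; seed externally
#' for reproducibility.
#'
#' @param sig one row of \code{\link{samplePopulation}} (data.frame or list).
#' @param bout a \code{\link{boutSpec}}.
#' @param spec the \code{\link{populationSpec}} (jitter scales).
#' @param snr_db signal-to-noise ratio for later rendering, dB
#'   (\code{Inf} = noiseless).
#' @return list of \code{SynthWhoopParams}, one per whoop, in bout order.
#' @export
generateBout <- function(sig, bout = boutSpec(), spec = populationSpec(),
                         snr_db = 15) {
  if (is.data.frame(sig)) sig <- as.list(sig[1, ])
  lens <- seq(bout$length_min, bout$length_max)
  len <- lens[sample.int(length(lens), 1L)]
  types <- rep("S", len)
  body <- seq_len(len)
  if (len > 2L && runif(1) < bout$p_leading) {
    types[1] <- "P"; body <- body[-1]
  }
  if (len > 2L && runif(1) < bout$p_terminal) {
    types[len] <- "T"; body <- setdiff(body, len)
  }
  types[body] <- ifelse(runif(length(body)) < bout$p_asymmetric, "A", "S")
  bout_f0 <- jitterFactor(1, spec$bout_effect_cv)
  bout_dur <- jitterFactor(1, spec$bout_effect_cv)
  lapply(types, whoopParams, sig = sig, spec = spec,
         bout_f0 = bout_f0, bout_dur = bout_dur, snr_db = snr_db)
}

## Analytic fundamental contour of a synthetic whoop: quadratic onset rise
## from 0.6 f0_cf, flat plateau, sine-eased upsweep (zero slope at the
## peak), cosine decay to 0.8 f0_max.
f0Curve <- function(tt, p) {
  f <- numeric(length(tt))
  on <- tt < p$cf_start
  f[on] <- p$f0_cf * (0.6 + 0.4 * (tt[on] / p$cf_start)^2)
  pl <- tt >= p$cf_start & tt < p$cf_end
  f[pl] <- p$f0_cf
  if (p$upsweep_end > p$cf_end) {
    up <- tt >= p$cf_end & tt < p$upsweep_end
    s <- (tt[up] - p$cf_end) / (p$upsweep_end - p$cf_end)
    f[up] <- p$f0_cf + (p$f0_max - p$f0_cf) * sin(pi / 2 * s)
  }
  de <- tt >= p$upsweep_end
  if (any(de)) {
    u <- (tt[de] - p$upsweep_end) / max(p$dur - p$upsweep_end, 1e-9)
    f[de] <- p$f0_max - 0.2 * p$f0_max * (1 - cos(pi * pmin(u, 1))) / 2
  }
  f
}

#' Render a synthetic whoop to a waveform
#'
#' Sums \code{n_harmonics} phase-continuous harmonics of the analytic
#' fundamental contour (phase integrated from instantaneous frequency)
#' with the configured amplitude rolloff, adds an optional subharmonic
#' component at half the fundamental on its interval, applies a
#' raised-cosine onset/offset envelope (1.5\% of the duration per side),
#' and adds Gaussian noise at the stated SNR.
#'
#' @param params a \code{SynthWhoopParams} (see \code{\link{generateBout}}).
#' @param sample_rate output rate, Hz; must be at least
#'   \code{4 * n_harmonics * f0_max} (anti-aliasing margin).
#' @param metadata optional metadata list carried into the record.
#' @return a \linkS4class{WhoopRecord}.
#' @export
renderWhoop <- function(params, sample_rate = 32000, metadata = list()) {
  p <- params
  if (sample_rate < 4 * p$n_harmonics * p$f0_max)
    stop("renderWhoop: sample_rate ", sample_rate,
         " below anti-aliasing bound 4 * n_harmonics * f0_max = ",
         round(4 * p$n_harmonics * p$f0_max))
  n <- round(p$dur * sample_rate)
  tt <- (seq_len(n) - 1) / sample_rate
  f0 <- f0Curve(tt, p)
  ph <- 2 * pi * cumsum(f0) / sample_rate
  x <- numeric(n)
  for (k in seq_len(p$n_harmonics))
    x <- x + 10^(-(k - 1) * p$amplitude_rolloff / 20) * sin(k * ph)
  if (!is.null(p$subharmonic)) {
    sb <- p$subharmonic
    amp <- 10^(sb$level_db / 20)
    seg <- tt >= sb$start & tt <= sb$end
    if (any(seg)) {
      sph <- 2 * pi * cumsum(0.5 * f0) / sample_rate
      ramp <- 0.1 * (sb$end - sb$start)
      w <- pmin(1, pmax(0, pmin(tt - sb$start, sb$end - tt) / ramp))
      x <- x + amp * w * sin(sph)
    }
  }
  nr <- max(2L, round(0.015 * n))
  env <- rep(1, n)
  up <- (1 - cos(pi * (seq_len(nr) - 1) / nr)) / 2
  env[seq_len(nr)] <- up
  env[n + 1 - seq_len(nr)] <- up
  x <- x * env
  if (is.finite(p$snr)) {
    ps <- mean(x^2)
    x <- x + rnorm(n, sd = sqrt(ps / 10^(p$snr / 10)))
  }
  whoopRecord(x, sample_rate, metadata)
}

#' Ground-truth features of a synthetic whoop
#'
#' Applies the CF/upsweep segmentation rule (the \code{\link{segmentCF}}
#' definition: longest contiguous run within +-10\% of the pre-peak median,
#' ending no later than the peak) to the analytic noiseless contour on a
#' 1 ms grid. This is the reference against which extracted features are
#' scored, since the CF portion is operationally defined.
#'
#' @param params a \code{SynthWhoopParams}.
#' @return one-row data.frame: \code{dur}, \code{f0_cf}, \code{freq_max},
#'   \code{dur_cf}, \code{freq_mean_cf}, \code{cf_start}, \code{cf_end},
#'   \code{upsweep_end}, \code{dur_subharm}, \code{type}.
#' @export
trueWhoopFeatures <- function(params) {
  p <- params
  tg <- seq(0, p$dur, by = 0.001)
  ft <- f0Curve(tg, p)
  seg <- runSegmentation(tg, ft)
  sub <- if (is.null(p$subharmonic)) 0 else
    p$subharmonic$end - p$subharmonic$start
  data.frame(type = p$type, dur = p$dur, f0_cf = p$f0_cf,
             freq_max = max(ft), dur_cf = seg$dur_cf,
             freq_mean_cf = seg$freq_mean_cf,
             cf_start = p$cf_start, cf_end = p$cf_end,
             upsweep_end = p$upsweep_end, dur_subharm = sub,
             stringsAsFactors = FALSE)
}
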