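## Specification objects for the synthetic whoop-bout generator.

#' Population specification for the synthetic generator
#'
#' Describes a population of clans and individuals producing harmonic,
#' frequency-modulated long-distance calls. Individual (and optionally
#' clan-level) signatures are multiplicative offsets on a set of base call
#' parameters. The default world matches the tested hypotheses: individual
#' signatures present (8\% between-individual s.d.), clan signatures absent
#' (clan effect zero), with a flag to inject a clan effect for power tests.
#'
#' A single frequency offset scales \code{f0_cf} and \code{f0_max} jointly
#' (an overall pitch shift), which preserves \code{f0_max >= f0_cf} by
#' construction. Offsets are truncated at 2.5 s.d. and per-call jitter at
#' 3 s.d. to keep parameters physiological and renders alias-free.
#'
#' @param n_clans number of clans.
#' @param individuals_per_clan number of individuals in each clan.
#' @param clan_effect_scale relative s.d. of clan-level offsets (unitless
#'   multiplier; 0 = no clan signature, the default).
#' @param individual_effect_scale relative s.d. of individual offsets.
#' @param within_individual_cv coefficient of variation of per-call
#'   lognormal jitter.
#' @param bout_effect_cv coefficient of variation of bout-level lognormal
#'   jitter shared by every whoop in a bout (the mechanism behind
#'   correlated within-bout classification errors).
#' @param f0_cf_base base fundamental frequency of the constant-frequency
#'   plateau, Hz.
#' @param f0_max_base base peak fundamental frequency, Hz.
#' @param dur_base base call duration, s.
#' @param cf_fraction_base base fraction of the pre-peak call occupied by
#'   the constant-frequency plateau, in (0, 1).
#' @param n_harmonics number of harmonics rendered.
#' @param amplitude_rolloff amplitude decay per harmonic, dB.
#' @param subharmonic_propensity probability that a whoop carries a
#'   subharmonic episode.
#' @param subharmonic_level_db subharmonic level re the fundamental, dB.
#' @param signature_params which parameters carry the clan/individual
#'   offsets; subset of \code{c("f0", "dur", "cf_fraction")}. \code{"f0"}
#'   scales \code{f0_cf} and \code{f0_max} jointly.
#' @param seed integer seed controlling population sampling.
#' @return a \code{PopulationSpec} (named list, classed).
#' @export
populationSpec <- function(n_clans = 4, individuals_per_clan = 5,
                           clan_effect_scale = 0,
                           individual_effect_scale = 0.08,
                           within_individual_cv = 0.025,
                           bout_effect_cv = 0.05,
                           f0_cf_base = 700, f0_max_base = 1000,
                           dur_base = 3.0, cf_fraction_base = 0.5,
                           n_harmonics = 6, amplitude_rolloff = 6,
                           subharmonic_propensity = 0.25,
                           subharmonic_level_db = 6,
                           signature_params = c("f0", "dur", "cf_fraction"),
                           seed = 1L) {
  spec <- list(n_clans = as.integer(n_clans),
               individuals_per_clan = as.integer(individuals_per_clan),
               clan_effect_scale = clan_effect_scale,
               individual_effect_scale = individual_effect_scale,
               within_individual_cv = within_individual_cv,
               bout_effect_cv = bout_effect_cv,
               f0_cf_base = f0_cf_base, f0_max_base = f0_max_base,
               dur_base = dur_base, cf_fraction_base = cf_fraction_base,
               n_harmonics = as.integer(n_harmonics),
               amplitude_rolloff = amplitude_rolloff,
               subharmonic_propensity = subharmonic_propensity,
               subharmonic_level_db = subharmonic_level_db,
               signature_params = signature_params,
               seed = as.integer(seed))
  class(spec) <- "PopulationSpec"
  validatePopulationSpec(spec)
  spec
}

validatePopulationSpec <- function(spec) {
  if (spec$n_clans < 1L || spec$individuals_per_clan < 1L)
    stop("PopulationSpec: need at least one clan and one individual per clan")
  scales <- c(spec$clan_effect_scale, spec$individual_effect_scale,
              spec$within_individual_cv, spec$bout_effect_cv)
  if (any(scales < 0))
    stop("PopulationSpec: effect scales and CVs must be >= 0")
  if (!(spec$f0_max_base > spec$f0_cf_base && spec$f0_cf_base > 0))
    stop("PopulationSpec: need f0_max_base > f0_cf_base > 0")
  if (!(spec$cf_fraction_base > 0 && spec$cf_fraction_base < 1))
    stop("PopulationSpec: cf_fraction_base must lie in (0, 1)")
  if (!(spec$subharmonic_propensity >= 0 && spec$subharmonic_propensity <= 1))
    stop("PopulationSpec: subharmonic_propensity must lie in [0, 1]")
  bad <- setdiff(spec$signature_params, c("f0", "dur", "cf_fraction"))
  if (length(bad))
    stop("PopulationSpec: unknown signature_params: ",
         paste(bad, collapse = ", "))
  invisible(TRUE)
}

#' Bout specification
#'
#' Bout length is drawn uniformly over \code{[length_min, length_max]}
#' (the naturally observed range is 2 to 34 whoops; only the range, not the
#' distribution, is documented for wild bouts, so uniform is used). The
#' type template produces an optional leading preliminary (P) whoop, a body
#' of asymmetric/symmetric (A/S) whoops, and an optional trailing terminal
#' (T) whoop; the type base rates are assumptions, not field estimates.
#'
#' @param length_min minimum bout length (whoops), >= 2.
#' @param length_max maximum bout length (whoops).
#' @param p_leading probability of a leading P whoop (bouts of length > 2).
#' @param p_terminal probability of a trailing T whoop (bouts of length > 2).
#' @param p_asymmetric probability that a body whoop is A (else S).
#' @param inter_whoop_interval nominal gap between whoops, s (metadata
#'   only; calls are rendered individually).
#' @return a \code{BoutSpec} (named list, classed).
#' @export
boutSpec <- function(length_min = 2, length_max = 34, p_leading = 0.5,
                     p_terminal = 0.5, p_asymmetric = 0.5,
                     inter_whoop_interval = 2) {
  spec <- list(length_min = as.integer(length_min),
               length_max = as.integer(length_max),
               p_leading = p_leading, p_terminal = p_terminal,
               p_asymmetric = p_asymmetric,
               inter_whoop_interval = inter_whoop_interval)
  class(spec) <- "BoutSpec"
  if (!(2L <= spec$length_min && spec$length_min <= spec$length_max))
    stop("BoutSpec: need 2 <= length_min <= length_max")
  probs <- c(p_leading, p_terminal, p_asymmetric)
  if (any(probs < 0 | probs > 1))
    stop("BoutSpec: type-template probabilities must lie in [0, 1]")
  spec
}

## Counter-based fan-out of one global seed into per-stage seeds, so each
## stage is independently reproducible. Kept below 2^31 - 1.
deriveSeed <- function(seed, index) {
  as.integer((as.double(seed) %% 2147483647 * 48271 +
                as.double(index) * 104729) %% 2147483647)
}
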