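## Shared synthetic worlds, built once per test run and cached.

.world_cache <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (!exists(key, envir = .world_cache)) {
    assign(key, builder(), envir = .world_cache)
  }
  get(key, envir = .world_cache)
}

## The main study world: 4 clans x 5 callers, 4 bouts x 6 whoops each,
## individual effect 0.08, no clan effect, SNR 15 dB.
studyWorld <- function() {
  cached("study", function() {
    spec <- populationSpec(n_clans = 4, individuals_per_clan = 5,
                           clan_effect_scale = 0,
                           individual_effect_scale = 0.08, seed = 101)
    ds <- synthesizeDataset(spec,
                            boutSpec(length_min = 6, length_max = 6),
                            bouts_per_individual = 4, snr_db = 15,
                            seed = 101)
    ft <- extractFeatureTable(ds$records, ds$metadata)
    list(features = ft, truth = ds$truth, spec = spec)
  })
}

## 200 noiseless whoops with ground truth (20 callers x 1 bout of 10).
noiselessBatch <- function() {
  cached("noiseless", function() {
    spec <- populationSpec(seed = 202)
    ds <- synthesizeDataset(spec,
                            boutSpec(length_min = 10, length_max = 10),
                            bouts_per_individual = 1, snr_db = Inf,
                            seed = 202)
    ft <- extractFeatureTable(ds$records, ds$metadata)
    merge(ft, ds$truth, by = "whoop_id", suffixes = c("", ".truth"))
  })
}

## A world where only fundamental-frequency parameters differ between
## individuals (duration and CF fraction carry no signature).
f0OnlyWorld <- function() {
  cached("f0only", function() {
    spec <- populationSpec(n_clans = 2, individuals_per_clan = 4,
                           clan_effect_scale = 0,
                           individual_effect_scale = 0.08,
                           signature_params = "f0", seed = 303)
    ds <- synthesizeDataset(spec,
                            boutSpec(length_min = 5, length_max = 5),
                            bouts_per_individual = 3, snr_db = 15,
                            seed = 303)
    extractFeatureTable(ds$records, ds$metadata)
  })
}

## Fast fully synthetic feature table (no audio): per-caller Gaussian
## feature shifts, optional bout-level shared shifts.
makeFakeTable <- function(n_clans = 2, callers_per_clan = 4, n_bouts = 3,
                          whoops_per_bout = 4, effect = 1,
                          bout_effect = 0.5, n_features = 5, seed = 1) {
  set.seed(seed)
  rows <- list()
  fn <- sprintf("f%d", seq_len(n_features))
  ind <- 0L
  for (cl in seq_len(n_clans)) for (i in seq_len(callers_per_clan)) {
    ind <- ind + 1L
    mu <- rnorm(n_features, sd = effect)
    for (b in seq_len(n_bouts)) {
      bmu <- mu + rnorm(n_features, sd = bout_effect)
      for (w in seq_len(whoops_per_bout)) {
        x <- bmu + rnorm(n_features)
        rows[[length(rows) + 1L]] <- data.frame(
          whoop_id = sprintf("c%02d_i%02d_b%02d_w%02d", cl, ind, b, w),
          bout_id = sprintf("i%02d_b%02d", ind, b),
          caller_id = sprintf("i%02d", ind),
          clan_id = sprintf("c%02d", cl),
          position_in_bout = w,
          whoop_type = sample(c("A", "S"), 1),
          age_months = 60, sex = "f", recording_method = "synthetic",
          failed = FALSE,
          as.data.frame(setNames(as.list(x), fn)),
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}

fakeFeatures <- function(n = 5) sprintf("f%d", seq_len(n))
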