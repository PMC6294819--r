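#' Analysis configuration
#'
#' All tunable thresholds of the signal pipeline, the correlation screen and
#' the prediction stage live in one configuration object. Every default is
#' overridable by name; unknown names are rejected so typos fail loudly.
#'
#' @param ... named overrides of the defaults listed below.
#'
#' @details
#' Signal analysis defaults: `f0_min = 60`, `f0_max = 400` (Hz, pitch search
#' band), `frame_hop = 0.010` and `frame_window = 0.040` (s, one frame grid for
#' all tracks), `voicing_threshold = 0.45` (periodicity strength above which a
#' frame counts as voiced), `octave_cost = 0.05` (per-octave penalty against
#' subharmonic period picks), `silence_floor_db = 25` (frames more than this many
#' dB below the utterance intensity peak are unvoiced/pause candidates),
#' `max_formant = 5500` and `n_formants = 5` (formant analysis resamples to
#' `2 * max_formant` first), `preemphasis = 0.97`, `min_pause = 0.25` (s),
#' `nucleus_dip_db = 2` (intensity dip required between syllable nuclei),
#' `min_cycles = 6` (voiced stretches shorter than this many glottal cycles are
#' skipped by cycle extraction; the five-point perturbation quotients need 5).
#'
#' Statistics defaults: `alpha = 0.05`, `covariates` = age, gender, LED,
#' UPDRS III, BDI and ACE-R, `spir_denominator = "TST"` (pauses per minute of
#' total speech time).
#'
#' Prediction defaults: `folds = 10`, `repetitions = 100`, boosted-tree
#' hyperparameters `n_trees = 200`, `max_depth = 3`, `learning_rate = 0.05`,
#' greedy selection `selection_tol = 0.1` (EER points), `selection_cap = 8`,
#' `selection_reps = 3`, `nested = FALSE`.
#'
#' @return A named list with class `hd_config`.
#' @examples
#' cfg <- hd_config(f0_min = 75, min_pause = 0.3)
#' cfg$f0_min
#' @export
hd_config <- function(...) {
  defaults <- list(
    # signal_core
    f0_min = 60, f0_max = 400,
    frame_hop = 0.010, frame_window = 0.040,
    voicing_threshold = 0.45,
    octave_cost = 0.05,
    silence_floor_db = 25,
    max_formant = 5500, n_formants = 5,
    preemphasis = 0.97,
    min_pause = 0.25,
    nucleus_dip_db = 2,
    min_cycles = 6,
    # corr_stats
    alpha = 0.05,
    covariates = c("age", "gender", "LED", "UPDRS_III", "BDI", "ACE_R"),
    spir_denominator = "TST",
    # fog_predict
    folds = 10, repetitions = 100,
    n_trees = 200, max_depth = 3, learning_rate = 0.05,
    strat_bins = 4,
    selection_tol = 0.1, selection_cap = 8, selection_reps = 3,
    nested = FALSE
  )
  over <- list(...)
  if (length(over)) {
    if (is.null(names(over)) || any(names(over) == ""))
      stop("all configuration overrides must be named", call. = FALSE)
    bad <- setdiff(names(over), names(defaults))
    if (length(bad))
      stop("unknown configuration option(s): ", paste(bad, collapse = ", "), call. = FALSE)
    defaults[names(over)] <- over
  }
  structure(defaults, class = "hd_config")
}

#' @export
print.hd_config <- function(x, ...) {
  cat("<hd_config>\n")
  for (nm in names(x)) {
    v <- x[[nm]]
    cat(sprintf("  %-18s %s\n", nm, paste(format(v), collapse = ", ")))
  }
  invisible(x)
}

# Stable short hash of a config (and anything else serializable) used to stamp
# provenance into output files without a digest dependency.
config_hash <- function(x) {
  raw <- serialize(x, NULL, version = 2)
  # FNV-1a over the serialized payload
  h <- 2166136261
  for (b in as.integer(raw)) {
    h <- bitwXor(as.integer(h %% 2^31), b)
    h <- (h * 16777619) %% 2^31
  }
  sprintf("%08x", as.integer(h))
}
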