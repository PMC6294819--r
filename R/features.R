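# The acoustic measure set: 16 measure names whose routing across vocal-task
# contexts yields the 19 quantified (measure, context) pairs -- phonation
# measures on sustained tasks, articulation measures on running speech and the
# diadochokinetic task, prosody measures on running speech.

#' Vocal task protocol metadata
#'
#' The 14-task recording protocol: sustained phonations (TSK2-4), the
#' diadochokinetic /pa/-/ta/-/ka/ task (TSK5), and read/spontaneous speech
#' (TSK1, TSK6-14). Scripted tasks carry a default phone count used by the
#' speech-rate measures; the counts are configurable because reading texts
#' differ between sites (defaults assume Czech-like phone/word ratios of the
#' protocol's text lengths). The monologue (TSK1) has no script, so any
#' speech-rate computation on it requires a user-supplied count.
#'
#' @return A data.frame with columns `code`, `description`, `phone_count`.
#' @export
hd_tasks <- function() {
  data.frame(
    code = paste0("TSK", 1:14),
    description = c(
      "Monologue (spontaneous speech)",
      "Sustained /m/, closed lips, one breath",
      "Sustained /i/, open lips, one breath",
      "Sustained /a/ at comfortable pitch and loudness",
      "Rapid steady /pa/-/ta/-/ka/ repetition, one breath",
      "Rhythmical reading: 4 rhymes of 16 words",
      "Three-word sentence, interrogative",
      "Three-word sentence, imperative",
      "Three-word sentence, declarative",
      "Reading paragraph, 135 words",
      "Eight-word sentence, neutral",
      "Six-word sentence, angry",
      "Nine-word sentence, bored",
      "Five-word sentence, excited"),
    phone_count = c(NA, NA, NA, NA, NA, 280, 12, 12, 12, 560,
                    32, 26, 38, 22),
    stringsAsFactors = FALSE)
}

# (measure, task) routing of the feature set
measure_routing <- function() {
  running <- paste0("TSK", c(1, 6:14))
  rated <- paste0("TSK", 7:14)
  list(
    MPT       = c("TSK2", "TSK3"),
    relF0SD   = c("TSK4", running),
    jitter    = "TSK4",
    shimmer   = "TSK4",
    meanHNR   = "TSK4",
    DUV       = "TSK4",
    F1SD      = c("TSK4", running),
    F2SD      = c("TSK4", running),
    F1IR      = running,
    F2IR      = running,
    DDKrate   = "TSK5",
    DDKreg    = "TSK5",
    relSEOSD  = running,
    SPIR      = "TSK10",
    TSR       = rated,
    NSR       = rated)
}

measure_units <- c(
  MPT = "s", relF0SD = "", jitter = "%", shimmer = "%", meanHNR = "dB",
  DUV = "fraction", F1SD = "Hz", F2SD = "Hz", F1IR = "Hz", F2IR = "Hz",
  DDKrate = "syll/s", DDKreg = "s", relSEOSD = "", SPIR = "1/min",
  TSR = "phones/s", NSR = "phones/s")

# HD dimension membership of (measure, task) column names
#' Candidate feature columns of an HD dimension
#'
#' @param dimension one of `"articulation"`, `"phonation"`, `"prosody"`,
#'   `"combination"` (the union of all three).
#' @return Character vector of `measure_task` column names.
#' @export
dimension_features <- function(dimension = c("combination", "articulation",
                                             "phonation", "prosody")) {
  dimension <- match.arg(dimension)
  running <- paste0("TSK", c(1, 6:14))
  rated <- paste0("TSK", 7:14)
  phon <- c(paste0("MPT_", c("TSK2", "TSK3")),
            paste0(c("relF0SD", "jitter", "shimmer", "F1SD", "F2SD",
                     "meanHNR", "DUV"), "_TSK4"))
  artic <- c(as.vector(outer(c("F1IR", "F2IR", "F1SD", "F2SD"), running,
                             paste, sep = "_")),
             "DDKrate_TSK5", "DDKreg_TSK5")
  pros <- c(paste0("relSEOSD_", running), paste0("relF0SD_", running),
            "SPIR_TSK10",
            as.vector(outer(c("TSR", "NSR"), rated, paste, sep = "_")))
  switch(dimension,
         articulation = artic, phonation = phon, prosody = pros,
         combination = unique(c(artic, phon, pros)))
}

#' Maximum phonation time
#'
#' Duration of the longest continuously voiced stretch, for the sustained
#' expiration tasks (TSK2, TSK3).
#'
#' @param signal an [audio_signal].
#' @param config an [hd_config].
#' @param contour optional precomputed [estimate_f0] result.
#' @return Seconds.
#' @export
mpt <- function(signal, config = hd_config(), contour = NULL) {
  if (is.null(contour)) contour <- estimate_f0(signal, config = config)
  if (!any(contour$voiced)) stop("no voiced frames", call. = FALSE)
  runs <- voiced_runs(contour$voiced)
  hop <- if (length(contour$times) > 1) diff(contour$times[1:2]) else config$frame_hop
  max(contour$times[runs[, "end"]] - contour$times[runs[, "start"]] + hop)
}

#' Relative standard deviation of F0 (relF0SD)
#'
#' Coefficient of variation of the F0 contour over voiced frames: monopitch
#' on running speech, pitch instability on sustained phonation. Sample SD
#' convention (divide by n - 1).
#'
#' @param contour an [estimate_f0] result.
#' @return Dimensionless ratio.
#' @export
rel_f0_sd <- function(contour) {
  f0 <- contour$f0[contour$voiced]
  if (length(f0) < 2) stop("need at least 2 voiced frames", call. = FALSE)
  sd_desc(f0) / mean(f0)
}

#' Jitter as the five-point period perturbation quotient (PPQ5)
#'
#' `100 * mean_i |T_i - mean(T_{i-2}..T_{i+2})| / mean(T)` with `i` over
#' interior cycles. Scale-free; in percent.
#'
#' @param periods cycle lengths in seconds (or the data.frame from
#'   [extract_periods], whose `length` column is used).
#' @return Percent.
#' @export
jitter_ppq5 <- function(periods) {
  if (is.data.frame(periods)) periods <- periods$length
  ppq5(periods)
}

#' Shimmer as the five-point amplitude perturbation quotient (APQ5)
#'
#' The PPQ5 formula applied to per-cycle peak amplitudes.
#'
#' @param amplitudes cycle peak amplitudes (or the data.frame from
#'   [extract_periods], whose `amplitude` column is used).
#' @return Percent.
#' @export
shimmer_apq5 <- function(amplitudes) {
  if (is.data.frame(amplitudes)) amplitudes <- amplitudes$amplitude
  ppq5(amplitudes)
}

ppq5 <- function(v) {
  v <- as.numeric(v)
  n <- length(v)
  if (n < 5) stop("need at least 5 cycles", call. = FALSE)
  i <- 3:(n - 2)
  win_mean <- (v[i - 2] + v[i - 1] + v[i] + v[i + 1] + v[i + 2]) / 5
  100 * mean(abs(v[i] - win_mean)) / mean(v)
}

#' Mean harmonics-to-noise ratio
#'
#' Per voiced frame, `10 log10(r / (1 - r))` where `r` is the normalised
#' autocorrelation at the pitch period (the harmonic energy fraction);
#' averaged over voiced frames.
#'
#' @param signal an [audio_signal] (accepted for interface symmetry; the
#'   periodicity strengths already live in the contour).
#' @param contour an [estimate_f0] result.
#' @return dB.
#' @export
mean_hnr <- function(signal, contour) {
  r <- contour$strength[contour$voiced]
  if (!length(r)) stop("no voiced frames", call. = FALSE)
  r <- pmin(pmax(r, 1e-6), 1 - 1e-6)
  mean(10 * log10(r / (1 - r)))
}

#' Degree of unvoiced segments
#'
#' Fraction of pitch frames marked unvoiced, within the trimmed utterance
#' (leading/trailing silence excluded when a trim window is supplied, so that
#' recording habits are not read as aperiodicity).
#'
#' @param contour an [estimate_f0] result.
#' @param trim optional `c(start, end)` in seconds (e.g. the `trim` element
#'   of [detect_pauses]); frames outside it are ignored.
#' @return Fraction in `[0, 1]`.
#' @export
duv <- function(contour, trim = NULL) {
  keep <- rep(TRUE, length(contour$times))
  if (!is.null(trim))
    keep <- contour$times >= trim[1] & contour$times <= trim[2]
  if (!any(keep)) stop("no frames inside the trim window", call. = FALSE)
  sum(!contour$voiced[keep]) / sum(keep)
}

#' Formant dispersion statistics (SD and 1st-99th interpercentile range)
#'
#' @param track an [estimate_formants] result.
#' @param which `"F1"` or `"F2"`.
#' @param stat `"SD"` (sample standard deviation) or `"IR"`
#'   (99th minus 1st percentile, linear interpolation between order
#'   statistics). Fewer than 100 defined frames triggers a warning for IR.
#' @return Hz.
#' @export
formant_stats <- function(track, which = c("F1", "F2"), stat = c("SD", "IR")) {
  which <- match.arg(which); stat <- match.arg(stat)
  v <- if (which == "F1") track$f1 else track$f2
  v <- v[is.finite(v)]
  if (!length(v)) stop("no defined formant frames", call. = FALSE)
  if (stat == "SD") {
    if (length(v) < 2) stop("need at least 2 defined frames for SD", call. = FALSE)
    sd_desc(v)
  } else {
    if (length(v) < 100)
      warning("fewer than 100 formant frames; interpercentile range is unstable")
    q <- quantile(v, c(0.01, 0.99), names = FALSE, type = 7)
    q[2] - q[1]
  }
}

#' Diadochokinetic rate
#'
#' Syllable vocalizations per second: nucleus count over the trimmed
#' utterance duration.
#'
#' @param nuclei a [detect_syllable_nuclei] result.
#' @return Syllables per second (0 when no nuclei were found).
#' @export
ddk_rate <- function(nuclei) {
  if (nuclei$duration <= 0) stop("nonpositive utterance duration", call. = FALSE)
  length(nuclei$nuclei) / nuclei$duration
}

#' Diadochokinetic regularity
#'
#' Sample standard deviation of successive inter-nucleus intervals;
#' 0 for an isochronous train.
#'
#' @param nuclei a [detect_syllable_nuclei] result.
#' @return Seconds.
#' @export
ddk_reg <- function(nuclei) {
  if (length(nuclei$nuclei) < 3) stop("need at least 3 nuclei", call. = FALSE)
  sd_desc(diff(nuclei$nuclei))
}

#' Relative standard deviation of the intensity contour (relSEOSD)
#'
#' Coefficient of variation of frame intensity (RMS amplitude) over speech
#' (non-pause) frames: the monoloudness measure. Only frames whose analysis
#' window lies fully inside a speech segment enter (frames straddling a pause
#' boundary measure the boundary, not loudness variation).
#'
#' @param contour an [energy_contour].
#' @param segments a [detect_pauses] result restricting the frames to speech
#'   segments; `NULL` uses all frames.
#' @return Dimensionless ratio.
#' @export
rel_seo_sd <- function(contour, segments = NULL) {
  intensity <- sqrt(contour$energy)
  keep <- rep(TRUE, length(intensity))
  if (!is.null(segments)) {
    t_rel <- contour$times - segments$trim["start"]
    half <- (contour$window %||% 0.04) / 2
    sp <- segments$segments[segments$segments$label == "speech", , drop = FALSE]
    keep <- vapply(t_rel, function(t)
      any(t - half >= sp$start & t + half <= sp$end), logical(1))
  }
  v <- intensity[keep]
  if (length(v) < 2) stop("need at least 2 speech frames", call. = FALSE)
  m <- mean(v)
  if (m <= 0) stop("degenerate zero-mean intensity", call. = FALSE)
  sd_desc(v) / m
}

#' Speech inter-pauses per minute (SPIR)
#'
#' @param segments a [detect_pauses] result.
#' @param config an [hd_config]; `spir_denominator` selects total (`"TST"`,
#'   default) or net (`"NST"`) speech time as the time base.
#' @return Pauses per minute.
#' @export
spir <- function(segments, config = hd_config()) {
  denom <- if (identical(config$spir_denominator, "NST"))
    segments$net_time else segments$total_time
  if (denom <= 0) stop("nonpositive speech time", call. = FALSE)
  sum(segments$segments$label == "pause") / (denom / 60)
}

#' Total and net speech rate
#'
#' TSR = phones per second of total speech time; NSR = phones per second of
#' net (pause-free) speech time. `NSR >= TSR` always.
#'
#' @param segments a [detect_pauses] result.
#' @param phone_count number of phones in the scripted text (> 0). For
#'   unscripted speech a transcript-derived count must be supplied.
#' @return Named numeric vector `c(TSR = , NSR = )` in phones/s.
#' @export
speech_rates <- function(segments, phone_count) {
  if (is.null(phone_count) || is.na(phone_count))
    stop("phone_count missing: supply the transcript phone count for this task",
         call. = FALSE)
  if (phone_count <= 0) stop("phone_count must be positive", call. = FALSE)
  if (segments$net_time <= 0) stop("nonpositive net speech time", call. = FALSE)
  c(TSR = phone_count / segments$total_time,
    NSR = phone_count / segments$net_time)
}

#' Extract all measures defined for one vocal task
#'
#' Routes the recording to exactly the measures defined for its task code:
#' the phonation set for TSK2-TSK4, articulation formant statistics and
#' prosody measures for running speech (TSK1, TSK6-14), the diadochokinetic
#' pair for TSK5, pause rate for the reading paragraph (TSK10) and speech
#' rates for the scripted tasks TSK7-14. Individual measure failures (for
#' example no voiced frames) are recorded as `NA` with a warning rather than
#' aborting the batch.
#'
#' @param signal an [audio_signal].
#' @param task a task code `"TSK1"`..`"TSK14"`.
#' @param config an [hd_config].
#' @param phone_count overrides the task's default phone count (needed for
#'   speech rates on unscripted tasks).
#' @return A data.frame with columns `measure`, `task`, `value`, `units`.
#' @export
extract_all <- function(signal, task, config = hd_config(), phone_count = NULL) {
  tasks <- hd_tasks()
  if (!task %in% tasks$code) stop("unknown task code: ", task, call. = FALSE)
  routing <- measure_routing()
  measures <- names(routing)[vapply(routing, function(tt) task %in% tt, logical(1))]
  if (is.null(phone_count)) phone_count <- tasks$phone_count[tasks$code == task]

  contour <- tryCatch(estimate_f0(signal, config = config), error = function(e) NULL)
  need_formants <- any(c("F1SD", "F2SD", "F1IR", "F2IR") %in% measures)
  need_segments <- any(c("relSEOSD", "SPIR", "TSR", "NSR") %in% measures) ||
    "DUV" %in% measures
  track <- if (need_formants && !is.null(contour))
    tryCatch(estimate_formants(signal, config = config, contour = contour),
             error = function(e) NULL)
  segments <- if (need_segments)
    tryCatch(detect_pauses(signal, config = config), error = function(e) NULL)
  ec <- if ("relSEOSD" %in% measures)
    tryCatch(energy_contour(signal, config), error = function(e) NULL)
  nuclei <- if (any(c("DDKrate", "DDKreg") %in% measures))
    tryCatch(detect_syllable_nuclei(signal, config, contour = contour),
             error = function(e) NULL)

  one <- function(m) {
    tryCatch(switch(m,
      MPT = mpt(signal, config, contour = contour),
      relF0SD = rel_f0_sd(contour),
      jitter = jitter_ppq5(extract_periods(signal, contour, config)),
      shimmer = shimmer_apq5(extract_periods(signal, contour, config)),
      meanHNR = mean_hnr(signal, contour),
      DUV = duv(contour, trim = if (!is.null(segments)) segments$trim),
      F1SD = formant_stats(track, "F1", "SD"),
      F2SD = formant_stats(track, "F2", "SD"),
      F1IR = suppressWarnings(formant_stats(track, "F1", "IR")),
      F2IR = suppressWarnings(formant_stats(track, "F2", "IR")),
      DDKrate = ddk_rate(nuclei),
      DDKreg = ddk_reg(nuclei),
      relSEOSD = rel_seo_sd(ec, segments),
      SPIR = spir(segments, config),
      TSR = speech_rates(segments, phone_count)[["TSR"]],
      NSR = speech_rates(segments, phone_count)[["NSR"]]),
      error = function(e) {
        warning(sprintf("%s (%s): %s", m, task, conditionMessage(e)),
                call. = FALSE)
        NA_real_
      })
  }
  vals <- vapply(measures, one, 0)
  data.frame(measure = measures, task = task, value = unname(vals),
             units = unname(measure_units[measures]),
             stringsAsFactors = FALSE)
}

#' Batch feature extraction from a recording manifest
#'
#' @param manifest data.frame (or path to a tab-delimited file) with columns
#'   `subject_id`, `session`, `task`, `path` and optionally `phone_count`.
#' @param config an [hd_config].
#' @return A wide `feature_table` data.frame: one row per subject x session,
#'   one column per `measure_task` pair present.
#' @export
extract_features <- function(manifest, config = hd_config()) {
  if (is.character(manifest)) manifest <- read.delim(manifest, stringsAsFactors = FALSE)
  need <- c("subject_id", "session", "task", "path")
  if (!all(need %in% names(manifest)))
    stop("manifest needs columns: ", paste(need, collapse = ", "), call. = FALSE)
  rows <- vector("list", nrow(manifest))
  for (i in seq_len(nrow(manifest))) {
    sig <- read_wav(manifest$path[i])
    pc <- if ("phone_count" %in% names(manifest)) manifest$phone_count[i]
    fv <- extract_all(sig, manifest$task[i], config, phone_count = pc)
    fv$subject_id <- manifest$subject_id[i]
    fv$session <- manifest$session[i]
    rows[[i]] <- fv
  }
  long <- do.call(rbind, rows)
  feature_table(long)
}

#' Assemble a wide feature table from long (measure, task, value) rows
#'
#' @param long data.frame with columns `subject_id`, `session`, `measure`,
#'   `task`, `value`.
#' @return A `feature_table` data.frame (wide).
#' @export
feature_table <- function(long) {
  long$column <- paste(long$measure, long$task, sep = "_")
  ids <- unique(long[c("subject_id", "session")])
  wide <- ids
  for (cl in unique(long$column)) {
    sub <- long[long$column == cl, c("subject_id", "session", "value")]
    names(sub)[3] <- cl
    wide <- merge(wide, sub, by = c("subject_id", "session"),
                  all.x = TRUE, sort = FALSE)
  }
  wide <- wide[order(wide$subject_id, wide$session), , drop = FALSE]
  rownames(wide) <- NULL
  class(wide) <- c("feature_table", "data.frame")
  wide
}

#' Write a feature table as long delimited text
#'
#' Columns: `subject_id`, `session`, `task`, `measure`, `value`, `units`.
#'
#' @param features a `feature_table` (wide).
#' @param path output path (tab-delimited).
#' @param provenance optional character lines written as `#`-prefixed header.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(features, path, provenance = NULL) {
  meta <- c("subject_id", "session")
  fcols <- setdiff(names(features), meta)
  ms <- sub("_TSK.*$", "", fcols)
  tk <- sub("^.*_(TSK[0-9]+)$", "\\1", fcols)
  rows <- do.call(rbind, lapply(seq_along(fcols), function(j) {
    data.frame(subject_id = features$subject_id, session = features$session,
               task = tk[j], measure = ms[j], value = features[[fcols[j]]],
               units = unname(measure_units[ms[j]]), stringsAsFactors = FALSE)
  }))
  rows <- rows[order(rows$subject_id, rows$session, rows$task, rows$measure), ]
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(provenance)) writeLines(paste0("# ", provenance), con)
  write.table(rows, con, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
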