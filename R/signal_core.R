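# Frame-wise speech analysis primitives. All tracks share one frame grid:
# Hann-windowed frames of length `frame_window` advancing by `frame_hop`,
# indexed by their centre times.

frame_centres <- function(n_samples, rate, config) {
  win <- round(config$frame_window * rate)
  hop <- round(config$frame_hop * rate)
  if (n_samples < win) return(numeric(0))
  starts <- seq(1L, n_samples - win + 1L, by = hop)
  (starts - 1 + win / 2) / rate
}

# Autocorrelation of one frame: local mean subtracted, then tapered; the
# result is normalised to lag-0 = 1 and divided by the window's own
# autocorrelation so a perfectly periodic signal scores ~1 at its period lag
# regardless of the taper.
frame_nacf <- function(x, w, w_nacf, nfft) {
  x <- (x - mean(x)) * w
  X <- fft(c(x, rep(0, nfft - length(x))))
  ac <- Re(fft(Mod(X)^2, inverse = TRUE))
  if (ac[1] <= 0) return(NULL)
  r <- ac[seq_along(w_nacf)] / ac[1]
  r / w_nacf
}

#' Estimate the fundamental frequency contour
#'
#' Autocorrelation-based pitch tracking on Hann-windowed frames. Within each
#' frame the normalised autocorrelation (tapers divided out) is searched over
#' the lag band implied by `[f0_min, f0_max]`; candidate peaks are scored with
#' a small per-octave penalty against subharmonic (period-doubling) picks and
#' refined by parabolic interpolation. A second pass re-searches frames that
#' landed an octave away from the utterance median inside a band around it,
#' correcting isolated subharmonic/harmonic picks. A frame is voiced when the
#' winning periodicity strength exceeds `config$voicing_threshold` and the
#' frame is not silent. Unvoiced frames carry `NA` F0, never 0 Hz.
#'
#' @param signal an [audio_signal].
#' @param f0_min,f0_max pitch search band in Hz; `f0_max` must be below the
#'   Nyquist frequency.
#' @param config an [hd_config].
#' @return An `f0_contour`: list with `times` (s), `f0` (Hz, `NA` when
#'   unvoiced), `voiced` (logical) and `strength` (periodicity r at the chosen
#'   lag, used by the harmonics-to-noise ratio).
#' @examples
#' s <- audio_signal(0.5 * sin(2 * pi * 120 * seq(0, 2, by = 1/16000)), 16000)
#' ctr <- estimate_f0(s)
#' mean(ctr$f0[ctr$voiced])
#' @export
estimate_f0 <- function(signal, f0_min = NULL, f0_max = NULL,
                        config = hd_config()) {
  stopifnot(inherits(signal, "audio_signal"))
  f0_min <- f0_min %||% config$f0_min
  f0_max <- f0_max %||% config$f0_max
  if (f0_min >= f0_max) stop("f0_min must be below f0_max", call. = FALSE)
  if (f0_max >= signal$rate / 2)
    stop("f0_max must be below the Nyquist frequency", call. = FALSE)
  rate <- signal$rate
  win <- round(config$frame_window * rate)
  hop <- round(config$frame_hop * rate)
  if (length(signal$samples) < win)
    stop("signal too short for one analysis frame", call. = FALSE)
  if (win < 2 * rate / f0_min)
    win <- round(2 * rate / f0_min)        # window must hold >= 2 periods
  if (length(signal$samples) < win)
    stop("signal too short for the requested f0_min", call. = FALSE)

  lag_min <- max(2L, floor(rate / f0_max))
  lag_max <- min(win - 2L, ceiling(rate / f0_min))
  nfft <- 2^ceiling(log2(2 * win))
  w <- 0.5 - 0.5 * cos(2 * pi * (seq_len(win) - 1) / (win - 1))
  Wf <- fft(c(w, rep(0, nfft - win)))
  acw <- Re(fft(Mod(Wf)^2, inverse = TRUE))
  w_nacf <- acw[seq_len(lag_max + 2L)] / acw[1]

  starts <- seq(1L, length(signal$samples) - win + 1L, by = hop)
  times <- (starts - 1 + win / 2) / rate
  nfr <- length(starts)
  f0 <- rep(NA_real_, nfr); strength <- rep(NA_real_, nfr)
  rms <- vapply(starts, function(s0)
    sqrt(mean(signal$samples[s0:(s0 + win - 1L)]^2)), 0)
  peak_rms <- max(rms)

  for (k in seq_len(nfr)) {
    if (rms[k] < 1e-6 || (peak_rms > 0 && rms[k] < peak_rms * 1e-4)) next
    fr <- signal$samples[starts[k]:(starts[k] + win - 1L)]
    r <- frame_nacf(fr, w, w_nacf, nfft)
    if (is.null(r)) next
    lag_band <- (lag_min + 1L):(lag_max + 1L)   # r is 1-indexed at lag 0
    rb <- r[lag_band]
    # local maxima within the band
    d <- diff(rb)
    pk <- which(d[-length(d)] > 0 & d[-1] <= 0) + 1L
    if (!length(pk)) next
    lags <- lag_band[pk] - 1L
    score <- rb[pk] - config$octave_cost * log2(lags / lag_min)
    best <- pk[which.max(score)]
    lag0 <- lag_band[best] - 1L
    # parabolic refinement of both lag and strength
    ym <- r[lag0]; y0 <- r[lag0 + 1L]; yp <- r[lag0 + 2L]
    denom <- ym - 2 * y0 + yp
    delta <- if (abs(denom) > 1e-12) 0.5 * (ym - yp) / denom else 0
    delta <- max(-0.5, min(0.5, delta))
    lag_hat <- lag0 + delta
    r_hat <- y0 - 0.25 * (ym - yp) * delta
    if (r_hat > config$voicing_threshold) {
      cand <- rate / lag_hat
      if (cand >= f0_min && cand <= f0_max) {
        f0[k] <- cand
        strength[k] <- min(r_hat, 1 - 1e-6)
      }
    }
  }
  # second pass: frames that landed an octave off the utterance's median get
  # re-searched in a band around it (single-frame subharmonic/harmonic picks)
  if (sum(!is.na(f0)) >= 5) {
    med <- median(f0, na.rm = TRUE)
    redo <- which(!is.na(f0) & (f0 < 0.7 * med | f0 > 1.4 * med))
    if (length(redo)) {
      lag_lo <- max(lag_min, floor(rate / (1.4 * med)))
      lag_hi <- min(lag_max, ceiling(rate / (0.7 * med)))
      for (k in redo) {
        fr <- signal$samples[starts[k]:(starts[k] + win - 1L)]
        r <- frame_nacf(fr, w, w_nacf, nfft)
        if (is.null(r) || lag_hi - lag_lo < 3) next
        band <- (lag_lo + 1L):(lag_hi + 1L)
        rb <- r[band]
        d <- diff(rb)
        pk <- which(d[-length(d)] > 0 & d[-1] <= 0) + 1L
        if (!length(pk)) next
        best <- pk[which.max(rb[pk])]
        lag0 <- band[best] - 1L
        ym <- r[lag0]; y0 <- r[lag0 + 1L]; yp <- r[lag0 + 2L]
        denom <- ym - 2 * y0 + yp
        delta <- if (abs(denom) > 1e-12) max(-0.5, min(0.5, 0.5 * (ym - yp) / denom)) else 0
        r_hat <- y0 - 0.25 * (ym - yp) * delta
        if (r_hat > config$voicing_threshold) {
          cand <- rate / (lag0 + delta)
          if (cand >= f0_min && cand <= f0_max) {
            f0[k] <- cand
            strength[k] <- min(r_hat, 1 - 1e-6)
          }
        }
      }
    }
  }
  structure(list(times = times, f0 = f0, voiced = !is.na(f0),
                 strength = strength, rate = rate,
                 f0_min = f0_min, f0_max = f0_max),
            class = "f0_contour")
}

#' @export
print.f0_contour <- function(x, ...) {
  nv <- sum(x$voiced)
  cat(sprintf("<f0_contour> %d frames, %d voiced (%.1f%%)", length(x$times),
              nv, 100 * nv / max(1, length(x$times))))
  if (nv) cat(sprintf(", mean F0 %.1f Hz", mean(x$f0[x$voiced])))
  cat("\n")
  invisible(x)
}

voiced_runs <- function(voiced) {
  r <- rle(voiced)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  cbind(start = starts[r$values], end = ends[r$values])
}

#' Extract glottal cycles (periods and peak amplitudes)
#'
#' Cycle timing is taken from the fundamental band: within each voiced
#' stretch the signal is zero-phase bandpass filtered to
#' `[0.5, 1.5] x` the stretch's mean F0, which leaves exactly one
#' unambiguous positive peak per glottal cycle; peak times are refined by
#' parabolic interpolation. Cycle lengths are differences of consecutive
#' peak times; the cycle peak amplitude is the maximum absolute excursion of
#' the raw waveform within the cycle. Cycles are never formed across a
#' voicing gap, and stretches shorter than `config$min_cycles` cycles are
#' skipped (the five-point perturbation quotients need five).
#'
#' @param signal an [audio_signal].
#' @param contour the matching [estimate_f0] result.
#' @param config an [hd_config].
#' @return A data.frame with columns `length` (s) and `amplitude`.
#' @export
extract_periods <- function(signal, contour, config = hd_config()) {
  stopifnot(inherits(signal, "audio_signal"), inherits(contour, "f0_contour"))
  if (!any(contour$voiced)) stop("no voiced frames", call. = FALSE)
  x <- signal$samples; rate <- signal$rate
  runs <- voiced_runs(contour$voiced)
  hop <- if (length(contour$times) > 1) diff(contour$times[1:2]) else config$frame_hop
  out_len <- numeric(0); out_amp <- numeric(0)

  for (ri in seq_len(nrow(runs))) {
    fr <- runs[ri, 1]:runs[ri, 2]
    if (length(fr) < 2) next
    t0 <- max(0, contour$times[fr[1]] - hop / 2)
    t1 <- min(signal$duration, contour$times[fr[length(fr)]] + hop / 2)
    f0m <- mean(contour$f0[fr])
    T0 <- 1 / f0m
    i0 <- max(1L, floor(t0 * rate) + 1L)
    i1 <- min(length(x), ceiling(t1 * rate))
    if ((i1 - i0) / rate < (config$min_cycles + 2) * T0) next
    # pad one window on each side so the zero-phase filter transient stays
    # outside the stretch
    pad <- min(i0 - 1L, length(x) - i1, round(0.05 * rate))
    seg <- x[(i0 - pad):(i1 + pad)]
    hi <- min(1.5 * f0m, 0.45 * rate)          # keep below Nyquist
    bf <- signal::butter(2, c(0.5 * f0m, hi) / (rate / 2), "pass")
    xf <- signal::filtfilt(bf, seg)
    xf <- xf[(pad + 1L):(length(xf) - pad)]
    n <- length(xf)
    thr <- 0.2 * max(xf)
    if (thr <= 0) next
    pk <- which(xf[2:(n - 1)] > xf[1:(n - 2)] & xf[2:(n - 1)] >= xf[3:n] &
                  xf[2:(n - 1)] > thr) + 1L
    # enforce a minimum separation of half a period (keep the larger peak)
    if (length(pk) > 1) {
      keep <- pk[1]
      for (p in pk[-1]) {
        if ((p - keep[length(keep)]) / rate < 0.5 * T0) {
          if (xf[p] > xf[keep[length(keep)]]) keep[length(keep)] <- p
        } else keep <- c(keep, p)
      }
      pk <- keep
    }
    if (length(pk) < config$min_cycles + 1L) next
    tt <- vapply(pk, function(p) refine_peak(xf, p, rate)[1, 1], 0)
    lens <- diff(tt)
    idx0 <- i0 - 1L
    amps <- vapply(seq_len(length(tt) - 1L), function(i) {
      a <- idx0 + floor(tt[i] * rate) + 1L
      b <- min(length(x), idx0 + ceiling(tt[i + 1L] * rate))
      max(abs(x[a:b]))
    }, 0)
    out_len <- c(out_len, lens); out_amp <- c(out_amp, amps)
  }
  if (!length(out_len))
    stop("no voiced stretch long enough for cycle extraction", call. = FALSE)
  data.frame(length = out_len, amplitude = out_amp)
}

# parabolic refinement of a sample-domain peak -> c(time, value)
refine_peak <- function(x, i, rate) {
  if (i <= 1L || i >= length(x)) return(cbind((i - 1) / rate, x[i]))
  ym <- x[i - 1L]; y0 <- x[i]; yp <- x[i + 1L]
  den <- ym - 2 * y0 + yp
  d <- if (abs(den) > 1e-15) max(-0.5, min(0.5, 0.5 * (ym - yp) / den)) else 0
  cbind((i - 1 + d) / rate, y0 - 0.25 * (ym - yp) * d)
}

#' Estimate formant tracks (F1, F2)
#'
#' All-pole (Burg) spectral fit per voiced frame after resampling to
#' `2 * max_formant` and pre-emphasis. Model order is `2 * n_formants`
#' (one pole pair per expected resonance; surplus pairs chase inter-formant
#' harmonic structure);
#' pole angles inside the band with bandwidth under 700 Hz become formant
#' candidates, and the lowest two are reported as F1 and F2.
#'
#' @param signal an [audio_signal].
#' @param n_formants number of formants the all-pole model allows for.
#' @param max_formant analysis ceiling in Hz; must be below the Nyquist
#'   frequency of the recording.
#' @param config an [hd_config].
#' @param contour optional precomputed [estimate_f0] result (reused for the
#'   voicing decision and frame grid).
#' @return A `formant_track`: list with `times`, `f1`, `f2` (Hz, `NA` on
#'   unvoiced frames) and `voiced`.
#' @export
estimate_formants <- function(signal, n_formants = NULL, max_formant = NULL,
                              config = hd_config(), contour = NULL) {
  stopifnot(inherits(signal, "audio_signal"))
  n_formants <- n_formants %||% config$n_formants
  max_formant <- max_formant %||% config$max_formant
  if (max_formant >= signal$rate / 2)
    stop("max_formant must be below the Nyquist frequency", call. = FALSE)
  if (n_formants < 2) stop("need n_formants >= 2", call. = FALSE)
  if (is.null(contour)) contour <- estimate_f0(signal, config = config)

  fs2 <- 2 * max_formant
  rs <- resample_signal(signal, fs2)
  y <- rs$samples - config$preemphasis * c(0, rs$samples[-length(rs$samples)])
  win <- round(0.025 * fs2)
  order <- 2L * n_formants
  hw <- 0.54 - 0.46 * cos(2 * pi * (seq_len(win) - 1) / (win - 1))

  nfr <- length(contour$times)
  f1 <- rep(NA_real_, nfr); f2 <- rep(NA_real_, nfr)
  for (k in which(contour$voiced)) {
    c0 <- round(contour$times[k] * fs2)
    a <- c0 - win %/% 2L; b <- a + win - 1L
    if (a < 1L || b > length(y)) next
    fr <- (y[a:b] - mean(y[a:b])) * hw
    if (sum(fr^2) < 1e-12) next
    ar <- tryCatch(stats::ar.burg(fr, aic = FALSE, order.max = order,
                                  demean = FALSE)$ar,
                   error = function(e) NULL)
    if (is.null(ar) || !length(ar)) next
    rts <- polyroot(c(1, -ar))
    rts <- rts[Im(rts) > 1e-9]
    fr_hz <- Arg(rts) * fs2 / (2 * pi)
    bw <- -log(pmin(Mod(rts), 1 - 1e-12)) * fs2 / pi
    keep <- fr_hz > 90 & fr_hz < max_formant - 50 & bw < 700
    cand <- sort(fr_hz[keep])
    if (length(cand) >= 1) f1[k] <- cand[1]
    if (length(cand) >= 2) f2[k] <- cand[2]
  }
  structure(list(times = contour$times, f1 = f1, f2 = f2,
                 voiced = contour$voiced),
            class = "formant_track")
}

#' @export
print.formant_track <- function(x, ...) {
  ok <- is.finite(x$f1)
  cat(sprintf("<formant_track> %d frames, %d with formants", length(x$times), sum(ok)))
  if (any(ok)) cat(sprintf("; median F1 %.0f Hz, F2 %.0f Hz",
                           median(x$f1[ok]), median(x$f2[is.finite(x$f2)])))
  cat("\n")
  invisible(x)
}

#' Short-time energy contour
#'
#' Frame-wise Hann-weighted mean squared amplitude on the shared frame grid
#' (the taper suppresses sensitivity to how glottal pulses align with frame
#' boundaries), with a dB view (`10 log10`) used by the pause and
#' syllable-nucleus detectors.
#'
#' @param signal an [audio_signal].
#' @param config an [hd_config].
#' @return An `energy_contour`: list with `times`, `energy` (linear, >= 0)
#'   and `db`.
#' @export
energy_contour <- function(signal, config = hd_config()) {
  stopifnot(inherits(signal, "audio_signal"))
  rate <- signal$rate
  win <- round(config$frame_window * rate)
  hop <- round(config$frame_hop * rate)
  if (length(signal$samples) < win)
    stop("signal too short for one analysis frame", call. = FALSE)
  starts <- seq(1L, length(signal$samples) - win + 1L, by = hop)
  w <- 0.5 - 0.5 * cos(2 * pi * (seq_len(win) - 1) / (win - 1))
  w <- w / sum(w)
  en <- vapply(starts, function(s0)
    sum(w * signal$samples[s0:(s0 + win - 1L)]^2), 0)
  structure(list(times = (starts - 1 + win / 2) / rate,
                 energy = en,
                 db = 10 * log10(pmax(en, 1e-12)),
                 window = win / rate),
            class = "energy_contour")
}

#' Detect pauses and compute total/net speech time
#'
#' Frames more than `config$silence_floor_db` dB below the utterance speech
#' level are silence candidates. Leading and trailing silence is trimmed
#' first (it reflects recording habits, not speech pausing); within the
#' trimmed utterance, maximal silent runs of at least `min_pause` seconds are
#' counted as inter-pauses. Total speech time (TST) is the trimmed duration
#' and net speech time (NST) is TST minus the summed pause time.
#'
#' @param signal an [audio_signal].
#' @param min_pause minimum pause duration in seconds (> 0).
#' @param config an [hd_config].
#' @return A `segment_set`: list with `segments` (data.frame of `start`,
#'   `end`, `label` in seconds relative to the trimmed utterance, tiling
#'   `[0, total_time]`), `total_time`, `net_time` and `trim` (absolute
#'   start/end of the analyzed region).
#' @export
detect_pauses <- function(signal, min_pause = NULL, config = hd_config()) {
  stopifnot(inherits(signal, "audio_signal"))
  min_pause <- min_pause %||% config$min_pause
  if (min_pause <= 0) stop("min_pause must be positive", call. = FALSE)
  ec <- energy_contour(signal, config)
  level <- as.numeric(quantile(ec$db, 0.95, names = FALSE))
  speech <- ec$db >= level - config$silence_floor_db & ec$db > -115
  if (!any(speech)) stop("no speech found (all-silent input)", call. = FALSE)
  hop <- if (length(ec$times) > 1) diff(ec$times[1:2]) else config$frame_hop

  first <- which(speech)[1]; last <- tail(which(speech), 1)
  t_start <- max(0, ec$times[first] - hop / 2)
  t_end <- min(signal$duration, ec$times[last] + hop / 2)
  idx <- first:last
  r <- rle(speech[idx])
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  seg_start <- pmax(0, ec$times[idx[starts]] - hop / 2 - t_start)
  seg_end <- pmin(t_end - t_start, ec$times[idx[ends]] + hop / 2 - t_start)
  lab <- ifelse(r$values, "speech", "pause")
  # silent runs shorter than min_pause are speech-internal, relabel
  short <- lab == "pause" & (seg_end - seg_start) < min_pause
  lab[short] <- "speech"
  # merge adjacent same-label segments
  keep_start <- seg_start[c(TRUE, lab[-1] != lab[-length(lab)])]
  keep_lab <- lab[c(TRUE, lab[-1] != lab[-length(lab)])]
  grp <- cumsum(c(TRUE, lab[-1] != lab[-length(lab)]))
  keep_end <- tapply(seg_end, grp, max)
  segments <- data.frame(start = keep_start, end = as.numeric(keep_end),
                         label = keep_lab, stringsAsFactors = FALSE)
  # close any float gaps so segments tile exactly
  if (nrow(segments) > 1)
    segments$start[-1] <- segments$end[-nrow(segments)]
  total <- t_end - t_start
  pause_time <- sum(segments$end[segments$label == "pause"] -
                    segments$start[segments$label == "pause"])
  structure(list(segments = segments, total_time = total,
                 net_time = total - pause_time,
                 trim = c(start = t_start, end = t_end)),
            class = "segment_set")
}

#' @export
print.segment_set <- function(x, ...) {
  np <- sum(x$segments$label == "pause")
  cat(sprintf("<segment_set> TST %.2f s, NST %.2f s, %d pause(s)\n",
              x$total_time, x$net_time, np))
  invisible(x)
}

#' Detect syllable nuclei
#'
#' Intensity-peak based nucleus detection: a nucleus is a local maximum of
#' the dB energy contour that (i) lies in a voiced region, (ii) exceeds a
#' global threshold (`silence_floor_db` below the utterance peak), and
#' (iii) is separated from its accepted neighbour by an intensity dip of at
#' least `nucleus_dip_db` dB; peaks without a dip between them are merged,
#' keeping the louder one.
#'
#' @param signal an [audio_signal].
#' @param config an [hd_config].
#' @param contour optional precomputed [estimate_f0] result.
#' @return A `nuclei_set`: list with `nuclei` (times in s, strictly
#'   increasing) and `duration` (trimmed utterance duration in s).
#' @export
detect_syllable_nuclei <- function(signal, config = hd_config(), contour = NULL) {
  stopifnot(inherits(signal, "audio_signal"))
  ec <- energy_contour(signal, config)
  if (is.null(contour)) contour <- estimate_f0(signal, config = config)
  peak_db <- max(ec$db)
  thr <- peak_db - config$silence_floor_db
  speech <- ec$db >= thr & ec$db > -115
  dur <- if (any(speech)) {
    hop <- if (length(ec$times) > 1) diff(ec$times[1:2]) else config$frame_hop
    min(signal$duration, ec$times[tail(which(speech), 1)] + hop / 2) -
      max(0, ec$times[which(speech)[1]] - hop / 2)
  } else signal$duration
  db <- ec$db
  n <- length(db)
  if (n < 3) return(structure(list(nuclei = numeric(0), duration = dur),
                              class = "nuclei_set"))
  is_pk <- which(db[2:(n - 1)] >= db[1:(n - 2)] & db[2:(n - 1)] > db[3:n]) + 1L
  is_pk <- is_pk[db[is_pk] >= thr]
  nv <- length(contour$voiced)
  is_pk <- is_pk[is_pk <= nv & contour$voiced[pmin(is_pk, nv)]]
  if (!length(is_pk)) return(structure(list(nuclei = numeric(0), duration = dur),
                                       class = "nuclei_set"))
  # enforce a dip between consecutive accepted peaks
  acc <- is_pk[1]
  for (p in is_pk[-1]) {
    prev <- acc[length(acc)]
    dip <- min(db[prev:p])
    if (dip <= min(db[prev], db[p]) - config$nucleus_dip_db) {
      acc <- c(acc, p)
    } else if (db[p] > db[prev]) {
      acc[length(acc)] <- p
    }
  }
  structure(list(nuclei = ec$times[acc], duration = dur),
            class = "nuclei_set")
}

#' @export
print.nuclei_set <- function(x, ...) {
  cat(sprintf("<nuclei_set> %d nuclei over %.2f s (%.2f /s)\n",
              length(x$nuclei), x$duration,
              if (x$duration > 0) length(x$nuclei) / x$duration else NA))
  invisible(x)
}

#' Write a frame track as delimited text
#'
#' @param track an `f0_contour`, `formant_track` or `energy_contour`.
#' @param path output path for a tab-delimited file.
#' @return `path`, invisibly.
#' @export
write_track <- function(track, path) {
  df <- if (inherits(track, "f0_contour")) {
    data.frame(time = track$times, f0 = track$f0, voiced = track$voiced)
  } else if (inherits(track, "formant_track")) {
    data.frame(time = track$times, f1 = track$f1, f2 = track$f2,
               voiced = track$voiced)
  } else if (inherits(track, "energy_contour")) {
    data.frame(time = track$times, energy = track$energy, db = track$db)
  } else stop("unsupported track type", call. = FALSE)
  write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
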