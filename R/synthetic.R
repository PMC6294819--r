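# Deterministic synthetic generators. Every generator emits its ground truth
# alongside the data; defaults emulate the recording protocol (48 kHz mono)
# and a cohort of the study's size (75 subjects, ~1/3 female).

#' Specification for synthetic sustained phonation
#'
#' Source-filter synthesis: a glottal pulse train with per-cycle length
#' perturbation (planted jitter, Gaussian, CV = `jitter_level`) and per-cycle
#' amplitude perturbation (planted shimmer), low-pass source shaping, a
#' cascade of second-order vocal-tract resonators, and white noise scaled to
#' the target harmonics-to-noise ratio. A nonzero `unvoiced_fraction` is
#' realised as interior noise-only gaps.
#'
#' @param duration seconds of phonation.
#' @param f0 mean fundamental frequency (Hz).
#' @param jitter_level cycle-length coefficient of variation in [0, 0.2).
#' @param shimmer_level cycle-amplitude coefficient of variation in [0, 0.2).
#' @param snr harmonics-to-noise target in dB.
#' @param formants list of `c(freq, bandwidth)` pairs in Hz.
#' @param unvoiced_fraction fraction of the utterance replaced by unvoiced
#'   gaps, in [0, 1).
#' @param rate sampling rate in Hz (protocol default 48000).
#' @param seed integer seed.
#' @return A `phonation_spec` list.
#' @export
phonation_spec <- function(duration = 5, f0 = 120, jitter_level = 0.005,
                           shimmer_level = 0.03, snr = 25,
                           formants = list(c(700, 80), c(1220, 100),
                                           c(2600, 150), c(3500, 200),
                                           c(4500, 250)),
                           unvoiced_fraction = 0, rate = 48000, seed = 1) {
  if (duration <= 0) stop("duration must be positive", call. = FALSE)
  if (jitter_level < 0 || jitter_level >= 0.2)
    stop("jitter_level must be in [0, 0.2)", call. = FALSE)
  if (shimmer_level < 0 || shimmer_level >= 0.2)
    stop("shimmer_level must be in [0, 0.2)", call. = FALSE)
  if (unvoiced_fraction < 0 || unvoiced_fraction >= 1)
    stop("unvoiced_fraction must be in [0, 1)", call. = FALSE)
  structure(list(duration = duration, f0 = f0, jitter_level = jitter_level,
                 shimmer_level = shimmer_level, snr = snr,
                 formants = formants, unvoiced_fraction = unvoiced_fraction,
                 rate = rate, seed = seed), class = "phonation_spec")
}

# per-sample planted amplitude envelope (used to normalise synthesis gain
# without flattening the planted intensity variation)
amp_frames <- function(amp_at, n, rate) amp_at((seq_len(n) - 1) / rate)

# replace leading/trailing NAs (moving-average edges) by the nearest value
fill_ends <- function(v) {
  ok <- which(!is.na(v))
  if (!length(ok)) return(rep(0, length(v)))
  if (ok[1] > 1) v[1:(ok[1] - 1)] <- v[ok[1]]
  last <- ok[length(ok)]
  if (last < length(v)) v[(last + 1):length(v)] <- v[last]
  v
}

# place unit impulses at fractional sample positions (linear split)
impulse_train <- function(times, amps, n, rate) {
  x <- numeric(n)
  pos <- times * rate + 1
  i0 <- floor(pos)
  frac <- pos - i0
  ok <- i0 >= 1 & i0 < n
  for (j in which(ok)) {
    x[i0[j]] <- x[i0[j]] + amps[j] * (1 - frac[j])
    x[i0[j] + 1L] <- x[i0[j] + 1L] + amps[j] * frac[j]
  }
  x
}

resonator_cascade <- function(x, formants, rate) {
  for (fm in formants) {
    f <- fm[1]; bw <- fm[2]
    r <- exp(-pi * bw / rate)
    theta <- 2 * pi * f / rate
    a <- c(1, -2 * r * cos(theta), r^2)
    b <- (1 - r) * sqrt(1 - 2 * r * cos(2 * theta) + r^2)  # ~unit peak gain
    x <- as.numeric(signal::filter(b, a, x))
  }
  x
}

#' Synthesize sustained phonation with known ground truth
#'
#' @param spec a [phonation_spec].
#' @return List with `signal` ([audio_signal]) and `truth` (the planted
#'   parameters plus realised cycle lengths/amplitudes and gap times).
#' @examples
#' ph <- synth_phonation(phonation_spec(duration = 1, rate = 16000))
#' ph$truth$f0
#' @export
synth_phonation <- function(spec) {
  stopifnot(inherits(spec, "phonation_spec"))
  with_seed(spec$seed, {
    rate <- spec$rate
    T0 <- 1 / spec$f0
    n_cycles <- ceiling(spec$duration / T0) + 2L
    lens <- T0 * (1 + spec$jitter_level * pmax(-3, pmin(3, rnorm(n_cycles))))
    amps <- 1 + spec$shimmer_level * pmax(-3, pmin(3, rnorm(n_cycles)))
    times <- cumsum(c(0, lens))[seq_len(n_cycles)]
    keep <- times < spec$duration
    times <- times[keep]; amps <- amps[keep]; lens <- lens[keep]
    n <- round(spec$duration * rate)
    src <- impulse_train(times, amps, n, rate)
    # low-pass source shaping (glottal-flow-like spectral tilt)
    src <- as.numeric(signal::filter(1, c(1, -0.98), src))
    voiced <- resonator_cascade(src, spec$formants, rate)
    voiced <- voiced / max(1e-12, sqrt(mean(voiced^2))) * 0.15
    sig_rms <- sqrt(mean(voiced^2))
    noise_sd <- sig_rms * 10^(-spec$snr / 20)
    noise <- rnorm(n, sd = noise_sd)

    gaps <- NULL
    if (spec$unvoiced_fraction > 0) {
      gap_total <- spec$unvoiced_fraction * spec$duration
      n_gaps <- max(1L, round(gap_total / 0.4))
      gap_len <- gap_total / n_gaps
      centres <- spec$duration * (seq_len(n_gaps)) / (n_gaps + 1)
      gaps <- cbind(start = centres - gap_len / 2, end = centres + gap_len / 2)
      for (g in seq_len(n_gaps)) {
        a <- max(1L, floor(gaps[g, 1] * rate)); b <- min(n, ceiling(gaps[g, 2] * rate))
        voiced[a:b] <- 0
      }
    }
    x <- voiced + noise
    list(signal = audio_signal(x, rate),
         truth = list(f0 = spec$f0, jitter_level = spec$jitter_level,
                      shimmer_level = spec$shimmer_level, snr = spec$snr,
                      formants = spec$formants,
                      unvoiced_fraction = spec$unvoiced_fraction,
                      cycle_lengths = lens, cycle_amplitudes = amps,
                      gaps = gaps, seed = spec$seed))
  })
}

#' Specification for a synthetic diadochokinetic burst train
#'
#' @param rate_syll syllable rate (bursts per second, > 0).
#' @param irregularity SD (s) of the inter-burst onset intervals.
#' @param n_bursts number of syllable bursts.
#' @param f0 voicing frequency inside each burst (Hz).
#' @param rate sampling rate (Hz).
#' @param seed integer seed.
#' @return A `ddk_spec` list.
#' @export
ddk_spec <- function(rate_syll = 5, irregularity = 0, n_bursts = 15,
                     f0 = 140, rate = 48000, seed = 1) {
  if (rate_syll <= 0) stop("rate_syll must be positive", call. = FALSE)
  if (irregularity < 0) stop("irregularity must be >= 0", call. = FALSE)
  structure(list(rate_syll = rate_syll, irregularity = irregularity,
                 n_bursts = n_bursts, f0 = f0, rate = rate, seed = seed),
            class = "ddk_spec")
}

#' Synthesize a /pa/-/ta/-/ka/-like burst train
#'
#' Each syllable is a short voiced vowel burst (Hann-enveloped pulse train
#' through two resonators) followed by a closure gap; onset intervals are
#' `1/rate_syll` plus Gaussian noise of SD `irregularity`. Truth nuclei are
#' the burst centres.
#'
#' @param spec a [ddk_spec].
#' @return List with `signal`, `truth` (planted rate, onset times, nuclei).
#' @export
synth_ddk <- function(spec) {
  stopifnot(inherits(spec, "ddk_spec"))
  with_seed(spec$seed, {
    rate <- spec$rate
    burst_dur <- min(0.10, 0.5 / spec$rate_syll)
    lead <- 0.25
    if (spec$n_bursts == 0) {
      n <- round(2 * lead * rate)
      return(list(signal = audio_signal(rep(1e-7, n), rate),
                  truth = list(rate_syll = spec$rate_syll, onsets = numeric(0),
                               nuclei = numeric(0), irregularity = spec$irregularity)))
    }
    iv <- 1 / spec$rate_syll + rnorm(spec$n_bursts - 1, sd = spec$irregularity)
    iv <- pmax(iv, burst_dur + 0.02)
    onsets <- lead + cumsum(c(0, iv))
    total <- tail(onsets, 1) + burst_dur + lead
    n <- round(total * rate)
    x <- numeric(n)
    nb <- round(burst_dur * rate)
    env <- 0.5 - 0.5 * cos(2 * pi * (seq_len(nb) - 1) / (nb - 1))
    T0 <- 1 / spec$f0
    for (on in onsets) {
      pt <- seq(0, burst_dur - T0 / 2, by = T0)
      burst <- impulse_train(pt, rep(1, length(pt)), nb, rate)
      burst <- as.numeric(signal::filter(1, c(1, -0.98), burst))
      burst <- resonator_cascade(burst, list(c(700, 90), c(1220, 110)), rate)
      burst <- burst / max(1e-12, sqrt(mean(burst^2))) * 0.2 * env
      a <- floor(on * rate) + 1L
      b <- min(n, a + nb - 1L)
      x[a:b] <- x[a:b] + burst[seq_len(b - a + 1L)]
    }
    x <- x + rnorm(n, sd = 2e-5)          # recording-floor noise
    list(signal = audio_signal(x, rate),
         truth = list(rate_syll = spec$rate_syll, onsets = onsets,
                      nuclei = onsets + burst_dur / 2,
                      irregularity = spec$irregularity,
                      intervals = iv, burst_dur = burst_dur))
  })
}

#' Specification for synthetic pseudo-read-speech
#'
#' @param phone_count planted phone count of the "script".
#' @param n_pauses number of interior pauses.
#' @param pause_dur pause duration (s).
#' @param net_time total voiced (speech) time (s).
#' @param f0_cv planted coefficient of variation of the F0 trajectory.
#' @param intensity_cv planted coefficient of variation of segment intensity.
#' @param f0 mean F0 (Hz).
#' @param rate sampling rate (Hz).
#' @param seed integer seed.
#' @return A `read_speech_spec` list.
#' @export
read_speech_spec <- function(phone_count = 300, n_pauses = 3, pause_dur = 0.5,
                             net_time = 12, f0_cv = 0.08, intensity_cv = 0.15,
                             f0 = 120, rate = 48000, seed = 1) {
  if (net_time <= 0) stop("net_time must be positive", call. = FALSE)
  if (n_pauses < 0 || pause_dur < 0) stop("counts must be >= 0", call. = FALSE)
  structure(list(phone_count = phone_count, n_pauses = n_pauses,
                 pause_dur = pause_dur, net_time = net_time, f0_cv = f0_cv,
                 intensity_cv = intensity_cv, f0 = f0, rate = rate,
                 seed = seed), class = "read_speech_spec")
}

#' Synthesize pseudo-read-speech with planted pauses and variability
#'
#' `n_pauses + 1` voiced stretches of equal total `net_time`, separated by
#' silent gaps of `pause_dur`. Each stretch is a concatenation of short
#' quasi-stationary vowel chunks whose F0, intensity and formants follow
#' slow seeded random walks, realising the planted F0/intensity coefficients
#' of variation. No leading/trailing silence beyond the recording floor.
#'
#' @param spec a [read_speech_spec].
#' @return List with `signal` and `truth` (TST, NST, phone_count, pause
#'   times, chunk parameters).
#' @export
synth_read_speech <- function(spec) {
  stopifnot(inherits(spec, "read_speech_spec"))
  with_seed(spec$seed, {
    rate <- spec$rate
    n_seg <- spec$n_pauses + 1L
    seg_dur <- spec$net_time / n_seg
    pieces <- list()
    pauses <- NULL
    t_cursor <- 0
    f1w <- 600; f2w <- 1400      # formant random-walk state across segments
    clipz <- function(k) pmax(-2.5, pmin(2.5, rnorm(k)))
    for (s in seq_len(n_seg)) {
      # smooth F0 and intensity trajectories: knots every 250 ms,
      # linearly interpolated, realising the planted CVs
      nk <- max(2L, ceiling(seg_dur / 0.25) + 1L)
      kt <- seq(0, seg_dur, length.out = nk)
      f0k <- spec$f0 * (1 + spec$f0_cv * clipz(nk))
      ampk <- pmax(0.15, 1 + spec$intensity_cv * clipz(nk))
      f0_at <- stats::approxfun(kt, f0k, rule = 2)
      amp_at <- stats::approxfun(kt, ampk, rule = 2)
      # one continuous pulse train per segment (no mid-segment transients)
      pt <- numeric(0); tp <- 0
      while (tp < seg_dur) { pt <- c(pt, tp); tp <- tp + 1 / f0_at(tp) }
      nb <- round(seg_dur * rate)
      # power of a filtered pulse train scales with pulse rate; compensate so
      # intensity tracks only the planted amplitude envelope
      y <- impulse_train(pt, amp_at(pt) * sqrt(spec$f0 / f0_at(pt)), nb, rate)
      y <- as.numeric(signal::filter(1, c(1, -0.98), y))
      f1w <- min(850, max(350, f1w + rnorm(1, sd = 80)))
      f2w <- min(2300, max(950, f2w + rnorm(1, sd = 180)))
      y <- resonator_cascade(y, list(c(f1w, 90), c(f2w, 120)), rate)
      # impose the planted intensity envelope exactly: divide out the realised
      # RMS envelope (harmonic-resonance alignment and pulse-count granularity
      # would otherwise leak into the intensity contour) and apply the target
      nw <- max(3L, round(0.04 * rate))
      for (pass in 1:2) {   # two passes flatten the residual ripple
        env <- as.numeric(stats::filter(y^2, rep(1 / nw, nw), sides = 2))
        env <- sqrt(pmax(fill_ends(env), 0))
        y <- y / pmax(env, 0.05 * stats::median(env))
      }
      y <- y * (0.15 * amp_frames(amp_at, nb, rate))
      nf <- min(nb %/% 4L, round(0.003 * rate))
      if (nf > 1) {
        ramp <- seq(0, 1, length.out = nf)
        y[seq_len(nf)] <- y[seq_len(nf)] * ramp
        y[(nb - nf + 1L):nb] <- y[(nb - nf + 1L):nb] * rev(ramp)
      }
      pieces[[length(pieces) + 1L]] <- y
      t_cursor <- t_cursor + seg_dur
      if (s < n_seg) {
        pauses <- rbind(pauses, c(start = t_cursor, end = t_cursor + spec$pause_dur))
        pieces[[length(pieces) + 1L]] <- numeric(round(spec$pause_dur * rate))
        t_cursor <- t_cursor + spec$pause_dur
      }
    }
    x <- unlist(pieces)
    x <- x + rnorm(length(x), sd = 2e-5)
    tst <- spec$net_time + spec$n_pauses * spec$pause_dur
    list(signal = audio_signal(x, rate),
         truth = list(TST = tst, NST = spec$net_time,
                      phone_count = spec$phone_count,
                      n_pauses = spec$n_pauses, pauses = pauses,
                      f0_cv = spec$f0_cv, intensity_cv = spec$intensity_cv,
                      seed = spec$seed))
  })
}

#' Specification for a synthetic clinical cohort
#'
#' @param n_subjects number of subjects (>= 10; study-scale default 75).
#' @param features feature column names to generate.
#' @param planted data.frame with columns `feature`, `item`, `rho`: partial
#'   correlations (given the covariates) to plant between features and FOG-Q
#'   items.
#' @param delta_weights named list: for each response (`"Q3"`..`"Q6"`,
#'   `"total"`), a named numeric vector of feature weights generating the
#'   2-year change as a linear function of (standardised) features.
#' @param noise_sd SD of the Gaussian noise added to each generated change
#'   score.
#' @param seed integer seed.
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(n_subjects = 75,
                        features = default_cohort_features(),
                        planted = NULL,
                        delta_weights = list(
                          total = c(F1IR_TSK10 = -0.8, jitter_TSK4 = 0.6,
                                    TSR_TSK10 = -0.5)),
                        noise_sd = 0.5, seed = 1) {
  if (n_subjects < 10) stop("n_subjects must be >= 10", call. = FALSE)
  if (!is.null(planted)) {
    stopifnot(all(c("feature", "item", "rho") %in% names(planted)))
    if (any(abs(planted$rho) >= 1)) stop("|rho| must be < 1", call. = FALSE)
  }
  structure(list(n_subjects = n_subjects, features = features,
                 planted = planted, delta_weights = delta_weights,
                 noise_sd = noise_sd, seed = seed), class = "cohort_spec")
}

#' @rdname cohort_spec
#' @export
default_cohort_features <- function() {
  c("jitter_TSK4", "shimmer_TSK4", "relF0SD_TSK4", "meanHNR_TSK4",
    "DUV_TSK4", "MPT_TSK3", "F1IR_TSK10", "F2IR_TSK10", "F1SD_TSK6",
    "F2SD_TSK11", "F2IR_TSK11", "F1SD_TSK9", "DDKrate_TSK5", "DDKreg_TSK5",
    "relSEOSD_TSK1", "relF0SD_TSK10", "SPIR_TSK10", "TSR_TSK10",
    "TSR_TSK7", "NSR_TSK12")
}

# plausible clinical marginals (mean, sd) used to scale generated columns
cohort_marginals <- function() {
  list(age = c(65, 8), LED = c(800, 300), UPDRS_III = c(22, 10),
       BDI = c(9, 5), ACE_R = c(88, 7), PD_dur = c(8, 4), NMSS = c(42, 20),
       RBDSQ = c(4, 3), MMSE = c(28, 1.3))
}

# plausible feature marginals by measure name
feature_marginals <- function(feature) {
  m <- sub("_TSK.*$", "", feature)
  switch(m,
         jitter = c(0.8, 0.4), shimmer = c(6, 2.5), relF0SD = c(0.03, 0.015),
         meanHNR = c(18, 4), DUV = c(0.08, 0.06), MPT = c(18, 7),
         F1IR = c(450, 120), F2IR = c(900, 250), F1SD = c(120, 40),
         F2SD = c(280, 90), DDKrate = c(5.5, 1.2), DDKreg = c(0.04, 0.02),
         relSEOSD = c(0.35, 0.12), SPIR = c(12, 6), TSR = c(11, 2),
         NSR = c(13, 2.5), c(0, 1))
}

#' Generate a synthetic cohort with planted partial-correlation structure
#'
#' Covariates are drawn with plausible clinical marginals; each feature and
#' each FOG-Q latent score loads moderately on a few covariates, and their
#' residuals are drawn jointly Gaussian with the planted correlations, so
#' the partial correlation of a planted (feature, item) pair given the
#' covariates equals `rho` before discretisation. Items are discretised to
#' the 0-4 questionnaire scale (round half away from zero, clip), which
#' attenuates the planted correlation; the attenuation is measured by the
#' test suite rather than assumed away. Two-year change scores are generated
#' as the planted linear function of standardised features plus Gaussian
#' noise, stored both as continuous `d<item>` columns (the regression
#' response) and as integer session-2 items.
#'
#' @param spec a [cohort_spec].
#' @return List with `cohort` (long data.frame: one row per subject and
#'   session), `features` (wide `feature_table` for session 1) and `truth`
#'   (full generative parameterisation, including the continuous latent
#'   items and deltas).
#' @export
synth_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  items <- c("Q3", "Q4", "Q5", "Q6")
  p <- length(spec$features)
  with_seed(spec$seed, {
    n <- spec$n_subjects
    marg <- cohort_marginals()
    Zs <- matrix(rnorm(n * length(marg)), n)
    colnames(Zs) <- names(marg)
    gender <- rbinom(n, 1, 1 / 3)

    # residual correlation among (features, item latents)
    q <- p + length(items)
    R <- diag(q)
    nm <- c(spec$features, items)
    if (!is.null(spec$planted)) {
      for (i in seq_len(nrow(spec$planted))) {
        fi <- match(spec$planted$feature[i], nm)
        qi <- match(spec$planted$item[i], nm)
        if (is.na(fi) || is.na(qi))
          stop("planted pair refers to unknown feature/item: ",
               spec$planted$feature[i], " / ", spec$planted$item[i],
               call. = FALSE)
        R[fi, qi] <- R[qi, fi] <- spec$planted$rho[i]
      }
      ch <- tryCatch(chol(R), error = function(e) NULL)
      if (is.null(ch))
        stop("planted correlations are not jointly positive definite: ",
             paste(sprintf("(%s,%s,%.2f)", spec$planted$feature,
                           spec$planted$item, spec$planted$rho),
                   collapse = " "), call. = FALSE)
    } else ch <- diag(q)
    E <- matrix(rnorm(n * q), n) %*% ch

    # covariate loadings: deterministic assignment so partialling matters
    covs <- c("age", "UPDRS_III", "LED", "BDI", "ACE_R")
    feat_std <- matrix(NA_real_, n, p, dimnames = list(NULL, spec$features))
    for (j in seq_len(p)) {
      z1 <- covs[(j - 1) %% length(covs) + 1]
      z2 <- covs[j %% length(covs) + 1]
      lat <- 0.35 * Zs[, z1] + 0.25 * Zs[, z2] + 0.2 * (gender - 1 / 3) +
        sqrt(1 - 0.35^2 - 0.25^2) * E[, j]
      feat_std[, j] <- lat
    }
    item_lat <- matrix(NA_real_, n, length(items),
                       dimnames = list(NULL, items))
    for (m in seq_along(items)) {
      item_lat[, m] <- 0.35 * Zs[, "age"] + 0.3 * Zs[, "UPDRS_III"] +
        sqrt(1 - 0.35^2 - 0.3^2) * E[, p + m]
    }

    # scale features to plausible units
    feat <- feat_std
    for (j in seq_len(p)) {
      ms <- feature_marginals(spec$features[j])
      feat[, j] <- pmax(ms[1] + ms[2] * feat_std[, j],
                        if (grepl("DUV", spec$features[j])) 0 else -Inf)
    }

    # discretise items to the 0-4 questionnaire scale
    round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)
    clip04 <- function(m) { m[] <- pmin(4, pmax(0, m)); m }
    items_s1 <- clip04(round_half_away(2 + 1.1 * item_lat))

    # continuous 2-year change per response: the planted linear function of
    # standardised features plus noise; pure noise where nothing is planted
    deltas <- matrix(rnorm(n * 5, sd = spec$noise_sd), n, 5,
                     dimnames = list(NULL, c(items, "total")))
    for (resp in names(spec$delta_weights)) {
      w <- spec$delta_weights[[resp]]
      miss <- setdiff(names(w), spec$features)
      if (length(miss))
        stop("delta_weights refer to unknown features: ",
             paste(miss, collapse = ", "), call. = FALSE)
      deltas[, resp] <- feat_std[, names(w), drop = FALSE] %*% w +
        rnorm(n, sd = spec$noise_sd)
    }
    items_s2 <- clip04(items_s1 + round_half_away(deltas[, items]))

    mk_session <- function(ses, it) {
      df <- data.frame(subject_id = sprintf("S%03d", seq_len(n)), session = ses,
                       age = marg$age[1] + marg$age[2] * Zs[, "age"] + 2 * (ses - 1),
                       gender = gender, stringsAsFactors = FALSE)
      for (v in c("PD_dur", "UPDRS_III", "LED", "NMSS", "RBDSQ", "MMSE",
                  "ACE_R", "BDI"))
        df[[v]] <- marg[[v]][1] + marg[[v]][2] * Zs[, v] +
          (ses - 1) * marg[[v]][2] * 0.2
      df[items] <- it
      df$total <- rowSums(it)
      df
    }
    cohort <- rbind(mk_session(1, items_s1), mk_session(2, items_s2))

    fdf <- data.frame(subject_id = sprintf("S%03d", seq_len(n)), session = 1,
                      stringsAsFactors = FALSE)
    fdf[spec$features] <- as.data.frame(feat)
    # attach the continuous change responses used by the prediction stage
    fdf[paste0("d", colnames(deltas))] <- as.data.frame(deltas)
    class(fdf) <- c("feature_table", "data.frame")

    list(cohort = cohort, features = fdf,
         truth = list(spec = spec, item_latent = item_lat,
                      features_std = feat_std, deltas = deltas,
                      residual_corr = R))
  })
}

#' Write a synthetic cohort to delimited text
#'
#' @param cohort_out a [synth_cohort] result.
#' @param dir output directory (`cohort.tsv`, `features.tsv`,
#'   `truth.json`).
#' @param provenance optional `#`-prefixed header lines.
#' @return The directory, invisibly.
#' @export
write_cohort <- function(cohort_out, dir, provenance = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wr <- function(df, f) {
    con <- file(file.path(dir, f), "w")
    on.exit(close(con))
    if (!is.null(provenance)) writeLines(paste0("# ", provenance), con)
    write.table(df, con, sep = "\t", row.names = FALSE, quote = FALSE)
  }
  wr(cohort_out$cohort, "cohort.tsv")
  wr(as.data.frame(cohort_out$features), "features.tsv")
  truth <- cohort_out$truth
  truth$spec <- unclass(truth$spec)
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
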