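cfg <- hd_config()

test_that("pure periodic signals across the band are recovered within 1%", {
  for (f in c(80, 120, 200, 300)) {
    ctr <- estimate_f0(sine_signal(f, dur = 0.6))
    expect_true(all(ctr$voiced[5:(length(ctr$voiced) - 4)]))
    expect_lt(abs(mean(ctr$f0[ctr$voiced]) - f) / f, 0.01)
    ctr2 <- estimate_f0(saw_signal(f, dur = 0.6))
    expect_lt(abs(mean(ctr2$f0[ctr2$voiced]) - f) / f, 0.01)
  }
})

test_that("silence yields an all-unvoiced contour, not an error", {
  ctr <- estimate_f0(audio_signal(rep(0, 48000), 48000))
  expect_false(any(ctr$voiced))
  expect_true(all(is.na(ctr$f0)))
})

test_that("too-short input and bad pitch bands are explicit errors", {
  expect_error(estimate_f0(audio_signal(rep(0.1, 100), 48000)), "short")
  s <- sine_signal(120, dur = 0.5)
  expect_error(estimate_f0(s, f0_min = 300, f0_max = 200), "f0_min")
  expect_error(estimate_f0(audio_signal(rep(0.1, 8000), 1000), f0_max = 600),
               "Nyquist")
})

test_that("all frame tracks share one frame grid", {
  s <- sine_signal(150, dur = 0.8)
  ctr <- estimate_f0(s)
  ec <- energy_contour(s)
  expect_equal(ctr$times, ec$times)
})

test_that("cycle extraction recovers period and amplitude of a pure tone", {
  s <- sine_signal(100, dur = 1)
  p <- extract_periods(s, estimate_f0(s))
  expect_true(all(abs(p$length - 0.010) < 1e-4))
  expect_lt(max(abs(p$amplitude / mean(p$amplitude) - 1)), 0.01)
})

test_that("cycle-length CV of a frequency-modulated tone matches theory", {
  # 2% peak FM at 5 Hz -> cycle-length CV ~ 0.02 / sqrt(2)
  fs <- 48000
  t <- seq(0, 2, by = 1 / fs)
  phi <- 2 * pi * 100 * t + (0.02 * 100 / 5) * sin(2 * pi * 5 * t)
  s <- audio_signal(0.5 * sin(phi), fs)
  p <- extract_periods(s, estimate_f0(s))
  cv <- oracle_sd(p$length) / mean(p$length)
  expect_lt(abs(cv - 0.02 / sqrt(2)) / (0.02 / sqrt(2)), 0.20)
})

test_that("cycle extraction refuses unvoiced input", {
  s <- audio_signal(rep(0, 48000), 48000)
  ctr <- estimate_f0(s)
  expect_error(extract_periods(s, ctr), "voiced")
})

test_that("formants of source-filter vowels are recovered within 10%", {
  specs <- list(list(f1 = 700, f2 = 1220),
                list(f1 = 300, f2 = 2300),
                list(f1 = 850, f2 = 1600))
  for (sp in specs) {
    fms <- list(c(sp$f1, 80), c(sp$f2, 120), c(2900, 180), c(3800, 220),
                c(4600, 260))
    if (sp$f2 > 2500) fms[[3]] <- c(3100, 180)
    ph <- synth_phonation(phonation_spec(duration = 1.2, f0 = 110,
                                         jitter_level = 0, shimmer_level = 0,
                                         snr = 30, formants = fms, seed = 2))
    tr <- estimate_formants(ph$signal)
    expect_lt(abs(median(tr$f1, na.rm = TRUE) - sp$f1) / sp$f1, 0.10)
    expect_lt(abs(median(tr$f2, na.rm = TRUE) - sp$f2) / sp$f2, 0.10)
  }
})

test_that("formant analysis rejects a ceiling above Nyquist and silence", {
  s <- audio_signal(rep(0.1, 8000), 8000)
  expect_error(estimate_formants(s, max_formant = 5500), "Nyquist")
  sil <- audio_signal(rep(0, 48000), 48000)
  tr <- estimate_formants(sil)
  expect_true(all(is.na(tr$f1)))
})

test_that("energy contour squares with amplitude and zeros are zero", {
  fs <- 16000
  x <- c(0.2 * sin(2 * pi * 200 * seq(0, 1, by = 1 / fs)),
         0.4 * sin(2 * pi * 200 * seq(0, 1, by = 1 / fs)))
  ec <- energy_contour(audio_signal(x, fs))
  n <- length(ec$energy)
  first <- ec$energy[5:(n / 2 - 5)]
  second <- ec$energy[(n / 2 + 5):(n - 5)]
  expect_lt(abs(mean(second) / mean(first) - 4), 0.1)
  ec0 <- energy_contour(audio_signal(rep(0, fs), fs))
  expect_true(all(ec0$energy == 0))
  ecs <- energy_contour(sine_signal(200, dur = 1, rate = fs))
  interior <- ecs$energy[5:(length(ecs$energy) - 5)]
  expect_lt(oracle_sd(interior) / mean(interior), 0.01)
})

test_that("pause detection counts constructed gaps and tiles the utterance", {
  rs <- synth_read_speech(read_speech_spec(n_pauses = 1, pause_dur = 0.8,
                                           net_time = 4, seed = 3))
  seg <- detect_pauses(rs$signal, min_pause = 0.3)
  expect_equal(sum(seg$segments$label == "pause"), 1)
  expect_lt(abs(seg$net_time - 4), 0.2)
  # segments tile [0, total_time] within one frame
  expect_lt(abs(sum(seg$segments$end - seg$segments$start) - seg$total_time),
            0.011)
  expect_equal(seg$segments$start[1], 0)
  # gaps below min_pause are not pauses
  rs2 <- synth_read_speech(read_speech_spec(n_pauses = 3, pause_dur = 0.5,
                                            net_time = 6, seed = 4))
  seg2 <- detect_pauses(rs2$signal, min_pause = 0.6)
  expect_equal(sum(seg2$segments$label == "pause"), 0)
  expect_equal(seg2$net_time, seg2$total_time)
})

test_that("all-silent input is a pause-detection error", {
  expect_error(detect_pauses(audio_signal(rep(0, 48000), 48000)), "silent")
})

test_that("syllable nuclei: burst trains count, vowels give at most one", {
  dd <- synth_ddk(ddk_spec(rate_syll = 5, irregularity = 0, n_bursts = 10))
  nu <- detect_syllable_nuclei(dd$signal)
  expect_true(abs(length(nu$nuclei) - 10) <= 1)
  expect_true(all(diff(nu$nuclei) > 0))
  ph <- synth_phonation(phonation_spec(duration = 2, seed = 5))
  nu2 <- detect_syllable_nuclei(ph$signal)
  expect_lte(length(nu2$nuclei), 1)
  nu0 <- detect_syllable_nuclei(audio_signal(rep(0, 48000), 48000))
  expect_equal(length(nu0$nuclei), 0)
})
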