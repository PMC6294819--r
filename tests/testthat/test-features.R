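test_that("relF0SD matches direct arithmetic and is scale invariant", {
  mk <- function(f0) {
    structure(list(times = seq_along(f0) * 0.01, f0 = f0,
                   voiced = !is.na(f0), strength = rep(0.9, length(f0))),
              class = "f0_contour")
  }
  expect_equal(rel_f0_sd(mk(rep(120, 10))), 0)
  v <- c(100, 110, 90, 100)
  expect_equal(rel_f0_sd(mk(v)), oracle_sd(v) / mean(v), tolerance = 1e-12)
  expect_equal(rel_f0_sd(mk(v)), 0.08165, tolerance = 1e-3)
  expect_equal(rel_f0_sd(mk(2 * v)), rel_f0_sd(mk(v)), tolerance = 1e-12)
  expect_error(rel_f0_sd(mk(c(100, NA, NA))), "voiced")
})

test_that("PPQ5/APQ5 agree with the direct-formula oracle and are scale-free", {
  expect_equal(jitter_ppq5(rep(0.010, 10)), 0)
  v <- c(10, 10, 10, 10, 10, 12, 10, 10, 10, 10) / 1000
  expect_equal(jitter_ppq5(v), oracle_ppq5(v), tolerance = 1e-12)
  expect_equal(jitter_ppq5(1.5 * v), jitter_ppq5(v), tolerance = 1e-12)
  expect_error(jitter_ppq5(c(0.01, 0.01)), "5 cycles")
  a <- c(1, 1, 1, 1, 1, 1.2, 1, 1, 1, 1)
  expect_equal(shimmer_apq5(a), oracle_ppq5(a), tolerance = 1e-12)
  expect_equal(shimmer_apq5(3 * a), shimmer_apq5(a), tolerance = 1e-12)
  # random-vector agreement
  set.seed(1)
  for (i in 1:5) {
    v <- abs(rnorm(20, 0.01, 0.001))
    expect_equal(jitter_ppq5(v), oracle_ppq5(v), tolerance = 1e-10)
  }
})

test_that("HNR responds to planted noise level and is monotone in it", {
  ph <- synth_phonation(phonation_spec(duration = 1.5, jitter_level = 0,
                                       shimmer_level = 0, snr = 60, seed = 6))
  ctr <- estimate_f0(ph$signal)
  expect_gt(mean_hnr(ph$signal, ctr), 25)
  hnrs <- vapply(c(30, 15, 5, 0), function(snr) {
    p2 <- synth_phonation(phonation_spec(duration = 1.5, jitter_level = 0,
                                         shimmer_level = 0, snr = snr, seed = 6))
    mean_hnr(p2$signal, estimate_f0(p2$signal))
  }, 0)
  expect_true(all(diff(hnrs) < 0))
  expect_lt(abs(hnrs[4]), 3)   # harmonic ~ noise energy at 0 dB SNR
})

test_that("DUV counts unvoiced frames within the trim window", {
  mk <- function(voiced) {
    structure(list(times = seq_along(voiced) * 0.01,
                   f0 = ifelse(voiced, 120, NA), voiced = voiced,
                   strength = ifelse(voiced, 0.9, NA)), class = "f0_contour")
  }
  expect_equal(duv(mk(rep(TRUE, 50))), 0)
  expect_equal(duv(mk(rep(FALSE, 50))), 1)
  expect_equal(duv(mk(c(rep(TRUE, 80), rep(FALSE, 20)))), 0.20)
  # trim excludes leading silence frames
  v <- c(rep(FALSE, 10), rep(TRUE, 40))
  expect_equal(duv(mk(v), trim = c(0.105, 0.505)), 0)
})

test_that("formant dispersion statistics match their oracles", {
  mk <- function(f1) structure(list(times = seq_along(f1) * 0.01, f1 = f1,
                                    f2 = f1 * 2, voiced = !is.na(f1)),
                               class = "formant_track")
  expect_equal(formant_stats(mk(rep(700, 200)), "F1", "SD"), 0)
  expect_equal(suppressWarnings(formant_stats(mk(rep(700, 200)), "F1", "IR")), 0)
  v <- c(1000, 1200, 1400)
  expect_equal(formant_stats(mk(v / 2), "F2", "SD"), oracle_sd(v),
               tolerance = 1e-12)
  set.seed(2)
  u <- runif(1e4, 400, 800)
  ir <- formant_stats(mk(u), "F1", "IR")
  expect_equal(ir, unname(diff(quantile(u, c(0.01, 0.99)))), tolerance = 1e-12)
  expect_lt(abs(ir - 392), 10)
  expect_warning(formant_stats(mk(v), "F1", "IR"), "100")
  expect_error(formant_stats(mk(rep(NA_real_, 5)), "F1", "SD"), "defined")
})

test_that("DDK rate and regularity are counting arithmetic", {
  mk <- function(nuc, dur) structure(list(nuclei = nuc, duration = dur),
                                     class = "nuclei_set")
  expect_equal(ddk_rate(mk(seq(0.1, 1.9, by = 0.2), 2)), 5)
  expect_equal(ddk_rate(mk(numeric(0), 2)), 0)
  expect_equal(ddk_rate(mk(seq(0.1, 1.9, by = 0.2), 4)), 2.5)
  expect_equal(ddk_reg(mk(c(0, 0.2, 0.4, 0.6), 1)), 0)
  iv <- c(0.20, 0.25, 0.20, 0.25)
  nuc <- cumsum(c(0.1, iv))
  expect_equal(ddk_reg(mk(nuc, 1.2)), oracle_sd(iv), tolerance = 1e-12)
  expect_equal(ddk_reg(mk(nuc + 5, 20)), ddk_reg(mk(nuc, 1.2)),
               tolerance = 1e-12)
  expect_error(ddk_reg(mk(c(0.1, 0.3), 1)), "3 nuclei")
})

test_that("relSEOSD is the CV of speech-frame intensity", {
  mk <- function(en) structure(list(times = seq_along(en) * 0.01,
                                    energy = en, db = 10 * log10(pmax(en, 1e-12))),
                               class = "energy_contour")
  expect_equal(rel_seo_sd(mk(rep(0.04, 100))), 0)
  two <- c(rep(1, 50), rep(4, 50))     # intensity (RMS) 1 and 2
  i <- sqrt(two)
  expect_equal(rel_seo_sd(mk(two)), oracle_sd(i) / mean(i), tolerance = 1e-12)
  expect_equal(rel_seo_sd(mk(9 * two)), rel_seo_sd(mk(two)), tolerance = 1e-12)
  expect_error(rel_seo_sd(mk(rep(0, 10))), "zero-mean")
})

test_that("SPIR and speech rates follow their definitions", {
  seg <- structure(list(
    segments = data.frame(start = c(0, 10, 12, 22, 24, 26, 28),
                          end = c(10, 12, 22, 24, 26, 28, 30),
                          label = c("speech", "pause", "speech", "pause",
                                    "speech", "pause", "speech")),
    total_time = 30, net_time = 24,
    trim = c(start = 0, end = 30)), class = "segment_set")
  # 3 pauses here; build a 5-pause variant for the arithmetic example
  seg5 <- seg; seg5$segments$label[c(1, 3)] <- "pause"
  expect_equal(spir(seg), 3 / (30 / 60))
  rates <- speech_rates(seg, 300)
  expect_equal(unname(rates["TSR"]), 10)
  expect_equal(unname(rates["NSR"]), 12.5)
  expect_gte(rates["NSR"], rates["TSR"])
  segnp <- seg; segnp$segments$label[] <- "speech"; segnp$net_time <- 30
  r2 <- speech_rates(segnp, 300)
  expect_equal(unname(r2["TSR"]), unname(r2["NSR"]))
  expect_error(speech_rates(seg, NA), "phone_count")
  expect_equal(spir(segnp), 0)
})

test_that("maximum phonation time takes the longest voiced stretch", {
  fs <- 48000
  stretch <- function(d) 0.4 * sin(2 * pi * 130 * seq(0, d, by = 1 / fs))
  x <- c(stretch(1.5), rep(0, fs), stretch(0.6))
  m <- mpt(audio_signal(x, fs))
  expect_lt(abs(m - 1.5), 0.2)
  expect_error(mpt(audio_signal(rep(0, fs), fs)), "voiced")
})

test_that("extract_all routes exactly the measures of each task", {
  ph <- synth_phonation(phonation_spec(duration = 1.5, seed = 8))
  f4 <- extract_all(ph$signal, "TSK4")
  expect_setequal(f4$measure, c("relF0SD", "jitter", "shimmer", "meanHNR",
                                "DUV", "F1SD", "F2SD"))
  f2 <- extract_all(ph$signal, "TSK2")
  expect_equal(f2$measure, "MPT")
  dd <- synth_ddk(ddk_spec(n_bursts = 10, seed = 8))
  f5 <- extract_all(dd$signal, "TSK5")
  expect_setequal(f5$measure, c("DDKrate", "DDKreg"))
  rs <- synth_read_speech(read_speech_spec(net_time = 6, n_pauses = 2, seed = 8))
  f10 <- extract_all(rs$signal, "TSK10")
  expect_setequal(f10$measure, c("F1IR", "F2IR", "F1SD", "F2SD", "relSEOSD",
                                 "relF0SD", "SPIR", "TSR", "NSR"))
  f7 <- extract_all(rs$signal, "TSK7", phone_count = 12)
  expect_false("SPIR" %in% f7$measure)
  expect_true(all(c("TSR", "NSR") %in% f7$measure))
  expect_error(extract_all(ph$signal, "TSK99"), "unknown task")
})

test_that("per-measure failures become NA, not batch aborts", {
  sil <- audio_signal(rep(c(0, 1e-7), 48000), 48000)
  w <- capture_warnings(fv <- extract_all(sil, "TSK4"))
  expect_true(any(grepl("TSK4", w)))
  expect_true(all(is.na(fv$value[fv$measure %in% c("jitter", "meanHNR")])))
})

test_that("feature tables assemble wide and write long with units", {
  long <- data.frame(subject_id = rep(c("A", "B"), each = 2), session = 1,
                     measure = rep(c("jitter", "DUV"), 2), task = "TSK4",
                     value = c(0.5, 0.1, 0.7, 0.2))
  wide <- feature_table(long)
  expect_true(all(c("jitter_TSK4", "DUV_TSK4") %in% names(wide)))
  expect_equal(wide$jitter_TSK4[wide$subject_id == "B"], 0.7)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_feature_table(wide, f, provenance = "test")
  back <- read.delim(f, comment.char = "#")
  expect_equal(nrow(back), 4)
  expect_true(all(c("measure", "units") %in% names(back)))
})
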