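test_that("generators are deterministic under a fixed seed", {
  a <- synth_phonation(phonation_spec(duration = 0.5, seed = 21, rate = 16000))
  b <- synth_phonation(phonation_spec(duration = 0.5, seed = 21, rate = 16000))
  expect_identical(a$signal$samples, b$signal$samples)
  expect_identical(a$truth, b$truth)
  c1 <- synth_cohort(cohort_spec(n_subjects = 20, seed = 22))
  c2 <- synth_cohort(cohort_spec(n_subjects = 20, seed = 22))
  expect_identical(c1$cohort, c2$cohort)
  expect_identical(as.data.frame(c1$features), as.data.frame(c2$features))
  d1 <- synth_ddk(ddk_spec(seed = 23, irregularity = 0.03))
  d2 <- synth_ddk(ddk_spec(seed = 23, irregularity = 0.03))
  expect_identical(d1$signal$samples, d2$signal$samples)
})

test_that("generators do not disturb the caller's RNG stream", {
  set.seed(99)
  before <- .Random.seed
  invisible(synth_phonation(phonation_spec(duration = 0.3, seed = 1,
                                           rate = 16000)))
  expect_identical(.Random.seed, before)
})

test_that("phonation truth is recovered: F0, DUV, zero-jitter floor", {
  ph <- synth_phonation(phonation_spec(duration = 2, f0 = 150, seed = 24))
  ctr <- estimate_f0(ph$signal)
  expect_lt(abs(mean(ctr$f0[ctr$voiced]) - 150) / 150, 0.01)
  tr <- estimate_formants(ph$signal, contour = ctr)
  expect_lt(abs(median(tr$f1, na.rm = TRUE) - 700) / 700, 0.10)
  expect_lt(abs(median(tr$f2, na.rm = TRUE) - 1220) / 1220, 0.10)
  # zero planted jitter -> extracted cycle CV below 0.003
  p0 <- synth_phonation(phonation_spec(duration = 2, jitter_level = 0,
                                       shimmer_level = 0, snr = 40, seed = 25))
  per <- extract_periods(p0$signal, estimate_f0(p0$signal))
  expect_lt(sd(per$length) / mean(per$length), 0.003)
  # planted unvoiced fraction -> DUV within 0.03
  pu <- synth_phonation(phonation_spec(duration = 5, unvoiced_fraction = 0.2,
                                       seed = 26))
  ctu <- estimate_f0(pu$signal)
  sg <- detect_pauses(pu$signal)
  expect_lt(abs(duv(ctu, sg$trim) - 0.2), 0.03)
})

test_that("planted jitter and shimmer orderings are recovered monotonically", {
  ppq <- vapply(c(0.005, 0.01, 0.02), function(j) {
    ph <- synth_phonation(phonation_spec(duration = 2, jitter_level = j,
                                         shimmer_level = 0, snr = 40, seed = 27))
    jitter_ppq5(extract_periods(ph$signal, estimate_f0(ph$signal)))
  }, 0)
  expect_true(all(diff(ppq) > 0))
  apq <- vapply(c(0.005, 0.01, 0.02), function(sh) {
    ph <- synth_phonation(phonation_spec(duration = 2, jitter_level = 0.002,
                                         shimmer_level = sh, snr = 40, seed = 28))
    shimmer_apq5(extract_periods(ph$signal, estimate_f0(ph$signal)))
  }, 0)
  expect_true(all(diff(apq) > 0))
})

test_that("DDK truth is recovered: rate, regularity, empty train", {
  dd <- synth_ddk(ddk_spec(rate_syll = 5, irregularity = 0, n_bursts = 15))
  nu <- detect_syllable_nuclei(dd$signal)
  expect_lt(abs(ddk_rate(nu) - 5) / 5, 0.05)
  expect_lt(ddk_reg(nu), 0.01)
  di <- synth_ddk(ddk_spec(rate_syll = 5, irregularity = 0.05, n_bursts = 20,
                           seed = 29))
  nui <- detect_syllable_nuclei(di$signal)
  expect_lt(abs(ddk_reg(nui) - sd(di$truth$intervals)), 0.015)
  d0 <- synth_ddk(ddk_spec(n_bursts = 0))
  expect_equal(length(detect_syllable_nuclei(d0$signal)$nuclei), 0)
})

test_that("read-speech truth is recovered: pauses, NST, SPIR, rates", {
  rs <- synth_read_speech(read_speech_spec(n_pauses = 3, pause_dur = 0.5,
                                           net_time = 12, phone_count = 300,
                                           seed = 30))
  seg <- detect_pauses(rs$signal)
  expect_equal(sum(seg$segments$label == "pause"), 3)
  expect_lt(abs(seg$net_time - 12), 0.5)
  expect_lt(abs(spir(seg) - 3 / (rs$truth$TST / 60)) / (3 / (rs$truth$TST / 60)),
            0.05)
  rates <- speech_rates(seg, 300)
  expect_lt(abs(rates["TSR"] - 300 / rs$truth$TST) / (300 / rs$truth$TST), 0.05)
  expect_lt(abs(rates["NSR"] - 300 / rs$truth$NST) / (300 / rs$truth$NST), 0.05)
  # flat intensity -> relSEOSD near zero
  rs0 <- synth_read_speech(read_speech_spec(intensity_cv = 0, n_pauses = 1,
                                            net_time = 6, seed = 31))
  seg0 <- detect_pauses(rs0$signal)
  expect_lt(rel_seo_sd(energy_contour(rs0$signal), seg0), 0.02)
})

test_that("planted rho survives partialling; discretisation attenuates it", {
  co <- synth_cohort(cohort_spec(n_subjects = 4000, seed = 32,
    planted = data.frame(feature = "F1IR_TSK10", item = "Q3", rho = -0.5)))
  covs <- hd_config()$covariates
  ses1 <- co$cohort[co$cohort$session == 1, ]
  # against the continuous latent item the planted value is exact
  r_lat <- partial_corr(co$features$F1IR_TSK10, co$truth$item_latent[, "Q3"],
                        ses1[covs], "pearson")$estimate
  expect_lt(abs(r_lat - (-0.5)), 0.04)
  # against the discretised 0-4 item it is attenuated but present
  r_obs <- partial_corr(co$features$F1IR_TSK10, ses1$Q3,
                        ses1[covs], "pearson")$estimate
  expect_lt(r_obs, -0.35)
  expect_gt(abs(r_lat), abs(r_obs) - 0.02)
})

test_that("impossible planted structures fail loudly", {
  expect_error(synth_cohort(cohort_spec(n_subjects = 20, seed = 1,
    planted = data.frame(feature = c("jitter_TSK4", "jitter_TSK4"),
                         item = c("Q3", "Q4"), rho = c(0.95, -0.95)))),
    "positive definite")
  expect_error(cohort_spec(planted = data.frame(feature = "a", item = "Q3",
                                                rho = 1.2)), "rho")
  expect_error(synth_cohort(cohort_spec(n_subjects = 20, seed = 1,
    planted = data.frame(feature = "nope", item = "Q3", rho = 0.4))),
    "unknown")
})

test_that("cohort tables respect the questionnaire scale invariants", {
  co <- synth_cohort(cohort_spec(n_subjects = 50, seed = 33))
  for (it in c("Q3", "Q4", "Q5", "Q6"))
    expect_true(all(co$cohort[[it]] %in% 0:4))
  expect_true(all(co$cohort$total >= 0 & co$cohort$total <= 16))
  expect_equal(co$cohort$total,
               with(co$cohort, Q3 + Q4 + Q5 + Q6))
  expect_equal(nrow(co$cohort), 100)   # two sessions per subject
})
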