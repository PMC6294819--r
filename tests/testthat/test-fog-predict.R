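test_that("metrics agree with the direct-formula oracle", {
  # worked example: y = [0,4], yhat = [1,1], r = 4
  m <- fog_metrics(c(0, 4), c(1, 1), scale_range = 4)
  expect_equal(m$mae, 2)
  expect_equal(m$rmse, sqrt(5))
  expect_equal(m$eer, 50)
  expect_equal(m$sse, 10)
  expect_equal(m$r2, 1 - 10 / 8)
  # perfect prediction and mean predictor
  mp <- fog_metrics(c(1, 2, 3), c(1, 2, 3), 2)
  expect_equal(unlist(mp[c("mae", "rmse", "eer", "sse")]), rep(0, 4),
               ignore_attr = TRUE)
  expect_equal(mp$r2, 1)
  y <- c(2, 5, 8, 3)
  expect_equal(fog_metrics(y, rep(mean(y), 4))$r2, 0)
  # random vectors against the oracle
  set.seed(9)
  for (i in 1:10) {
    y <- rnorm(30); yh <- rnorm(30); r <- diff(range(y))
    expect_equal(unlist(fog_metrics(y, yh, r)), unlist(oracle_metrics(y, yh, r)),
                 tolerance = 1e-12)
  }
  expect_error(fog_metrics(rep(1, 5), rnorm(5)), "constant")
})

test_that("RMSE >= MAE with equality iff all absolute errors equal", {
  set.seed(10)
  for (i in 1:20) {
    y <- rnorm(25); yh <- rnorm(25)
    m <- fog_metrics(y, yh, diff(range(y)))
    expect_gte(m$rmse, m$mae - 1e-12)
  }
  m <- fog_metrics(c(0, 2, 4), c(1, 3, 3), 4)   # all |err| = 1
  expect_equal(m$rmse, m$mae, tolerance = 1e-12)
})

test_that("EER is linear in the error scale at fixed range", {
  y <- c(0, 1, 2, 3, 4)
  e <- c(0.1, -0.2, 0.3, -0.1, 0.2)
  m1 <- fog_metrics(y, y + e, 4)
  m3 <- fog_metrics(y, y + 3 * e, 4)
  expect_equal(m3$eer, 3 * m1$eer, tolerance = 1e-12)
})

test_that("stratified folds are deterministic, sized and proportionate", {
  set.seed(11)
  y <- rnorm(40)
  f1 <- stratified_folds(y, 10, seed = 4)
  f2 <- stratified_folds(y, 10, seed = 4)
  expect_identical(f1, f2)
  expect_equal(unname(table(f1)), rep(4L, 10), ignore_attr = TRUE)
  # binary response: per-fold class counts within 1 of proportional
  yb <- rep(c(0, 1), c(30, 10))
  fb <- stratified_folds(yb, 5, seed = 2)
  counts <- table(fb, yb)
  expect_true(all(abs(counts[, "1"] - 2) <= 1))
  expect_error(stratified_folds(rnorm(5), 10, 1), "folds")
})

test_that("greedy selection finds the informative feature and respects caps", {
  co <- synth_cohort(cohort_spec(n_subjects = 80, seed = 12, noise_sd = 0.3,
    delta_weights = list(total = c(F1IR_TSK10 = 1.0))))
  cfg <- hd_config(repetitions = 5, selection_reps = 2)
  sel <- select_features(co$features, "dtotal",
                         c("F1IR_TSK10", "jitter_TSK4", "MPT_TSK3"), cfg, 5)
  expect_equal(sel[1], "F1IR_TSK10")
  # all-noise candidates stall quickly
  sel0 <- select_features(co$features, "dQ3",
                          c("jitter_TSK4", "MPT_TSK3", "DDKrate_TSK5"), cfg, 5)
  expect_lte(length(sel0), 2)
  cfg1 <- hd_config(repetitions = 5, selection_reps = 2, selection_cap = 1)
  sel1 <- select_features(co$features, "dtotal",
                          c("F1IR_TSK10", "jitter_TSK4"), cfg1, 5)
  expect_length(sel1, 1)
})

test_that("repeated CV: learnable targets fit, independent targets do not", {
  co <- synth_cohort(cohort_spec(n_subjects = 80, seed = 13, noise_sd = 1e-4,
    delta_weights = list(total = c(F1IR_TSK10 = 1.0))))
  cfg <- hd_config(repetitions = 10)
  fit <- fog_cv(co$features, "dtotal", c("F1IR_TSK10", "jitter_TSK4"),
                select = FALSE, config = cfg, seed = 3)
  expect_gt(fit$metrics$mean[fit$metrics$metric == "r2"], 0.9)
  null_fit <- fog_cv(co$features, "dQ4", c("F1IR_TSK10", "jitter_TSK4"),
                     select = FALSE, config = cfg, seed = 3)
  expect_lt(null_fit$metrics$mean[null_fit$metrics$metric == "r2"], 0.05)
  # EER of the null fit is near the mean-predictor baseline
  y <- null_fit$y
  base_eer <- 100 * mean(abs(y - mean(y))) / diff(range(y))
  expect_lt(abs(null_fit$metrics$mean[null_fit$metrics$metric == "eer"] -
                  base_eer) / base_eer, 0.15)
})

test_that("every subject is predicted exactly once per repetition", {
  co <- synth_cohort(cohort_spec(n_subjects = 40, seed = 14,
    delta_weights = list(total = c(jitter_TSK4 = 0.8))))
  cfg <- hd_config(repetitions = 3)
  fit <- fog_cv(co$features, "dtotal", c("jitter_TSK4", "MPT_TSK3"),
                select = FALSE, config = cfg, seed = 6)
  expect_equal(dim(fit$predictions), c(3, 40))
  expect_false(any(is.na(fit$predictions)))
})

test_that("the fitted model object supports the standard methods", {
  co <- synth_cohort(cohort_spec(n_subjects = 40, seed = 15, noise_sd = 0.2,
    delta_weights = list(total = c(jitter_TSK4 = 1.0))))
  cfg <- hd_config(repetitions = 3)
  fit <- fog_cv(co$features, "dtotal", c("jitter_TSK4", "MPT_TSK3"),
                select = FALSE, config = cfg, seed = 7)
  expect_s3_class(fit, "fog_cv")
  expect_output(print(fit), "fog_cv")
  expect_length(fitted(fit), 40)
  expect_equal(residuals(fit), fit$y - fitted(fit), ignore_attr = TRUE)
  expect_named(coef(fit), fit$selected, ignore.order = TRUE)
  pred <- predict(fit, co$features[1:5, ])
  expect_length(pred, 5)
  f <- withr::local_tempfile(fileext = ".png")
  grDevices::png(f); plot(fit); grDevices::dev.off()
  expect_true(file.exists(f))
  # same master seed twice -> identical report
  fit2 <- fog_cv(co$features, "dtotal", c("jitter_TSK4", "MPT_TSK3"),
                 select = FALSE, config = cfg, seed = 7)
  expect_identical(fit$metrics, fit2$metrics)
  expect_identical(fit$predictions, fit2$predictions)
})

test_that("achieved RMSE approaches the planted noise SD as n grows", {
  rmse_at <- function(n, seed) {
    co <- synth_cohort(cohort_spec(n_subjects = n, seed = seed, noise_sd = 0.4,
      delta_weights = list(total = c(F1IR_TSK10 = 1.0, jitter_TSK4 = 0.6))))
    cfg <- hd_config(repetitions = 3)
    fit <- fog_cv(co$features, "dtotal", c("F1IR_TSK10", "jitter_TSK4"),
                  select = FALSE, config = cfg, seed = 8)
    fit$metrics$mean[fit$metrics$metric == "rmse"]
  }
  r <- vapply(c(50, 200, 1000), rmse_at, 0, seed = 16)
  excess <- r - 0.4
  expect_lt(excess[3], 0.5 * excess[1])   # excess error shrinks with n
  expect_lt(r[3], 0.4 * 1.35)             # within 35% of the noise SD
  expect_gt(min(r), 0.4 * 0.98)           # never below the noise floor
})
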