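# Shared fixtures built in code. Short durations keep the suite fast; the
# sampling rate stays at the protocol's 48 kHz where cycle-level accuracy
# matters and drops to 16 kHz for cheap frame-level checks.

sine_signal <- function(freq, dur = 1, amp = 0.5, rate = 48000) {
  audio_signal(amp * sin(2 * pi * freq * seq(0, dur, by = 1 / rate)), rate)
}

saw_signal <- function(freq, dur = 1, amp = 0.4, rate = 48000) {
  t <- seq(0, dur, by = 1 / rate)
  audio_signal(amp * (2 * ((freq * t) %% 1) - 1), rate)
}

# direct-arithmetic five-point perturbation quotient (independent oracle)
oracle_ppq5 <- function(v) {
  n <- length(v)
  dev <- numeric(0)
  for (i in 3:(n - 2)) {
    dev <- c(dev, abs(v[i] - mean(v[(i - 2):(i + 2)])))
  }
  100 * mean(dev) / mean(v)
}

# sample SD oracle (the pipeline-wide descriptive convention)
oracle_sd <- function(x) sqrt(sum((x - mean(x))^2) / (length(x) - 1))

# brute-force Kendall tau-b by explicit pair counting
oracle_tau_b <- function(x, y) {
  n <- length(x)
  conc <- disc <- tx <- ty <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    dx <- x[i] - x[j]; dy <- y[i] - y[j]
    if (dx == 0 && dy == 0) next
    if (dx == 0) tx <- tx + 1
    else if (dy == 0) ty <- ty + 1
    else if (dx * dy > 0) conc <- conc + 1
    else disc <- disc + 1
  }
  (conc - disc) / sqrt((conc + disc + tx) * (conc + disc + ty))
}

# direct evaluation of the five evaluation metrics
oracle_metrics <- function(y, yhat, r) {
  n <- length(y)
  sse <- sum((y - yhat)^2)
  list(mae = sum(abs(y - yhat)) / n,
       rmse = sqrt(sum((y - yhat)^2) / n),
       eer = 100 * sum(abs(y - yhat)) / (n * r),
       sse = sse,
       r2 = 1 - sse / sum((y - mean(y))^2))
}
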