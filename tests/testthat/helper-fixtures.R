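# Shared fixtures and independent oracles for the test suite.

# A pure sinusoid signal on one axis at 30 Hz.
make_sine_signal <- function(freq_hz, amplitude_g, minutes = 2, fs = 30,
                             axis = "x", offset = 0, record_id = "sine") {
  t <- (seq_len(minutes * 60 * fs) - 1) / fs
  v <- amplitude_g * sin(2 * pi * freq_hz * t) + offset
  vals <- list(x = 0, y = 0, z = 0)
  vals[[axis]] <- v
  raw_accel(time = t, x = vals$x, y = vals$y, z = vals$z,
            record_id = record_id, sample_rate_hz = fs)
}

# Frozen oracle values for the reference count chain: 2-min, 30 Hz, 2 Hz
# sinusoid of 0.5 g amplitude, computed once with an independent
# scipy.signal implementation of the published algorithm.
frozen_sine_counts <- c(231L, 246L, 246L, 247L, rep(248L, 116L))

# Independent ICC oracle: two-way mean squares via stats::aov on long data.
icc_oracle_aov <- function(m) {
  long <- data.frame(
    y = as.vector(m),
    subject = factor(rep(seq_len(nrow(m)), ncol(m))),
    rater = factor(rep(seq_len(ncol(m)), each = nrow(m)))
  )
  fit <- stats::aov(y ~ subject + rater, data = long)
  ms <- summary(fit)[[1]][["Mean Sq"]]
  names(ms) <- trimws(rownames(summary(fit)[[1]]))
  k <- ncol(m)
  msr <- ms[["subject"]]
  mse <- ms[["Residuals"]]
  list(single = (msr - mse) / (msr + (k - 1) * mse),
       average = (msr - mse) / msr)
}

# Pearson correlation written out from first principles.
pearson_manual <- function(a, b) {
  am <- a - mean(a)
  bm <- b - mean(b)
  sum(am * bm) / sqrt(sum(am^2) * sum(bm^2))
}

# A small complete manifest for io tests.
toy_manifest <- function(n = 10) {
  tibble::tibble(
    record_id = sprintf("r%02d", seq_len(n)),
    participant_id = "p1",
    device = "actigraph",
    placement = "wrist",
    configuration = 1,
    speed_kmh = rep_len(study_speeds(), n),
    duration_min = 2
  )
}
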