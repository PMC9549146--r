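test_that("notch filter removes line frequencies and preserves the passband", {
  fs <- 1024
  tt <- seq_len(16 * fs) / fs
  rms <- function(v) sqrt(mean(v^2))
  # evaluate away from the filter-length edge transient
  core <- seq(3 * fs, length(tt) - 3 * fs)

  line <- matrix(sin(2 * pi * 50 * tt), 1)
  out <- notch_filter(line, fs)
  expect_lt(rms(out[1, core]) / rms(line[1, core]), 0.05)

  slow <- matrix(sin(2 * pi * 20 * tt), 1)
  out2 <- notch_filter(slow, fs)
  expect_lt(abs(rms(out2[1, core]) / rms(slow[1, core]) - 1), 0.02)

  zeros <- matrix(0, 2, fs)
  expect_equal(notch_filter(zeros, fs), zeros)

  expect_error(notch_filter(line, fs = 200), "sampling rate")
})

test_that("common average reference subtracts the good-channel mean only", {
  same <- matrix(rnorm(10), 1)[c(1, 1), ]
  expect_equal(common_average_reference(same), matrix(0, 2, 10))

  pm <- rbind(rep(1, 5), rep(-1, 5))
  expect_equal(common_average_reference(pm), pm)

  # 4 channels x 3 samples, channel 4 flagged bad: hand-computed reference
  h <- rbind(c(1, 2, 3), c(3, 2, 1), c(2, 2, 2), c(10, 10, 10))
  good <- c(TRUE, TRUE, TRUE, FALSE)
  ref <- colMeans(h[1:3, ])
  expect_equal(common_average_reference(h, good),
               sweep(h, 2, ref, "-"))
  expect_error(common_average_reference(h, c(TRUE, FALSE, FALSE, FALSE)),
               "good channels")
})

test_that("epoching cuts buffered windows and resamples to 256 Hz", {
  fs <- 4096
  x <- matrix(rnorm(20 * fs), 1)

  e0 <- epoch_and_resample(x, fs, numeric(0))
  expect_equal(dim(e0$data)[1], 0)

  e1 <- epoch_and_resample(x, fs, 5)
  expect_equal(dim(e1$data)[3], round(3.3 * 256))
  expect_equal(e1$fs, 256)

  const <- matrix(5, 1, 20 * fs)
  e2 <- epoch_and_resample(const, fs, c(4, 8))
  expect_equal(max(abs(e2$data - 5)), 0, tolerance = 1e-9)

  expect_warning(e3 <- epoch_and_resample(x, fs, c(0.5, 10)), "edge")
  expect_equal(e3$kept, 2L)
})

test_that("Morlet power peaks at the stimulus frequency and scales quadratically", {
  cfg <- spectral_config(freqs_hz = seq(40, 120, by = 5))
  fs <- 256
  tt <- time_axis(-1.3, 2, fs)
  sig <- sin(2 * pi * 70 * tt)
  epochs <- structure(list(data = array(sig, c(1, 1, length(tt))),
                           fs = fs, time_s = tt, kept = 1L),
                      class = "epoch_set")
  pw <- morlet_power(epochs, cfg)
  profile <- apply(pw$power[1, 1, , ], 1, mean)
  expect_equal(cfg$freqs_hz[which.max(profile)], 70)

  epochs2 <- epochs
  epochs2$data <- epochs$data * 3
  pw2 <- morlet_power(epochs2, cfg)
  expect_equal(pw2$power, pw$power * 9, tolerance = 1e-8)

  set.seed(1)
  epochs3 <- epochs
  epochs3$data <- array(rnorm(length(tt)), c(1, 1, length(tt)))
  pw3 <- morlet_power(epochs3, cfg)
  expect_false(anyNA(pw3$power))

  bad <- spectral_config(freqs_hz = 1:125, target_fs = 256)
  bad$freqs_hz <- 1:200  # above Nyquist
  expect_error(morlet_power(epochs, bad), "Nyquist")
})

test_that("baseline correction maps power to dB relative to the baseline mean", {
  tt <- time_axis(-0.3, 1, 256)
  pw <- array(4, c(2, 1, 3, length(tt)))
  tfr <- structure(list(power = pw, freqs_hz = c(10, 20, 30), time_s = tt,
                        fs = 256), class = "tfr_power")
  out <- baseline_correct(tfr)
  expect_equal(max(abs(out$power)), 0, tolerance = 1e-12)

  # doubling power during the task window gives 10*log10(2) ~ 3.01 dB
  pw2 <- pw
  pw2[, , , tt > 0] <- 8
  tfr2 <- tfr
  tfr2$power <- pw2
  out2 <- baseline_correct(tfr2)
  expect_equal(out2$power[1, 1, 1, sum(tt <= 0) + 1], 10 * log10(2),
               tolerance = 1e-10)

  expect_error(baseline_correct(tfr, c(-5, -4)), "baseline window")
  tfr3 <- tfr
  tfr3$power[1, 1, 2, tt <= 0] <- 0
  expect_error(baseline_correct(tfr3), "trial 1, channel 1, frequency index 2")
})

test_that("gamma traces average the configured band", {
  tt <- time_axis(-0.3, 1, 256)
  freqs <- 50:120
  pw <- array(rep(freqs, each = 1), c(1, 1, length(freqs), length(tt)))
  for (i in seq_along(freqs)) pw[1, 1, i, ] <- freqs[i]
  tfr <- structure(list(power = pw, freqs_hz = freqs, time_s = tt, fs = 256),
                   class = "tfr_power")
  g <- gamma_trace(tfr, c(55, 115))
  expect_equal(unique(as.vector(g)), mean(55:115))
  expect_equal(sum(freqs >= 55 & freqs <= 115), 61)

  toy <- structure(list(power = array(c(1, 2, 6), c(1, 1, 3, 1)),
                        freqs_hz = c(60, 70, 80), time_s = 0, fs = 256),
                   class = "tfr_power")
  expect_equal(as.vector(gamma_trace(toy, c(55, 115))), 3)
  expect_error(gamma_trace(toy, c(300, 400)), "no computed frequencies")
})

test_that("a gamma burst injected in raw voltage is recovered in the right channel and window", {
  # several burst-free channels so the common average reference does not
  # mirror the burst into them
  contacts <- dplyr::bind_rows(
    contact_row(contact = "T1", x = -36, y = 0, z = 2, label = "INSULA"),
    contact_row(contact = paste0("N", 1:8),
                x = -36 - 3.5 * (1:8), y = -52, z = -18,
                label = "FUSIFORM")
  )
  eff <- effect_spec(
    target_structures = tibble::tibble(structure = "INSULA",
                                       hemisphere = "LH"),
    effect_size = 3, effect_window_s = c(0.3, 0.5))
  spec <- cohort_spec(n_subjects = 1, trials_per_condition = c(6, 6),
                      seed = 11)
  raw <- generate_raw(contacts, spec, eff, burst_amp = 2)[[1]]
  gpts <- compute_gpts(raw$signal, raw$fs, raw$events, raw$contacts)
  tt <- gpts[["T1"]]$time_s
  angry <- gpts[["T1"]]$conditions == "angry"
  contrast_t <- colMeans(gpts[["T1"]]$values[angry, , drop = FALSE]) -
    colMeans(gpts[["T1"]]$values[!angry, , drop = FALSE])
  peak_t <- tt[which.max(contrast_t)]
  expect_gte(peak_t, 0.25)
  expect_lte(peak_t, 0.55)
  # burst-free channel shows no comparable contrast
  contrast_n <- colMeans(gpts[["N1"]]$values[angry, , drop = FALSE]) -
    colMeans(gpts[["N1"]]$values[!angry, , drop = FALSE])
  win <- tt >= 0.3 & tt <= 0.5
  expect_gt(mean(contrast_t[win]), 3 * max(abs(mean(contrast_n[win])), 0.5))
})

test_that("the 50 Hz line component is attenuated by more than 20 dB end to end", {
  contacts <- contact_row(contact = "T1", x = -36, y = 0, z = 2)
  spec <- cohort_spec(n_subjects = 1, trials_per_condition = c(3, 3),
                      seed = 3)
  raw <- generate_raw(contacts, spec, effect_spec(), line_amp = 5)[[1]]
  power_50 <- function(v, fs) {
    n <- length(v)
    X <- Mod(fft(v))^2 / n
    f <- (seq_len(n) - 1) / n * fs
    sum(X[abs(f - 50) < 0.5])
  }
  before <- power_50(raw$signal[1, ], raw$fs)
  after <- power_50(notch_filter(raw$signal, raw$fs)[1, ], raw$fs)
  expect_gt(10 * log10(before / after), 20)
})
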