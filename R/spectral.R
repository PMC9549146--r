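#' Spectral preprocessing configuration
#'
#' Parameters of the chain raw voltage -> gamma power traces (GPTs): notch
#' filtering of the 50 Hz mains line and its 100/150 Hz harmonics, common
#' average reference, epoching on \[-0.3, 1\] s around stimulus onset with a
#' 1 s buffer on each edge, resampling to 256 Hz, Morlet time-frequency
#' decomposition on 1..125 Hz, baseline correction, and averaging over the
#' 55-115 Hz gamma band.
#'
#' @param notch_hz Frequencies to notch out (Hz).
#' @param notch_width_hz Stop-band width of each notch (Hz).
#' @param freqs_hz Frequency grid of the wavelet transform (Hz).
#' @param n_cycles Number of wavelet cycles per frequency; the default
#'   `max(3, f/2)` trades temporal for spectral resolution as frequency grows.
#' @param gamma_band_hz Band averaged into the GPT (Hz, inclusive).
#' @param target_fs Sampling rate after resampling (Hz); its Nyquist must
#'   cover the top analysis frequency.
#' @param epoch_window_s Analysis window relative to stimulus onset (s).
#' @param buffer_s Extra signal kept on each epoch edge until after the
#'   wavelet transform, to absorb filtering edge artifacts (s).
#' @param baseline_window_s Window whose mean power defines 0 dB (s).
#' @return A list of class `spectral_config`.
#' @export
spectral_config <- function(notch_hz = c(50, 100, 150),
                            notch_width_hz = 2,
                            freqs_hz = 1:125,
                            n_cycles = function(f) pmax(3, f / 2),
                            gamma_band_hz = c(55, 115),
                            target_fs = 256,
                            epoch_window_s = c(-0.3, 1),
                            buffer_s = 1,
                            baseline_window_s = c(-0.3, 0)) {
  stopifnot(target_fs / 2 >= max(freqs_hz),
            gamma_band_hz[1] >= min(freqs_hz),
            gamma_band_hz[2] <= max(freqs_hz))
  structure(
    list(notch_hz = notch_hz, notch_width_hz = notch_width_hz,
         freqs_hz = freqs_hz, n_cycles = n_cycles,
         gamma_band_hz = gamma_band_hz, target_fs = target_fs,
         epoch_window_s = epoch_window_s, buffer_s = buffer_s,
         baseline_window_s = baseline_window_s),
    class = "spectral_config"
  )
}

#' Sample-aligned time axis
#'
#' Time points k/fs for all integers k with `tmin <= k/fs <= tmax`; t = 0 is
#' always on the grid, which keeps epochs aligned to stimulus onset.
#'
#' @param tmin,tmax Window bounds in seconds.
#' @param fs Sampling rate in Hz.
#' @return Numeric vector of times (s).
#' @export
time_axis <- function(tmin, tmax, fs = 256) {
  seq(ceiling(tmin * fs), floor(tmax * fs)) / fs
}

# FFT convolution of each row of x (channels x samples) with kernel h,
# compensating the group delay of a symmetric odd-length FIR => zero phase.
apply_fir_zerophase <- function(x, h) {
  L <- length(h)
  stopifnot(L %% 2 == 1)
  half <- (L - 1L) / 2L
  n <- ncol(x)
  padlen <- n + 2L * min(half, n)
  nfft <- stats::nextn(padlen + L, 2)
  H <- fft(c(h, rep(0, nfft - L)))
  out <- t(apply(x, 1, function(row) {
    # reflect-pad to soften edge transients
    pad <- c(rev(row[seq_len(min(half, n))]), row,
             rev(row[n - seq_len(min(half, n)) + 1L]))
    np <- length(pad)
    X <- fft(c(pad, rep(0, nfft - np)))
    y <- Re(fft(X * H, inverse = TRUE)) / nfft
    y[(half + min(half, n)) + seq_len(n)]
  }))
  if (nrow(x) == 1) out <- matrix(out, nrow = 1)
  out
}

# Hamming-window FIR band-stop kernels for each notch frequency, convolved
# into a single kernel. Order ~ two seconds of signal so the Hamming
# transition (~3.3 * fs / L ~ 1.65 Hz) fits inside the narrow stop band
# while keeping 55 Hz — the gamma band edge — untouched.
design_notch_fir <- function(fs, notch_hz, width_hz = 2) {
  order <- round(2 * fs)
  if (order %% 2 == 1) order <- order + 1  # even order -> odd length
  h <- 1
  for (f0 in notch_hz) {
    band <- c(f0 - width_hz / 2, f0 + width_hz / 2) / (fs / 2)
    k <- signal::fir1(order, band, type = "stop", window = signal::hamming(order + 1))
    h <- stats::convolve(h, rev(k), type = "open")
  }
  h
}

#' Notch filter mains interference
#'
#' Removes the 50 Hz line component and its 100/150 Hz harmonics with a
#' linear-phase Hamming-window FIR band-stop filter (2 Hz stop-band per notch),
#' applied with exact group-delay compensation so the net phase is zero.
#'
#' @param x Numeric matrix, channels x samples.
#' @param fs Sampling rate (Hz).
#' @param config A [spectral_config()].
#' @return Filtered matrix, same shape.
#' @export
notch_filter <- function(x, fs, config = spectral_config()) {
  if (fs <= 2 * max(config$notch_hz)) {
    abort("sampling rate too low for the configured notch frequencies")
  }
  x <- rbind(x)
  h <- design_notch_fir(fs, config$notch_hz, config$notch_width_hz)
  apply_fir_zerophase(x, h)
}

#' Common average reference
#'
#' Subtracts, at every sample, the mean over the good channels from *every*
#' channel. Bad channels are re-referenced but do not contribute to the
#' reference.
#'
#' @param x Numeric matrix, channels x samples.
#' @param good Logical vector, one entry per channel (default: all good).
#' @return Re-referenced matrix, same shape.
#' @export
common_average_reference <- function(x, good = rep(TRUE, nrow(x))) {
  stopifnot(is.matrix(x), length(good) == nrow(x))
  if (sum(good) < 2) abort("common average reference needs >= 2 good channels")
  ref <- colMeans(x[good, , drop = FALSE])
  sweep(x, 2, ref, "-")
}

# Fourier-domain resampling of a vector to n_out samples (low-pass inherent
# in spectrum truncation).
resample_fft <- function(v, n_out) {
  n <- length(v)
  if (n_out == n) return(v)
  X <- fft(v)
  Y <- complex(length.out = n_out)
  keep <- min(n, n_out)
  hi <- ceiling(keep / 2)          # positive freqs kept (incl. DC)
  lo <- keep - hi                  # negative freqs kept
  Y[seq_len(hi)] <- X[seq_len(hi)]
  if (lo > 0) Y[n_out - seq_len(lo) + 1L] <- X[n - seq_len(lo) + 1L]
  # dividing by the *input* length preserves amplitude; Re() symmetrizes a
  # possibly unpaired Nyquist bin
  Re(fft(Y, inverse = TRUE)) / n
}

#' Cut buffered epochs and resample to the analysis rate
#'
#' Cuts one epoch per stimulus onset covering the analysis window plus the
#' buffer on both sides (\[-1.3, 2\] s at defaults), then resamples each epoch
#' to `config$target_fs` by Fourier-domain resampling (anti-aliasing by
#' construction). Onsets too close to the recording edge are dropped with a
#' warning. Buffers are retained until after the wavelet transform.
#'
#' @param x Continuous signal, channels x samples.
#' @param fs Sampling rate of `x` (Hz).
#' @param onsets_s Stimulus onset times (s).
#' @param config A [spectral_config()].
#' @return A list of class `epoch_set`: `data` (array trials x channels x
#'   samples), `fs`, `time_s` (buffered axis), `kept` (indices of onsets kept).
#' @export
epoch_and_resample <- function(x, fs, onsets_s, config = spectral_config()) {
  x <- rbind(x)
  w <- config$epoch_window_s
  b <- config$buffer_s
  t_out <- time_axis(w[1] - b, w[2] + b, config$target_fs)
  n_out <- length(t_out)
  n_in <- round((w[2] - w[1] + 2 * b) * fs) + 1
  first <- round((onsets_s + w[1] - b) * fs) + 1
  ok <- first >= 1 & (first + n_in - 1) <= ncol(x)
  if (any(!ok)) {
    warn(sprintf("dropping %d trial(s) too close to the recording edge",
                 sum(!ok)))
  }
  kept <- which(ok)
  dat <- array(0, dim = c(length(kept), nrow(x), n_out))
  for (i in seq_along(kept)) {
    seg <- x[, first[kept[i]] + seq_len(n_in) - 1L, drop = FALSE]
    for (ch in seq_len(nrow(x))) {
      dat[i, ch, ] <- resample_fft(seg[ch, ], n_out)
    }
  }
  structure(
    list(data = dat, fs = config$target_fs, time_s = t_out, kept = kept),
    class = "epoch_set"
  )
}

# Half-width (samples) of the truncated Morlet kernel at 5 temporal SDs.
morlet_half_width <- function(f, n_cycles, fs) {
  ceiling(5 * n_cycles / (2 * pi * f) * fs)
}

# Frequency-domain complex Morlet wavelets, one column per frequency.
morlet_bank_fft <- function(freqs, n_cycles, fs, nfft) {
  sapply(seq_along(freqs), function(i) {
    f <- freqs[i]
    sigma_t <- n_cycles[i] / (2 * pi * f)
    half <- min(morlet_half_width(f, n_cycles[i], fs), floor((nfft - 1) / 2))
    tt <- (-half:half) / fs
    w <- exp(-tt^2 / (2 * sigma_t^2)) * exp(2i * pi * f * tt)
    w <- w / sqrt(sum(Mod(w)^2))  # unit energy
    fft(c(w[(half + 1):(2 * half + 1)], rep(0, nfft - 2 * half - 1),
          w[1:half]))  # zero-centered kernel
  })
}

#' Morlet time-frequency power
#'
#' Complex Morlet wavelet transform of buffered epochs over the configured
#' frequency grid, returning power cropped back to the analysis window so that
#' convolution edge artifacts fall in the discarded buffers.
#'
#' @param epochs An `epoch_set` from [epoch_and_resample()] (buffered).
#' @param config A [spectral_config()].
#' @return A list of class `tfr_power`: `power` (array trials x channels x
#'   freqs x timepoints), `freqs_hz`, `time_s` (cropped axis), `fs`.
#' @export
morlet_power <- function(epochs, config = spectral_config()) {
  fs <- epochs$fs
  freqs <- config$freqs_hz
  if (max(freqs) > fs / 2) abort("analysis frequency above Nyquist")
  nc <- config$n_cycles(freqs)
  nt <- length(epochs$time_s)
  max_half <- max(morlet_half_width(freqs, nc, fs))
  nfft <- stats::nextn(nt + 2 * max_half, 2)
  W <- morlet_bank_fft(freqs, nc, fs, nfft)
  w <- config$epoch_window_s
  keep <- which(epochs$time_s >= w[1] - 1e-9 & epochs$time_s <= w[2] + 1e-9)
  dims <- dim(epochs$data)
  out <- array(0, dim = c(dims[1], dims[2], length(freqs), length(keep)))
  for (tr in seq_len(dims[1])) {
    for (ch in seq_len(dims[2])) {
      X <- fft(c(epochs$data[tr, ch, ], rep(0, nfft - nt)))
      conv <- mvfft(W * X, inverse = TRUE) / nfft
      out[tr, ch, , ] <- t(Mod(conv[keep, , drop = FALSE])^2)
    }
  }
  structure(
    list(power = out, freqs_hz = freqs, time_s = epochs$time_s[keep], fs = fs),
    class = "tfr_power"
  )
}

#' Baseline-correct time-frequency power (dB)
#'
#' For every trial, channel and frequency, divides power by its mean over the
#' baseline window and converts to decibels (10 log10). Power that averages to
#' its own baseline is thus 0 dB.
#'
#' @param tfr A `tfr_power` from [morlet_power()].
#' @param baseline_window_s Baseline window (s); default pre-stimulus
#'   \[-0.3, 0\].
#' @return The `tfr_power` object with corrected power.
#' @export
baseline_correct <- function(tfr, baseline_window_s = c(-0.3, 0)) {
  tt <- tfr$time_s
  sel <- tt >= baseline_window_s[1] - 1e-9 & tt <= baseline_window_s[2] + 1e-9
  if (!any(sel)) abort("baseline window lies outside the epoch time axis")
  base <- apply(tfr$power[, , , sel, drop = FALSE], c(1, 2, 3), mean)
  if (any(base == 0)) {
    bad <- which(base == 0, arr.ind = TRUE)[1, ]
    abort(sprintf(
      "zero baseline mean power at trial %d, channel %d, frequency index %d",
      bad[1], bad[2], bad[3]))
  }
  tfr$power <- 10 * log10(sweep(tfr$power, c(1, 2, 3), base, "/"))
  tfr
}

#' Average power over the gamma band into per-contact traces
#'
#' Averages the (baseline-corrected) power over all frequency rows inside the
#' gamma band (inclusive), yielding one gamma power trace (GPT) per trial per
#' contact — the common input of all three contrast-detection methods.
#'
#' @param tfr A `tfr_power`.
#' @param gamma_band_hz Inclusive band bounds (Hz), default \[55, 115\].
#' @return Array trials x channels x timepoints of gamma power.
#' @export
gamma_trace <- function(tfr, gamma_band_hz = c(55, 115)) {
  rows <- which(tfr$freqs_hz >= gamma_band_hz[1] &
                  tfr$freqs_hz <= gamma_band_hz[2])
  if (!length(rows)) abort("gamma band contains no computed frequencies")
  apply(tfr$power[, , rows, , drop = FALSE], c(1, 2, 4), mean)
}

#' Gamma power trace container
#'
#' Single-contact bundle of per-trial gamma power traces with the time axis,
#' condition labels and contact identity.
#'
#' @param values Numeric matrix, trials x timepoints.
#' @param time_s Strictly increasing time axis (s), length `ncol(values)`.
#' @param conditions Per-trial condition labels (`"angry"`/`"happy"`).
#' @param contact One-row data frame with at least `subject`, `contact`,
#'   `label`, `hemisphere` (may be `NULL` for anonymous traces).
#' @return An object of class `gpt`.
#' @export
gpt <- function(values, time_s, conditions, contact = NULL) {
  values <- rbind(values)
  stopifnot(ncol(values) == length(time_s),
            nrow(values) == length(conditions),
            !is.unsorted(time_s, strictly = TRUE))
  if (anyNA(values)) abort("gamma power traces must not contain missing values")
  structure(
    list(values = values, time_s = time_s,
         conditions = as.character(conditions), contact = contact),
    class = "gpt"
  )
}

#' @export
print.gpt <- function(x, ...) {
  cat(sprintf("<gpt> %d trials x %d timepoints [%.3f, %.3f] s",
              nrow(x$values), ncol(x$values), min(x$time_s), max(x$time_s)))
  if (!is.null(x$contact)) {
    cat(sprintf("  %s/%s (%s, %s)", x$contact$subject, x$contact$contact,
                x$contact$label, x$contact$hemisphere))
  }
  cat("\n")
  invisible(x)
}

#' Full preprocessing chain: continuous voltage to GPTs
#'
#' Notch filter, common average reference, buffered epoching with resampling
#' to 256 Hz, Morlet power, baseline correction, and gamma-band averaging.
#' Only trials flagged correct and artifact-free should be passed in
#' (`events` is filtered on its `correct` and `artifact` columns when
#' present).
#'
#' @param x Continuous signal, channels x samples.
#' @param fs Sampling rate (Hz).
#' @param events Data frame with `onset_s`, `condition`, and optionally
#'   `correct` (logical) and `artifact` (logical).
#' @param contacts Contact table rows matching the channels of `x`, in order
#'   (optional).
#' @param good Logical per-channel mask for the common average reference.
#' @param config A [spectral_config()].
#' @return A named list of [gpt()] objects, one per channel.
#' @export
compute_gpts <- function(x, fs, events, contacts = NULL,
                         good = rep(TRUE, nrow(rbind(x))),
                         config = spectral_config()) {
  x <- rbind(x)
  keep <- rep(TRUE, nrow(events))
  if ("correct" %in% names(events)) keep <- keep & events$correct
  if ("artifact" %in% names(events)) keep <- keep & !events$artifact
  events <- events[keep, , drop = FALSE]
  filtered <- notch_filter(x, fs, config)
  referenced <- common_average_reference(filtered, good)
  epochs <- epoch_and_resample(referenced, fs, events$onset_s, config)
  conditions <- events$condition[epochs$kept]
  tfr <- baseline_correct(morlet_power(epochs, config),
                          config$baseline_window_s)
  g <- gamma_trace(tfr, config$gamma_band_hz)
  n_ch <- dim(g)[2]
  out <- lapply(seq_len(n_ch), function(ch) {
    info <- if (!is.null(contacts)) contacts[ch, , drop = FALSE] else NULL
    gpt(g[, ch, , drop = TRUE], tfr$time_s, conditions, info)
  })
  names(out) <- if (!is.null(contacts)) contacts$contact else
    paste0("ch", seq_len(n_ch))
  out
}
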