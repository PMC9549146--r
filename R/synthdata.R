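#' Synthetic-cohort specification
#'
#' Defaults emulate the study conditions of a 13-subject stereo-EEG cohort:
#' 8-14 depth electrodes per subject with 8-18 contacts each at 3.5 mm
#' spacing, 45-65 artifact-free correct trials per condition, gamma power
#' traces on a \[-0.3, 1\] s axis at 256 Hz, and reaction times with a
#' condition offset (0.97 s angry vs 0.85 s happy on average).
#'
#' @param n_subjects Number of subjects (default 13).
#' @param electrodes_per_subject Range (min, max) of electrodes per subject.
#' @param contacts_per_electrode Range of contacts per electrode.
#' @param contact_spacing_mm Spacing between adjacent contacts of one
#'   electrode (default 3.5 mm).
#' @param trials_per_condition Range of trials per condition per subject.
#' @param noise_sd Standard deviation of the GPT background noise (dB scale).
#' @param rt_mean_s Named mean reaction times per condition (s).
#' @param rt_sd_s Reaction-time SD (s).
#' @param seed Integer seed; all generators are fully deterministic given it.
#' @return A list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects = 13,
                        electrodes_per_subject = c(8, 14),
                        contacts_per_electrode = c(8, 18),
                        contact_spacing_mm = 3.5,
                        trials_per_condition = c(45, 65),
                        noise_sd = 1,
                        rt_mean_s = c(angry = 0.97, happy = 0.85),
                        rt_sd_s = 0.12,
                        seed = 1) {
  stopifnot(n_subjects >= 1, contact_spacing_mm > 0, noise_sd > 0,
            all(rt_mean_s > 0), rt_sd_s > 0)
  structure(
    list(n_subjects = n_subjects,
         electrodes_per_subject = electrodes_per_subject,
         contacts_per_electrode = contacts_per_electrode,
         contact_spacing_mm = contact_spacing_mm,
         trials_per_condition = trials_per_condition,
         noise_sd = noise_sd, rt_mean_s = rt_mean_s, rt_sd_s = rt_sd_s,
         seed = seed),
    class = "cohort_spec"
  )
}

#' Condition-effect specification
#'
#' Describes the ground-truth contrast injected into synthetic gamma power
#' traces: which (structure, hemisphere) pairs carry it, how large it is in
#' units of the noise SD, in which post-stimulus window, and whether it is an
#' amplitude offset (default) or a latency shift between conditions.
#'
#' @param target_structures Tibble with columns `structure`, `hemisphere`;
#'   `NULL` for a pure null cohort.
#' @param effect_size Class mean difference in units of noise SD (0 = null).
#' @param effect_window_s Post-stimulus window carrying the effect (s).
#' @param effect_kind `"amplitude"` or `"latency"`.
#' @param latency_shift_s Shift of the happy-condition response when
#'   `effect_kind = "latency"`.
#' @return A list of class `effect_spec`.
#' @export
effect_spec <- function(target_structures = NULL, effect_size = 0,
                        effect_window_s = c(0.3, 0.6),
                        effect_kind = c("amplitude", "latency"),
                        latency_shift_s = 0.15) {
  effect_kind <- match.arg(effect_kind)
  stopifnot(effect_window_s[1] >= 0, effect_window_s[2] <= 1,
            effect_window_s[1] < effect_window_s[2])
  structure(
    list(target_structures = target_structures, effect_size = effect_size,
         effect_window_s = effect_window_s, effect_kind = effect_kind,
         latency_shift_s = latency_shift_s),
    class = "effect_spec"
  )
}

#' Approximate template-space structure centroids
#'
#' A packaged table of approximate Desikan-Killiany structure centroid
#' coordinates (mm, symmetric across hemispheres). These are synthetic,
#' package-authored approximations intended only to give simulated electrode
#' geometries a realistic spatial layout; they are not atlas measurements.
#'
#' @return Tibble with `structure`, `hemisphere`, `x`, `y`, `z`.
#' @export
dk_centroids <- function() {
  readr::read_tsv(
    system.file("extdata", "dk_centroids_approx.tsv",
                package = "ieegcontrasts", mustWork = TRUE),
    show_col_types = FALSE)
}

#' Generate synthetic electrode geometry
#'
#' Places linear depth-electrode trajectories with equidistant contacts at the
#' configured spacing. Each electrode targets a randomly chosen structure
#' centroid of the subject's implanted hemisphere(s); each contact is labeled
#' by its nearest centroid. Hemisphere coverage mimics a clinical cohort:
#' roughly 7/13 subjects left-only, 2/13 right-only, 4/13 bilateral.
#'
#' @param spec A [cohort_spec()].
#' @param centroids Structure centroid table (default [dk_centroids()]).
#' @return A contact table ([contact_table()]).
#' @export
generate_geometry <- function(spec = cohort_spec(),
                              centroids = dk_centroids()) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (spec$contact_spacing_mm <= 0) abort("contact spacing must be > 0")
  set.seed(spec$seed)
  hemi_type <- sample(c(rep("LH", 7), rep("RH", 2), rep("both", 4)),
                      spec$n_subjects, replace = spec$n_subjects > 13)
  rows <- map(seq_len(spec$n_subjects), function(s) {
    hemis <- if (hemi_type[s] == "both") c("LH", "RH") else hemi_type[s]
    n_el <- sample_range(spec$electrodes_per_subject)
    el_rows <- map(seq_len(n_el), function(e) {
      h <- if (length(hemis) == 1) hemis else sample(hemis, 1)
      cand <- centroids[centroids$hemisphere == h, ]
      target <- cand[sample(nrow(cand), 1), ]
      n_ct <- sample_range(spec$contacts_per_electrode)
      # entry roughly lateral, tip near the target centroid
      dir <- c(if (h == "LH") -1 else 1, rnorm(2, 0, 0.3))
      dir <- dir / sqrt(sum(dir^2))
      tip <- c(target$x, target$y, target$z) + rnorm(3, 0, 2)
      pos <- t(sapply(seq_len(n_ct) - 1,
                      function(k) tip + k * spec$contact_spacing_mm * dir))
      tibble(
        subject = sprintf("SYN%02d", s),
        contact = sprintf("E%d-%d", e, seq_len(n_ct)),
        x = pos[, 1], y = pos[, 2], z = pos[, 3]
      )
    })
    bind_rows(el_rows)
  })
  tbl <- bind_rows(rows)
  # nearest-centroid labeling (hemisphere follows the winning centroid)
  cxyz <- as.matrix(centroids[c("x", "y", "z")])
  xyz <- as.matrix(tbl[c("x", "y", "z")])
  d2 <- outer(rowSums(xyz^2), rep(1, nrow(cxyz))) -
    2 * xyz %*% t(cxyz) + outer(rep(1, nrow(xyz)), rowSums(cxyz^2))
  nearest <- max.col(-d2)
  tbl$label <- centroids$structure[nearest]
  tbl$hemisphere <- centroids$hemisphere[nearest]
  contact_table(tbl)
}

#' Rasterize centroid labels into a label volume
#'
#' Builds a [label_volume()] over a bounding box by assigning every voxel the
#' code of its nearest structure centroid — a consistent companion to
#' [generate_geometry()] for exercising [assign_anatomical_label()].
#'
#' @param centroids Centroid table (`structure`, `hemisphere`, `x`, `y`, `z`).
#' @param bbox_min,bbox_max Length-3 corners of the box (mm).
#' @param voxel_size_mm Isotropic voxel size (default 1 mm).
#' @return A list: `volume` (a [label_volume()]), `origin_mm` (template
#'   coordinate of voxel (0,0,0)).
#' @export
rasterize_label_volume <- function(centroids, bbox_min, bbox_max,
                                   voxel_size_mm = 1) {
  key <- paste(centroids$structure, centroids$hemisphere)
  codes <- seq_along(key)
  gx <- seq(bbox_min[1], bbox_max[1], by = voxel_size_mm)
  gy <- seq(bbox_min[2], bbox_max[2], by = voxel_size_mm)
  gz <- seq(bbox_min[3], bbox_max[3], by = voxel_size_mm)
  grid <- as.matrix(expand.grid(x = gx, y = gy, z = gz))
  cxyz <- as.matrix(centroids[c("x", "y", "z")])
  d2 <- outer(rowSums(grid^2), rep(1, nrow(cxyz))) -
    2 * grid %*% t(cxyz) + outer(rep(1, nrow(grid)), rowSums(cxyz^2))
  vox <- array(codes[max.col(-d2)],
               dim = c(length(gx), length(gy), length(gz)))
  vol <- label_volume(vox, setNames(centroids$structure, codes),
                      rep(voxel_size_mm, 3))
  list(volume = vol, origin_mm = as.numeric(bbox_min))
}

# sample() treats a scalar first argument as 1:n; draw from integer ranges
# explicitly to avoid that
sample_range <- function(rng, n = 1) {
  vals <- seq(rng[1], rng[2])
  if (length(vals) == 1) rep(vals, n) else sample(vals, n, replace = TRUE)
}

# Temporally smoothed Gaussian noise (moving average ~50 ms) rescaled to unit
# SD, mimicking the autocorrelation of gamma power traces.
smooth_noise <- function(n_trials, n_time, fs = 256, smooth_s = 0.05) {
  k <- max(1, round(smooth_s * fs))
  raw <- matrix(rnorm(n_trials * (n_time + k)), n_trials)
  sm <- t(apply(raw, 1, function(v) {
    as.vector(stats::filter(v, rep(1 / k, k), sides = 1))[-seq_len(k)]
  }))
  sm / sqrt(1 / k)  # moving average of N(0,1) has SD 1/sqrt(k)
}

#' Generate synthetic gamma power traces for a cohort
#'
#' Produces baseline-corrected-scale GPTs: temporally smoothed Gaussian noise
#' (SD `spec$noise_sd`), with contacts in the effect's target structures
#' receiving an additive offset of `effect_size * noise_sd` in the angry
#' condition inside the effect window (or a latency-shifted response under
#' `effect_kind = "latency"`). Per-trial reaction times are drawn per
#' condition from a truncated normal.
#'
#' @param contacts A contact table (e.g. from [generate_geometry()]).
#' @param spec A [cohort_spec()].
#' @param effect An [effect_spec()].
#' @return A list: `gpts` (named list of [gpt()], names `subject/contact`),
#'   `events` (tibble `subject`, `trial`, `condition`, `rt_s`, `correct`,
#'   `artifact`), `truth` (the effect spec plus target contact ids).
#' @export
generate_gpts <- function(contacts, spec = cohort_spec(),
                          effect = effect_spec()) {
  contacts <- contact_table(contacts)
  targets <- effect$target_structures
  if (!is.null(targets)) {
    known <- paste(contacts$label, contacts$hemisphere)
    miss <- setdiff(paste(targets$structure, targets$hemisphere), known)
    if (length(miss)) {
      abort(paste0("target structure(s) not present in the cohort: ",
                   paste(miss, collapse = "; ")))
    }
  }
  set.seed(spec$seed + 1L)
  tt <- time_axis(-0.3, 1, 256)
  n_time <- length(tt)
  in_window <- tt >= effect$effect_window_s[1] & tt <= effect$effect_window_s[2]
  shifted_window <- tt >= effect$effect_window_s[1] + effect$latency_shift_s &
    tt <= effect$effect_window_s[2] + effect$latency_shift_s
  is_target <- if (is.null(targets)) rep(FALSE, nrow(contacts)) else
    paste(contacts$label, contacts$hemisphere) %in%
      paste(targets$structure, targets$hemisphere)

  gpts <- list()
  events <- list()
  for (s in unique(contacts$subject)) {
    sub <- contacts[contacts$subject == s, ]
    n_per <- sample_range(spec$trials_per_condition, 2)
    conditions <- c(rep("angry", n_per[1]), rep("happy", n_per[2]))
    n_tr <- length(conditions)
    rt <- numeric(n_tr)
    for (cond in c("angry", "happy")) {
      idx <- conditions == cond
      r <- rnorm(sum(idx), spec$rt_mean_s[[cond]], spec$rt_sd_s)
      r[r < 0.1] <- 0.1
      rt[idx] <- r
    }
    events[[s]] <- tibble(subject = s, trial = seq_len(n_tr),
                          condition = conditions, rt_s = rt,
                          correct = TRUE, artifact = FALSE)
    for (i in seq_len(nrow(sub))) {
      v <- smooth_noise(n_tr, n_time) * spec$noise_sd
      if (is_target[which(contacts$subject == s)[i]] &&
          effect$effect_size != 0) {
        bump <- effect$effect_size * spec$noise_sd
        if (effect$effect_kind == "amplitude") {
          v[conditions == "angry", in_window] <-
            v[conditions == "angry", in_window] + bump
        } else {
          v[conditions == "angry", in_window] <-
            v[conditions == "angry", in_window] + bump
          v[conditions == "happy", shifted_window] <-
            v[conditions == "happy", shifted_window] + bump
        }
      }
      key <- paste(s, sub$contact[i], sep = "/")
      gpts[[key]] <- gpt(v, tt, conditions, sub[i, , drop = FALSE])
    }
  }
  truth <- list(effect = effect,
                target_contacts = paste(contacts$subject,
                                        contacts$contact, sep = "/")[is_target])
  list(gpts = gpts, events = bind_rows(events), truth = truth)
}

# 1/f (pink) noise via FFT spectral shaping, unit SD.
pink_noise <- function(n) {
  X <- fft(rnorm(n))
  f <- c(1, seq_len(n - 1))
  f <- pmin(f, n - f + 1)
  X <- X / sqrt(f)
  v <- Re(fft(X, inverse = TRUE)) / n
  as.vector(scale(v))
}

# Band-limited burst: white noise FFT-filtered to [55, 115] Hz, Hann-windowed.
band_burst <- function(n, fs, band = c(55, 115)) {
  X <- fft(rnorm(n))
  f <- (seq_len(n) - 1) / n * fs
  f <- pmin(f, fs - f)
  X[f < band[1] | f > band[2]] <- 0
  v <- Re(fft(X, inverse = TRUE)) / n
  as.vector(scale(v)) * 0.5 * (1 - cos(2 * pi * seq_len(n) / (n + 1)))
}

#' Generate continuous synthetic voltage recordings
#'
#' Emulates raw stereo-EEG at 4096 Hz: pink-noise background per channel, an
#' additive 50 Hz line component, and condition-dependent 55-115 Hz
#' band-limited bursts inside the effect window on target contacts during
#' angry trials — exercising the whole spectral chain end-to-end.
#'
#' @param contacts A contact table (one subject's worth of channels is
#'   generated per subject present).
#' @param spec A [cohort_spec()].
#' @param effect An [effect_spec()].
#' @param fs Sampling rate (default 4096 Hz).
#' @param line_amp Amplitude of the 50 Hz line component (0 disables it).
#' @param burst_amp Burst amplitude in units of background SD.
#' @param iti_s Interval between stimulus onsets (s).
#' @return A named list per subject: `signal` (channels x samples), `fs`,
#'   `events` (with `onset_s`), `contacts`.
#' @export
generate_raw <- function(contacts, spec = cohort_spec(),
                         effect = effect_spec(), fs = 4096,
                         line_amp = 2, burst_amp = 3, iti_s = 4) {
  contacts <- contact_table(contacts)
  set.seed(spec$seed + 2L)
  is_target <- if (is.null(effect$target_structures)) {
    rep(FALSE, nrow(contacts))
  } else {
    paste(contacts$label, contacts$hemisphere) %in%
      paste(effect$target_structures$structure,
            effect$target_structures$hemisphere)
  }
  out <- list()
  for (s in unique(contacts$subject)) {
    sub_idx <- which(contacts$subject == s)
    sub <- contacts[sub_idx, ]
    n_per <- sample_range(spec$trials_per_condition, 2)
    conditions <- sample(c(rep("angry", n_per[1]), rep("happy", n_per[2])))
    n_tr <- length(conditions)
    onsets <- 2.5 + (seq_len(n_tr) - 1) * iti_s
    n_samp <- ceiling((max(onsets) + 3) * fs)
    sig <- matrix(0, nrow(sub), n_samp)
    tline <- seq_len(n_samp) / fs
    w <- effect$effect_window_s
    burst_len <- round((w[2] - w[1]) * fs)
    for (ch in seq_len(nrow(sub))) {
      v <- pink_noise(n_samp) +
        line_amp * sin(2 * pi * 50 * tline + runif(1, 0, 2 * pi))
      if (is_target[sub_idx][ch]) {
        for (tr in which(conditions == "angry")) {
          i0 <- round((onsets[tr] + w[1]) * fs)
          v[i0 + seq_len(burst_len)] <- v[i0 + seq_len(burst_len)] +
            burst_amp * band_burst(burst_len, fs)
        }
      }
      sig[ch, ] <- v
    }
    rt <- rnorm(n_tr, spec$rt_mean_s[ifelse(conditions == "angry",
                                            "angry", "happy")], spec$rt_sd_s)
    out[[s]] <- list(
      signal = sig, fs = fs, contacts = sub,
      events = tibble(subject = s, trial = seq_len(n_tr),
                      onset_s = onsets, condition = conditions,
                      rt_s = pmax(rt, 0.1), correct = TRUE, artifact = FALSE)
    )
  }
  out
}
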