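#' Configuration for the synthetic speech-EEG generator
#'
#' Defaults emulate the study conditions the analysis assumes: 25 speech
#' segments of about 45.7 s, EEG sampled at 16,384 Hz, 32 scalp plus 4
#' auxiliary electrodes, pink (1/f) and white background noise, 50 Hz
#' line noise with harmonics at 100 and 150 Hz, and sporadic blink
#' artifacts. Amplitudes are in microvolts. `snr_db`, when set, rescales
#' the summed noise so that var(signal)/var(noise) matches the requested
#' ratio on the generated record (an SNR dial for recovery experiments).
#'
#' @param n_segments number of speech segments (>= 1).
#' @param segment_duration_s segment duration in seconds.
#' @param fs_eeg EEG sampling rate in Hz.
#' @param fs_feature feature sampling rate in Hz (defaults to `fs_eeg`).
#' @param n_channels number of scalp channels (<= 32).
#' @param noise_pink_sd,noise_white_sd noise standard deviations, µV.
#' @param line_noise_amp 50 Hz amplitude, µV (harmonics scaled 0.4, 0.2).
#' @param blink_rate_hz blink events per second.
#' @param blink_amp blink amplitude at the EOG, µV.
#' @param silence_s near-silent lead-in retained at each segment onset,
#'   seconds (stimulus-onset jitter stand-in).
#' @param snr_db target signal-to-noise ratio in dB, or `NULL` to use the
#'   raw noise levels.
#' @param seed master random seed.
#' @return an object of class `synth_config` (a validated list).
#' @export
synth_config <- function(n_segments = 25, segment_duration_s = 45.7,
                         fs_eeg = 16384, fs_feature = NULL,
                         n_channels = 32, noise_pink_sd = 8,
                         noise_white_sd = 4, line_noise_amp = 5,
                         blink_rate_hz = 0.2, blink_amp = 120,
                         silence_s = 0.467, snr_db = NULL, seed = 1L) {
  if (is.null(fs_feature)) fs_feature <- fs_eeg
  cfg <- list(n_segments = n_segments,
              segment_duration_s = segment_duration_s,
              fs_eeg = fs_eeg, fs_feature = fs_feature,
              n_channels = n_channels, noise_pink_sd = noise_pink_sd,
              noise_white_sd = noise_white_sd,
              line_noise_amp = line_noise_amp,
              blink_rate_hz = blink_rate_hz, blink_amp = blink_amp,
              silence_s = silence_s, snr_db = snr_db,
              seed = as.integer(seed))
  with(cfg, {
    if (n_segments < 1) stop("`n_segments` must be >= 1")
    if (segment_duration_s <= 0 || fs_eeg <= 0 || fs_feature <= 0) {
      stop("durations and rates must be positive")
    }
    if (n_channels < 1 || n_channels > 32) {
      stop("`n_channels` must be between 1 and 32")
    }
    if (any(c(noise_pink_sd, noise_white_sd, line_noise_amp,
              blink_rate_hz) < 0)) {
      stop("noise parameters must be non-negative")
    }
  })
  structure(cfg, class = "synth_config")
}

#' Generate a synthetic stimulus feature
#'
#' A non-negative regressor with broadband fast fluctuations whose
#' envelope is modulated in the 2-8 Hz syllable-rate band, preceded by a
#' near-silent lead-in of `silence_s` seconds (stimulus-onset jitter
#' stand-in). The series is normalized to unit standard deviation over
#' the non-silent part. Deterministic given `seed`.
#'
#' @param duration_s duration in seconds (> 0).
#' @param fs sampling rate in Hz (> 0).
#' @param seed random seed.
#' @param silence_s lead-in duration in seconds.
#' @param segment_id passed to [feature_series()].
#' @return a [feature_series()].
#' @export
generate_feature <- function(duration_s, fs, seed, silence_s = 0.4,
                             segment_id = NA_character_) {
  if (duration_s <= 0) stop("`duration_s` must be positive")
  if (fs <= 0) stop("`fs` must be positive")
  n <- round(duration_s * fs)
  withr_seed <- .preserve_seed()
  on.exit(.restore_seed(withr_seed))
  set.seed(as.integer(seed))
  carrier <- abs(rnorm(n))
  # slow 2-8 Hz envelope modulator, built at a low rate and interpolated
  fs_mod <- 64
  nm <- max(ceiling(duration_s * fs_mod) + 8L, 32L)
  bp <- signal::butter(2, c(2, 8) / (fs_mod / 2), type = "pass")
  m <- signal::filtfilt(bp, rnorm(nm))
  m <- m / max(sd(m), 1e-12)
  mod <- approx(x = seq(0, by = 1 / fs_mod, length.out = nm),
                y = m, xout = seq(0, by = 1 / fs, length.out = n),
                rule = 2)$y
  env <- pmax(1 + 0.8 * mod, 0)
  x <- carrier * env
  n_sil <- min(round(silence_s * fs), n)
  if (n_sil > 0) {
    gate <- rep(1, n)
    gate[seq_len(n_sil)] <- 1e-3
    n_ramp <- min(round(0.05 * fs), n - n_sil)
    if (n_ramp > 1) {
      gate[n_sil + seq_len(n_ramp)] <-
        seq(1e-3, 1, length.out = n_ramp)
    }
    x <- x * gate
  }
  live <- x[(n_sil + 1L):n]
  x <- x / max(sd(live), 1e-12)
  feature_series(x, fs = fs, segment_id = segment_id)
}

#' Ground-truth response kernels for simulation
#'
#' Builds a subcortical kernel (lags -10 to 30 ms) with a single dominant
#' positive wave V-like peak, and a cortical kernel (lags -300 to 600 ms)
#' with a signed P1-N1-P2 complex, formed as sums of Gaussian bumps. The
#' cortical lag x channel kernel is the outer product of the waveform and
#' per-channel topography weights that peak over the frontotemporal
#' cluster. Amplitudes are in microvolts per unit feature.
#'
#' @param waveV_latency_ms wave V-like peak latency (must lie in
#'   (-10, 30)).
#' @param waveV_amp,waveV_width_ms amplitude and Gaussian width (sd) of
#'   the subcortical peak.
#' @param cortical_latencies_ms named numeric vector with components
#'   `P1`, `N1`, `P2` (each must lie in (-300, 600)).
#' @param cortical_amps signed amplitudes for P1 (+), N1 (-), P2 (+).
#' @param cortical_widths_ms Gaussian widths (sd) of the three bumps.
#' @param fs_sub,fs_cort sampling rates of the two kernels in Hz.
#' @param channels scalp channel labels for the cortical kernel.
#' @param topography per-channel weights; default a smooth falloff from
#'   the frontotemporal cluster (maximal on the cluster labels).
#' @return an object of class `ground_truth_kernels`: `subcortical`
#'   (vector with `lags_ms` attribute), `cortical` (lag x channel matrix
#'   with `lags_ms`), `topography`, and the sampling rates.
#' @export
make_kernels <- function(waveV_latency_ms = 9, waveV_amp = 0.35,
                         waveV_width_ms = 1.2,
                         cortical_latencies_ms = c(P1 = 50, N1 = 91,
                                                   P2 = 170),
                         cortical_amps = c(P1 = 1.5, N1 = -3, P2 = 2.5),
                         cortical_widths_ms = c(P1 = 14, N1 = 20,
                                                P2 = 28),
                         fs_sub = 16384, fs_cort = 16384,
                         channels = NULL, topography = NULL) {
  if (waveV_latency_ms <= -10 || waveV_latency_ms >= 30) {
    stop("`waveV_latency_ms` outside the -10..30 ms lag range")
  }
  if (any(cortical_latencies_ms <= -300 | cortical_latencies_ms >= 600)) {
    stop("cortical latency outside the -300..600 ms lag range")
  }
  gauss_sum <- function(lags_ms, lat, amp, width) {
    out <- numeric(length(lags_ms))
    for (i in seq_along(lat)) {
      out <- out + amp[i] * exp(-0.5 * ((lags_ms - lat[i]) / width[i])^2)
    }
    out
  }
  # integer sample grids, matching lag_design(-0.01, 0.03, fs) exactly
  sub_lags <- seq.int(round(-0.01 * fs_sub), round(0.03 * fs_sub)) /
    fs_sub * 1000
  sub <- gauss_sum(sub_lags, waveV_latency_ms, waveV_amp, waveV_width_ms)
  attr(sub, "lags_ms") <- sub_lags
  cort_lags <- seq.int(round(-0.3 * fs_cort), round(0.6 * fs_cort)) /
    fs_cort * 1000
  wave <- gauss_sum(cort_lags, cortical_latencies_ms, cortical_amps,
                    cortical_widths_ms)
  if (is.null(channels)) {
    mon <- standard_montage()
    channels <- mon$label[mon$type == "scalp"]
  }
  if (is.null(topography)) topography <- .frontotemporal_topography(channels)
  if (length(topography) != length(channels)) {
    stop("`topography` length must match `channels`")
  }
  cort <- outer(as.numeric(wave), as.numeric(topography))
  dimnames(cort) <- list(NULL, channels)
  attr(cort, "lags_ms") <- cort_lags
  structure(
    list(subcortical = sub, cortical = cort,
         topography = setNames(as.numeric(topography), channels),
         fs_sub = fs_sub, fs_cort = fs_cort, channels = channels),
    class = "ground_truth_kernels"
  )
}

# smooth topography peaking on the frontotemporal cluster
.frontotemporal_topography <- function(channels) {
  mon <- standard_montage()
  cl <- frontotemporal_cluster()
  idx <- match(channels, mon$label)
  w <- vapply(seq_along(channels), function(i) {
    if (is.na(idx[i]) || mon$type[idx[i]] != "scalp") return(0)
    d2 <- (mon$x[idx[i]] - mon$x[match(cl, mon$label)])^2 +
          (mon$y[idx[i]] - mon$y[match(cl, mon$label)])^2
    exp(-min(d2) / (2 * 0.35^2))
  }, numeric(1))
  w
}

# broad vertex-positive weighting for the subcortical response
.vertex_topography <- function(channels) {
  mon <- standard_montage()
  idx <- match(channels, mon$label)
  vapply(seq_along(channels), function(i) {
    if (is.na(idx[i]) || mon$type[idx[i]] != "scalp") return(0)
    d2 <- mon$x[idx[i]]^2 + mon$y[idx[i]]^2
    0.25 + 0.75 * exp(-d2 / (2 * 0.5^2))
  }, numeric(1))
}

# frontal-dominant blink projection incl. EOG channels
.blink_topography <- function(channels) {
  mon <- standard_montage()
  idx <- match(channels, mon$label)
  vapply(seq_along(channels), function(i) {
    if (is.na(idx[i])) return(0)
    if (mon$type[idx[i]] == "eog") return(1)
    if (mon$type[idx[i]] == "mastoid") return(0.02)
    exp(-((mon$x[idx[i]])^2 + (mon$y[idx[i]] - 1)^2) / (2 * 0.45^2))
  }, numeric(1))
}

#' Synthesize a multi-channel EEG recording from features and kernels
#'
#' Each epoch is the lagged convolution of the segment's feature with the
#' subcortical kernel (projected with a broad vertex-positive topography)
#' plus the per-channel cortical kernel response, superimposed with pink
#' noise, white noise, 50/100/150 Hz line sinusoids and, on frontal and
#' EOG channels, biphasic blink transients. Returns epochs aligned to
#' feature onset. When `cfg$snr_db` is set, the summed noise is rescaled
#' so the realized var(signal)/var(noise) matches the dial.
#'
#' @param features list of [feature_series()] (one per segment) at the
#'   EEG sampling rate.
#' @param kernels a [make_kernels()] object at the same rate.
#' @param cfg a [synth_config()].
#' @param kernel_scale multiplicative scale of both kernels (the
#'   participant's response gain).
#' @param channels channel labels; default the scalp channels named by
#'   the kernels plus EOG1/EOG2/M1/M2 auxiliaries.
#' @param keep_components keep the noise-free signal and summed noise as
#'   attributes `"signal"` and `"noise"` (epoch x channel x time arrays).
#' @param seed seed for noise and blinks (default `cfg$seed`).
#' @return an `epoch_set` (epoch x channel x time, µV).
#' @export
synthesize_recording <- function(features, kernels, cfg, kernel_scale = 1,
                                 channels = NULL, keep_components = FALSE,
                                 seed = cfg$seed) {
  stopifnot(inherits(cfg, "synth_config"))
  fs <- cfg$fs_eeg
  for (f in features) {
    if (inherits(f, "feature_series") && abs(f$fs - fs) > 1e-9) {
      stop("feature and EEG sampling rates differ")
    }
  }
  if (abs(kernels$fs_sub - fs) > 1e-9 || abs(kernels$fs_cort - fs) > 1e-9) {
    stop("kernel sampling rate differs from the EEG rate")
  }
  scalp <- kernels$channels[seq_len(min(cfg$n_channels,
                                        length(kernels$channels)))]
  if (is.null(channels)) channels <- c(scalp, "EOG1", "EOG2", "M1", "M2")
  nch <- length(channels)
  sub_topo <- .vertex_topography(channels)
  cort_topo <- setNames(numeric(nch), channels)
  cort_topo[scalp] <- kernels$topography[scalp]
  blink_topo <- .blink_topography(channels)
  sub_lag_first <- round(attr(kernels$subcortical, "lags_ms")[1] / 1000 * fs)
  cort_lag_first <- round(attr(kernels$cortical, "lags_ms")[1] / 1000 * fs)
  # recover the pure waveform: divide out the largest topography weight
  ref <- which.max(abs(kernels$topography))
  cort_wave <- kernels$cortical[, ref] / kernels$topography[ref]

  withr_seed <- .preserve_seed()
  on.exit(.restore_seed(withr_seed))
  set.seed(as.integer(seed))

  n_ep <- length(features)
  nt <- length(if (inherits(features[[1]], "feature_series"))
    features[[1]]$values else features[[1]])
  sig <- array(0, dim = c(n_ep, nch, nt))
  noi <- array(0, dim = c(n_ep, nch, nt))
  tvec <- (seq_len(nt) - 1L) / fs
  blink_kernel <- .blink_waveform(fs)
  for (e in seq_len(n_ep)) {
    fv <- if (inherits(features[[e]], "feature_series"))
      features[[e]]$values else as.numeric(features[[e]])
    if (length(fv) != nt) stop("all segments must share one length")
    sub_resp <- if (any(kernels$subcortical != 0)) {
      .conv_lagged(fv, kernel_scale * kernels$subcortical, sub_lag_first)
    } else numeric(nt)
    cort_resp <- if (any(cort_wave != 0)) {
      .conv_lagged(fv, kernel_scale * cort_wave, cort_lag_first)
    } else numeric(nt)
    phase <- runif(3, 0, 2 * pi)
    line <- cfg$line_noise_amp *
      (sin(2 * pi * 50 * tvec + phase[1]) +
       0.4 * sin(2 * pi * 100 * tvec + phase[2]) +
       0.2 * sin(2 * pi * 150 * tvec + phase[3]))
    blink <- numeric(nt)
    n_blinks <- rpois(1, cfg$blink_rate_hz * nt / fs)
    if (n_blinks > 0) {
      onsets <- sort(sample.int(max(nt - length(blink_kernel), 1),
                                n_blinks, replace = TRUE))
      for (o in onsets) {
        idx <- o:min(o + length(blink_kernel) - 1L, nt)
        blink[idx] <- blink[idx] +
          cfg$blink_amp * blink_kernel[seq_along(idx)]
      }
    }
    for (c in seq_len(nch)) {
      sig[e, c, ] <- sub_topo[c] * sub_resp + cort_topo[c] * cort_resp
      ch_noise <- line + blink_topo[c] * blink
      if (cfg$noise_pink_sd > 0) {
        ch_noise <- ch_noise + cfg$noise_pink_sd * .pink_noise(nt)
      }
      if (cfg$noise_white_sd > 0) {
        ch_noise <- ch_noise + rnorm(nt, sd = cfg$noise_white_sd)
      }
      noi[e, c, ] <- ch_noise
    }
  }
  if (!is.null(cfg$snr_db)) {
    vs <- var(as.numeric(sig))
    vn <- var(as.numeric(noi))
    if (vn > 0 && vs > 0) {
      noi <- noi * sqrt(vs / (vn * 10^(cfg$snr_db / 10)))
    }
  }
  ep <- epoch_set(sig + noi, fs = fs, channels = channels, t0 = 0)
  if (keep_components) {
    attr(ep, "signal") <- sig
    attr(ep, "noise") <- noi
  }
  ep
}

# biphasic blink transient, ~400 ms, unit peak
.blink_waveform <- function(fs) {
  tt <- seq(0, 0.45, by = 1 / fs)
  w <- exp(-0.5 * ((tt - 0.15) / 0.05)^2) -
    0.35 * exp(-0.5 * ((tt - 0.28) / 0.07)^2)
  w / max(abs(w))
}

#' Simulate a two-group cohort
#'
#' Generates `n_low + n_normal` synthetic participants. Response-kernel
#' scales are log-normal across participants; the "low" group's scales
#' are multiplied by `1 + effect_delta` (a pure amplitude effect;
#' `latency_shift_ms` optionally also shifts the low group's wave V and
#' cortical latencies). Per-participant seeds derive deterministically
#' from `cfg$seed`, so the same master seed reproduces the same cohort.
#'
#' With `signal = FALSE` the expensive EEG synthesis is skipped and the
#' cohort carries simulated peak-amplitude measurements instead
#' (true scale times the kernel peak amplitude plus measurement noise,
#' plus a per-electrode amplitude matrix for the cluster permutation
#' test); this light mode drives the statistical calibration studies.
#'
#' @param n_low,n_normal group sizes (>= 1).
#' @param effect_delta relative amplitude increase of the low group
#'   (> -1; 0 = null cohort).
#' @param cfg a [synth_config()].
#' @param kernels a [make_kernels()] object (defaults to the standard
#'   component latencies at `cfg$fs_eeg`).
#' @param signal generate full EEG (`TRUE`) or amplitude summaries only.
#' @param scale_sdlog between-participant log-sd of the kernel scale.
#' @param meas_sd measurement noise of light-mode amplitude summaries
#'   (fraction of the base amplitude).
#' @param latency_shift_ms optional latency shift of the low group, ms.
#' @return an object of class `synth_cohort`: `table` (participant
#'   covariates and, in light mode, measured amplitudes), and in full
#'   mode `participants`, a list with per-participant `epochs` and
#'   `features`.
#' @export
generate_cohort <- function(n_low, n_normal, effect_delta = 0, cfg,
                            kernels = NULL, signal = TRUE,
                            scale_sdlog = 0.25, meas_sd = 0.1,
                            latency_shift_ms = 0) {
  if (n_low < 1 || n_normal < 1) stop("group sizes must be >= 1")
  if (effect_delta <= -1) {
    stop("`effect_delta` must exceed -1 (amplitudes must stay positive)")
  }
  stopifnot(inherits(cfg, "synth_config"))
  if (is.null(kernels)) {
    kernels <- make_kernels(fs_sub = cfg$fs_eeg, fs_cort = cfg$fs_eeg)
  }
  n <- n_low + n_normal
  group <- c(rep("low", n_low), rep("normal", n_normal))
  withr_seed <- .preserve_seed()
  on.exit(.restore_seed(withr_seed))
  set.seed(.child_seed(cfg$seed, 0L))
  scale0 <- exp(rnorm(n, 0, scale_sdlog))
  scale <- scale0 * ifelse(group == "low", 1 + effect_delta, 1)
  pta <- pmin(pmax(rnorm(n, mean = 20, sd = 11.5), 0), 60)
  age <- round(pmin(pmax(
    rnorm(n, mean = ifelse(group == "low", 71.7, 68.6),
          sd = ifelse(group == "low", 6.3, 5.3)), 60), 85))
  tab <- data.frame(
    participant = sprintf("P%02d", seq_len(n)),
    group = group, true_scale = scale, pta = pta, age = age,
    stringsAsFactors = FALSE
  )
  cohort <- list(table = tab, cfg = cfg, kernels = kernels,
                 effect_delta = effect_delta)
  if (!signal) {
    waveV_base <- max(kernels$subcortical)
    n1_base <- min(kernels$cortical[, which.max(kernels$topography)])
    p2_idx <- attr(kernels$cortical, "lags_ms") > 120
    p2_base <- max(kernels$cortical[p2_idx, which.max(kernels$topography)])
    noise <- function() rnorm(n, 0, meas_sd)
    tab$waveV_amp <- scale * waveV_base * (1 + noise())
    tab$N1_amp <- scale * n1_base * (1 + noise())
    tab$P2_amp <- scale * p2_base * (1 + noise())
    scalp <- kernels$channels
    topo <- kernels$topography[scalp]
    amp_n1 <- outer(scale * n1_base, topo) *
      (1 + matrix(rnorm(n * length(scalp), 0, meas_sd), n))
    amp_p2 <- outer(scale * p2_base, topo) *
      (1 + matrix(rnorm(n * length(scalp), 0, meas_sd), n))
    cohort$table <- tab
    cohort$electrode_amps <- list(N1 = amp_n1, P2 = amp_p2)
    class(cohort) <- "synth_cohort"
    return(cohort)
  }
  participants <- vector("list", n)
  for (i in seq_len(n)) {
    pseed <- .child_seed(cfg$seed, i)
    feats <- lapply(seq_len(cfg$n_segments), function(s) {
      generate_feature(cfg$segment_duration_s, cfg$fs_eeg,
                       seed = .child_seed(pseed, s),
                       silence_s = cfg$silence_s,
                       segment_id = sprintf("S%02d", s))
    })
    kern_i <- kernels
    if (latency_shift_ms != 0 && group[i] == "low") {
      kern_i <- make_kernels(
        waveV_latency_ms = 9 + latency_shift_ms / 4,
        cortical_latencies_ms = c(P1 = 50, N1 = 91 + latency_shift_ms,
                                  P2 = 170 + latency_shift_ms),
        fs_sub = cfg$fs_eeg, fs_cort = cfg$fs_eeg,
        channels = kernels$channels)
    }
    ep <- synthesize_recording(feats, kern_i, cfg,
                               kernel_scale = scale[i],
                               seed = .child_seed(pseed, 1000L))
    participants[[i]] <- list(features = feats, epochs = ep,
                              group = group[i], true_scale = scale[i])
  }
  cohort$participants <- participants
  class(cohort) <- "synth_cohort"
  cohort
}

#' @export
print.synth_cohort <- function(x, ...) {
  tb <- table(x$table$group)
  cat(sprintf(
    "<synth_cohort> %d participants (low %d / normal %d), delta = %g%s\n",
    nrow(x$table), tb[["low"]], tb[["normal"]], x$effect_delta,
    if (is.null(x$participants)) " [amplitude summaries only]" else ""))
  invisible(x)
}

#' Write a cohort to disk as plain-text artifacts
#'
#' One directory per participant: epochs as one tab-separated channel x
#' time matrix per epoch, a JSON sidecar (sampling rate, channel labels,
#' units µV), features as single-column files; ground-truth kernels as
#' lag-amplitude tables at the cohort root.
#'
#' @param cohort a full-signal [generate_cohort()] result.
#' @param dir output directory (created).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synth_cohort"))
  if (is.null(cohort$participants)) {
    stop("light-mode cohorts carry no signals to write")
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write.table(
    data.frame(lag_ms = attr(cohort$kernels$subcortical, "lags_ms"),
               amplitude = as.numeric(cohort$kernels$subcortical)),
    file.path(dir, "kernel_subcortical.tsv"),
    sep = "\t", row.names = FALSE, quote = FALSE)
  cort <- as.data.frame(cohort$kernels$cortical)
  cort <- cbind(lag_ms = attr(cohort$kernels$cortical, "lags_ms"), cort)
  write.table(cort, file.path(dir, "kernel_cortical.tsv"),
              sep = "\t", row.names = FALSE, quote = FALSE)
  write.table(cohort$table, file.path(dir, "participants.tsv"),
              sep = "\t", row.names = FALSE, quote = FALSE)
  for (i in seq_along(cohort$participants)) {
    p <- cohort$participants[[i]]
    pdir <- file.path(dir, cohort$table$participant[i])
    dir.create(pdir, showWarnings = FALSE)
    ep <- p$epochs
    jsonlite::write_json(
      list(fs = ep$fs, channels = ep$channels, units = "uV",
           n_epochs = dim(ep$data)[1L], t0 = ep$t0),
      file.path(pdir, "epochs.json"), auto_unbox = TRUE, digits = NA)
    for (e in seq_len(dim(ep$data)[1L])) {
      m <- matrix(ep$data[e, , ], nrow = dim(ep$data)[2L])
      rownames(m) <- ep$channels
      write.table(m, file.path(pdir, sprintf("epoch_%02d.tsv", e)),
                  sep = "\t", col.names = FALSE, quote = FALSE)
    }
    for (s in seq_along(p$features)) {
      write_feature_file(p$features[[s]],
                         file.path(pdir, sprintf("feature_%02d.txt", s)))
    }
  }
  invisible(dir)
}
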