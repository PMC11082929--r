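test_that("generated features are non-negative, deterministic and the right length", {
  f1 <- generate_feature(4, 512, seed = 7)
  f2 <- generate_feature(4, 512, seed = 7)
  expect_length(f1$values, 4 * 512)
  expect_true(all(f1$values >= 0))
  expect_identical(f1$values, f2$values)
  expect_false(identical(f1$values, generate_feature(4, 512, seed = 8)$values))
  expect_error(generate_feature(-1, 512, 1), "positive")
  expect_error(generate_feature(4, 0, 1), "positive")
  # leading lead-in is near silent
  lead <- f1$values[seq_len(round(0.3 * 512))]
  expect_lt(max(lead), 0.05 * max(f1$values))
})

test_that("feature envelope modulation peaks in the 2-8 Hz syllable band", {
  fs <- 512
  f <- generate_feature(30, fs, seed = 3)
  # independent oracle: smooth to an envelope, demean, locate the
  # periodogram argmax
  env <- as.numeric(stats::filter(f$values, rep(1 / 51, 51), sides = 2))
  env <- env[!is.na(env)]
  env <- env - mean(env)
  sp <- Mod(fft(env))[seq_len(length(env) %/% 2)]
  freqs <- (seq_along(sp) - 1) / length(env) * fs
  band <- freqs > 0.5
  peak_f <- freqs[band][which.max(sp[band])]
  expect_gte(peak_f, 2)
  expect_lte(peak_f, 8)
})

test_that("kernels place peaks at the requested latencies with the right signs", {
  fs <- 4096
  k <- make_kernels(waveV_latency_ms = 9, fs_sub = fs, fs_cort = fs)
  lags <- attr(k$subcortical, "lags_ms")
  expect_lt(abs(lags[which.max(k$subcortical)] - 9), 1000 / fs + 1e-9)
  # single dominant positive peak inside 4-11 ms
  expect_gt(max(k$subcortical), 0)
  expect_true(lags[which.max(k$subcortical)] >= 4 &&
                lags[which.max(k$subcortical)] <= 11)
  # N1 minimum precedes P2 maximum within 50-300 ms
  clags <- attr(k$cortical, "lags_ms")
  wave <- k$cortical[, "F3"]
  sel <- clags >= 50 & clags <= 300
  expect_lt(clags[sel][which.min(wave[sel])], clags[sel][which.max(wave[sel])])
  # zero amplitudes give all-zero kernels
  k0 <- make_kernels(waveV_amp = 0,
                     cortical_amps = c(P1 = 0, N1 = 0, P2 = 0),
                     fs_sub = fs, fs_cort = fs)
  expect_equal(max(abs(k0$subcortical)), 0)
  expect_equal(max(abs(k0$cortical)), 0)
  # out-of-range latency errors
  expect_error(make_kernels(waveV_latency_ms = 50), "lag range")
  expect_error(make_kernels(cortical_latencies_ms = c(P1 = 50, N1 = 91,
                                                      P2 = 700)),
               "lag range")
})

test_that("topography is maximal on the frontotemporal cluster", {
  k <- make_kernels(fs_sub = 512, fs_cort = 512)
  topo <- k$topography
  cl <- frontotemporal_cluster()
  expect_true(all(topo[cl] >= max(topo[setdiff(names(topo), cl)])))
})

test_that("an identity kernel with zero noise reproduces the feature exactly", {
  fs <- 512
  cfg <- synth_config(n_segments = 1, segment_duration_s = 4, fs_eeg = fs,
                      noise_pink_sd = 0, noise_white_sd = 0,
                      line_noise_amp = 0, blink_rate_hz = 0, seed = 2)
  k <- make_kernels(fs_sub = fs, fs_cort = fs)
  # unit impulse at lag 0, no cortical contribution
  k$subcortical[] <- 0
  k$subcortical[which.min(abs(attr(k$subcortical, "lags_ms")))] <- 1
  k$cortical[] <- 0
  f <- generate_feature(4, fs, seed = 5)
  ep <- synthesize_recording(list(f), k, cfg)
  cz <- ep$data[1, match("Cz", ep$channels), ]
  # vertex topography weight at Cz is 1 by construction
  expect_close(cz, f$values, 1e-10)
})

test_that("doubling the kernel scale doubles the noise-free signal exactly", {
  fs <- 512
  cfg <- synth_config(n_segments = 1, segment_duration_s = 3, fs_eeg = fs,
                      noise_pink_sd = 0, noise_white_sd = 0,
                      line_noise_amp = 0, blink_rate_hz = 0, seed = 2)
  k <- make_kernels(fs_sub = fs, fs_cort = fs)
  f <- generate_feature(3, fs, seed = 5)
  e1 <- synthesize_recording(list(f), k, cfg, kernel_scale = 1)
  e2 <- synthesize_recording(list(f), k, cfg, kernel_scale = 2)
  expect_close(e2$data, 2 * e1$data, 1e-9)
})

test_that("noise-only recordings are uncorrelated with the feature", {
  fs <- 512
  cfg <- synth_config(n_segments = 1, segment_duration_s = 48, fs_eeg = fs,
                      blink_rate_hz = 0, seed = 4)
  k <- make_kernels(waveV_amp = 0,
                    cortical_amps = c(P1 = 0, N1 = 0, P2 = 0),
                    fs_sub = fs, fs_cort = fs)
  f <- generate_feature(48, fs, seed = 9)
  ep <- synthesize_recording(list(f), k, cfg, seed = 123)
  r <- cor(ep$data[1, match("Cz", ep$channels), ], f$values)
  expect_lt(abs(r), 0.05)
})

test_that("the SNR dial hits the requested ratio within 10% over 60 s", {
  fs <- 256
  cfg <- synth_config(n_segments = 1, segment_duration_s = 64, fs_eeg = fs,
                      snr_db = 6, seed = 10)
  k <- make_kernels(fs_sub = fs, fs_cort = fs)
  f <- generate_feature(64, fs, seed = 2)
  ep <- synthesize_recording(list(f), k, cfg, keep_components = TRUE)
  vs <- var(as.numeric(attr(ep, "signal")))
  vn <- var(as.numeric(attr(ep, "noise")))
  expect_close(vs / vn, 10^(6 / 10), 0.1 * 10^(6 / 10))
})

test_that("mismatched sampling rates are rejected", {
  cfg <- synth_config(n_segments = 1, segment_duration_s = 2, fs_eeg = 512,
                      seed = 1)
  k <- make_kernels(fs_sub = 256, fs_cort = 256)
  f <- generate_feature(2, 512, seed = 1)
  expect_error(synthesize_recording(list(f), k, cfg), "rate")
})

test_that("cohorts honour sizes, effect scaling and determinism", {
  cfg <- synth_config(n_segments = 1, segment_duration_s = 2, fs_eeg = 128,
                      seed = 42)
  co <- generate_cohort(19, 25, 0, cfg, signal = FALSE)
  expect_equal(nrow(co$table), 44)
  expect_equal(sum(co$table$group == "low"), 19)
  # delta = 0: identical scale distributions by construction (same
  # log-normal, no group factor)
  expect_equal(co$table$true_scale,
               generate_cohort(19, 25, 0, cfg, signal = FALSE)$table$true_scale)
  co2 <- generate_cohort(2, 2, 0.5, cfg, signal = FALSE)
  base <- generate_cohort(2, 2, 0, cfg, signal = FALSE)
  expect_close(co2$table$true_scale[1:2] / base$table$true_scale[1:2],
               rep(1.5, 2), 1e-12)
  expect_close(co2$table$true_scale[3:4], base$table$true_scale[3:4], 1e-12)
  expect_error(generate_cohort(2, 2, -1, cfg), "exceed -1")
  # full-signal determinism on a tiny cohort
  c1 <- generate_cohort(1, 1, 0, cfg)
  c2 <- generate_cohort(1, 1, 0, cfg)
  expect_identical(c1$participants[[1]]$epochs$data,
                   c2$participants[[1]]$epochs$data)
})

test_that("cohort directories round-trip kernels, features and sidecars", {
  cfg <- synth_config(n_segments = 2, segment_duration_s = 1.5,
                      fs_eeg = 128, seed = 3)
  co <- generate_cohort(1, 1, 0, cfg)
  dir <- withr::local_tempdir()
  write_cohort(co, dir)
  expect_true(file.exists(file.path(dir, "kernel_subcortical.tsv")))
  expect_true(file.exists(file.path(dir, "P01", "epochs.json")))
  meta <- jsonlite::read_json(file.path(dir, "P01", "epochs.json"),
                              simplifyVector = TRUE)
  expect_equal(meta$fs, 128)
  expect_equal(meta$units, "uV")
  f <- read_feature_file(file.path(dir, "P01", "feature_01.txt"))
  expect_equal(f$fs, 128)
  expect_close(f$values, co$participants[[1]]$features[[1]]$values, 1e-6)
})
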