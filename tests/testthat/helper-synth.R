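# Small fixtures shared across test files. Everything is generated in
# code; sizes are kept desk-scale so the default run stays fast.

# one small level-isolated participant: features + single-channel (Cz)
# responses driven by the subcortical kernel only
make_sub_participant <- function(n_segments = 6, duration_s = 10,
                                 fs = 2048, snr_db = 10, seed = 11) {
  cfg <- synth_config(n_segments = n_segments,
                      segment_duration_s = duration_s, fs_eeg = fs,
                      seed = seed, snr_db = snr_db, blink_rate_hz = 0)
  kern <- make_kernels(cortical_amps = c(P1 = 0, N1 = 0, P2 = 0),
                       fs_sub = fs, fs_cort = fs)
  feats <- lapply(seq_len(n_segments), function(s) {
    generate_feature(duration_s, fs, seed = .mix_seed(seed, s))
  })
  ep <- synthesize_recording(feats, kern, cfg)
  vi <- match("Cz", ep$channels)
  eeg <- lapply(seq_len(n_segments), function(e) {
    matrix(ep$data[e, vi, ], ncol = 1)
  })
  list(features = lapply(feats, function(f) f$values), eeg = eeg,
       kernel = kern, cfg = cfg,
       design = lag_design(-0.01, 0.03, fs))
}

# cortical-level participant at 128 Hz, wave V amplitude zero
make_cort_participant <- function(n_segments = 6, duration_s = 12,
                                  fs = 128, snr_db = 10, seed = 21) {
  cfg <- synth_config(n_segments = n_segments,
                      segment_duration_s = duration_s, fs_eeg = fs,
                      seed = seed, snr_db = snr_db, blink_rate_hz = 0,
                      line_noise_amp = 0)
  kern <- make_kernels(waveV_amp = 0, fs_sub = fs, fs_cort = fs)
  feats <- lapply(seq_len(n_segments), function(s) {
    generate_feature(duration_s, fs, seed = .mix_seed(seed, s))
  })
  ep <- synthesize_recording(feats, kern, cfg)
  scalp <- kern$channels
  ci <- match(scalp, ep$channels)
  eeg <- lapply(seq_len(n_segments), function(e) {
    m <- t(matrix(ep$data[e, ci, ], nrow = length(ci)))
    colnames(m) <- scalp
    m
  })
  list(features = lapply(feats, function(f) f$values), eeg = eeg,
       kernel = kern, cfg = cfg,
       design = lag_design(-0.3, 0.6, fs))
}

.mix_seed <- function(seed, i) (seed * 1009 + i * 9973) %% 2147483629

expect_close <- function(object, expected, tol) {
  expect_true(max(abs(object - expected)) < tol,
              label = sprintf("max|diff| = %g (tol %g)",
                              max(abs(object - expected)), tol))
}
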