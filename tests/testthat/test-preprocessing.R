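test_that("the FIR length rule reproduces known designs and is monotone", {
  expect_identical(fir_length(20, 16384), 2705L)
  expect_identical(fir_length(1.0, 128), 423L)
  # doubling the transition bandwidth never increases the length
  for (tbw in c(0.5, 1, 2, 5, 17, 100)) {
    expect_lte(fir_length(2 * tbw, 4096), fir_length(tbw, 4096))
  }
  expect_error(fir_length(0, 128), "positive")
  expect_error(fir_length(5, -1), "positive")
})

test_that("Hamming designs meet DC gain, ripple and attenuation specs", {
  lp <- design_fir(h_freq = 42.7, fs = 512, h_trans = 12.8)
  expect_identical(lp$length, 133L)
  expect_close(fir_response(lp, 0), 1, 0.01)
  bp <- design_fir(l_freq = 1, h_freq = 9, fs = 128,
                   l_trans = 1, h_trans = 2.25)
  expect_identical(bp$length, 423L)
  f <- seq(0.05, 64, by = 0.05)
  H <- fir_response(bp, f)
  stop_hi <- f >= 9 + 2.25
  expect_gte(-20 * log10(max(H[stop_hi])), 53)
  pass <- f >= 1 & f <= 9
  expect_lte(max(abs(20 * log10(H[pass]))), 0.05)
  expect_error(design_fir(h_freq = 80, fs = 128), "Nyquist")
})

test_that("causal filtering delays by the group delay; zero-phase does not", {
  lp <- design_fir(h_freq = 20, fs = 256, h_trans = 10)
  n <- 3 * lp$length
  imp <- numeric(n)
  ctr <- n %/% 2
  imp[ctr] <- 1
  yc <- apply_filter(imp, lp, "causal")
  expect_equal(which.max(yc) - ctr, (lp$length - 1) %/% 2)
  yz <- apply_filter(imp, lp, "zero_phase")
  expect_equal(which.max(yz), ctr)
  # unity-DC-gain low-pass preserves a constant in the interior
  const <- rep(2.5, n)
  yz2 <- apply_filter(const, lp, "zero_phase")
  interior <- (lp$length + 1):(n - lp$length)
  expect_close(yz2[interior], 2.5, 1e-6)
  expect_error(apply_filter(numeric(10), lp), "longer")
})

test_that("the causal chain never uses future samples", {
  lp <- design_fir(h_freq = 30, fs = 256, h_trans = 10)
  set.seed(5)
  x <- rnorm(800)
  y_full <- apply_filter(x, lp, "causal")
  y_trunc <- apply_filter(x[1:600], lp, "causal")
  expect_close(y_full[1:600], y_trunc, 1e-12)
})

test_that("power-line notches remove 50 Hz, spare 80 Hz and pass DC", {
  fs <- 2048
  t <- seq(0, 2, by = 1 / fs)
  s50 <- sin(2 * pi * 50 * t)
  y50 <- notch_powerline(s50, fs, max_hz = 200)
  mid <- seq(round(0.25 * length(t)), round(0.75 * length(t)))
  expect_lt(sqrt(mean(y50[mid]^2)), 0.01 * sqrt(mean(s50[mid]^2)))
  s80 <- sin(2 * pi * 80 * t)
  y80 <- notch_powerline(s80, fs, max_hz = 200)
  expect_close(sqrt(mean(y80[mid]^2)) / sqrt(mean(s80[mid]^2)), 1, 0.1)
  dc <- rep(1, length(t))
  ydc <- notch_powerline(dc, fs, max_hz = 200)
  expect_close(ydc[mid], 1, 0.01)
})

test_that("re-referencing subtracts the pair mean and rejects common mode", {
  dat <- rbind(A = c(1, 2), M1 = c(3, 4), M2 = c(5, 8))
  rec <- eeg_recording(dat, fs = 10, channels = rownames(dat))
  rr <- rereference(rec, c("M1", "M2"))
  # hand-computed: pair mean is (4, 6)
  expect_equal(unname(rr$data["A", ]), c(-3, -4))
  expect_equal(unname(rr$data["M1", ] + rr$data["M2", ]), c(0, 0))
  # adding a common offset changes nothing
  rec2 <- eeg_recording(dat + 7, fs = 10, channels = rownames(dat))
  rr2 <- rereference(rec2, c("M1", "M2"))
  expect_close(rr2$data, rr$data, 1e-12)
  # fallback pair engages when a mastoid is bad
  dat4 <- rbind(dat, T7 = c(0, 0), T8 = c(0, 0))
  rec3 <- eeg_recording(dat4, fs = 10, channels = rownames(dat4),
                        bad_channels = "M1")
  expect_message(rr3 <- rereference(rec3), "falling back")
  expect_identical(attr(rr3, "reference"), c("T7", "T8"))
  rec4 <- eeg_recording(dat, fs = 10, channels = rownames(dat),
                        bad_channels = "M1")
  expect_error(rereference(rec4), "neither")
})

test_that("epoching aligns to events and decimation preserves tone amplitude", {
  fs <- 512
  n <- fs * 12
  set.seed(6)
  dat <- matrix(rnorm(2 * n, sd = 0.01), 2)
  ev <- c(fs * 2, fs * 5, fs * 8)
  dat[1, ev] <- 5
  rec <- eeg_recording(dat, fs, c("Cz", "Pz"))
  ep <- epoch_and_decimate(rec, ev, tmin = 0, tmax = 1)
  expect_equal(dim(ep$data)[1], 3)
  expect_equal(unname(ep$data[2, 1, 1]), 5) # sample 0 = recording at event
  # event at the very edge is dropped with a warning
  expect_warning(ep2 <- epoch_and_decimate(rec, c(ev, n - 5), 0, 1),
                 "dropped")
  expect_equal(dim(ep2$data)[1], 3)
  # decimation: 20 Hz tone, well below target_fs / 3
  tone <- sin(2 * pi * 20 * seq(0, 12, by = 1 / fs))[seq_len(n)]
  rec3 <- eeg_recording(rbind(tone, tone), fs, c("Cz", "Pz"))
  ep3 <- epoch_and_decimate(rec3, c(fs * 2), 0, 4, target_fs = 128)
  expect_equal(ep3$fs, 128)
  amp <- max(abs(ep3$data[1, 1, 64:450]))
  expect_close(amp, 1, 0.05)
  expect_error(epoch_and_decimate(rec3, c(fs * 2), 0, 1, target_fs = 100),
               "divide")
})

test_that("artifact zeroing masks centered windows, unions overlaps", {
  fs <- 100
  dat <- array(0, c(1, 1, 30 * fs))
  dat[1, 1, 10 * fs] <- 150
  ep <- epoch_set(dat, fs, "Cz")
  out <- zero_artifact_segments(ep, 100, 1)
  bad <- which(!out$valid[1, 1, ])
  expect_equal(range(bad), c(10 * fs - 50, 10 * fs + 50))
  expect_true(all(is.na(out$data[1, 1, bad])))
  # below threshold: untouched
  ep2 <- epoch_set(array(50, c(1, 1, 200)), fs, "Cz")
  out2 <- zero_artifact_segments(ep2, 100, 1)
  expect_true(all(out2$valid))
  expect_equal(attr(out2, "masked_fraction"), 0)
  # overlapping spike windows are unioned, not double counted
  dat3 <- array(0, c(1, 1, 10 * fs))
  dat3[1, 1, c(500, 530)] <- 150
  out3 <- zero_artifact_segments(epoch_set(dat3, fs, "Cz"), 100, 1)
  expect_equal(sum(!out3$valid), length(450:580))
})

test_that("epoch rejection drops offenders and refuses to drop everything", {
  dat <- array(rnorm(30 * 2 * 50, sd = 1), c(30, 2, 50))
  dat[3, 1, 10] <- 60
  dat[9, 2, 20] <- -70
  ep <- epoch_set(dat, 100, c("Cz", "Pz"))
  expect_message(out <- reject_epochs(ep, 40), "2 epoch")
  expect_equal(dim(out$data)[1], 28)
  expect_identical(attr(out, "n_rejected"), 2L)
  # infinite threshold is the identity
  out2 <- reject_epochs(ep, Inf)
  expect_equal(dim(out2$data)[1], 30)
  expect_error(reject_epochs(ep, 1e-9), "all epochs")
  # rejection is decided per epoch across retained channels
  dat2 <- array(0, c(2, 2, 10))
  dat2[1, 2, 5] <- 100
  ep2 <- epoch_set(dat2, 100, c("Cz", "Pz"))
  out3 <- suppressMessages(reject_epochs(ep2, 40))
  expect_equal(dim(out3$data)[1], 1)
  ep3 <- epoch_set(dat2, 100, c("Cz", "Pz"), bad_channels = "Pz")
  out4 <- reject_epochs(ep3, 40) # offending channel is flagged bad
  expect_equal(dim(out4$data)[1], 2)
})

test_that("baseline correction zeroes the window mean", {
  fs <- 100
  dat <- array(rnorm(3 * 2 * 200), c(3, 2, 200))
  ep <- epoch_set(dat, fs, c("Cz", "Pz"), t0 = -0.5)
  out <- baseline_correct(ep, c(-0.4, -0.1))
  tt <- epoch_times(out)
  sel <- tt >= -0.4 & tt <= -0.1
  for (e in 1:3) {
    expect_close(rowMeans(out$data[e, , sel]), 0, 1e-10)
  }
  # constant epochs become all zero
  epc <- epoch_set(array(3, c(1, 1, 100)), fs, "Cz", t0 = -0.5)
  expect_close(baseline_correct(epc, c(-0.4, -0.1))$data, 0, 1e-12)
  # hand-computed 5-sample case: baseline mean of first 2 samples
  eph <- epoch_set(array(c(1, 3, 5, 7, 9), c(1, 1, 5)), 1, "Cz", t0 = 0)
  outh <- baseline_correct(eph, c(0, 1))
  expect_equal(as.numeric(outh$data[1, 1, ]), c(1, 3, 5, 7, 9) - 2)
  expect_error(baseline_correct(ep, c(5, 6)), "no samples")
})

test_that("EOG regression restores a known clean signal", {
  fs <- 128
  n <- 6 * fs
  set.seed(7)
  clean <- matrix(rnorm(2 * n), ncol = 2)
  eog <- matrix(rnorm(2 * n, sd = 3), ncol = 2)
  mixed <- clean + eog %*% matrix(c(0.5, 0.2, 0.1, 0.6), 2)
  dat <- array(0, c(1, 4, n))
  dat[1, 1, ] <- mixed[, 1]
  dat[1, 2, ] <- mixed[, 2]
  dat[1, 3, ] <- eog[, 1]
  dat[1, 4, ] <- eog[, 2]
  ep <- epoch_set(dat, fs, c("Cz", "Fz", "EOG1", "EOG2"))
  out <- remove_ocular(ep)
  expect_gt(cor(out$data[1, 1, ], clean[, 1]), 0.99)
  expect_gt(cor(out$data[1, 2, ], clean[, 2]), 0.99)
  # zero EOG leaves the data untouched (nothing to regress out)
  dat0 <- dat
  dat0[1, 3:4, ] <- 0
  ep0 <- epoch_set(dat0, fs, c("Cz", "Fz", "EOG1", "EOG2"))
  out0 <- remove_ocular(ep0)
  expect_identical(out0$data, ep0$data)
  # missing EOG channels: skip with warning
  ep_no <- epoch_set(dat[, 1:2, , drop = FALSE], fs, c("Cz", "Fz"))
  expect_warning(same <- remove_ocular(ep_no), "skipped")
  expect_identical(same$data, ep_no$data)
})

test_that("blink-laden frontal channels lose kurtosis after EOG regression", {
  fs <- 256
  cfg <- synth_config(n_segments = 2, segment_duration_s = 12, fs_eeg = fs,
                      blink_rate_hz = 0.6, blink_amp = 150, seed = 13)
  k <- make_kernels(fs_sub = fs, fs_cort = fs)
  feats <- lapply(1:2, function(s) generate_feature(12, fs, seed = s))
  ep <- synthesize_recording(feats, k, cfg)
  kurt <- function(x) mean((x - mean(x))^4) / var(x)^2
  fp1 <- match("Fp1", ep$channels)
  before <- kurt(as.numeric(ep$data[, fp1, ]))
  cleaned <- remove_ocular(ep)
  after <- kurt(as.numeric(cleaned$data[, fp1, ]))
  expect_lt(after, before)
})

test_that("bad-channel interpolation reconstructs from neighbors", {
  fs <- 100
  n <- 200
  mon <- standard_montage()
  scalp <- mon$label[mon$type == "scalp"]
  set.seed(8)
  dat <- array(0, c(1, length(scalp), n))
  # linear spatial gradient: value = 2x + y at every time point
  base <- rnorm(n)
  for (i in seq_along(scalp)) {
    g <- 2 * mon$x[match(scalp[i], mon$label)] +
      mon$y[match(scalp[i], mon$label)]
    dat[1, i, ] <- g + base
  }
  truth <- dat[1, match("C3", scalp), ]
  ep <- epoch_set(dat, fs, scalp, bad_channels = "C3")
  ep$data[1, match("C3", scalp), ] <- 999
  out <- interpolate_bad(ep)
  err <- sqrt(mean((out$data[1, match("C3", scalp), ] - truth)^2)) /
    sd(truth)
  expect_lt(err, 0.1)
  expect_length(out$bad_channels, 0)
  # identical neighbors reproduce exactly; no bad channels = identity
  ep2 <- epoch_set(array(rep(1, length(scalp) * 50),
                         c(1, length(scalp), 50)), fs, scalp,
                   bad_channels = "Cz")
  out2 <- interpolate_bad(ep2)
  expect_close(out2$data[1, match("Cz", scalp), ], 1, 1e-12)
  ep3 <- epoch_set(dat, fs, scalp)
  expect_identical(interpolate_bad(ep3)$data, ep3$data)
})
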