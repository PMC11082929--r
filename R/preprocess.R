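#' FIR filter length from transition bandwidth
#'
#' Tap count of a Hamming-window FIR design for a given transition
#' bandwidth: `ceil(3.3 / transition_bw * fs)`, rounded up to the next odd
#' integer. For multi-edge (band-pass) designs the narrowest transition
#' bandwidth governs the length.
#'
#' @param transition_bw_hz transition bandwidth in Hz (> 0); for band-pass
#'   designs pass the narrower of the two.
#' @param fs sampling rate in Hz (> 0).
#' @return integer tap count (odd).
#' @export
#' @examples
#' fir_length(20, 16384)  # 2705
#' fir_length(1, 128)     # 423
fir_length <- function(transition_bw_hz, fs) {
  if (!is.numeric(transition_bw_hz) || any(transition_bw_hz <= 0)) {
    stop("`transition_bw_hz` must be positive")
  }
  if (!is.numeric(fs) || any(fs <= 0)) stop("`fs` must be positive")
  n <- ceiling(3.3 / transition_bw_hz * fs)
  n <- ifelse(n %% 2 == 0, n + 1, n)
  as.integer(n)
}

#' Design a Hamming-window FIR filter
#'
#' Windowed-sinc design with a Hamming window (nominal 0.0194 dB pass-band
#' ripple, 53 dB stop-band attenuation). The -6 dB cutoffs sit half a
#' transition band outside the stated pass-band edges, so the transition
#' region spans `edge - tbw` to `edge` (high-pass side) and `edge` to
#' `edge + tbw` (low-pass side) around the half-transition-shifted cutoff;
#' the stop band begins one full transition bandwidth beyond the edge.
#' Filter length follows [fir_length()] with the narrowest transition
#' bandwidth unless `length` is given.
#'
#' @param l_freq lower pass-band edge in Hz (`NULL` for a low-pass).
#' @param h_freq upper pass-band edge in Hz (`NULL` for a high-pass).
#' @param fs sampling rate in Hz.
#' @param l_trans,h_trans transition bandwidths in Hz. Defaults: one
#'   quarter of the corresponding edge frequency, at least 2 Hz, never
#'   wider than the edge itself (lower side) or the room left below
#'   Nyquist (upper side).
#' @param length optional explicit tap count (odd).
#' @return An object of class `fir_filter`: list with coefficients `b`,
#'   `length`, `fs`, `kind` and the resolved edges.
#' @export
#' @examples
#' f <- design_fir(h_freq = 42.7, fs = 512, h_trans = 12.8)
#' f$length  # 133
design_fir <- function(l_freq = NULL, h_freq = NULL, fs,
                       l_trans = NULL, h_trans = NULL, length = NULL) {
  if (is.null(l_freq) && is.null(h_freq)) {
    stop("at least one of `l_freq`, `h_freq` must be given")
  }
  nyq <- fs / 2
  if (!is.null(l_freq) && (l_freq <= 0 || l_freq >= nyq)) {
    stop("`l_freq` must lie strictly between 0 and Nyquist")
  }
  if (!is.null(h_freq) && (h_freq <= 0 || h_freq >= nyq)) {
    stop("`h_freq` must lie strictly between 0 and Nyquist")
  }
  if (!is.null(l_freq)) {
    if (is.null(l_trans)) l_trans <- min(max(0.25 * l_freq, 2), l_freq)
    if (l_trans <= 0) stop("`l_trans` must be positive")
  }
  if (!is.null(h_freq)) {
    if (is.null(h_trans)) h_trans <- min(max(0.25 * h_freq, 2), nyq - h_freq)
    if (h_trans <= 0) stop("`h_trans` must be positive")
  }
  tbw <- min(c(l_trans, h_trans))
  if (is.null(length)) length <- fir_length(tbw, fs)
  if (length %% 2 == 0) length <- length + 1L
  if (!is.null(l_freq) && !is.null(h_freq)) {
    kind <- "pass"
    w <- c(l_freq - l_trans / 2, h_freq + h_trans / 2)
    if (w[1] <= 0 || w[2] >= nyq) {
      stop("cutoffs (edge +/- transition/2) must stay inside (0, Nyquist)")
    }
    b <- signal::fir1(length - 1L, w / nyq, type = "pass",
                      window = signal::hamming(length))
  } else if (is.null(l_freq)) {
    kind <- "low"
    w <- h_freq + h_trans / 2
    if (w >= nyq) stop("cutoff must stay below Nyquist")
    b <- signal::fir1(length - 1L, w / nyq, type = "low",
                      window = signal::hamming(length))
    b <- b / sum(b) # exact unity DC gain
  } else {
    kind <- "high"
    w <- l_freq - l_trans / 2
    if (w <= 0) stop("cutoff must stay above 0 Hz")
    b <- signal::fir1(length - 1L, w / nyq, type = "high",
                      window = signal::hamming(length))
  }
  structure(
    list(b = as.numeric(b), length = as.integer(length), fs = fs,
         kind = kind, l_freq = l_freq, h_freq = h_freq,
         l_trans = l_trans, h_trans = h_trans),
    class = "fir_filter"
  )
}

#' Magnitude response of an FIR filter on a frequency grid
#'
#' @param filt a `fir_filter` or a numeric coefficient vector.
#' @param freqs frequencies in Hz.
#' @param fs sampling rate (taken from the filter if absent).
#' @return numeric vector of linear magnitude gains.
#' @export
fir_response <- function(filt, freqs, fs = NULL) {
  if (inherits(filt, "fir_filter")) {
    b <- filt$b
    if (is.null(fs)) fs <- filt$fs
  } else {
    b <- as.numeric(filt)
    if (is.null(fs)) stop("`fs` required when passing raw coefficients")
  }
  k <- seq_along(b) - 1
  vapply(freqs, function(f) Mod(sum(b * exp(-2i * pi * f * k / fs))),
         numeric(1))
}

#' Apply an FIR filter causally or with zero phase
#'
#' Causal one-pass application leaves the linear-phase group delay of
#' `(L - 1) / 2` samples in place (as used by the subcortical chain).
#' Zero-phase application runs the same one-pass filter and compensates
#' the group delay by shifting, padding the tail with zeros (edge samples
#' within half a filter length of either end carry filter transients).
#' Output length always equals input length.
#'
#' @param x numeric vector, or matrix with time in rows (one column per
#'   channel).
#' @param filt a `fir_filter` or numeric coefficient vector (odd length
#'   for the zero-phase path).
#' @param phase `"causal"` or `"zero_phase"`.
#' @return filtered data, same shape as `x`.
#' @export
apply_filter <- function(x, filt, phase = c("causal", "zero_phase")) {
  phase <- match.arg(phase)
  b <- if (inherits(filt, "fir_filter")) filt$b else as.numeric(filt)
  vec <- is.null(dim(x))
  xm <- if (vec) matrix(x, ncol = 1) else as.matrix(x)
  if (nrow(xm) <= length(b)) {
    stop("signal must be longer than the filter")
  }
  gd <- (length(b) - 1L) %/% 2L
  out <- apply(xm, 2L, function(col) {
    if (phase == "causal") {
      as.numeric(signal::filter(b, 1, col))
    } else {
      y <- as.numeric(signal::filter(b, 1, c(col, numeric(gd))))
      y[(gd + 1L):(gd + length(col))]
    }
  })
  out <- matrix(out, nrow = nrow(xm), dimnames = dimnames(xm))
  if (vec) as.numeric(out) else out
}

#' Power-line notch filtering
#'
#' Cascaded zero-phase Butterworth band-stop filters at every multiple of
#' `base_hz` up to `min(max_hz, Nyquist)`. Each harmonic uses a 2nd-order
#' band-stop applied forward-backward (effective order 8 in poles per
#' harmonic after the two band edges and the two passes).
#'
#' @param x numeric vector or time-by-channel matrix.
#' @param fs sampling rate in Hz.
#' @param base_hz line frequency (default 50 Hz).
#' @param max_hz highest harmonic to remove (default 1350 Hz).
#' @param tbw stop-band width around each harmonic in Hz (default 5).
#' @param order Butterworth prototype order per pass (default 2).
#' @return filtered data, same shape as `x`.
#' @export
notch_powerline <- function(x, fs, base_hz = 50, max_hz = 1350, tbw = 5,
                            order = 2) {
  if (base_hz >= fs / 2) stop("`base_hz` must be below Nyquist")
  harmonics <- seq(base_hz, min(max_hz, fs / 2 - tbw), by = base_hz)
  vec <- is.null(dim(x))
  xm <- if (vec) matrix(x, ncol = 1) else as.matrix(x)
  for (h in harmonics) {
    bt <- signal::butter(order, c(h - tbw / 2, h + tbw / 2) / (fs / 2),
                         type = "stop")
    for (j in seq_len(ncol(xm))) {
      xm[, j] <- signal::filtfilt(bt, xm[, j])
    }
  }
  out <- matrix(xm, nrow = nrow(xm), dimnames = dimnames(xm))
  if (vec) as.numeric(out) else out
}

#' Re-reference to a linked electrode pair
#'
#' Subtracts the mean of the reference pair (linked mastoids by default)
#' from every channel. If a reference channel is missing or flagged bad,
#' the fallback pair (T7/T8 by default) is used instead; if neither pair
#' is usable this is a hard error. The pair actually used is recorded in
#' the `"reference"` attribute and reported via a message.
#'
#' @param rec an `eeg_recording` or `epoch_set`.
#' @param reference primary reference pair labels.
#' @param fallback fallback pair labels.
#' @return the re-referenced object with attribute `"reference"`.
#' @export
rereference <- function(rec, reference = c("M1", "M2"),
                        fallback = c("T7", "T8")) {
  usable <- function(labs) {
    all(labs %in% rec$channels) && !any(labs %in% rec$bad_channels)
  }
  if (usable(reference)) {
    ref <- reference
  } else if (usable(fallback)) {
    ref <- fallback
    message("reference pair unavailable; falling back to ",
            paste(fallback, collapse = "/"))
  } else {
    stop("neither the reference nor the fallback pair is usable")
  }
  if (inherits(rec, "eeg_recording")) {
    refsig <- colMeans(rec$data[ref, , drop = FALSE])
    rec$data <- sweep(rec$data, 2L, refsig)
  } else if (inherits(rec, "epoch_set")) {
    ri <- match(ref, rec$channels)
    d <- dim(rec$data)
    for (e in seq_len(d[1L])) {
      refsig <- colMeans(matrix(rec$data[e, ri, ], nrow = length(ri)))
      rec$data[e, , ] <- sweep(matrix(rec$data[e, , ], nrow = d[2L]),
                               2L, refsig)
    }
  } else {
    stop("`rec` must be an eeg_recording or epoch_set")
  }
  attr(rec, "reference") <- ref
  rec
}

#' Epoch a continuous recording and reduce its sampling rate
#'
#' Cuts epochs around event samples, optionally after anti-alias
#' low-pass filtering at one third of the target rate (transition
#' bandwidth 0.3 times the cutoff) followed by decimation. Events too
#' close to the recording edges are dropped with a warning. The decimation
#' factor `fs / target_fs` must be an integer.
#'
#' @param rec an `eeg_recording`.
#' @param events event onsets in samples (1-based) at the original rate.
#' @param tmin,tmax epoch window in seconds relative to each event.
#' @param target_fs target sampling rate in Hz (`NULL` = keep rate).
#' @param phase phase mode for the anti-alias filter (`"zero_phase"`
#'   default; `"causal"` for the strictly causal chain).
#' @return an `epoch_set` with `t0 = tmin`.
#' @export
epoch_and_decimate <- function(rec, events, tmin, tmax, target_fs = NULL,
                               phase = "zero_phase") {
  stopifnot(inherits(rec, "eeg_recording"))
  if (tmin >= tmax) stop("`tmin` must be below `tmax`")
  fs <- rec$fs
  x <- t(rec$data) # time x channel
  if (!is.null(target_fs) && target_fs < fs) {
    dec <- fs / target_fs
    if (abs(dec - round(dec)) > 1e-9) {
      stop("`target_fs` must divide the recording rate")
    }
    dec <- as.integer(round(dec))
    cutoff <- target_fs / 3
    aa <- design_fir(h_freq = cutoff, fs = fs, h_trans = 0.3 * cutoff)
    x <- apply_filter(x, aa, phase = phase)
    keep <- seq(1L, nrow(x), by = dec)
    x <- x[keep, , drop = FALSE]
    events_new <- floor((events - 1L) / dec) + 1L
    fs_new <- target_fs
  } else {
    events_new <- as.integer(events)
    fs_new <- fs
  }
  n <- nrow(x)
  i0 <- round(tmin * fs_new)
  i1 <- round(tmax * fs_new)
  len <- i1 - i0 + 1L
  ok <- (events_new + i0) >= 1L & (events_new + i1) <= n
  if (any(!ok)) {
    warning(sum(!ok), " event(s) too close to the recording edge; dropped")
  }
  ev <- events_new[ok]
  if (!length(ev)) stop("no usable events")
  dat <- array(0, dim = c(length(ev), ncol(x), len))
  for (e in seq_along(ev)) {
    dat[e, , ] <- t(x[(ev[e] + i0):(ev[e] + i1), , drop = FALSE])
  }
  epoch_set(dat, fs = fs_new, channels = rec$channels, t0 = i0 / fs_new,
            bad_channels = rec$bad_channels)
}

#' Zero out high-amplitude artifact segments
#'
#' Every sample whose absolute value exceeds `amp_threshold` microvolts
#' seeds a window of `window_s` seconds centered on it; all samples in the
#' union of those windows are marked invalid and set to `NA`. The missing
#' markers are replaced by zeros only after feature-target scaling (see
#' [scale_pair()]), so the scaling statistics are not biased by them.
#'
#' @param ep an `epoch_set`.
#' @param amp_threshold amplitude threshold in microvolts (default 100).
#' @param window_s window length in seconds (default 1).
#' @return the `epoch_set` with masked samples `NA` and `valid` updated;
#'   the fraction masked is stored in attribute `"masked_fraction"`.
#' @export
zero_artifact_segments <- function(ep, amp_threshold = 100, window_s = 1) {
  stopifnot(inherits(ep, "epoch_set"))
  if (amp_threshold <= 0) stop("`amp_threshold` must be positive")
  half <- round(window_s * ep$fs / 2)
  d <- dim(ep$data)
  nt <- d[3L]
  for (e in seq_len(d[1L])) {
    for (c in seq_len(d[2L])) {
      tr <- ep$data[e, c, ]
      hits <- which(abs(tr) > amp_threshold)
      if (!length(hits)) next
      bad <- rep(FALSE, nt)
      for (h in hits) {
        bad[max(1L, h - half):min(nt, h + half)] <- TRUE
      }
      ep$data[e, c, bad] <- NA_real_
      ep$valid[e, c, bad] <- FALSE
    }
  }
  attr(ep, "masked_fraction") <- 1 - mean(ep$valid)
  ep
}

#' Reject epochs exceeding an amplitude threshold
#'
#' Drops every epoch in which any retained channel exceeds
#' `amp_threshold` microvolts in absolute value. Rejecting all epochs is a
#' hard error. The number dropped is reported via a message and stored in
#' attribute `"n_rejected"`.
#'
#' @param ep an `epoch_set`.
#' @param amp_threshold rejection threshold in microvolts.
#' @return the pruned `epoch_set`.
#' @export
reject_epochs <- function(ep, amp_threshold) {
  stopifnot(inherits(ep, "epoch_set"))
  keep_ch <- !(ep$channels %in% ep$bad_channels)
  peak <- apply(abs(ep$data[, keep_ch, , drop = FALSE]), 1L, max, na.rm = TRUE)
  keep <- peak <= amp_threshold
  if (!any(keep)) stop("all epochs exceed the rejection threshold")
  n_rej <- sum(!keep)
  if (n_rej > 0) message(n_rej, " epoch(s) rejected (> ", amp_threshold,
                         " µV)")
  out <- epoch_set(ep$data[keep, , , drop = FALSE], fs = ep$fs,
                   channels = ep$channels, t0 = ep$t0,
                   bad_channels = ep$bad_channels,
                   valid = ep$valid[keep, , , drop = FALSE])
  attr(out, "n_rejected") <- n_rej
  out
}

#' Baseline-correct epochs
#'
#' Subtracts, per epoch and channel, the mean over a baseline window.
#'
#' @param ep an `epoch_set`.
#' @param window `c(t1, t2)` in seconds relative to the event; must lie
#'   inside the epoch and contain at least one sample.
#' @return the corrected `epoch_set`.
#' @export
baseline_correct <- function(ep, window) {
  stopifnot(inherits(ep, "epoch_set"))
  tt <- epoch_times(ep)
  sel <- tt >= window[1] & tt <= window[2]
  if (!any(sel)) stop("baseline window contains no samples")
  d <- dim(ep$data)
  for (e in seq_len(d[1L])) {
    base <- matrix(ep$data[e, , sel], nrow = d[2L])
    mu <- rowMeans(base, na.rm = TRUE)
    ep$data[e, , ] <- matrix(ep$data[e, , ], nrow = d[2L]) - mu
  }
  ep
}

#' Remove ocular artifacts by EOG regression
#'
#' Default method: each EEG channel is regressed on the EOG channels,
#' with regression coefficients estimated on 1 Hz high-pass filtered
#' copies (drifts should not drive the fit), and the fitted EOG projection
#' is subtracted from the unfiltered data. When epochs are too short for
#' the high-pass filter, the copies are mean-detrended instead. The
#' `"external"` method accepts a user-supplied function (e.g., wrapping an
#' ICA implementation) called as `fun(ep, eog_channels)`; component
#' labeling against the EOG reference is then that function's business.
#'
#' @param ep an `epoch_set` containing the EOG channels.
#' @param eog_channels EOG channel labels.
#' @param method `"regression"` (default) or `"external"`.
#' @param external_fun function used when `method = "external"`.
#' @return the cleaned `epoch_set`; regression coefficients are stored in
#'   attribute `"ocular_coefficients"`. Missing EOG channels make this a
#'   no-op with a warning.
#' @export
remove_ocular <- function(ep, eog_channels = c("EOG1", "EOG2"),
                          method = c("regression", "external"),
                          external_fun = NULL) {
  stopifnot(inherits(ep, "epoch_set"))
  method <- match.arg(method)
  if (!all(eog_channels %in% ep$channels)) {
    warning("EOG channel(s) missing; ocular removal skipped")
    return(ep)
  }
  if (method == "external") {
    if (!is.function(external_fun)) stop("`external_fun` must be a function")
    return(external_fun(ep, eog_channels))
  }
  d <- dim(ep$data)
  eog_i <- match(eog_channels, ep$channels)
  eeg_i <- setdiff(seq_len(d[2L]), eog_i)
  # concatenate epochs: time x channel
  flat <- matrix(aperm(ep$data, c(3L, 1L, 2L)), ncol = d[2L])
  hp_len <- fir_length(1, ep$fs)
  if (nrow(flat) > 3L * hp_len) {
    hp <- design_fir(l_freq = 1, fs = ep$fs, l_trans = 1)
    flat_hp <- apply_filter(flat, hp, phase = "zero_phase")
  } else {
    flat_hp <- sweep(flat, 2L, colMeans(flat, na.rm = TRUE))
  }
  flat_hp[is.na(flat_hp)] <- 0
  E <- flat_hp[, eog_i, drop = FALSE]
  if (all(apply(E, 2L, sd) < 1e-10)) {
    # flat EOG carries no artifact information: nothing to remove
    attr(ep, "ocular_coefficients") <- matrix(0, length(eog_i),
                                              length(eeg_i))
    return(ep)
  }
  beta <- solve(crossprod(E), crossprod(E, flat_hp[, eeg_i, drop = FALSE]))
  Eraw <- flat[, eog_i, drop = FALSE]
  Eraw[is.na(Eraw)] <- 0
  flat[, eeg_i] <- flat[, eeg_i, drop = FALSE] - Eraw %*% beta
  ep$data <- aperm(array(flat, dim = c(d[3L], d[1L], d[2L])), c(2L, 3L, 1L))
  dimnames(ep$data) <- list(NULL, ep$channels, NULL)
  attr(ep, "ocular_coefficients") <- beta
  ep
}

#' Interpolate bad channels from montage neighbors
#'
#' Replaces each bad channel by an inverse-distance-weighted average of
#' its `k` nearest good scalp neighbors on the standard montage.
#'
#' @param ep an `epoch_set` whose `bad_channels` are to be repaired.
#' @param k number of neighbors (default 4).
#' @return the `epoch_set` with bad channels reconstructed and the
#'   bad-channel list cleared.
#' @export
interpolate_bad <- function(ep, k = 4) {
  stopifnot(inherits(ep, "epoch_set"))
  bad <- intersect(ep$bad_channels, ep$channels)
  if (!length(bad)) return(ep)
  mon <- standard_montage()
  scalp <- intersect(ep$channels, mon$label[mon$type == "scalp"])
  good <- setdiff(scalp, bad)
  if (length(good) < length(bad)) {
    stop("more bad channels than good ones; cannot interpolate")
  }
  xy <- mon[match(ep$channels, mon$label), c("x", "y")]
  for (b in bad) {
    bi <- match(b, ep$channels)
    gi <- match(good, ep$channels)
    d <- sqrt((xy$x[gi] - xy$x[bi])^2 + (xy$y[gi] - xy$y[bi])^2)
    ord <- order(d)[seq_len(min(k, length(gi)))]
    w <- 1 / pmax(d[ord], 1e-6)
    w <- w / sum(w)
    acc <- 0
    for (j in seq_along(ord)) {
      acc <- acc + w[j] * ep$data[, gi[ord[j]], , drop = TRUE]
    }
    ep$data[, bi, ] <- acc
  }
  ep$bad_channels <- character()
  ep
}
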