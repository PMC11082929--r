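#' Stimulus feature time series
#'
#' Container for a stimulus-derived regressor (e.g., a surrogate auditory
#' nerve rate) at a stated sampling rate. Values may contain `NA` markers
#' after padding; they are replaced by zeros only after feature-target
#' scaling (see [scale_pair()]).
#'
#' @param values numeric vector of regressor amplitudes.
#' @param fs sampling rate in Hz (> 0).
#' @param segment_id segment identifier.
#' @param polarity `"original"` or `"inverted"`.
#' @return An object of class `feature_series`.
#' @export
feature_series <- function(values, fs, segment_id = NA_character_,
                           polarity = c("original", "inverted")) {
  polarity <- match.arg(polarity)
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0) {
    stop("`fs` must be a single positive number")
  }
  if (!is.numeric(values)) stop("`values` must be numeric")
  if (any(!is.finite(values) & !is.na(values))) {
    stop("`values` must be finite or NA")
  }
  structure(
    list(values = as.numeric(values), fs = fs,
         segment_id = segment_id, polarity = polarity),
    class = "feature_series"
  )
}

#' @export
print.feature_series <- function(x, ...) {
  cat(sprintf("<feature_series> segment %s (%s), %d samples @ %g Hz (%.2f s)\n",
              x$segment_id, x$polarity, length(x$values), x$fs,
              length(x$values) / x$fs))
  invisible(x)
}

#' @export
length.feature_series <- function(x) length(x$values)

#' Epoched multi-channel EEG
#'
#' An epoch x channel x time numeric array (microvolts) with channel
#' labels, a time axis anchored at `t0` seconds relative to the event, a
#' bad-channel list and a validity mask of the same shape as the data
#' (`TRUE` = valid sample).
#'
#' @param data numeric array, epoch x channel x time.
#' @param fs sampling rate in Hz.
#' @param channels character vector of channel labels (length = dim 2).
#' @param t0 time of the first sample relative to the event, in seconds.
#' @param bad_channels labels of channels flagged bad.
#' @param valid logical array of the same shape as `data`; defaults to all
#'   `TRUE` (non-finite data samples are marked invalid).
#' @return An object of class `epoch_set`.
#' @export
epoch_set <- function(data, fs, channels, t0 = 0, bad_channels = character(),
                      valid = NULL) {
  if (length(dim(data)) != 3L) stop("`data` must be a 3D array")
  if (length(channels) != dim(data)[2L]) {
    stop("`channels` length must equal dim(data)[2]")
  }
  if (fs <= 0) stop("`fs` must be positive")
  if (is.null(valid)) {
    valid <- array(TRUE, dim = dim(data))
    valid[!is.finite(data)] <- FALSE
  }
  if (!identical(dim(valid), dim(data))) {
    stop("`valid` must have the same shape as `data`")
  }
  dimnames(data) <- list(NULL, channels, NULL)
  structure(
    list(data = data, fs = fs, channels = as.character(channels), t0 = t0,
         bad_channels = as.character(bad_channels), valid = valid),
    class = "epoch_set"
  )
}

#' @export
print.epoch_set <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "<epoch_set> %d epoch(s) x %d channel(s) x %d samples @ %g Hz, t0 = %g s\n",
    d[1], d[2], d[3], x$fs, x$t0))
  if (length(x$bad_channels)) {
    cat("  bad channels:", paste(x$bad_channels, collapse = ", "), "\n")
  }
  frac <- 1 - mean(x$valid)
  if (frac > 0) cat(sprintf("  invalid samples: %.2f%%\n", 100 * frac))
  invisible(x)
}

#' Time axis of an epoch set
#'
#' @param x an `epoch_set`.
#' @return numeric vector of sample times in seconds relative to the event.
#' @export
epoch_times <- function(x) {
  stopifnot(inherits(x, "epoch_set"))
  x$t0 + (seq_len(dim(x$data)[3L]) - 1L) / x$fs
}

#' Continuous multi-channel recording
#'
#' @param data channel x time numeric matrix (microvolts).
#' @param fs sampling rate in Hz.
#' @param channels channel labels (length = nrow(data)).
#' @param bad_channels labels flagged bad.
#' @return An object of class `eeg_recording`.
#' @export
eeg_recording <- function(data, fs, channels, bad_channels = character()) {
  data <- as.matrix(data)
  if (length(channels) != nrow(data)) {
    stop("`channels` length must equal nrow(data)")
  }
  rownames(data) <- channels
  structure(
    list(data = data, fs = fs, channels = as.character(channels),
         bad_channels = as.character(bad_channels)),
    class = "eeg_recording"
  )
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d channel(s) x %d samples @ %g Hz (%.1f s)\n",
              nrow(x$data), ncol(x$data), x$fs, ncol(x$data) / x$fs))
  invisible(x)
}

# lagged convolution: y[t] = sum_j k[j] * x[t - lag[j]], lags in samples
# starting at `lag_first` (may be negative = acausal), zero outside x.
# direct-form FIR (signal::filter) rather than an FFT: segment lengths
# are arbitrary and can hit prime-length FFT worst cases.
.conv_lagged <- function(x, kernel, lag_first) {
  n <- length(x)
  l <- length(kernel)
  pad <- max(0L, -lag_first) + 1L
  z <- as.numeric(signal::filter(kernel, 1, c(x, numeric(pad))))
  idx <- seq_len(n) - lag_first
  y <- numeric(n)
  ok <- idx >= 1L & idx <= length(z)
  y[ok] <- z[idx[ok]]
  y
}

# 1/f ("pink") noise via spectral shaping, normalized to sd = 1
.pink_noise <- function(n) {
  white <- rnorm(n)
  spec <- fft(white)
  f <- c(1, seq_len(n - 1))
  f <- pmin(f, n - f + 1) # two-sided frequency index
  spec <- spec / sqrt(f)
  x <- Re(fft(spec, inverse = TRUE)) / n
  as.numeric(scale(x))
}

# derive a reproducible 31-bit child seed from a master seed and an index
.child_seed <- function(seed, index) {
  as.integer((as.numeric(seed) * 48271 + index * 104729) %% 2147483629)
}

# save/restore the caller's RNG state so seeded generators are pure
.preserve_seed <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
}

.restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}
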