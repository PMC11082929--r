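#' Surrogate auditory-nerve firing-rate feature
#'
#' Produces a rate-like stimulus regressor from an acoustic waveform by a
#' gammatone-style band decomposition: the waveform is band-pass filtered
#' into `n_bands` log-spaced bands between `f_lo` and `f_hi`, each band is
#' half-wave rectified, compressed with a power law (default exponent 0.4,
#' a standard cochlear-compression value), low-pass smoothed, and the
#' bands are averaged into a single non-negative time series. This is a
#' documented surrogate for phenomenological auditory-periphery models;
#' externally computed firing-rate series can be imported instead via
#' [read_feature_file()].
#'
#' @param waveform numeric acoustic waveform (finite values).
#' @param fs_in sampling rate of the waveform in Hz.
#' @param n_bands number of analysis bands (default 43).
#' @param f_lo,f_hi band center-frequency range in Hz (defaults 125 and
#'   16000; bands above 0.45 * fs_in are dropped with a message).
#' @param compression_exponent power-law exponent (default 0.4).
#' @param lp_cutoff smoothing low-pass cutoff in Hz (default 250: the
#'   rate feature follows envelopes up to a few hundred Hz but discards
#'   carrier fine structure).
#' @param spontaneous_rate constant offset added to the output (default 0).
#' @param segment_id,polarity passed to [feature_series()].
#' @return a [feature_series()] at `fs_in`.
#' @export
nerve_rate_surrogate <- function(waveform, fs_in, n_bands = 43,
                                 f_lo = 125, f_hi = 16000,
                                 compression_exponent = 0.4,
                                 lp_cutoff = 250, spontaneous_rate = 0,
                                 segment_id = NA_character_,
                                 polarity = "original") {
  if (!length(waveform)) stop("`waveform` must be non-empty")
  if (any(!is.finite(waveform))) stop("`waveform` must be finite")
  if (n_bands < 1) stop("`n_bands` must be >= 1")
  if (fs_in <= 0) stop("`fs_in` must be positive")
  cf <- exp(seq(log(f_lo), log(f_hi), length.out = n_bands))
  usable <- cf < 0.45 * fs_in
  if (!any(usable)) stop("no analysis band fits below Nyquist")
  if (!all(usable)) {
    message(sum(!usable), " band(s) above 0.45 * fs dropped")
    cf <- cf[usable]
  }
  lp_c <- min(lp_cutoff, 0.4 * fs_in)
  lp <- signal::butter(2, lp_c / (fs_in / 2), type = "low")
  acc <- numeric(length(waveform))
  for (f in cf) {
    bw <- max(24.7 * (4.37 * f / 1000 + 1), 10) # ERB-like bandwidth
    lo <- max(f - bw / 2, 1)
    hi <- min(f + bw / 2, 0.47 * fs_in)
    bp <- signal::butter(2, c(lo, hi) / (fs_in / 2), type = "pass")
    band <- signal::filtfilt(bp, waveform)
    band <- pmax(band, 0) ^ compression_exponent
    band <- signal::filtfilt(lp, band)
    acc <- acc + band
  }
  out <- pmax(acc / length(cf), 0) + spontaneous_rate
  feature_series(out, fs = fs_in, segment_id = segment_id,
                 polarity = polarity)
}

#' Features for original and polarity-inverted stimuli
#'
#' Computes the rate surrogate for the waveform and for its sign-inverted
#' copy. Averaging TRF models fitted to the two cancels response
#' components that are odd in stimulus polarity (stimulus artifacts),
#' analogous to alternating-polarity click averaging.
#'
#' @param waveform numeric acoustic waveform.
#' @param fs sampling rate in Hz.
#' @param ... further arguments to [nerve_rate_surrogate()].
#' @return list with elements `original` and `inverted`, both
#'   [feature_series()] of equal length.
#' @export
make_polarity_pair <- function(waveform, fs, ...) {
  list(
    original = nerve_rate_surrogate(waveform, fs, ...,
                                    polarity = "original"),
    inverted = nerve_rate_surrogate(-waveform, fs, ...,
                                    polarity = "inverted")
  )
}

#' Trim segment edges and pad to a common length
#'
#' Removes `trim_s` seconds from both ends of every segment (discarding
#' onset responses and filter edge artifacts) and pads the tail of shorter
#' segments with `NA` up to `target_len` samples so that segments can be
#' stacked into a matrix. The returned mask records padded samples; the
#' `NA` markers are only replaced by zeros after feature-target scaling.
#'
#' @param features_by_segment list of numeric vectors or
#'   [feature_series()] objects sharing one sampling rate.
#' @param trim_s seconds trimmed from each end (>= 0).
#' @param fs sampling rate in Hz (taken from the first `feature_series`
#'   if absent).
#' @param target_len target length in samples; default the longest
#'   trimmed segment. Must not be shorter than that.
#' @return list with `features`: segment x time matrix (padded with `NA`),
#'   and `mask`: logical matrix of the same shape, `TRUE` where padded.
#' @export
trim_and_pad <- function(features_by_segment, trim_s, fs = NULL,
                         target_len = NULL) {
  if (trim_s < 0) stop("`trim_s` must be >= 0")
  vals <- lapply(features_by_segment, function(f) {
    if (inherits(f, "feature_series")) {
      if (is.null(fs)) fs <<- f$fs
      f$values
    } else {
      as.numeric(f)
    }
  })
  if (is.null(fs)) stop("`fs` required when passing plain vectors")
  nt <- round(trim_s * fs)
  trimmed <- lapply(vals, function(v) {
    if (length(v) <= 2 * nt) {
      stop("segment shorter than twice the trim duration")
    }
    v[(nt + 1L):(length(v) - nt)]
  })
  lens <- lengths(trimmed)
  if (is.null(target_len)) target_len <- max(lens)
  if (target_len < max(lens)) {
    stop("`target_len` shorter than the longest trimmed segment")
  }
  feats <- matrix(NA_real_, nrow = length(trimmed), ncol = target_len)
  mask <- matrix(TRUE, nrow = length(trimmed), ncol = target_len)
  for (i in seq_along(trimmed)) {
    feats[i, seq_len(lens[i])] <- trimmed[[i]]
    mask[i, seq_len(lens[i])] <- FALSE
  }
  list(features = feats, mask = mask)
}
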