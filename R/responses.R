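#' Evoked average across epochs
#'
#' Arithmetic mean over epochs per channel and time point (click-ABR or
#' AEP, depending on the epoch window).
#'
#' @param ep an `epoch_set` with at least one epoch.
#' @return object of class `evoked`: channel x time matrix (µV), `fs`,
#'   `t0`, `channels` and `n_epochs`.
#' @export
evoked_average <- function(ep) {
  stopifnot(inherits(ep, "epoch_set"))
  d <- dim(ep$data)
  if (d[1L] < 1) stop("no epochs to average")
  avg <- apply(ep$data, c(2L, 3L), mean, na.rm = TRUE)
  structure(
    list(data = avg, fs = ep$fs, t0 = ep$t0, channels = ep$channels,
         n_epochs = d[1L]),
    class = "evoked"
  )
}

#' @export
print.evoked <- function(x, ...) {
  cat(sprintf("<evoked> %d channel(s) x %d samples @ %g Hz, n = %d epochs\n",
              nrow(x$data), ncol(x$data), x$fs, x$n_epochs))
  invisible(x)
}

#' Baseline-correct and z-standardize TRF weights across a cohort
#'
#' Per participant, the mean weight over the baseline window is
#' subtracted (conventionally -10 to -5 ms for subcortical, -200 to -50
#' ms for cortical models); the baseline-corrected weights are then
#' z-standardized with a single mean and SD pooled over all participants'
#' samples, making waveforms dimensionless and comparable across the
#' cohort.
#'
#' @param weights list (one element per participant) of numeric vectors
#'   or lag x channel matrices on a common lag axis.
#' @param lag_times_s lag axis in seconds.
#' @param baseline_window `c(t1, t2)` in seconds.
#' @return list of standardized waveforms (same shapes); pooled `center`
#'   and `scale` are attached as attributes.
#' @export
standardize_weights <- function(weights, lag_times_s, baseline_window) {
  if (length(weights) < 2) stop("need >= 2 participants")
  sel <- lag_times_s >= baseline_window[1] & lag_times_s <= baseline_window[2]
  if (!any(sel)) stop("baseline window contains no lag samples")
  corrected <- lapply(weights, function(w) {
    w <- as.matrix(w)
    if (nrow(w) != length(lag_times_s)) {
      stop("weights do not match the lag axis")
    }
    sweep(w, 2L, colMeans(w[sel, , drop = FALSE]))
  })
  pool <- unlist(lapply(corrected, as.numeric))
  mu <- mean(pool)
  sdev <- sd(pool)
  if (!is.finite(sdev) || sdev == 0) stop("pooled SD is zero")
  out <- lapply(corrected, function(w) (w - mu) / sdev)
  attr(out, "center") <- mu
  attr(out, "scale") <- sdev
  out
}

#' Extract a response peak from a waveform
#'
#' Finds the extremum latency within a search window (argmax for
#' positive components such as wave V and P2, argmin for N1; the
#' earliest sample wins exact ties) and measures the mean amplitude over
#' an averaging window centered on that latency (3 ms for subcortical, 50
#' ms for cortical components by convention). The averaging window is
#' clipped at the waveform edges, with clipping flagged. A "peak" of the
#' wrong sign (e.g., no negative deflection in an N1 search) is flagged
#' `no_deflection`.
#'
#' @param waveform numeric vector.
#' @param times_ms time axis in ms (same length).
#' @param search_window `c(t1, t2)` in ms, inside the time axis.
#' @param polarity `"positive"` or `"negative"`.
#' @param avg_window_ms width of the amplitude-averaging window, ms.
#' @param component,response_type optional labels stored in the result.
#' @return object of class `peak_measure`: `latency_ms`,
#'   `mean_amplitude`, `peak_value`, flags `clipped` and `no_deflection`,
#'   plus the windows used.
#' @export
extract_peak <- function(waveform, times_ms, search_window,
                         polarity = c("positive", "negative"),
                         avg_window_ms, component = NA_character_,
                         response_type = NA_character_) {
  polarity <- match.arg(polarity)
  stopifnot(length(waveform) == length(times_ms))
  if (search_window[1] < min(times_ms) - 1e-9 ||
      search_window[2] > max(times_ms) + 1e-9) {
    stop("search window outside the waveform span")
  }
  sel <- which(times_ms >= search_window[1] & times_ms <= search_window[2])
  seg <- waveform[sel]
  i <- if (polarity == "positive") which.max(seg) else which.min(seg)
  latency <- times_ms[sel[i]]
  peak_value <- seg[i]
  no_deflection <- (polarity == "positive" && peak_value < 0) ||
    (polarity == "negative" && peak_value > 0)
  half <- avg_window_ms / 2
  win <- which(times_ms >= latency - half & times_ms <= latency + half)
  clipped <- (latency - half < min(times_ms) - 1e-9) ||
    (latency + half > max(times_ms) + 1e-9)
  structure(
    list(latency_ms = latency, mean_amplitude = mean(waveform[win]),
         peak_value = peak_value, clipped = clipped,
         no_deflection = no_deflection, search_window = search_window,
         avg_window_ms = avg_window_ms, polarity = polarity,
         component = component, response_type = response_type),
    class = "peak_measure"
  )
}

#' @export
print.peak_measure <- function(x, ...) {
  cat(sprintf("<peak_measure> %s%s: latency %.2f ms, mean amplitude %.4g%s%s\n",
              ifelse(is.na(x$component), x$polarity, x$component),
              ifelse(is.na(x$response_type), "",
                     paste0(" (", x$response_type, ")")),
              x$latency_ms, x$mean_amplitude,
              if (x$clipped) " [clipped]" else "",
              if (x$no_deflection) " [no deflection]" else ""))
  invisible(x)
}

#' Average a waveform over an electrode cluster
#'
#' Mean across the named channels of an `evoked`, a channel x time
#' matrix, or a lag x channel TRF weight matrix. Missing labels are
#' reported and averaged over the remainder; if none of the labels is
#' present this is a hard error.
#'
#' @param x an `evoked`, or a matrix with channels in rows (time in
#'   columns) or columns (named).
#' @param electrode_labels channels to average (default the
#'   frontotemporal cluster).
#' @return numeric waveform (the cluster mean).
#' @export
cluster_average <- function(x, electrode_labels = frontotemporal_cluster()) {
  if (inherits(x, "evoked")) {
    m <- x$data # channel x time
  } else if (inherits(x, "trf_model")) {
    m <- t(x$weights)
  } else {
    m <- as.matrix(x)
    if (!is.null(colnames(m)) && any(electrode_labels %in% colnames(m)) &&
        !any(electrode_labels %in% rownames(m))) {
      m <- t(m) # lag x channel input
    }
  }
  present <- intersect(electrode_labels, rownames(m))
  if (!length(present)) stop("none of the requested electrodes is present")
  if (length(present) < length(electrode_labels)) {
    message("missing electrode(s) skipped: ",
            paste(setdiff(electrode_labels, present), collapse = ", "))
  }
  colMeans(m[present, , drop = FALSE])
}

#' Cluster-based electrode permutation test
#'
#' Compares per-electrode scalar amplitudes between two groups with a
#' cluster-based permutation test: an independent-samples t statistic per
#' electrode, spatial clusters of electrodes exceeding the two-sided
#' cluster-forming threshold (same-sign neighbors), cluster mass = sum of
#' t values, and a null distribution of the maximum absolute cluster mass
#' under group-label shuffling. Seed-reproducible.
#'
#' @param groupA_amplitudes,groupB_amplitudes participant x electrode
#'   matrices (>= 2 rows each) with matching electrode columns.
#' @param adjacency logical electrode adjacency matrix; default
#'   [montage_adjacency()] on the column names.
#' @param n_perm number of permutations (>= 500).
#' @param cluster_alpha two-sided cluster-forming alpha (default 0.05).
#' @param alpha significance level for reporting clusters (default 0.05).
#' @param seed random seed.
#' @return object of class `electrode_perm_test`: per-electrode `t`,
#'   `clusters` (data.frame with electrodes, mass, p), `significant`
#'   (any cluster p < alpha) and the null max-mass sample.
#' @export
electrode_permutation_test <- function(groupA_amplitudes,
                                       groupB_amplitudes,
                                       adjacency = NULL, n_perm = 1000,
                                       cluster_alpha = 0.05, alpha = 0.05,
                                       seed = NULL) {
  A <- as.matrix(groupA_amplitudes)
  B <- as.matrix(groupB_amplitudes)
  if (nrow(A) < 2 || nrow(B) < 2) stop("each group needs >= 2 participants")
  if (ncol(A) != ncol(B)) stop("electrode sets differ between groups")
  if (n_perm < 500) stop("`n_perm` must be >= 500")
  E <- ncol(A)
  labels <- colnames(A)
  if (is.null(labels)) labels <- paste0("e", seq_len(E))
  if (is.null(adjacency)) {
    adjacency <- tryCatch(montage_adjacency(labels),
                          error = function(e) {
                            matrix(FALSE, E, E,
                                   dimnames = list(labels, labels))
                          })
  }
  nA <- nrow(A)
  nB <- nrow(B)
  X <- rbind(A, B)
  n <- nA + nB
  df <- n - 2
  tcrit <- qt(1 - cluster_alpha / 2, df)

  tstat <- function(idxA) {
    xa <- X[idxA, , drop = FALSE]
    xb <- X[-idxA, , drop = FALSE]
    ma <- colMeans(xa)
    mb <- colMeans(xb)
    va <- colSums(sweep(xa, 2L, ma)^2)
    vb <- colSums(sweep(xb, 2L, mb)^2)
    sp2 <- (va + vb) / df
    (ma - mb) / sqrt(sp2 * (1 / nA + 1 / nB))
  }

  max_mass <- function(tv) {
    m <- 0
    for (sgn in c(1, -1)) {
      supra <- which(sgn * tv > tcrit)
      if (!length(supra)) next
      comps <- .components(adjacency, supra)
      for (cmp in comps) m <- max(m, abs(sum(tv[cmp])))
    }
    m
  }

  t_obs <- tstat(seq_len(nA))
  # observed clusters
  clusters <- list()
  for (sgn in c(1, -1)) {
    supra <- which(sgn * t_obs > tcrit)
    if (!length(supra)) next
    for (cmp in .components(adjacency, supra)) {
      clusters[[length(clusters) + 1L]] <-
        list(electrodes = labels[cmp], sign = sgn,
             mass = sum(t_obs[cmp]))
    }
  }

  if (!is.null(seed)) {
    withr_seed <- .preserve_seed()
    on.exit(.restore_seed(withr_seed))
    set.seed(as.integer(seed))
  }
  null_max <- numeric(n_perm)
  for (p in seq_len(n_perm)) {
    idxA <- sample.int(n, nA)
    null_max[p] <- max_mass(tstat(idxA))
  }
  cl_df <- if (length(clusters)) {
    data.frame(
      electrodes = vapply(clusters, function(cl)
        paste(cl$electrodes, collapse = ","), character(1)),
      mass = vapply(clusters, `[[`, numeric(1), "mass"),
      p = vapply(clusters, function(cl)
        (1 + sum(null_max >= abs(cl$mass))) / (1 + n_perm), numeric(1)),
      stringsAsFactors = FALSE
    )
  } else {
    data.frame(electrodes = character(), mass = numeric(), p = numeric())
  }
  structure(
    list(t = setNames(t_obs, labels), clusters = cl_df,
         significant = any(cl_df$p < alpha), null_max = null_max,
         cluster_alpha = cluster_alpha, alpha = alpha, n_perm = n_perm),
    class = "electrode_perm_test"
  )
}

#' @export
print.electrode_perm_test <- function(x, ...) {
  cat(sprintf("<electrode_perm_test> %d permutation(s), %d cluster(s)%s\n",
              x$n_perm, nrow(x$clusters),
              if (x$significant) " [significant]" else ""))
  if (nrow(x$clusters)) print(x$clusters)
  invisible(x)
}

#' Tidy peak table for a cohort
#'
#' Convenience assembler: one row per participant x response type x
#' component, in the tidy layout consumed by the statistics layer.
#'
#' @param peaks list (per participant) of lists of `peak_measure`
#'   objects.
#' @param participants participant identifiers.
#' @param groups group labels.
#' @return data.frame with columns participant, group, response_type,
#'   component, latency_ms, amplitude, clipped, no_deflection.
#' @export
peak_table <- function(peaks, participants, groups) {
  rows <- list()
  for (i in seq_along(peaks)) {
    for (pk in peaks[[i]]) {
      rows[[length(rows) + 1L]] <- data.frame(
        participant = participants[i], group = groups[i],
        response_type = pk$response_type, component = pk$component,
        latency_ms = pk$latency_ms, amplitude = pk$mean_amplitude,
        clipped = pk$clipped, no_deflection = pk$no_deflection,
        stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, rows)
}
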