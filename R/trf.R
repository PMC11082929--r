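#' Lag design for TRF estimation
#'
#' Defines the lag axis of a temporal response function: all integer
#' sample lags between `tmin_lag` and `tmax_lag` at sampling rate `fs`.
#' Subcortical models conventionally span -10 to 30 ms, cortical models
#' -300 to 600 ms.
#'
#' @param tmin_lag,tmax_lag lag range in seconds (`tmin_lag < tmax_lag`).
#' @param fs sampling rate in Hz.
#' @return object of class `lag_design` with integer sample lags, lag
#'   times in seconds and `n_lags = round((tmax - tmin) * fs) + 1`.
#' @export
#' @examples
#' lag_design(-0.01, 0.03, 4096)$n_lags  # 165
lag_design <- function(tmin_lag, tmax_lag, fs) {
  if (tmin_lag >= tmax_lag) stop("`tmin_lag` must be below `tmax_lag`")
  if (fs <= 0) stop("`fs` must be positive")
  smin <- round(tmin_lag * fs)
  smax <- round(tmax_lag * fs)
  if (smax <= smin) stop("lag range shorter than one sample")
  lags <- seq.int(smin, smax)
  structure(
    list(tmin_lag = tmin_lag, tmax_lag = tmax_lag, fs = fs,
         lags = lags, lag_times = lags / fs,
         n_lags = length(lags)),
    class = "lag_design"
  )
}

#' Time-lagged design matrix of a stimulus feature
#'
#' Column `j` holds the feature delayed by `lags[j]` samples (zero-filled
#' outside the segment); row `t` corresponds to response time `t`, so
#' `S[t, j] = feature[t - lags[j]]`. Negative lags are acausal columns.
#'
#' @param feature numeric vector (a scaled feature segment; `NA`s should
#'   have been replaced by zeros beforehand, see [scale_pair()]).
#' @param design a [lag_design()].
#' @return a `length(feature)` x `n_lags` matrix.
#' @export
lag_matrix <- function(feature, design) {
  stopifnot(inherits(design, "lag_design"))
  f <- as.numeric(feature)
  n <- length(f)
  if (n <= design$n_lags) stop("feature shorter than the lag span")
  S <- matrix(0, n, design$n_lags)
  for (j in seq_len(design$n_lags)) {
    lg <- design$lags[j]
    if (lg >= 0) {
      if (lg < n) S[(lg + 1L):n, j] <- f[1L:(n - lg)]
    } else {
      if (-lg < n) S[1L:(n + lg), j] <- f[(1L - lg):n]
    }
  }
  S
}

#' Laplacian (second-difference) regularization matrix
#'
#' `M = t(D) %*% D` with `D` the first-difference operator: main diagonal
#' `(1, 2, ..., 2, 1)`, first off-diagonals `-1`. Penalizing `w' M w`
#' shrinks the squared differences of neighboring lag weights, imposing
#' smoothness. `M` is symmetric positive semidefinite with the constant
#' vector in its null space.
#'
#' @param n_lags number of lags (>= 2).
#' @return an `n_lags` x `n_lags` matrix.
#' @export
laplacian_matrix <- function(n_lags) {
  if (n_lags < 2) stop("`n_lags` must be >= 2")
  M <- diag(c(1, rep(2, n_lags - 2L), 1))
  idx <- seq_len(n_lags - 1L)
  M[cbind(idx, idx + 1L)] <- -1
  M[cbind(idx + 1L, idx)] <- -1
  M
}

#' Laplacian-regularized ridge solution
#'
#' Solves `(S'S + lambda * M) w = S'r` per response channel, i.e. the
#' smoothness-penalized least-squares TRF weights, via a linear solve (no
#' explicit inverse). A singular system gets a tiny diagonal jitter
#' (`1e-10 * trace`) with a message; if it is still singular this is a
#' hard error.
#'
#' @param S time x lag design matrix (see [lag_matrix()]).
#' @param r response vector or time x channel matrix.
#' @param lambda regularization parameter (>= 0).
#' @param M penalty matrix; default [laplacian_matrix()] of matching size.
#' @return lag x channel weight matrix (a plain vector for a single
#'   channel response vector input).
#' @export
ridge_solve <- function(S, r, lambda, M = NULL) {
  S <- as.matrix(S)
  vec <- is.null(dim(r))
  r <- as.matrix(r)
  if (nrow(S) != nrow(r)) stop("`S` and `r` must have equal rows")
  if (lambda < 0) stop("`lambda` must be >= 0")
  if (is.null(M)) M <- laplacian_matrix(ncol(S))
  w <- .ridge_solve_gram(crossprod(S), crossprod(S, r), lambda, M)
  if (vec) as.numeric(w) else w
}

.ridge_solve_gram <- function(XtX, Xty, lambda, M) {
  A <- XtX + lambda * M
  w <- tryCatch(solve(A, Xty), error = function(e) NULL)
  if (is.null(w)) {
    message("singular system; adding 1e-10 * trace jitter")
    A <- A + diag(1e-10 * sum(diag(A)), nrow(A))
    w <- tryCatch(solve(A, Xty), error = function(e) {
      stop("system singular even after jitter")
    })
  }
  w
}

#' Feature-target scaling with train-set statistics
#'
#' Z-standardizes the EEG globally (one mean/SD over all epochs, channels
#' and valid samples, computed before any train/test split) and
#' standardizes the features with training-subset statistics (mean/SD by
#' default, max-normalization optionally). Only after scaling are missing
#' markers (`NA`: padding, zeroed artifact segments) replaced by zeros, so
#' the statistics are not biased by them.
#'
#' @param features list of numeric feature vectors (one per segment),
#'   possibly containing `NA`.
#' @param eeg list of time x channel response matrices (one per segment),
#'   possibly containing `NA`.
#' @param train_ids indices of training segments (non-empty).
#' @param feature_norm `"zscore"` (default) or `"max"`.
#' @return list with `features`, `eeg` (scaled, `NA` replaced by 0) and
#'   `state`: an object of class `scaling_state` holding the statistics.
#' @export
scale_pair <- function(features, eeg, train_ids,
                       feature_norm = c("zscore", "max")) {
  feature_norm <- match.arg(feature_norm)
  if (!length(train_ids)) stop("`train_ids` must be non-empty")
  all_eeg <- unlist(lapply(eeg, as.numeric))
  mu_r <- mean(all_eeg, na.rm = TRUE)
  sd_r <- sd(all_eeg, na.rm = TRUE)
  if (!is.finite(sd_r) || sd_r == 0) stop("EEG has zero variance")
  train_f <- unlist(lapply(features[train_ids], as.numeric))
  mu_f <- mean(train_f, na.rm = TRUE)
  if (feature_norm == "zscore") {
    sc_f <- sd(train_f, na.rm = TRUE)
  } else {
    mu_f <- 0
    sc_f <- max(abs(train_f), na.rm = TRUE)
  }
  if (!is.finite(sc_f) || sc_f == 0) stop("features have zero variance")
  fs_out <- lapply(features, function(f) {
    v <- (as.numeric(f) - mu_f) / sc_f
    v[is.na(v)] <- 0
    v
  })
  eeg_out <- lapply(eeg, function(r) {
    m <- (as.matrix(r) - mu_r) / sd_r
    m[is.na(m)] <- 0
    m
  })
  state <- structure(
    list(eeg_mean = mu_r, eeg_sd = sd_r, feature_center = mu_f,
         feature_scale = sc_f, feature_norm = feature_norm),
    class = "scaling_state"
  )
  list(features = fs_out, eeg = eeg_out, state = state)
}

#' Invert a scaling (valid samples only)
#'
#' @param x scaled numeric data.
#' @param state a `scaling_state`.
#' @param what `"eeg"` or `"feature"`.
#' @return data on the original scale.
#' @export
unscale <- function(x, state, what = c("eeg", "feature")) {
  what <- match.arg(what)
  if (what == "eeg") {
    x * state$eeg_sd + state$eeg_mean
  } else {
    x * state$feature_scale + state$feature_center
  }
}

# per-segment Gram matrices for fast cross-validation and refitting
.segment_grams <- function(features, eeg, design) {
  lapply(seq_along(features), function(i) {
    S <- lag_matrix(features[[i]], design)
    list(XtX = crossprod(S), Xty = crossprod(S, as.matrix(eeg[[i]])))
  })
}

#' Pearson encoding accuracy
#'
#' Correlation between predicted and actual response, per channel. A
#' constant prediction (or constant actual) makes the correlation
#' undefined; it is returned as 0 with a warning.
#'
#' @param pred,actual time x channel matrices (or vectors).
#' @return numeric vector of per-channel correlations in `[-1, 1]`.
#' @export
encoding_accuracy <- function(pred, actual) {
  pred <- as.matrix(pred)
  actual <- as.matrix(actual)
  stopifnot(identical(dim(pred), dim(actual)))
  r <- vapply(seq_len(ncol(pred)), function(j) {
    sp <- sd(pred[, j])
    sa <- sd(actual[, j])
    if (!is.finite(sp) || !is.finite(sa) || sp == 0 || sa == 0) {
      warning("constant prediction or response; accuracy set to 0")
      return(0)
    }
    cor(pred[, j], actual[, j])
  }, numeric(1))
  r
}

#' Leave-one-segment-out search for the ridge parameter
#'
#' For every `lambda` on the grid, each training segment is held out
#' once: the model is fitted on the remaining segments and the held-out
#' segment's encoding accuracy (Pearson r, averaged over channels) is
#' recorded. Returns the `lambda` maximizing the fold-mean accuracy
#' (ties broken toward the smaller `lambda`, i.e. least smoothing) and
#' the full accuracy curve. Inputs are assumed already scaled
#' (see [scale_pair()]).
#'
#' @param features list of scaled feature vectors (training segments).
#' @param eeg list of scaled time x channel response matrices.
#' @param design a [lag_design()].
#' @param lambda_grid candidate values; default `10^(-3:9)`.
#' @param M penalty matrix; default [laplacian_matrix()].
#' @return list with `best_lambda`, `curve` (data.frame lambda/accuracy)
#'   and `fold_accuracy` (fold x lambda matrix).
#' @export
cv_lambda <- function(features, eeg, design, lambda_grid = 10^(-3:9),
                      M = NULL, grams = NULL) {
  n_seg <- length(features)
  if (n_seg < 2) stop("need at least 2 training segments")
  if (is.null(M)) M <- laplacian_matrix(design$n_lags)
  if (is.null(grams)) grams <- .segment_grams(features, eeg, design)
  XtX_tot <- Reduce(`+`, lapply(grams, `[[`, "XtX"))
  Xty_tot <- Reduce(`+`, lapply(grams, `[[`, "Xty"))
  acc <- matrix(NA_real_, n_seg, length(lambda_grid))
  for (f in seq_len(n_seg)) {
    XtX <- XtX_tot - grams[[f]]$XtX
    Xty <- Xty_tot - grams[[f]]$Xty
    Sval <- lag_matrix(features[[f]], design)
    rval <- as.matrix(eeg[[f]])
    for (l in seq_along(lambda_grid)) {
      w <- .ridge_solve_gram(XtX, Xty, lambda_grid[l], M)
      pred <- Sval %*% w
      acc[f, l] <- suppressWarnings(mean(encoding_accuracy(pred, rval)))
    }
  }
  curve <- data.frame(lambda = lambda_grid, accuracy = colMeans(acc))
  best <- which(curve$accuracy == max(curve$accuracy))[1L]
  list(best_lambda = lambda_grid[best], curve = curve,
       fold_accuracy = acc)
}

#' Fit a TRF on a set of segments
#'
#' Concatenates segment lag matrices (equivalently: sums segment Gram
#' matrices) and solves the Laplacian-regularized normal equations.
#'
#' @param features list of scaled feature vectors.
#' @param eeg list of scaled time x channel response matrices.
#' @param design a [lag_design()].
#' @param lambda ridge parameter.
#' @param channels optional channel labels.
#' @param M penalty matrix; default [laplacian_matrix()].
#' @return object of class `trf_model`: lag x channel `weights`,
#'   `lambda`, `design`, `channels`, `polarity = "single"` and slots for
#'   accuracies.
#' @export
fit_trf <- function(features, eeg, design, lambda, channels = NULL,
                    M = NULL, grams = NULL) {
  if (is.null(M)) M <- laplacian_matrix(design$n_lags)
  if (is.null(grams)) grams <- .segment_grams(features, eeg, design)
  XtX <- Reduce(`+`, lapply(grams, `[[`, "XtX"))
  Xty <- Reduce(`+`, lapply(grams, `[[`, "Xty"))
  w <- .ridge_solve_gram(XtX, Xty, lambda, M)
  w <- as.matrix(w)
  if (is.null(channels)) channels <- colnames(as.matrix(eeg[[1]]))
  if (is.null(channels)) channels <- paste0("ch", seq_len(ncol(w)))
  colnames(w) <- channels
  structure(
    list(weights = w, lambda = lambda, design = design,
         channels = channels, polarity = "single",
         accuracy = NULL, cv = NULL),
    class = "trf_model"
  )
}

#' @export
print.trf_model <- function(x, ...) {
  cat(sprintf(
    "<trf_model> %d lags (%g..%g s) x %d channel(s), lambda = %g, %s\n",
    x$design$n_lags, x$design$tmin_lag, x$design$tmax_lag,
    ncol(x$weights), x$lambda, x$polarity))
  if (!is.null(x$accuracy)) {
    cat(sprintf("  test encoding accuracy (mean r): %.4f\n",
                mean(x$accuracy)))
  }
  invisible(x)
}

#' Predict the response to a feature segment
#'
#' @param object a `trf_model`.
#' @param feature scaled feature vector.
#' @param ... unused.
#' @return time x channel matrix of predicted (scaled) responses.
#' @export
predict.trf_model <- function(object, feature, ...) {
  S <- lag_matrix(feature, object$design)
  S %*% object$weights
}

#' Full participant-level TRF fit
#'
#' The complete modeling procedure for one participant and one level:
#' random segment-level train/test split (default 22 training / 3 test
#' segments scaled to the available count), global EEG z-scoring and
#' train-statistics feature normalization, leave-one-segment-out search
#' of `lambda` over the grid, final fit on all training segments at the
#' best `lambda`, and test-set encoding accuracy (per segment, then
#' averaged; per channel, then averaged across electrodes).
#'
#' @param features list of feature vectors (may contain `NA` padding).
#' @param eeg list of time x channel response matrices (may contain `NA`).
#' @param design a [lag_design()].
#' @param lambda_grid candidate ridge parameters; default `10^(-3:9)`.
#' @param n_test number of held-out test segments (default 3).
#' @param seed seed for the random split.
#' @param feature_norm passed to [scale_pair()].
#' @param channels optional channel labels.
#' @return a `trf_model` with `accuracy` (per-channel test r), `cv`
#'   (accuracy curve), `split` and `scaling` filled in.
#' @export
fit_participant <- function(features, eeg, design,
                            lambda_grid = 10^(-3:9), n_test = 3,
                            seed = 1L, feature_norm = "zscore",
                            channels = NULL) {
  n_seg <- length(features)
  if (n_test >= n_seg) stop("`n_test` must leave at least 2 training segments")
  withr_seed <- .preserve_seed()
  on.exit(.restore_seed(withr_seed))
  set.seed(as.integer(seed))
  test_ids <- sort(sample.int(n_seg, n_test))
  train_ids <- setdiff(seq_len(n_seg), test_ids)
  sc <- scale_pair(features, eeg, train_ids, feature_norm = feature_norm)
  grams <- .segment_grams(sc$features[train_ids], sc$eeg[train_ids],
                          design)
  cv <- cv_lambda(sc$features[train_ids], sc$eeg[train_ids], design,
                  lambda_grid = lambda_grid, grams = grams)
  model <- fit_trf(sc$features[train_ids], sc$eeg[train_ids], design,
                   lambda = cv$best_lambda, channels = channels,
                   grams = grams)
  test_acc <- vapply(test_ids, function(i) {
    pred <- predict(model, sc$features[[i]])
    mean(encoding_accuracy(pred, sc$eeg[[i]]))
  }, numeric(1))
  per_ch <- rowMeans(matrix(vapply(test_ids, function(i) {
    pred <- predict(model, sc$features[[i]])
    encoding_accuracy(pred, sc$eeg[[i]])
  }, numeric(ncol(model$weights))), nrow = ncol(model$weights)))
  model$accuracy <- per_ch
  model$accuracy_mean <- mean(test_acc)
  model$cv <- cv
  model$split <- list(train = train_ids, test = test_ids, seed = seed)
  model$scaling <- sc$state
  model
}

#' Dual-polarity TRF fit
#'
#' Runs the full participant-level fit once with the original-polarity
#' features and once with the inverted-polarity features (each with its
#' own cross-validated `lambda`), then averages weights and accuracies
#' element-wise. Response components that are odd in stimulus polarity
#' (stimulus artifacts) cancel in the average.
#'
#' @param features_orig,features_inv lists of feature vectors covering
#'   identical segments.
#' @param eeg list of response matrices.
#' @param ... passed to [fit_participant()] (same split seed for both
#'   polarities).
#' @return a `trf_model` with `polarity = "averaged"` and both component
#'   fits in `$fits`.
#' @export
fit_dual_polarity <- function(features_orig, features_inv, eeg, ...) {
  if (length(features_orig) != length(features_inv)) {
    stop("polarities must cover identical segments")
  }
  fit1 <- fit_participant(features_orig, eeg, ...)
  fit2 <- fit_participant(features_inv, eeg, ...)
  out <- fit1
  out$weights <- (fit1$weights + fit2$weights) / 2
  out$accuracy <- (fit1$accuracy + fit2$accuracy) / 2
  out$accuracy_mean <- (fit1$accuracy_mean + fit2$accuracy_mean) / 2
  out$lambda <- c(original = fit1$lambda, inverted = fit2$lambda)
  out$polarity <- "averaged"
  out$fits <- list(original = fit1, inverted = fit2)
  out
}
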