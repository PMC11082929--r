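#' Mann-Whitney U test with rank-biserial effect size
#'
#' Wraps [stats::wilcox.test()] (exact enumeration for small samples
#' without ties, otherwise the normal approximation with tie correction)
#' and adds the rank-biserial correlation `r = 2U / (n1 * n2) - 1`, where
#' `U` counts pairs in which `x` exceeds `y` (midrank tie handling).
#'
#' @param x,y numeric samples (non-empty).
#' @param alternative `"two.sided"`, `"greater"` (x tends larger) or
#'   `"less"`.
#' @return object of class `mw_test`: `U`, `p`, `r`, `alternative`,
#'   `n1`, `n2`.
#' @export
#' @examples
#' rank_biserial(311.5, 19, 25)  # 0.31
mann_whitney <- function(x, y,
                         alternative = c("two.sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  if (!length(x) || !length(y)) stop("samples must be non-empty")
  wt <- suppressWarnings(
    wilcox.test(x, y, alternative = alternative, correct = TRUE))
  U <- unname(wt$statistic)
  structure(
    list(U = U, p = wt$p.value, r = rank_biserial(U, length(x), length(y)),
         alternative = alternative, n1 = length(x), n2 = length(y)),
    class = "mw_test"
  )
}

#' @export
print.mw_test <- function(x, ...) {
  cat(sprintf("Mann-Whitney U = %g, p = %.4g, rank-biserial r = %.3f (%s)\n",
              x$U, x$p, x$r, x$alternative))
  invisible(x)
}

#' Rank-biserial correlation from a U statistic
#'
#' `r = 2U / (n1 * n2) - 1`; the effect size conventionally reported next
#' to a Mann-Whitney U test.
#'
#' @param U the U statistic (pairs in which sample 1 exceeds sample 2).
#' @param n1,n2 group sizes.
#' @return numeric in `[-1, 1]`.
#' @export
rank_biserial <- function(U, n1, n2) {
  2 * U / (n1 * n2) - 1
}

#' Spearman rank correlation with Fisher z
#'
#' Wraps [stats::cor.test()] with `method = "spearman"` (exact p where
#' the implementation supports it, otherwise the t approximation with
#' midranks) and adds Fisher's `z = atanh(rho)`. Constant input makes the
#' coefficient undefined; it is returned as `NA` with `flagged = TRUE`.
#'
#' @param x,y numeric vectors (n >= 3).
#' @return object of class `spearman_test`: `rho`, `p`, `fisher_z`, `n`,
#'   `flagged`.
#' @export
spearman_test <- function(x, y) {
  if (length(x) != length(y)) stop("lengths differ")
  if (length(x) < 3) stop("need n >= 3")
  if (sd(x) == 0 || sd(y) == 0) {
    warning("constant input; Spearman correlation undefined")
    return(structure(list(rho = NA_real_, p = NA_real_,
                          fisher_z = NA_real_, n = length(x),
                          flagged = TRUE),
                     class = "spearman_test"))
  }
  ct <- suppressWarnings(cor.test(x, y, method = "spearman"))
  rho <- unname(ct$estimate)
  structure(
    list(rho = rho, p = ct$p.value,
         fisher_z = atanh(max(min(rho, 1 - 1e-15), -1 + 1e-15)),
         n = length(x), flagged = FALSE),
    class = "spearman_test"
  )
}

#' @export
print.spearman_test <- function(x, ...) {
  cat(sprintf("Spearman rho = %.3f, p = %.4g, Fisher z = %.3f (n = %d)\n",
              x$rho, x$p, x$fisher_z, x$n))
  invisible(x)
}

#' Design matrix for the group-prediction logistic model
#'
#' Builds the design of the model `group ~ waveV * N1P2_diff + PTA + age`
#' from a cohort table: columns intercept, wave V amplitude, absolute
#' N1-P2 amplitude difference, PTA, age, and the wave V x N1-P2
#' interaction (elementwise product of the two main-effect columns).
#' Group is coded low = 0, normal = 1. TRF-derived amplitudes enter
#' z-standardized (`standardize = TRUE`); evoked amplitudes conventionally
#' stay in µV.
#'
#' @param cohort data.frame with columns `group` (`"low"`/`"normal"`),
#'   `waveV_amp`, `N1_amp`, `P2_amp`, `pta`, `age`.
#' @param standardize z-score the wave V and N1-P2 difference columns.
#' @return list with `X` (n x 6 design matrix), `y` (0/1 response) and
#'   `dropped` (row indices removed for missing covariates).
#' @export
build_design <- function(cohort, standardize = TRUE) {
  need <- c("group", "waveV_amp", "N1_amp", "P2_amp", "pta", "age")
  miss <- setdiff(need, names(cohort))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  n1p2 <- abs(cohort$P2_amp - cohort$N1_amp)
  complete <- complete.cases(cohort[, need]) & !is.na(n1p2)
  dropped <- which(!complete)
  if (length(dropped)) {
    warning(length(dropped), " row(s) dropped for missing covariates")
  }
  d <- cohort[complete, ]
  n1p2 <- n1p2[complete]
  wv <- d$waveV_amp
  if (standardize) {
    wv <- as.numeric(scale(wv))
    n1p2 <- as.numeric(scale(n1p2))
  }
  X <- cbind(
    `(Intercept)` = 1,
    waveV = wv,
    n1p2_diff = n1p2,
    pta = d$pta,
    age = d$age,
    `waveV:n1p2_diff` = wv * n1p2
  )
  y <- ifelse(d$group == "normal", 1L, 0L)
  list(X = X, y = y, dropped = dropped)
}

#' Frequentist logistic regression (Bernoulli GLM, logit link)
#'
#' Maximum likelihood via iteratively reweighted least squares
#' ([stats::glm.fit()]), with Wald standard errors, z statistics, p
#' values and Wald 95% confidence intervals. Quasi-complete separation is
#' detected (fitted probabilities pinned at 0/1 or runaway coefficients)
#' and flagged rather than silently diverging.
#'
#' @param X design matrix including an intercept column.
#' @param y 0/1 response with at least 2 observations per class.
#' @param conf_level confidence level (default 0.95).
#' @return object of class `logistic_fit`: coefficient `table`
#'   (estimate, se, z, p, ll, ul), `separation` flag, `converged`,
#'   `loglik`.
#' @export
logistic_fit <- function(X, y, conf_level = 0.95) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  if (min(table(factor(y, levels = 0:1))) < 2) {
    stop("need >= 2 observations per class")
  }
  warned <- FALSE
  fit <- withCallingHandlers(
    glm.fit(X, y, family = binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities", conditionMessage(w))) {
        warned <<- TRUE
        invokeRestart("muffleWarning")
      }
    }
  )
  cf <- fit$coefficients
  # aliased (e.g. all-constant) predictors carry no information: report
  # a zero coefficient with an undefined standard error
  aliased <- is.na(cf)
  cf[aliased] <- 0
  # Wald covariance from the final IRLS weights
  W <- fit$weights
  XtWX <- crossprod(X * sqrt(W))
  vc <- tryCatch(solve(XtWX), error = function(e) {
    matrix(NA_real_, ncol(X), ncol(X))
  })
  se <- sqrt(diag(vc))
  se[aliased] <- NA_real_
  z <- cf / se
  p <- 2 * pnorm(-abs(z))
  q <- qnorm(1 - (1 - conf_level) / 2)
  separation <- warned || any(abs(cf) > 15, na.rm = TRUE)
  if (separation) warning("possible separation; estimates unreliable")
  tab <- data.frame(
    term = colnames(X), estimate = unname(cf), se = se, z = unname(z),
    p = unname(p), ll = unname(cf - q * se), ul = unname(cf + q * se),
    row.names = NULL, stringsAsFactors = FALSE
  )
  ll <- sum(dbinom(y, 1, pmin(pmax(fit$fitted.values, 1e-12),
                              1 - 1e-12), log = TRUE))
  structure(
    list(table = tab, separation = separation,
         converged = fit$converged, loglik = ll, fitted = fit$fitted.values),
    class = "logistic_fit"
  )
}

#' @export
print.logistic_fit <- function(x, ...) {
  cat("Logistic regression (Bernoulli GLM, logit link)\n")
  if (x$separation) cat("  WARNING: possible separation\n")
  print(x$table, digits = 3)
  invisible(x)
}
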