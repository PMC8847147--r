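#' Case-resampling bootstrap
#'
#' Resamples rows of `data` with replacement and evaluates `statistic` on
#' each resample. The resampling unit is the individual row within the
#' analysis stratum (call once per year under the local scheme). Resamples on
#' which the statistic fails (error or non-finite result — e.g. a
#' rank-deficient regression design) are re-drawn and counted: more than 1%
#' re-draws triggers a warning, more than 10% an error.
#'
#' @param data data.frame, matrix, or vector; rows/elements are resampled.
#' @param statistic function of one resample returning a numeric scalar or
#'   vector of fixed length.
#' @param n_replicates number of bootstrap replicates (default 10,000).
#' @param seed optional integer seed (sets the RNG; identical seeds give
#'   identical replicate sets).
#' @return matrix of replicates (`n_replicates` x length of statistic) with
#'   attribute `n_redrawn`.
#' @export
case_bootstrap <- function(data, statistic, n_replicates = 10000, seed = NULL) {
  if (n_replicates < 1) stop("case_bootstrap: n_replicates must be >= 1", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  n <- if (is.null(dim(data))) length(data) else nrow(data)
  take <- function(idx) if (is.null(dim(data))) data[idx] else data[idx, , drop = FALSE]
  proto <- statistic(take(seq_len(n)))
  p <- length(proto)
  reps <- matrix(NA_real_, n_replicates, p)
  colnames(reps) <- names(proto)
  redrawn <- 0L
  max_fail <- ceiling(0.10 * n_replicates)
  b <- 1L
  while (b <= n_replicates) {
    idx <- sample.int(n, n, replace = TRUE)
    val <- tryCatch(statistic(take(idx)), error = function(e) NULL)
    if (is.null(val) || length(val) != p || any(!is.finite(val))) {
      redrawn <- redrawn + 1L
      if (redrawn > max_fail) {
        stop("case_bootstrap: more than 10% of resamples failed (", redrawn,
             " re-draws); statistic is unstable on resamples", call. = FALSE)
      }
      next
    }
    reps[b, ] <- val
    b <- b + 1L
  }
  if (redrawn > 0.01 * n_replicates) {
    warning("case_bootstrap: ", redrawn, " resamples re-drawn (>1% of replicates)",
            call. = FALSE)
  }
  attr(reps, "n_redrawn") <- redrawn
  reps
}

#' Leave-one-out jackknife of a statistic
#'
#' The jackknife runs over the same unit as the case bootstrap (data rows),
#' as required for the acceleration constant of the BCa interval.
#'
#' @inheritParams case_bootstrap
#' @return matrix (n x length of statistic) of leave-one-out values.
#' @export
jackknife <- function(data, statistic) {
  n <- if (is.null(dim(data))) length(data) else nrow(data)
  take <- function(idx) if (is.null(dim(data))) data[idx] else data[idx, , drop = FALSE]
  proto <- statistic(take(seq_len(n)))
  out <- matrix(NA_real_, n, length(proto))
  colnames(out) <- names(proto)
  for (i in seq_len(n)) out[i, ] <- statistic(take(-i))
  out
}

#' Bias-corrected and accelerated (BCa) bootstrap interval
#'
#' First-principles BCa construction. The bias correction is
#' \deqn{z_0 = \Phi^{-1}\left(\frac{\#\{\theta^*_b < \hat\theta\} +
#'   \tfrac12\#\{\theta^*_b = \hat\theta\}}{B}\right)}
#' (mid-rank convention for ties, so discrete statistics do not produce an
#' infinite \eqn{z_0}); the acceleration comes from the jackknife skewness
#' \deqn{a = \frac{\sum_i (\bar\theta_{(\cdot)} - \theta_{(i)})^3}
#'   {6\left[\sum_i (\bar\theta_{(\cdot)} - \theta_{(i)})^2\right]^{3/2}}.}
#' The adjusted percentiles
#' \eqn{\alpha_k = \Phi\left(z_0 + \frac{z_0 + z^{(k)}}{1 - a(z_0 + z^{(k)})}\right)}
#' are applied to the empirical replicate distribution with type-7 linear
#' interpolation (the stated quantile rule, for bit-reproducibility).
#'
#' Degenerate replicate sets (< 2 distinct values) return the point as both
#' bounds. If all replicates fall on one side of the original (\eqn{z_0}
#' infinite even after the mid-rank convention) the function falls back to
#' the plain percentile interval with a warning.
#'
#' @param replicates numeric vector of bootstrap replicate statistics.
#' @param original the statistic on the original data.
#' @param jackknife_values leave-one-out statistics (for acceleration).
#' @param level confidence level in (0, 1), default 0.95.
#' @return numeric `c(lower, upper)` with attribute `method` ("bca" or
#'   "percentile_fallback").
#' @export
bca_interval <- function(replicates, original, jackknife_values, level = 0.95) {
  if (level <= 0 || level >= 1) stop("bca_interval: level must be in (0, 1)", call. = FALSE)
  B <- length(replicates)
  if (length(unique(replicates)) < 2) {
    return(structure(c(replicates[1], replicates[1]), method = "degenerate"))
  }
  alpha <- (1 - level) / 2
  prop <- (sum(replicates < original) + 0.5 * sum(replicates == original)) / B
  if (prop <= 0 || prop >= 1) {
    warning("bca_interval: all replicates on one side of the original estimate; ",
            "falling back to the percentile interval", call. = FALSE)
    out <- stats::quantile(replicates, c(alpha, 1 - alpha), names = FALSE, type = 7)
    return(structure(out, method = "percentile_fallback"))
  }
  z0 <- stats::qnorm(prop)
  d <- mean(jackknife_values) - jackknife_values
  denom <- 6 * sum(d^2)^1.5
  a <- if (denom == 0) 0 else sum(d^3) / denom
  zlo <- stats::qnorm(alpha)
  zhi <- stats::qnorm(1 - alpha)
  adj <- function(z) {
    g <- z0 + z
    stats::pnorm(z0 + g / (1 - a * g))
  }
  out <- stats::quantile(replicates, c(adj(zlo), adj(zhi)), names = FALSE, type = 7)
  structure(out, method = "bca")
}

#' Significance by interval exclusion of zero
#'
#' An estimate is significant at the interval's level iff 0 lies outside the
#' closed interval \[lower, upper\] — an endpoint exactly at 0 is NOT
#' significant.
#'
#' @param interval numeric `c(lower, upper)`.
#' @return logical flag.
#' @export
significance <- function(interval) {
  stopifnot(length(interval) == 2, interval[1] <= interval[2])
  !(interval[1] <= 0 && interval[2] >= 0)
}

#' One-call BCa confidence interval for a statistic of data rows
#'
#' Convenience wrapper: case bootstrap + leave-one-out jackknife +
#' [bca_interval()], for a scalar- or vector-valued statistic.
#'
#' @inheritParams case_bootstrap
#' @param level confidence level.
#' @return for a scalar statistic, the interval from [bca_interval()]; for a
#'   vector statistic, a matrix with rows (lower, upper) per component.
#' @export
bca_ci <- function(data, statistic, n_replicates = 10000, level = 0.95, seed = NULL) {
  if (n_replicates < 200) {
    stop("bca_ci: need n_replicates >= 200 for a stable BCa interval", call. = FALSE)
  }
  reps <- case_bootstrap(data, statistic, n_replicates, seed)
  n <- if (is.null(dim(data))) length(data) else nrow(data)
  take <- function(idx) if (is.null(dim(data))) data[idx] else data[idx, , drop = FALSE]
  orig <- statistic(take(seq_len(n)))
  jk <- jackknife(data, statistic)
  if (length(orig) == 1) {
    return(bca_interval(reps[, 1], orig, jk[, 1], level))
  }
  out <- vapply(seq_along(orig), function(j) {
    as.numeric(bca_interval(reps[, j], orig[j], jk[, j], level))
  }, numeric(2))
  colnames(out) <- names(orig)
  rownames(out) <- c("lower", "upper")
  out
}

# ---- internal fast path for OLS-based statistics -------------------------

# Bootstrap + closed-form jackknife for a list of OLS designs sharing rows.
# designs: named list of design matrices (with intercept); y: response.
# Returns list(orig = list of coef vectors, reps = list of B x p matrices,
#              jack = list of n x p matrices, n_redrawn).
# The leave-one-out coefficients use the exact identity
#   beta_(i) = beta - (X'X)^-1 x_i e_i / (1 - h_i),
# so no refitting is needed for the jackknife.
boot_ols_designs <- function(designs, y, n_replicates, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- length(y)
  orig <- list(); jack <- list()
  for (nm in names(designs)) {
    X <- designs[[nm]]
    qrx <- qr(X)
    if (qrx$rank < ncol(X)) {
      dep <- colnames(X)[qrx$pivot[(qrx$rank + 1):ncol(X)]]
      stop("selection model design is rank deficient; dependent column(s): ",
           paste(dep, collapse = ", "), call. = FALSE)
    }
    beta <- qr.coef(qrx, y)
    e <- y - drop(X %*% beta)
    R <- qr.R(qrx)
    XtXinv <- chol2inv(R)
    U <- X %*% XtXinv                       # n x p
    h <- rowSums(qr.Q(qrx)^2)
    fac <- e / pmax(1e-12, 1 - h)
    jk <- matrix(beta, n, length(beta), byrow = TRUE) - U * fac
    colnames(jk) <- colnames(X)
    orig[[nm]] <- beta
    jack[[nm]] <- jk
  }
  reps <- lapply(designs, function(X) {
    m <- matrix(NA_real_, n_replicates, ncol(X))
    colnames(m) <- colnames(X)
    m
  })
  redrawn <- 0L
  max_fail <- ceiling(0.10 * n_replicates)
  b <- 1L
  while (b <= n_replicates) {
    idx <- sample.int(n, n, replace = TRUE)
    ok <- TRUE
    vals <- vector("list", length(designs))
    for (k in seq_along(designs)) {
      f <- stats::.lm.fit(designs[[k]][idx, , drop = FALSE], y[idx])
      if (f$rank < ncol(designs[[k]]) || any(!is.finite(f$coefficients))) { ok <- FALSE; break }
      vals[[k]] <- f$coefficients[order(f$pivot)]
    }
    if (!ok) {
      redrawn <- redrawn + 1L
      if (redrawn > max_fail) {
        stop("bootstrap: more than 10% of resamples rank deficient", call. = FALSE)
      }
      next
    }
    for (k in seq_along(designs)) reps[[k]][b, ] <- vals[[k]]
    b <- b + 1L
  }
  if (redrawn > 0.01 * n_replicates) {
    warning("bootstrap: ", redrawn, " resamples re-drawn (>1% of replicates)", call. = FALSE)
  }
  list(orig = orig, reps = reps, jack = jack, n_redrawn = redrawn)
}
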