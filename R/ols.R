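#' Ordinary least squares on an explicit design matrix
#'
#' QR-based least squares used throughout the selection models. Errors on
#' rank deficiency, naming the dependent columns, rather than silently
#' dropping them (a silently dropped trait column would corrupt a selection
#' gradient).
#'
#' @param X numeric design matrix with column names (include the intercept
#'   column yourself).
#' @param y numeric response.
#' @return list with `coefficients` (named), `fitted`, `residuals`, `rank`.
#' @export
fit_ols <- function(X, y) {
  X <- as.matrix(X)
  stopifnot(nrow(X) == length(y))
  qrx <- qr(X)
  if (qrx$rank < ncol(X)) {
    dep <- colnames(X)[qrx$pivot[(qrx$rank + 1):ncol(X)]]
    stop("fit_ols: design matrix is rank deficient; dependent column(s): ",
         paste(dep, collapse = ", "), call. = FALSE)
  }
  beta <- qr.coef(qrx, y)
  fitted <- drop(X %*% beta)
  list(coefficients = beta, fitted = fitted, residuals = y - fitted, rank = qrx$rank)
}

#' Standardize values to mean 0, SD 1
#'
#' `scheme = "local"` standardizes within each level of `grouping` (within-year
#' moments, the soft-selection view); `scheme = "global"` uses pooled moments
#' across all values (hard selection). Sample SD (n-1 denominator).
#'
#' @param values numeric vector.
#' @param scheme `"local"` or `"global"`.
#' @param grouping group labels, required for `"local"`.
#' @return z-scores.
#' @export
standardize <- function(values, scheme = c("local", "global"), grouping = NULL) {
  scheme <- match.arg(scheme)
  if (scheme == "global") {
    s <- stats::sd(values)
    if (!is.finite(s) || s == 0) stop("standardize: zero variance in pooled values", call. = FALSE)
    return((values - mean(values)) / s)
  }
  if (is.null(grouping)) stop("standardize: grouping required for local scheme", call. = FALSE)
  out <- numeric(length(values))
  for (g in unique(grouping)) {
    i <- grouping == g
    s <- stats::sd(values[i])
    if (!is.finite(s) || s == 0) {
      stop("standardize: zero variance in group '", g, "'", call. = FALSE)
    }
    out[i] <- (values[i] - mean(values[i])) / s
  }
  out
}

#' Relativize fitness to mean 1
#'
#' Divides by the group mean (`"local"`) or the pooled mean (`"global"`).
#' Zeros stay zeros; a group whose fitness is all zero has no defined
#' relative fitness and is an error.
#'
#' @inheritParams standardize
#' @param fitness nonnegative fitness values.
#' @return relative fitness with mean exactly 1 per group (local) or pooled.
#' @export
relativize <- function(fitness, scheme = c("local", "global"), grouping = NULL) {
  scheme <- match.arg(scheme)
  if (any(fitness < 0, na.rm = TRUE)) stop("relativize: fitness must be >= 0", call. = FALSE)
  if (scheme == "global") {
    m <- mean(fitness)
    if (!is.finite(m) || m <= 0) stop("relativize: pooled mean fitness is not positive", call. = FALSE)
    return(fitness / m)
  }
  if (is.null(grouping)) stop("relativize: grouping required for local scheme", call. = FALSE)
  out <- numeric(length(fitness))
  for (g in unique(grouping)) {
    i <- grouping == g
    m <- mean(fitness[i])
    if (!is.finite(m) || m <= 0) {
      stop("relativize: mean fitness is not positive in group '", g, "'", call. = FALSE)
    }
    out[i] <- fitness[i] / m
  }
  out
}

#' Pearson correlation with t-test
#'
#' Product-moment correlation on untransformed variables, with
#' `t = r * sqrt(n - 2) / sqrt(1 - r^2)` and a two-sided p-value on
#' `n - 2` degrees of freedom.
#'
#' @param x,y numeric vectors (n >= 3).
#' @return list: `r`, `t`, `df`, `p`.
#' @export
pearson_correlation <- function(x, y) {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stop("pearson_correlation: need n >= 3 complete pairs", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("pearson_correlation: zero variance input", call. = FALSE)
  }
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  df <- n - 2
  if (abs(r) >= 1) {
    t <- sign(r) * Inf
    p <- 0
  } else {
    t <- r * sqrt(df) / sqrt(1 - r^2)
    p <- 2 * stats::pt(abs(t), df, lower.tail = FALSE)
  }
  list(r = r, t = t, df = df, p = p)
}

#' Variance inflation factors
#'
#' `VIF_j = 1 / (1 - R^2_j)` from regressing predictor j on the remaining
#' predictors (with intercept). Perfect collinearity reports `Inf`.
#'
#' @param X numeric matrix of predictors (no intercept column), >= 2 columns.
#' @return named vector of VIFs, each >= 1.
#' @export
vif <- function(X) {
  X <- as.matrix(X)
  if (ncol(X) < 2) stop("vif: need >= 2 predictors", call. = FALSE)
  out <- numeric(ncol(X))
  names(out) <- colnames(X)
  for (j in seq_len(ncol(X))) {
    y <- X[, j]
    Z <- cbind(1, X[, -j, drop = FALSE])
    qrz <- qr(Z)
    res <- qr.resid(qrz, y)
    sst <- sum((y - mean(y))^2)
    sse <- sum(res^2)
    r2 <- if (sst == 0) 1 else 1 - sse / sst
    out[j] <- if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }
  out
}
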