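#' Dice similarity coefficient of two masks
#'
#' `2 |A intersect B| / (|A| + |B|)` -- the standard overlap form with the
#' intersection in the numerator. Two empty masks are defined to agree
#' perfectly (Dice 1).
#'
#' @param a,b [VoxelMask-class] objects on the same grid.
#' @return Dice coefficient in \[0, 1\].
#' @export
diceCoefficient <- function(a, b) {
  stopifnot(is(a, "VoxelMask"), is(b, "VoxelMask"))
  if (!sameGrid(a, b)) stop("masks are not on the same grid")
  na <- sum(a@voxels)
  nb <- sum(b@voxels)
  if (na + nb == 0L) return(1.0)
  2 * sum(a@voxels & b@voxels) / (na + nb)
}

# two-way mean squares for n subjects x k raters
.twoWayMS <- function(M) {
  n <- nrow(M); k <- ncol(M)
  grand <- mean(M)
  rowm <- rowMeans(M)
  colm <- colMeans(M)
  msr <- k * sum((rowm - grand)^2) / (n - 1)
  msc <- n * sum((colm - grand)^2) / (k - 1)
  resid <- M - outer(rowm, rep(1, k)) - outer(rep(1, n), colm) + grand
  mse <- sum(resid^2) / ((n - 1) * (k - 1))
  list(msr = msr, msc = msc, mse = mse, n = n, k = k)
}

#' Intraclass correlation ICC(2,1) with 95% confidence interval
#'
#' Single-measure, absolute-agreement, two-way random-effects intraclass
#' correlation from the two-way ANOVA mean squares,
#' `(MSR - MSE) / (MSR + (k-1) MSE + k (MSC - MSE) / n)`, with the
#' F-distribution confidence interval of Shrout-Fleiss / McGraw-Wong.
#'
#' @param x,y Paired measurements (two raters), equal length >= 3, finite.
#' @param conf Confidence level (default 0.95).
#' @return An [AgreementStats-class] with the `icc` fields set. Note the
#'   sample estimator is not bounded below by -1 (e.g. perfectly
#'   anticorrelated raters in a tiny sample); the value is reported as
#'   computed.
#' @examples
#' icc21(c(1, 2, 3, 4, 5), c(1.1, 2.0, 3.2, 3.9, 5.1))
#' @export
icc21 <- function(x, y, conf = 0.95) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3L) stop("at least 3 measurement pairs are required")
  if (!all(is.finite(x)) || !all(is.finite(y))) {
    stop("measurements must be finite")
  }
  M <- cbind(x, y)
  if (stats::var(as.numeric(M)) == 0) {
    stop("zero total variance: ICC is undefined")
  }
  ms <- .twoWayMS(M)
  n <- ms$n; k <- ms$k
  icc <- (ms$msr - ms$mse) /
    (ms$msr + (k - 1) * ms$mse + k * (ms$msc - ms$mse) / n)

  alpha <- 1 - conf
  Fj <- ms$msc / ms$mse
  a <- k * icc / (n * (1 - icc))
  b <- 1 + k * icc * (n - 1) / (n * (1 - icc))
  v <- (a * Fj + b)^2 /
    (a^2 * Fj^2 / (k - 1) + b^2 / (n - 1))
  # qf can warn about quantile accuracy at the extreme df this formula
  # produces for near-degenerate inputs; the CI is approximate there anyway
  FL <- suppressWarnings(stats::qf(1 - alpha / 2, n - 1, v))
  FU <- suppressWarnings(stats::qf(1 - alpha / 2, v, n - 1))
  lower <- n * (ms$msr - FL * ms$mse) /
    (FL * (k * ms$msc + (k * n - k - n) * ms$mse) + n * ms$msr)
  upper <- n * (FU * ms$msr - ms$mse) /
    (k * ms$msc + (k * n - k - n) * ms$mse + n * FU * ms$msr)
  new("AgreementStats",
    icc = icc, icc_ci = c(min(lower, icc), max(upper, icc)),
    n = as.integer(n)
  )
}

#' Bland-Altman bias and limits of agreement
#'
#' For paired measurements, the bias is the mean difference `x - y` and the
#' limits of agreement are `bias +/- 1.96 sd(diff)` (sample sd, n - 1
#' denominator; the classical fixed 1.96 multiplier, not a t quantile).
#'
#' @param x,y Paired measurements, equal length >= 2.
#' @return An [AgreementStats-class] with the bias fields set.
#' @export
blandAltman <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 2L) stop("at least 2 measurement pairs are required")
  d <- x - y
  bias <- mean(d)
  s <- stats::sd(d)
  new("AgreementStats",
    bias = bias, loa_low = bias - 1.96 * s, loa_high = bias + 1.96 * s,
    n = length(d)
  )
}
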