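# Process-monitoring statistics: dynamic complexity, recurrence matrices,
# LOESS trend curves, weekly outcome change.

# points of return of a window: first index, last index, and interior
# local extrema (sign change of the successive nonzero differences)
.return_points <- function(w) {
  m <- length(w)
  if (m < 2L) return(seq_len(m))
  d <- diff(w)
  pts <- 1L
  last_sign <- 0
  for (i in seq_along(d)) {
    s <- sign(d[i])
    if (s != 0) {
      if (last_sign != 0 && s != last_sign) pts <- c(pts, i)
      last_sign <- s
    }
  }
  unique(c(pts, m))
}

#' Moving-window dynamic complexity
#'
#' An early-warning statistic for critical instabilities in a univariate
#' symptom series, computed in a moving window of width `m` as the product
#' `C = F * D` of two components:
#'
#' * Fluctuation intensity `F`: the window's points of return (first point,
#'   last point, and interior local extrema) split it into segments; each
#'   segment contributes its absolute slope `|dy|/dsteps`, and the sum is
#'   normalized by `R * n_segments` (`R = smax - smin`), the value attained
#'   by full-range alternation every step. A flat window has `F = 0`; a
#'   monotone ramp over the full range has `F = 1/(m-1)`.
#' * Distribution `D`: how evenly the window's values cover the scale.
#'   With `g_i` the gaps of the sorted window values,
#'   `D = max(0, 1 - sum(|g_i - R/(m-1)|)/R)`; uniform coverage of
#'   `[smin, smax]` gives 1, a constant window gives 0.
#'
#' Both components lie in `[0, 1]`, hence `C` does too. Values are aligned
#' causally: the complexity of a window is assigned to its last index, so
#' the statistic is computable in real time.
#'
#' @param series numeric vector, no missing values, length at least `m`.
#' @param m window width; 5-7 is typical, default 7.
#' @param smin,smax theoretical scale bounds of the series
#'   (`smax > smin`).
#' @return An object of class `complexity_series`: `values` (complexity, one
#'   per window end position `m..length(series)`), `fluctuation`,
#'   `distribution` (the per-window components), `index` (window end
#'   positions), `m`, `smin`, `smax`.
#' @export
dynamic_complexity <- function(series, m = 7L, smin, smax) {
  series <- as.numeric(series)
  if (anyNA(series))
    stop("dynamic_complexity: missing values in series", call. = FALSE)
  n <- length(series)
  if (m < 2L || n < m)
    stop("dynamic_complexity: series shorter than window m = ", m, call. = FALSE)
  if (smax <= smin)
    stop("dynamic_complexity: smax must exceed smin", call. = FALSE)
  R <- smax - smin
  ends <- m:n
  Fv <- Dv <- numeric(length(ends))
  ideal_gap <- R / (m - 1)
  for (ii in seq_along(ends)) {
    w <- series[(ends[ii] - m + 1L):ends[ii]]
    pts <- .return_points(w)
    if (length(pts) >= 2L) {
      seg_slopes <- abs(diff(w[pts])) / diff(pts)
      Fv[ii] <- sum(seg_slopes) / (R * length(seg_slopes))
    }
    g <- diff(sort(w))
    Dv[ii] <- max(0, 1 - sum(abs(g - ideal_gap)) / R)
  }
  structure(
    list(values = Fv * Dv, fluctuation = Fv, distribution = Dv,
         index = ends, m = m, smin = smin, smax = smax),
    class = "complexity_series")
}

#' @export
print.complexity_series <- function(x, ...) {
  cat(sprintf("<complexity_series> %d windows of width %d on [%g, %g]\n",
              length(x$values), x$m, x$smin, x$smax))
  cat(sprintf("  mean C = %.4f, max C = %.4f at index %d\n",
              mean(x$values), max(x$values), x$index[which.max(x$values)]))
  invisible(x)
}

#' Rescale complexity values to a plotting range
#'
#' Affine map of complexity values from `[0, 1]` onto `[ymin, ymax]` so the
#' complexity curve can be overlaid on the raw symptom plot at its
#' theoretical minimum and maximum.
#'
#' @param cs a [dynamic_complexity()] result, or a numeric vector in `[0, 1]`.
#' @param ymin,ymax target range, `ymax > ymin`.
#' @return Numeric vector of rescaled values.
#' @export
rescale_complexity <- function(cs, ymin, ymax) {
  if (ymax <= ymin)
    stop("rescale_complexity: ymax must exceed ymin", call. = FALSE)
  v <- if (inherits(cs, "complexity_series")) cs$values else as.numeric(cs)
  ymin + v * (ymax - ymin)
}

#' Recurrence matrix of a time series
#'
#' The time-by-time matrix of Euclidean distances between assessment
#' points (absolute differences for a univariate series). Recurring states
#' show as off-diagonal near-zero bands; far-from-normal states show as
#' uniformly large rows.
#'
#' @param points numeric vector (univariate) or `T x q` matrix, no missing
#'   values, at least 2 rows.
#' @return A symmetric `T x T` matrix of class `recurrence_matrix` with
#'   zero diagonal.
#' @export
recurrence_matrix <- function(points) {
  P <- as.matrix(points)
  if (anyNA(P)) stop("recurrence_matrix: missing values", call. = FALSE)
  if (nrow(P) < 2L) stop("recurrence_matrix: need at least 2 points", call. = FALSE)
  d <- as.matrix(stats::dist(P))
  dimnames(d) <- NULL
  structure(d, class = c("recurrence_matrix", "matrix", "array"))
}

#' LOESS trend curve with 95% confidence band
#'
#' Locally weighted linear regression (tricube kernel, degree 1) over the
#' observation index, evaluated at each observation, with a pointwise 95%
#' confidence interval from the local fit variance. Used for reading
#' long-term mean shifts off a noisy symptom series.
#'
#' @param series numeric vector, length at least 5, no missing values.
#' @param span LOESS span (fraction of points in each local fit),
#'   default 0.75.
#' @return An object of class `smoothed_series`: `fitted`, `lower`, `upper`
#'   (95% bounds), `span`, `index`.
#' @export
loess_ci <- function(series, span = 0.75) {
  y <- as.numeric(series)
  if (anyNA(y)) stop("loess_ci: missing values in series", call. = FALSE)
  n <- length(y)
  if (n < 5L) stop("loess_ci: need at least 5 points", call. = FALSE)
  if (span * n < 3)
    stop("loess_ci: span too small for local linear fits", call. = FALSE)
  x <- seq_len(n)
  fit <- stats::loess(y ~ x, span = span, degree = 1, family = "gaussian",
                      surface = "direct")
  pr <- stats::predict(fit, se = TRUE)
  half <- stats::qt(0.975, pr$df) * pr$se.fit
  structure(
    list(fitted = as.numeric(pr$fit),
         lower = as.numeric(pr$fit - half),
         upper = as.numeric(pr$fit + half),
         span = span, index = x),
    class = "smoothed_series")
}

#' Weekly percent-change outcome scores
#'
#' Pre-post change between consecutive weekly outcome assessments:
#' `100 * (score_w - score_{w-1}) / score_{w-1}`. Negative values indicate
#' symptom reduction.
#'
#' @param outcomes numeric vector of at least 2 weekly outcome scores; no
#'   score that serves as a denominator may be zero.
#' @return Numeric vector of length `length(outcomes) - 1`.
#' @export
weekly_change <- function(outcomes) {
  x <- as.numeric(outcomes)
  if (length(x) < 2L)
    stop("weekly_change: need at least 2 weekly scores", call. = FALSE)
  prev <- x[-length(x)]
  if (any(prev == 0))
    stop("weekly_change: change from a zero score is undefined", call. = FALSE)
  100 * diff(x) / prev
}
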