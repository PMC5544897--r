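# Synthetic-patient generator: latent VAR dynamics + factor measurement
# model + Likert discretization, with the generating truth retained so
# every pipeline stage can be validated against known parameters.

# spectral radius of the VAR companion matrix
.companion_radius <- function(A) {
  k <- dim(A)[1]; p <- dim(A)[3]
  Cm <- matrix(0, k * p, k * p)
  for (l in seq_len(p)) Cm[1:k, ((l - 1) * k + 1):(l * k)] <- A[, , l]
  if (p > 1) Cm[(k + 1):(k * p), 1:(k * (p - 1))] <- diag(k * (p - 1))
  max(Mod(eigen(Cm, only.values = TRUE)$values))
}

#' Ground truth for a synthetic patient
#'
#' Collects the generating parameters of a simulated patient: the latent
#' factor structure (loadings and factor-innovation correlations), the
#' latent VAR dynamics, linear trends, baseline item means, observation
#' noise, the Likert response grid, and the missingness regime.
#'
#' @param loadings `I x k` loading matrix, entries in `[-1, 1]`.
#' @param Phi `k x k` innovation correlation matrix.
#' @param A `k x k x p` latent VAR coefficient array (matrix input is
#'   treated as `p = 1`); the companion matrix must have spectral
#'   radius below 1.
#' @param trend length-`k` latent linear-trend slopes per index step.
#' @param item_means length-`I` baseline item means (scale units).
#' @param noise_sd observation noise standard deviation.
#' @param scale_min,scale_max response-scale bounds.
#' @param likert_levels number of response levels (grid points between the
#'   bounds), integer at least 2.
#' @param missing_rate cell-missingness fraction emulated by
#'   [inject_missing()]; the roughly 10-13% regime reported for daily
#'   symptom questionnaires is the default.
#' @param item_ids,item_texts optional item labels.
#' @return An object of class `ground_truth`.
#' @export
ground_truth <- function(loadings, Phi, A, trend = NULL, item_means,
                         noise_sd = 0.5, scale_min = 0, scale_max = 8,
                         likert_levels = as.integer(scale_max - scale_min + 1),
                         missing_rate = 0.12,
                         item_ids = NULL, item_texts = NULL) {
  loadings <- as.matrix(loadings)
  I <- nrow(loadings); k <- ncol(loadings)
  if (any(abs(loadings) > 1))
    stop("ground_truth: loadings must lie in [-1, 1]", call. = FALSE)
  Phi <- as.matrix(Phi)
  if (!isTRUE(all.equal(Phi, t(Phi))) || any(abs(diag(Phi) - 1) > 1e-8) ||
      min(eigen(Phi, only.values = TRUE)$values) < -1e-8)
    stop("ground_truth: Phi must be a valid correlation matrix", call. = FALSE)
  if (length(dim(A)) == 2L) A <- array(A, dim = c(dim(A), 1L))
  if (dim(A)[1] != k || dim(A)[2] != k)
    stop("ground_truth: A must be k x k x p", call. = FALSE)
  radius <- .companion_radius(A)
  if (radius >= 1)
    stop("ground_truth: latent VAR unstable (spectral radius ",
         round(radius, 3), " >= 1)", call. = FALSE)
  if (is.null(trend)) trend <- rep(0, k)
  if (length(item_means) != I)
    stop("ground_truth: item_means must have one entry per item", call. = FALSE)
  if (missing_rate < 0 || missing_rate >= 1)
    stop("ground_truth: missing_rate must be in [0, 1)", call. = FALSE)
  if (likert_levels < 2L)
    stop("ground_truth: need at least 2 Likert levels", call. = FALSE)
  if (is.null(item_ids)) item_ids <- paste0("item", seq_len(I))
  if (is.null(item_texts)) item_texts <- item_ids
  rownames(loadings) <- item_ids
  structure(
    list(k = k, I = I, p = dim(A)[3], loadings = loadings, Phi = Phi,
         A = A, trend = trend, item_means = item_means,
         noise_sd = noise_sd, scale_min = scale_min, scale_max = scale_max,
         likert_levels = as.integer(likert_levels),
         missing_rate = missing_rate, spectral_radius = radius,
         item_ids = item_ids, item_texts = item_texts),
    class = "ground_truth")
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf("<ground_truth> %d items, %d factors, VAR(%d), spectral radius %.3f\n",
              x$I, x$k, x$p, x$spectral_radius))
  invisible(x)
}

#' Named synthetic-patient presets
#'
#' Three scenario presets spanning the pipeline's behavioral regimes:
#'
#' * `"two-factor-dominant"`: a two-factor structure shaped like a
#'   worked social-anxiety example (oblique factors, correlated .243),
#'   where factor 1 has strong simple loadings, markedly stronger
#'   autoregression, cross-regression onto factor 2, and higher item means,
#'   so its items should surface at the top of the priority table. A tenth
#'   item loads on nothing (the exclusion case).
#' * `"pure-noise"`: ten mutually independent items with no factor
#'   structure; the planning run should end in `no_model`.
#' * `"three-factor"`: three well-separated factors with moderate
#'   dynamics, for factor-number selection checks.
#'
#' @param name preset name.
#' @return A [ground_truth()].
#' @export
patient_preset <- function(name = c("two-factor-dominant", "pure-noise",
                                    "three-factor")) {
  name <- match.arg(name)
  switch(name,
    "two-factor-dominant" = {
      L <- rbind(
        c(0.75, 0.10), c(0.85, 0.00), c(0.00, 0.60), c(0.00, 0.50),
        c(0.00, 0.62), c(0.70, 0.10), c(0.00, 0.42), c(0.00, 0.58),
        c(0.00, 0.45), c(0.05, 0.05))
      A <- array(c(0.60, 0.25,
                   0.00, 0.10), dim = c(2, 2, 1))
      ground_truth(
        loadings = L,
        Phi = matrix(c(1, 0.243, 0.243, 1), 2),
        A = A,
        item_means = c(5.5, 6.0, 3.0, 3.2, 2.8, 5.0, 2.5, 3.4, 2.6, 1.5),
        noise_sd = 0.45, scale_min = 0, scale_max = 8,
        missing_rate = 0.12)
    },
    "pure-noise" = {
      ground_truth(
        loadings = matrix(0, 10, 2),
        Phi = diag(2),
        A = array(0, dim = c(2, 2, 1)),
        item_means = rep(4, 10),
        noise_sd = 1.4, scale_min = 0, scale_max = 8,
        missing_rate = 0.12)
    },
    "three-factor" = {
      L <- matrix(0, 9, 3)
      L[1:3, 1] <- c(0.75, 0.70, 0.65)
      L[4:6, 2] <- c(0.72, 0.68, 0.66)
      L[7:9, 3] <- c(0.74, 0.69, 0.63)
      Phi <- matrix(0.3, 3, 3); diag(Phi) <- 1
      A <- array(0, dim = c(3, 3, 1)); diag(A[, , 1]) <- c(0.45, 0.35, 0.25)
      ground_truth(
        loadings = L, Phi = Phi, A = A,
        item_means = c(5, 5.2, 4.8, 4, 4.1, 3.9, 3, 3.2, 2.9),
        noise_sd = 0.4, scale_min = 0, scale_max = 8,
        missing_rate = 0.12)
    })
}

#' Simulate a synthetic patient
#'
#' Draws a latent `k`-variate VAR(`p`) series with innovation correlation
#' `Phi`, iterates it with the configured linear trend (after a discarded
#' burn-in), maps latent states to items through the loading matrix, adds
#' independent Gaussian observation noise, shifts by the baseline item
#' means, and discretizes to the Likert grid by rounding to the nearest
#' level and clamping to the scale bounds. Fully reproducible from `seed`.
#'
#' @param truth a [ground_truth()].
#' @param T_len number of assessments, at least 20.
#' @param seed integer RNG seed.
#' @param burn_in discarded initial VAR steps, default 50.
#' @param start date-time of the first assessment day's first measurement.
#' @param times daily assessment times (see [make_schedule()]).
#' @return A list with `ts` (a [symptom_ts()], no missingness; apply
#'   [inject_missing()] for the compliance regime), `truth`, and `latent`
#'   (the `T x k` latent factor series before measurement).
#' @export
simulate_patient <- function(truth, T_len, seed,
                             burn_in = 50L,
                             start = as.POSIXct("2026-01-05 08:00:00", tz = "UTC"),
                             times = c("08:00", "14:00", "20:00")) {
  stopifnot(inherits(truth, "ground_truth"))
  if (T_len < 20L) stop("simulate_patient: T_len must be at least 20", call. = FALSE)
  set.seed(seed)
  k <- truth$k; p <- truth$p
  n_tot <- T_len + burn_in
  chol_Phi <- chol(truth$Phi)
  innov <- matrix(stats::rnorm(n_tot * k), n_tot, k) %*% chol_Phi
  eta <- matrix(0, n_tot, k)
  for (t in seq_len(n_tot)) {
    mu <- rep(0, k)
    for (l in seq_len(p)) if (t - l >= 1)
      mu <- mu + truth$A[, , l] %*% eta[t - l, ]
    eta[t, ] <- mu + innov[t, ]
  }
  eta <- eta[(burn_in + 1L):n_tot, , drop = FALSE]
  eta <- eta + outer(seq_len(T_len), truth$trend)
  X <- eta %*% t(truth$loadings) +
    matrix(stats::rnorm(T_len * truth$I, sd = truth$noise_sd), T_len, truth$I)
  X <- sweep(X, 2L, truth$item_means, `+`)
  grid <- seq(truth$scale_min, truth$scale_max,
              length.out = truth$likert_levels)
  step <- grid[2] - grid[1]
  X <- truth$scale_min + step * round((X - truth$scale_min) / step)
  X <- pmin(pmax(X, truth$scale_min), truth$scale_max)
  tod <- .parse_tod(times)
  day0 <- as.POSIXct(format(start, "%Y-%m-%d"), tz = "UTC")
  n_days <- ceiling(T_len / length(tod))
  stamps <- rep(day0 + 86400 * (seq_len(n_days) - 1L), each = length(tod)) +
    rep(tod, n_days)
  stamps <- stamps[seq_len(T_len)]
  ts <- symptom_ts(X, stamps, truth$item_ids, truth$item_texts,
                   truth$scale_min, truth$scale_max)
  list(ts = ts, truth = truth, latent = eta)
}

#' Inject missing responses
#'
#' Masks responses at a given rate, emulating imperfect compliance with
#' intensive daily assessment: either independently per cell (default) or
#' by whole rows (skipped assessments).
#'
#' @param ts a [symptom_ts()].
#' @param rate missingness fraction in `[0, 1)`.
#' @param seed integer RNG seed; the mask is reproducible.
#' @param by_row mask whole assessments instead of single cells?
#' @return A `symptom_ts` with the mask applied.
#' @export
inject_missing <- function(ts, rate, seed, by_row = FALSE) {
  stopifnot(inherits(ts, "symptom_ts"))
  if (rate < 0 || rate >= 1)
    stop("inject_missing: rate must be in [0, 1)", call. = FALSE)
  if (rate == 0) return(ts)
  set.seed(seed)
  vals <- ts$values
  if (by_row) {
    drop_rows <- which(stats::runif(nrow(vals)) < rate)
    vals[drop_rows, ] <- NA_real_
  } else {
    mask <- matrix(stats::runif(length(vals)) < rate, nrow(vals))
    vals[mask] <- NA_real_
  }
  symptom_ts(vals, ts$timestamps, ts$item_ids, ts$item_texts,
             ts$scale_min, ts$scale_max)
}

#' Truth-implied item correlation matrix
#'
#' The population correlation matrix of the observed items under a ground
#' truth, before Likert discretization: the latent stationary covariance
#' (discrete Lyapunov solution of the VAR) is propagated through the
#' loadings and combined with the observation noise.
#'
#' @param truth a [ground_truth()].
#' @return `I x I` correlation matrix.
#' @export
implied_item_cor <- function(truth) {
  k <- truth$k; p <- truth$p
  kp <- k * p
  Cm <- matrix(0, kp, kp)
  for (l in seq_len(p)) Cm[1:k, ((l - 1) * k + 1):(l * k)] <- truth$A[, , l]
  if (p > 1) Cm[(k + 1):kp, 1:(k * (p - 1))] <- diag(k * (p - 1))
  Q <- matrix(0, kp, kp)
  Q[1:k, 1:k] <- truth$Phi
  # vec(S) = (I - C (x) C)^{-1} vec(Q)
  vecS <- solve(diag(kp^2) - kronecker(Cm, Cm), as.vector(Q))
  S_comp <- matrix(vecS, kp, kp)
  S_eta <- S_comp[1:k, 1:k]
  Sigma <- truth$loadings %*% S_eta %*% t(truth$loadings) +
    diag(truth$noise_sd^2, truth$I)
  stats::cov2cor(Sigma)
}
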