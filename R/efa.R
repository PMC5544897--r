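#' Exploratory P-technique factor analysis
#'
#' Step 1 of the planning pipeline. Items are z-scored per item and a
#' maximum-likelihood factor analysis of the sample correlation matrix is
#' fitted (minimizing the discrepancy
#' \eqn{F = \log|\hat\Sigma| + tr(S\hat\Sigma^{-1}) - \log|S| - I}),
#' followed by direct oblimin rotation because the latent dimensions of
#' psychopathology are expected to intercorrelate. Observations are the
#' patient's repeated assessments, so the "sample" is occasions, not
#' persons (P-technique).
#'
#' Zero-variance items are dropped with a warning. Uniquenesses are bounded
#' below at 0.005, so Heywood cases are floored there and flagged.
#'
#' @param ts a cleaned [symptom_ts()] (no missing values), or a numeric
#'   matrix of responses.
#' @param k number of factors (2, 3 or 4 in the default pipeline).
#' @return An object of class `efa_model`: `k`, `loadings` (rotated oblimin
#'   pattern matrix), `Phi` (factor correlations), `uniquenesses`,
#'   `loadings_unrotated`, `fit` (a `fit_indices`), `n_obs`, `items`,
#'   `S` (sample correlation matrix), `heywood` flag.
#' @export
fit_efa <- function(ts, k) {
  X <- if (inherits(ts, "symptom_ts")) ts$values else as.matrix(ts)
  if (anyNA(X))
    stop("fit_efa: series contains missing values; clean it first", call. = FALSE)
  Tn <- nrow(X); I <- ncol(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("item", seq_len(I))
  keep <- apply(X, 2L, stats::sd) > 0
  if (!all(keep)) {
    warning("fit_efa: dropping zero-variance item(s): ",
            paste(colnames(X)[!keep], collapse = ", "), call. = FALSE)
    X <- X[, keep, drop = FALSE]
    I <- ncol(X)
  }
  if (Tn <= I)
    stop("fit_efa: need more assessments than items (T > I)", call. = FALSE)
  df <- ((I - k)^2 - (I + k)) / 2
  if (df < 0)
    stop("fit_efa: model with ", k, " factors is not identified for ", I,
         " items (df < 0)", call. = FALSE)
  S <- stats::cor(X)
  fa <- tryCatch(
    stats::factanal(covmat = S, factors = k, n.obs = Tn, rotation = "none",
                    lower = 0.005, nstart = 1),
    error = function(e) stop("fit_efa: ML estimation failed: ",
                             conditionMessage(e), call. = FALSE))
  A <- matrix(fa$loadings, I, k, dimnames = list(colnames(X), paste0("F", 1:k)))
  uniq <- fa$uniquenesses
  heywood <- any(uniq <= 0.005 + 1e-8)
  if (heywood)
    warning("fit_efa: Heywood case; uniqueness floored at 0.005", call. = FALSE)
  rot <- rotate_oblimin(A)
  if (!rot$converged)
    warning("fit_efa: oblimin rotation did not fully converge", call. = FALSE)
  F_obj <- unname(fa$criteria["objective"])
  model <- structure(
    list(k = k, loadings = rot$loadings, Phi = rot$Phi,
         uniquenesses = uniq, loadings_unrotated = A,
         n_obs = Tn, items = colnames(X), S = S,
         discrepancy = F_obj, heywood = heywood),
    class = "efa_model")
  model$fit <- efa_fit_indices(model, S, Tn)
  model
}

#' @export
print.efa_model <- function(x, ...) {
  cat(sprintf("<efa_model> %d factors, %d items, T = %d\n",
              x$k, length(x$items), x$n_obs))
  cat(sprintf("  TLI = %.3f, RMS = %.3f (chi2 = %.2f on %d df)\n",
              x$fit$tli, x$fit$rms, x$fit$chi2, x$fit$df))
  cat("Oblimin pattern loadings:\n")
  print(round(x$loadings, 3))
  cat("Factor correlations:\n")
  print(round(x$Phi, 3))
  invisible(x)
}

#' Fit indices for an exploratory factor model
#'
#' Computes the likelihood-ratio statistic with Bartlett's correction,
#' \eqn{\chi^2 = (T - 1 - (2I+5)/6 - 2k/3)\,F}, its degrees of freedom
#' \eqn{df = ((I-k)^2 - (I+k))/2}, the Tucker-Lewis index against the
#' independence model, and the root mean squared residual (RMS) of the
#' off-diagonal correlation residuals \eqn{S - \hat\Sigma}. The
#' independence-model baseline has \eqn{F_0 = -\log|S|} and
#' \eqn{df_0 = I(I-1)/2}.
#'
#' @param model an `efa_model` (or any list with `k`, `loadings_unrotated`,
#'   `uniquenesses`, `discrepancy`).
#' @param S sample correlation matrix the model was fitted on.
#' @param n_obs number of observations `T`.
#' @return An object of class `fit_indices` with fields `chi2`, `df`,
#'   `chi2_null`, `df_null`, `tli`, `rms`, `srmr`.
#' @export
efa_fit_indices <- function(model, S, n_obs) {
  I <- nrow(S); k <- model$k
  df <- ((I - k)^2 - (I + k)) / 2
  if (df <= 0)
    stop("efa_fit_indices: model unidentifiable (df <= 0)", call. = FALSE)
  A <- model$loadings_unrotated
  Sigma <- A %*% t(A) + diag(model$uniquenesses, I)
  F_obj <- model$discrepancy
  if (is.null(F_obj)) {
    # recompute the ML discrepancy from the implied matrix
    F_obj <- log(det(Sigma)) + sum(diag(S %*% solve(Sigma))) - log(det(S)) - I
  }
  chi2 <- max(0, (n_obs - 1 - (2 * I + 5) / 6 - 2 * k / 3) * F_obj)
  F_null <- -log(det(S))
  df_null <- I * (I - 1) / 2
  chi2_null <- max(0, (n_obs - 1 - (2 * I + 5) / 6) * F_null)
  resid <- S - Sigma
  off <- resid[lower.tri(resid)]
  rms <- sqrt(mean(off^2))
  .fit_indices(chi2, df, chi2_null, df_null, rms = rms,
               srmr = .srmr(S, Sigma))
}

# TLI from chi-squares; srmr over all unique elements incl. diagonal
.fit_indices <- function(chi2, df, chi2_null, df_null, rms = NA_real_,
                         srmr = NA_real_) {
  tli <- ((chi2_null / df_null) - (chi2 / df)) / ((chi2_null / df_null) - 1)
  structure(list(chi2 = chi2, df = df, chi2_null = chi2_null,
                 df_null = df_null, tli = tli, rms = rms, srmr = srmr),
            class = "fit_indices")
}

.srmr <- function(S, Sigma) {
  resid <- S - Sigma
  sqrt(mean(resid[lower.tri(resid, diag = TRUE)]^2))
}

#' @export
print.fit_indices <- function(x, ...) {
  cat(sprintf("chi2 = %.3f (df = %g), null chi2 = %.3f (df = %g)\n",
              x$chi2, x$df, x$chi2_null, x$df_null))
  cat(sprintf("TLI = %.3f, RMS = %.3f, SRMR = %.3f\n", x$tli, x$rms, x$srmr))
  invisible(x)
}

#' Select the exploratory factor model
#'
#' Fits candidate models with 2, 3, ... `k_max` factors and gates each on
#' the Hu-Bentler joint criteria (TLI at least `tli_min` and RMS at most
#' `rms_max`). Among passing candidates the model with the smallest number
#' of factors is selected; a candidate whose fit fails with an error counts
#' as non-passing.
#'
#' Before any candidate can pass, Bartlett's test of sphericity must reject
#' the independence model (`chi2_null` above its upper `sphericity_alpha`
#' critical value). On structureless data the independence baseline fits,
#' which makes the incremental TLI numerically unstable (its denominator
#' approaches zero); requiring evidence of correlational structure before
#' factoring is the standard guard and ensures such data yields no model.
#'
#' @param ts cleaned [symptom_ts()] or response matrix.
#' @param k_max largest candidate factor count (default 4).
#' @param tli_min,rms_max fit-gate cutoffs; defaults 0.95 and 0.08.
#' @param sphericity_alpha significance level of the sphericity
#'   prerequisite, default 0.05.
#' @return An object of class `efa_selection`: `model` (the selected
#'   `efa_model`, or `NULL` if none passes), `k` (selected count or `NA`),
#'   `status` (`"found"`/`"no_model"`), and `trace`, a data frame with one
#'   row per candidate (k, tli, rms, passed, error).
#' @export
select_model <- function(ts, k_max = 4L, tli_min = 0.95, rms_max = 0.08,
                         sphericity_alpha = 0.05) {
  ks <- 2:k_max
  trace <- data.frame(k = ks, tli = NA_real_, rms = NA_real_,
                      sphericity = NA, passed = FALSE, error = NA_character_)
  best <- NULL
  for (i in seq_along(ks)) {
    m <- tryCatch(suppressWarnings(fit_efa(ts, ks[i])), error = identity)
    if (inherits(m, "error")) {
      trace$error[i] <- conditionMessage(m)
      next
    }
    spherical_ok <- m$fit$chi2_null >
      stats::qchisq(1 - sphericity_alpha, m$fit$df_null)
    trace$tli[i] <- m$fit$tli
    trace$rms[i] <- m$fit$rms
    trace$sphericity[i] <- spherical_ok
    trace$passed[i] <- spherical_ok && is.finite(m$fit$tli) &&
      m$fit$tli >= tli_min && m$fit$rms <= rms_max
    if (trace$passed[i] && is.null(best)) best <- m
  }
  structure(list(model = best,
                 k = if (is.null(best)) NA_integer_ else best$k,
                 status = if (is.null(best)) "no_model" else "found",
                 trace = trace),
            class = "efa_selection")
}

#' @export
print.efa_selection <- function(x, ...) {
  if (x$status == "found")
    cat(sprintf("<efa_selection> selected %d-factor model\n", x$k))
  else cat("<efa_selection> no candidate passed the fit gate\n")
  print(x$trace, row.names = FALSE)
  invisible(x)
}
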