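# Per-equation OLS vector autoregression with deterministic terms
# (intercept and linear trend over the observation index).

# build the lagged design for responses at rows (skip+1):T
.var_design <- function(Y, p, skip = p, trend = TRUE) {
  Tn <- nrow(Y); k <- ncol(Y)
  rows <- (skip + 1L):Tn
  X <- matrix(1, length(rows), 1L, dimnames = list(NULL, "const"))
  if (trend) X <- cbind(X, trend = rows)
  for (l in seq_len(p)) {
    lag_block <- Y[rows - l, , drop = FALSE]
    colnames(lag_block) <- paste0(colnames(Y), ".l", l)
    X <- cbind(X, lag_block)
  }
  list(X = X, Yresp = Y[rows, , drop = FALSE], rows = rows)
}

#' Fit a vector autoregression to factor scores
#'
#' Step 3 of the pipeline. Each factor-score equation is estimated by OLS on
#' an intercept, a linear trend over the observation index, and all factors
#' at lags `1..p`. Linear trends are included so that slow mean shifts are
#' not mistaken for lagged (auto- or cross-regressive) structure.
#'
#' The model AIC is \eqn{T_{eff}\log|\hat\Sigma_{res}| + 2m} with
#' \eqn{\hat\Sigma_{res}} the ML residual covariance and `m` the total
#' number of estimated coefficients; additive constants are omitted
#' consistently, so only AIC differences are meaningful. Synchronous
#' associations between the factors are reported as residual correlations.
#'
#' @param fs a [factor_score_series()], or a numeric `T x k` matrix.
#' @param p lag order.
#' @param trend include the linear trend regressor? Default `TRUE`.
#' @param skip rows dropped from the start of the sample before estimation
#'   (at least `p`; used by [select_lag()] to put all lag candidates on a
#'   common estimation sample).
#' @return An object of class `var_model`: `p`, `k`, `A` (`k x k x p`
#'   coefficient array, `A[, , l]` maps scores at `t-l` to `t`), `const`,
#'   `trend_slope`, `coef` (full coefficient matrix, regressors x equations),
#'   `se`, `tstat`, `pval` (same shape), `r2`, `aic`, `residual_cov`,
#'   `residual_cor`, `residuals`, `fitted`, `T_eff`, `df_residual`, `trend`.
#' @export
fit_var <- function(fs, p, trend = TRUE, skip = p) {
  Y <- if (inherits(fs, "factor_score_series")) fs$scores else as.matrix(fs)
  if (anyNA(Y)) stop("fit_var: missing values in scores", call. = FALSE)
  if (is.null(colnames(Y))) colnames(Y) <- paste0("F", seq_len(ncol(Y)))
  Tn <- nrow(Y); k <- ncol(Y)
  if (p < 1L || skip < p) stop("fit_var: need p >= 1 and skip >= p", call. = FALSE)
  n_reg <- 1L + as.integer(trend) + k * p
  if (Tn - skip <= n_reg)
    stop("fit_var: series too short for ", p, " lag(s)", call. = FALSE)
  d <- .var_design(Y, p, skip = skip, trend = trend)
  qr_x <- qr(d$X)
  if (qr_x$rank < ncol(d$X))
    stop("fit_var: singular regressor matrix (collinear scores)", call. = FALSE)
  B <- qr.coef(qr_x, d$Yresp)                    # n_reg x k
  fitted <- d$X %*% B
  res <- d$Yresp - fitted
  T_eff <- nrow(d$X)
  df_res <- T_eff - n_reg
  XtXinv <- chol2inv(qr.R(qr_x))
  sigma2 <- colSums(res^2) / df_res
  se <- sqrt(outer(diag(XtXinv), sigma2))
  dimnames(se) <- dimnames(B)
  tstat <- B / se
  pval <- 2 * stats::pt(abs(tstat), df_res, lower.tail = FALSE)
  tss <- colSums(scale(d$Yresp, scale = FALSE)^2)
  r2 <- 1 - colSums(res^2) / tss
  Sigma_res <- crossprod(res) / T_eff
  aic <- T_eff * determinant(Sigma_res, logarithm = TRUE)$modulus[1] +
    2 * (n_reg * k)
  A <- array(0, dim = c(k, k, p),
             dimnames = list(colnames(Y), colnames(Y), paste0("lag", 1:p)))
  for (l in seq_len(p)) {
    rows_l <- paste0(colnames(Y), ".l", l)
    A[, , l] <- t(B[rows_l, , drop = FALSE])
  }
  structure(
    list(p = p, k = k, A = A,
         const = B["const", ],
         trend_slope = if (trend) B["trend", ] else stats::setNames(rep(0, k), colnames(Y)),
         coef = B, se = se, tstat = tstat, pval = pval,
         r2 = unname(r2), aic = as.numeric(aic),
         residual_cov = Sigma_res, residual_cor = stats::cov2cor(Sigma_res),
         residuals = res, fitted = fitted,
         T_eff = T_eff, df_residual = df_res, trend = trend,
         skip = skip, scores = Y),
    class = "var_model")
}

#' @export
print.var_model <- function(x, ...) {
  cat(sprintf("<var_model> k = %d, p = %d, T_eff = %d, AIC = %.2f\n",
              x$k, x$p, x$T_eff, x$aic))
  cat("Per-equation R^2:", paste(sprintf("%.3f", x$r2), collapse = ", "), "\n")
  cat("Residual correlations (synchronous associations):\n")
  print(round(x$residual_cor, 3))
  invisible(x)
}

#' Select the VAR lag order by AIC
#'
#' Fits lag orders `1..max_lag` on a common estimation sample (the first
#' `max_lag` rows are withheld for every candidate, so the AIC values are
#' comparable) and returns the order with the smallest AIC; ties break
#' toward fewer lags.
#'
#' @param fs a [factor_score_series()] or `T x k` matrix.
#' @param max_lag largest candidate order, default 5.
#' @param trend include the linear trend regressor in every candidate?
#' @return The selected lag order (integer) with attribute `"aic"`, the
#'   named vector of candidate AICs.
#' @export
select_lag <- function(fs, max_lag = 5L, trend = TRUE) {
  Y <- if (inherits(fs, "factor_score_series")) fs$scores else as.matrix(fs)
  k <- ncol(Y)
  need <- max_lag + (1L + as.integer(trend) + k * max_lag) + 1L
  if (nrow(Y) < need)
    stop("select_lag: series too short for max_lag = ", max_lag, call. = FALSE)
  aics <- vapply(seq_len(max_lag), function(p)
    fit_var(Y, p, trend = trend, skip = max_lag)$aic, numeric(1))
  names(aics) <- paste0("p", seq_len(max_lag))
  p_sel <- which.min(aics)  # which.min returns the first (smallest p) on ties
  structure(as.integer(p_sel), aic = aics)
}

#' Between-time explained variance of each factor
#'
#' The incremental R-squared of the lagged block: for each equation,
#' the full-model R-squared minus the R-squared of a reduced regression on
#' the deterministic terms only (intercept, and trend if present), both on
#' the model's estimation sample. This is the variance attributable to the
#' auto- and cross-regressive parameters after trend adjustment, clipped
#' to `[0, 1]`.
#'
#' @param fs the [factor_score_series()] the model was fitted on.
#' @param model a fitted [fit_var()] model.
#' @return Numeric vector of `k` incremental R-squared values.
#' @export
lagged_block_r2 <- function(fs, model) {
  Y <- if (inherits(fs, "factor_score_series")) fs$scores else as.matrix(fs)
  if (is.null(colnames(Y))) colnames(Y) <- paste0("F", seq_len(ncol(Y)))
  d <- .var_design(Y, model$p, skip = model$skip, trend = model$trend)
  X0 <- d$X[, c("const", if (model$trend) "trend"), drop = FALSE]
  r2_red <- vapply(seq_len(ncol(Y)), function(j) {
    f <- stats::lm.fit(X0, d$Yresp[, j])
    1 - sum(f$residuals^2) / sum(scale(d$Yresp[, j], scale = FALSE)^2)
  }, numeric(1))
  pmin(pmax(model$r2 - r2_red, 0), 1)
}

#' Tabulate VAR coefficients
#'
#' Long-format per-equation coefficient table (estimate, SE, t, p) for
#' reports; `significant` flags two-sided p below `alpha`.
#'
#' @param model a `var_model`.
#' @param alpha significance level for flagging, default 0.05.
#' @return A data frame with columns `equation`, `term`, `estimate`, `se`,
#'   `tstat`, `pval`, `significant`.
#' @export
var_coef_table <- function(model, alpha = 0.05) {
  eqs <- colnames(model$coef)
  do.call(rbind, lapply(eqs, function(eq)
    data.frame(equation = eq, term = rownames(model$coef),
               estimate = model$coef[, eq], se = model$se[, eq],
               tstat = model$tstat[, eq], pval = model$pval[, eq],
               significant = model$pval[, eq] < alpha,
               row.names = NULL)))
}
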