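#' Derive the confirmatory model pattern from an exploratory solution
#'
#' Step 2 of the pipeline begins by converting the exploratory loading
#' matrix into a confirmatory measurement pattern: item `i` is assigned to
#' factor `j` iff its exploratory loading satisfies `|loading| > threshold`
#' (strictly greater; the conventional cutoff is .30). Items exceeding the
#' threshold on no factor are excluded from the confirmatory model.
#'
#' @param efa an `efa_model` (or any list with a `loadings` matrix whose
#'   rownames are item ids).
#' @param threshold loading cutoff, default 0.30.
#' @return An object of class `cfa_pattern`: `k`, `included` (per-factor
#'   character vectors of item ids), `excluded_items`, `items` (all included
#'   items in original order), `threshold`.
#' @export
build_pattern <- function(efa, threshold = 0.30) {
  L <- efa$loadings
  if (is.null(rownames(L))) rownames(L) <- paste0("item", seq_len(nrow(L)))
  assign <- abs(L) > threshold
  included <- lapply(seq_len(ncol(L)), function(j) rownames(L)[assign[, j]])
  names(included) <- colnames(L)
  n_items <- vapply(included, length, integer(1))
  if (any(n_items < 2L))
    stop("build_pattern: factor(s) ",
         paste(names(included)[n_items < 2L], collapse = ", "),
         " left with fewer than 2 items; pattern under-identified",
         call. = FALSE)
  in_any <- apply(assign, 1L, any)
  structure(
    list(k = ncol(L), included = included,
         excluded_items = rownames(L)[!in_any],
         items = rownames(L)[in_any], threshold = threshold),
    class = "cfa_pattern")
}

#' Render a pattern as model terms
#'
#' Text form `"Factor j = Item a + Item b + ..."`, one line per factor,
#' as used in reports.
#' @param pattern a `cfa_pattern`.
#' @return Character vector, one element per factor.
#' @export
pattern_terms <- function(pattern) {
  vapply(seq_along(pattern$included), function(j)
    paste0("Factor ", j, " = ",
           paste(pattern$included[[j]], collapse = " + ")),
    character(1))
}

#' @export
print.cfa_pattern <- function(x, ...) {
  cat("<cfa_pattern>\n")
  cat(paste0("  ", pattern_terms(x), collapse = "\n"), "\n")
  if (length(x$excluded_items) > 0L)
    cat("  excluded:", paste(x$excluded_items, collapse = ", "), "\n")
  invisible(x)
}

# spherical parameterization of a correlation matrix: k(k-1)/2 angles ->
# lower-triangular C with unit-norm rows, Phi = C C'
.phi_from_angles <- function(ang, k) {
  C <- diag(k)
  pos <- 1L
  for (i in seq_len(k)[-1]) {
    a <- ang[pos:(pos + i - 2L)]
    pos <- pos + i - 1L
    row <- numeric(k)
    sin_prod <- 1
    for (j in seq_len(i - 1L)) {
      row[j] <- sin_prod * cos(a[j])
      sin_prod <- sin_prod * sin(a[j])
    }
    row[i] <- sin_prod
    C[i, ] <- row
  }
  C %*% t(C)
}

# ML discrepancy for the confirmatory model; par = (lambda, log(theta-floor), angles)
.cfa_objective <- function(par, S, free_idx, k, n_lambda, theta_floor = 0.005) {
  I <- nrow(S)
  lambda <- par[seq_len(n_lambda)]
  theta <- theta_floor + exp(par[n_lambda + seq_len(I)])
  ang <- par[-(seq_len(n_lambda + I))]
  L <- matrix(0, I, k)
  L[free_idx] <- lambda
  Phi <- if (k > 1L) .phi_from_angles(ang, k) else matrix(1, 1, 1)
  Sigma <- L %*% Phi %*% t(L) + diag(theta, I)
  ch <- tryCatch(chol(Sigma), error = function(e) NULL)
  if (is.null(ch)) return(1e10)
  logdet <- 2 * sum(log(diag(ch)))
  tr <- sum(diag(chol2inv(ch) %*% S))
  logdet + tr - determinant(S, logarithm = TRUE)$modulus[1] - I
}

#' Fit a confirmatory P-factor model
#'
#' Maximum-likelihood estimation of the factor model
#' \eqn{\Sigma(\theta) = \Lambda\Phi\Lambda' + \Theta} on the standardized
#' (z-scored) included items, with loadings free exactly where the pattern
#' specifies, factor variances fixed to 1 for identification, factor
#' correlations free, and diagonal residual covariance. The discrepancy
#' \eqn{F = \log|\Sigma| + tr(S\Sigma^{-1}) - \log|S| - I'} is minimized by
#' quasi-Newton iteration; the likelihood-ratio statistic is the
#' uncorrected \eqn{(T-1)F}. Residual variances are bounded below at 0.005
#' (Heywood floor, flagged by warning when active).
#'
#' @param ts cleaned [symptom_ts()] or response matrix covering all
#'   pattern items.
#' @param pattern a [build_pattern()] result.
#' @param start optional `efa_model` whose loadings seed the optimizer.
#' @param weights_type `"loading"` (default: the factor-score weighting
#'   matrix equals the estimated pattern loadings) or `"regression"`
#'   (Thurstone weights \eqn{\hat\Sigma^{-1}\Lambda\Phi}).
#' @return An object of class `cfa_model`: `pattern`, `loadings` (`I' x k`,
#'   zeros where unspecified), `Phi`, `theta` (residual variances), `fit`
#'   (a `fit_indices` carrying TLI and SRMR), `weights`, `items`, `n_obs`,
#'   `S`, `discrepancy`, `heywood`, `convergence`.
#' @export
fit_cfa <- function(ts, pattern, start = NULL, weights_type = c("loading", "regression")) {
  weights_type <- match.arg(weights_type)
  stopifnot(inherits(pattern, "cfa_pattern"))
  X <- if (inherits(ts, "symptom_ts")) ts$values else as.matrix(ts)
  if (anyNA(X))
    stop("fit_cfa: series contains missing values; clean it first", call. = FALSE)
  miss <- setdiff(pattern$items, colnames(X))
  if (length(miss) > 0L)
    stop("fit_cfa: series lacks pattern items: ",
         paste(miss, collapse = ", "), call. = FALSE)
  X <- X[, pattern$items, drop = FALSE]
  Tn <- nrow(X); I <- ncol(X); k <- pattern$k
  S <- stats::cor(X)
  free <- matrix(FALSE, I, k,
                 dimnames = list(pattern$items, names(pattern$included)))
  for (j in seq_len(k)) free[pattern$included[[j]], j] <- TRUE
  free_idx <- which(free)
  n_lambda <- length(free_idx)
  n_par <- n_lambda + I + k * (k - 1) / 2
  df <- I * (I + 1) / 2 - n_par
  if (df < 0)
    stop("fit_cfa: more free parameters than distinct moments (df < 0)",
         call. = FALSE)
  if (Tn <= n_par)
    stop("fit_cfa: need more assessments than free parameters", call. = FALSE)
  # starts: EFA loadings where available, else 0.6; theta 0.5; Phi = I
  L0 <- matrix(0.6, I, k)
  if (!is.null(start) && !is.null(start$loadings)) {
    common <- intersect(rownames(start$loadings), pattern$items)
    L0[match(common, pattern$items), ] <- start$loadings[common, , drop = FALSE]
  }
  par0 <- c(L0[free_idx], rep(log(0.5 - 0.005), I),
            rep(pi / 2, k * (k - 1) / 2))
  opt <- stats::optim(par0, .cfa_objective, S = S, free_idx = free_idx,
                      k = k, n_lambda = n_lambda, method = "BFGS",
                      control = list(maxit = 2000, reltol = 1e-14))
  if (opt$convergence != 0)
    stop("fit_cfa: optimizer failed to converge (code ", opt$convergence, ")",
         call. = FALSE)
  lambda <- opt$par[seq_len(n_lambda)]
  theta <- 0.005 + exp(opt$par[n_lambda + seq_len(I)])
  ang <- opt$par[-(seq_len(n_lambda + I))]
  L <- matrix(0, I, k, dimnames = dimnames(free))
  L[free_idx] <- lambda
  Phi <- if (k > 1L) .phi_from_angles(ang, k) else matrix(1, 1, 1)
  dimnames(Phi) <- list(names(pattern$included), names(pattern$included))
  # sign alignment as in EFA
  for (j in seq_len(k)) {
    v <- L[, j]
    if (sign(v[which.max(abs(v))]) < 0) {
      L[, j] <- -L[, j]
      Phi[j, ] <- -Phi[j, ]; Phi[, j] <- -Phi[, j]; Phi[j, j] <- 1
    }
  }
  heywood <- any(theta <= 0.005 * (1 + 1e-4))
  if (heywood)
    warning("fit_cfa: Heywood case; residual variance floored at 0.005",
            call. = FALSE)
  Sigma <- L %*% Phi %*% t(L) + diag(theta, I)
  F_obj <- opt$value
  chi2 <- max(0, (Tn - 1) * F_obj)
  F_null <- -log(det(S))
  chi2_null <- max(0, (Tn - 1) * F_null)
  fit <- .fit_indices(chi2, df, chi2_null, I * (I - 1) / 2,
                      rms = {
                        r <- S - Sigma
                        sqrt(mean(r[lower.tri(r)]^2))
                      },
                      srmr = .srmr(S, Sigma))
  W <- if (weights_type == "loading") L else solve(Sigma, L %*% Phi)
  dimnames(W) <- dimnames(L)
  structure(
    list(pattern = pattern, loadings = L, Phi = Phi, theta = theta,
         fit = fit, weights = W, weights_type = weights_type,
         items = pattern$items, n_obs = Tn, S = S,
         discrepancy = F_obj, heywood = heywood,
         convergence = opt$convergence),
    class = "cfa_model")
}

#' @export
print.cfa_model <- function(x, ...) {
  cat(sprintf("<cfa_model> %d factors, %d items, T = %d\n",
              x$pattern$k, length(x$items), x$n_obs))
  cat(sprintf("  TLI = %.3f, SRMR = %.3f (chi2 = %.2f on %g df)\n",
              x$fit$tli, x$fit$srmr, x$fit$chi2, x$fit$df))
  cat("Loadings:\n"); print(round(x$loadings, 3))
  cat("Factor correlations:\n"); print(round(x$Phi, 3))
  invisible(x)
}

#' Confirmatory fit gate
#'
#' The confirmatory model passes when the Tucker-Lewis index reaches
#' `tli_min` and the standardized root mean squared residual does not
#' exceed `srmr_max` (Hu-Bentler joint criteria).
#'
#' @param model a `cfa_model`, or a list with `fit$tli` and `fit$srmr`.
#' @param tli_min,srmr_max cutoffs; defaults 0.95 and 0.08.
#' @return `TRUE` or `FALSE`.
#' @export
cfa_passes <- function(model, tli_min = 0.95, srmr_max = 0.08) {
  isTRUE(is.finite(model$fit$tli) && model$fit$tli >= tli_min &&
           model$fit$srmr <= srmr_max)
}

#' Extract the factor-score time series
#'
#' Step 3 input: multiplies the standardized included-item data by the
#' confirmatory weighting matrix, yielding one score row per assessment.
#'
#' @param ts cleaned [symptom_ts()] or response matrix.
#' @param model a fitted `cfa_model`.
#' @return An object of class `factor_score_series`: `scores` (`T x k`
#'   matrix) and `factor_labels`.
#' @export
factor_score_series <- function(ts, model) {
  X <- if (inherits(ts, "symptom_ts")) ts$values else as.matrix(ts)
  if (anyNA(X))
    stop("factor_score_series: series contains missing values; clean it first",
         call. = FALSE)
  miss <- setdiff(model$items, colnames(X))
  if (length(miss) > 0L)
    stop("factor_score_series: series lacks items: ",
         paste(miss, collapse = ", "), call. = FALSE)
  Z <- scale(X[, model$items, drop = FALSE])
  Z[is.nan(Z)] <- 0  # zero-variance item under scaling
  scores <- Z %*% model$weights
  structure(list(scores = unclass(scores),
                 factor_labels = colnames(model$weights)),
            class = "factor_score_series")
}

#' @export
print.factor_score_series <- function(x, ...) {
  cat(sprintf("<factor_score_series> T = %d, k = %d (%s)\n",
              nrow(x$scores), ncol(x$scores),
              paste(x$factor_labels, collapse = ", ")))
  invisible(x)
}
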