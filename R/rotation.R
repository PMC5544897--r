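# Oblique gradient-projection rotation (quartimin = direct oblimin, gamma 0).
# Minimizes the quartimin criterion over oblique rotation matrices with
# unit-length columns; Phi = t(Tmat) %*% Tmat.

# quartimin criterion value and gradient wrt the rotated loadings
.vgQ_quartimin <- function(L) {
  k <- ncol(L)
  L2 <- L^2
  N <- matrix(1, k, k) - diag(k)
  list(f = sum(L2 * (L2 %*% N)) / 4, Gq = L * (L2 %*% N))
}

#' Direct oblimin rotation of a loading matrix
#'
#' Gradient-projection rotation to the direct oblimin criterion with
#' rotation parameter 0 (quartimin), permitting correlated factors. The
#' rotated solution satisfies `L Phi L' = A A'` where `A` is the unrotated
#' loading matrix, so the model-implied correlation matrix is unchanged.
#' Factor signs are aligned so each factor's largest-magnitude loading is
#' positive.
#'
#' @param A unrotated `I x k` loading matrix, `k >= 2`.
#' @param maxit iteration cap for the gradient projection.
#' @param eps convergence tolerance on the projected gradient norm.
#' @return List with `loadings` (rotated pattern matrix), `Phi` (factor
#'   correlation matrix), `Tmat` (oblique rotation matrix), `f` (criterion
#'   value), `converged`.
#' @details The gradient projection is run from the identity and from a
#'   fixed set of pseudo-random oblique starts (the identity is a saddle
#'   point for perfectly symmetric loading patterns); the solution with the
#'   lowest criterion value is returned. The starts are deterministic and
#'   the caller's RNG state is left untouched, so rotation never perturbs
#'   reproducibility.
#' @references Jennrich, R. I. (2002). A simple general method for oblique
#'   rotation. Psychometrika, 67, 7-19.
#' @export
rotate_oblimin <- function(A, maxit = 1000L, eps = 1e-6, n_starts = 8L) {
  A <- as.matrix(A)
  k <- ncol(A)
  if (k < 2L) stop("rotate_oblimin: need at least 2 factors", call. = FALSE)
  best <- NULL
  for (Tmat0 in .fixed_oblique_starts(k, n_starts)) {
    cand <- .gpa_oblq(A, Tmat0, maxit = maxit, eps = eps)
    if (is.null(best) || cand$f < best$f - 1e-12 ||
        (cand$converged && !best$converged && cand$f < best$f + 1e-9))
      best <- cand
  }
  Tmat <- best$Tmat
  L <- A %*% solve(t(Tmat))
  Phi <- t(Tmat) %*% Tmat
  # sign alignment: largest-magnitude loading per factor positive
  flip <- vapply(seq_len(k), function(j) {
    v <- L[, j]; sign(v[which.max(abs(v))]) < 0
  }, logical(1))
  if (any(flip)) {
    L[, flip] <- -L[, flip]
    Phi[flip, ] <- -Phi[flip, ]
    Phi[, flip] <- -Phi[, flip]
    Tmat[, flip] <- -Tmat[, flip]
  }
  dimnames(L) <- dimnames(A)
  list(loadings = L, Phi = Phi, Tmat = Tmat, f = best$f,
       converged = best$converged)
}

# deterministic unit-column start matrices; caller RNG state is preserved
.fixed_oblique_starts <- function(k, n_starts = 8L) {
  starts <- list(diag(k))
  if (n_starts < 1L) return(starts)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(20170720L)
  for (s in seq_len(n_starts)) {
    M <- matrix(stats::rnorm(k * k), k, k)
    starts[[s + 1L]] <- M %*% diag(1 / sqrt(colSums(M^2)), k)
  }
  if (is.null(old)) {
    rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  starts
}

# gradient-projection descent for the quartimin criterion from one start
.gpa_oblq <- function(A, Tmat, maxit = 1000L, eps = 1e-6) {
  k <- ncol(A)
  al <- 1
  L <- A %*% solve(t(Tmat))
  vg <- .vgQ_quartimin(L)
  f <- vg$f
  G <- -t(t(L) %*% vg$Gq %*% solve(Tmat))
  converged <- FALSE
  for (iter in seq_len(maxit)) {
    Gp <- G - Tmat %*% diag(colSums(Tmat * G), k)
    s <- sqrt(sum(Gp^2))
    if (s < eps) { converged <- TRUE; break }
    al <- 2 * al
    for (i in 1:25) {
      X <- Tmat - al * Gp
      Tt <- X %*% diag(1 / sqrt(colSums(X^2)), k)
      L <- A %*% solve(t(Tt))
      vgt <- .vgQ_quartimin(L)
      if (vgt$f < f - 0.5 * s^2 * al) break
      al <- al / 2
    }
    Tmat <- Tt
    f <- vgt$f
    G <- -t(t(L) %*% vgt$Gq %*% solve(Tmat))
  }
  list(Tmat = Tmat, f = f, converged = converged)
}
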