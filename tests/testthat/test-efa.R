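test_that("oblimin rotation preserves the model-implied common variance", {
  set.seed(21)
  for (rep in 1:10) {
    A <- matrix(stats::rnorm(14), 7, 2)
    rot <- rotate_oblimin(A)
    expect_true(rot$converged)
    expect_lt(max(abs(rot$loadings %*% rot$Phi %*% t(rot$loadings) -
                        A %*% t(A))), 1e-8)
    expect_equal(diag(rot$Phi), rep(1, 2), tolerance = 1e-10)
    expect_equal(rot$Phi, t(rot$Phi), tolerance = 1e-12)
    # sign convention: each factor's largest-magnitude loading is positive
    for (j in 1:2)
      expect_gt(rot$loadings[which.max(abs(rot$loadings[, j])), j], 0)
  }
})

test_that("oblimin recovers an oblique simple structure", {
  L <- rbind(c(.8, 0), c(.7, 0), c(.6, 0), c(0, .8), c(0, .7), c(0, .6))
  Phi <- matrix(c(1, .5, .5, 1), 2)
  # orthogonalize to mimic an unrotated extraction: A A' = L Phi L'
  C <- chol(Phi)
  A <- L %*% t(C)
  rot <- rotate_oblimin(A)
  perm <- if (abs(rot$loadings[1, 1]) > abs(rot$loadings[1, 2])) 1:2 else 2:1
  expect_lt(max(abs(rot$loadings[, perm] - L)), 0.02)
  expect_equal(rot$Phi[perm[1], perm[2]], .5, tolerance = 0.02)
})

test_that("fit indices match an explicit-formula oracle on a 4-item fixture", {
  # one-factor fixture with a deliberately imperfect implied matrix
  A <- matrix(c(.8, .7, .6, .5), 4, 1)
  uniq <- c(.4, .5, .6, .7)
  S <- A %*% t(A) + diag(uniq)
  S[1, 2] <- S[2, 1] <- S[1, 2] + 0.05   # perturb one correlation
  diag(S) <- 1
  Tn <- 150; I <- 4; k <- 1
  model <- list(k = k, loadings_unrotated = A, uniquenesses = uniq,
                discrepancy = NULL)
  fit <- efa_fit_indices(model, S, Tn)

  # independent brute-force computation, written out term by term
  Sigma <- A %*% t(A) + diag(uniq)
  F_ml <- log(det(Sigma)) + sum(diag(S %*% solve(Sigma))) - log(det(S)) - I
  chi2 <- (Tn - 1 - (2 * I + 5) / 6 - 2 * k / 3) * F_ml
  df <- ((I - k)^2 - (I + k)) / 2
  chi2_null <- (Tn - 1 - (2 * I + 5) / 6) * (-log(det(S)))
  df_null <- I * (I - 1) / 2
  tli <- ((chi2_null / df_null) - (chi2 / df)) /
    ((chi2_null / df_null) - 1)
  resid <- S - Sigma
  rms <- sqrt(mean(resid[lower.tri(resid)]^2))

  expect_equal(fit$chi2, chi2, tolerance = 1e-10)
  expect_equal(fit$df, df)
  expect_equal(fit$tli, tli, tolerance = 1e-10)
  expect_equal(fit$rms, rms, tolerance = 1e-10)
})

test_that("degenerate fit-index cases behave as the formulas dictate", {
  # perfect reproduction: zero discrepancy, zero residual, TLI above 1 allowed
  A <- matrix(c(.8, .7, .6, .5), 4, 1)
  uniq <- 1 - A[, 1]^2
  S <- A %*% t(A) + diag(uniq)
  model <- list(k = 1, loadings_unrotated = A, uniquenesses = uniq,
                discrepancy = NULL)
  fit <- efa_fit_indices(model, S, 150)
  expect_equal(fit$chi2, 0, tolerance = 1e-8)
  expect_equal(fit$rms, 0, tolerance = 1e-8)
  expect_gte(fit$tli, 1)

  # constant off-diagonal residuals: RMS equals that constant
  S2 <- diag(4); S2[upper.tri(S2)] <- S2[lower.tri(S2)] <- 0.06
  model2 <- list(k = 1, loadings_unrotated = matrix(0, 4, 1),
                 uniquenesses = rep(1, 4), discrepancy = NULL)
  fit2 <- efa_fit_indices(model2, S2, 150)
  expect_equal(fit2$rms, 0.06, tolerance = 1e-12)

  expect_error(
    efa_fit_indices(list(k = 3, loadings_unrotated = matrix(0, 4, 3),
                         uniquenesses = rep(1, 4)), diag(4), 150),
    "df")
})

test_that("ML factor analysis recovers a known oblique 2-factor structure", {
  L <- rbind(c(.7, 0), c(.7, 0), c(.7, 0), c(.7, 0),
             c(0, .7), c(0, .7), c(0, .7), c(0, .7))
  rownames(L) <- paste0("item", 1:8)
  Phi <- matrix(c(1, .5, .5, 1), 2)
  X <- exact_cor_data(500, factor_model_sigma(L, Phi, 1 - rowSums((L %*% Phi) * L)),
                      seed = 31)
  m <- fit_efa(X, 2)
  expect_equal(m$k, 2)
  # Tucker congruence per factor after column matching
  congr <- function(x, y) sum(x * y) / sqrt(sum(x^2) * sum(y^2))
  cmat <- abs(outer(1:2, 1:2, Vectorize(function(i, j)
    congr(m$loadings[, i], L[, j]))))
  expect_gt(max(cmat[1, ]), .95)
  expect_gt(max(cmat[2, ]), .95)
  # communality + uniqueness close to 1 on standardized data
  expect_equal(rowSums(m$loadings_unrotated^2) + m$uniquenesses,
               rep(1, 8), ignore_attr = TRUE, tolerance = 1e-4)
})

test_that("independent noise yields mostly trivial communalities", {
  # ML extraction on structureless data can push single items to a Heywood
  # boundary, so the bulk of the communalities is the meaningful summary
  set.seed(41)
  X <- matrix(stats::rnorm(500 * 8), 500, 8)
  m <- suppressWarnings(fit_efa(X, 2))
  expect_lt(stats::median(1 - m$uniquenesses), .2)
  expect_gte(sum(1 - m$uniquenesses < .2), 6L)
})

test_that("unidentified or degenerate inputs are rejected", {
  set.seed(5)
  expect_error(fit_efa(matrix(stats::rnorm(50 * 4), 50, 4), 3), "df < 0")
  expect_error(fit_efa(matrix(stats::rnorm(4 * 5), 4, 5), 2), "T > I")
  X <- matrix(stats::rnorm(100 * 6), 100, 6)
  X[, 3] <- 5
  expect_warning(try(fit_efa(X, 2), silent = TRUE), "zero-variance")
})

test_that("model selection returns the smallest adequate factor count", {
  L <- rbind(c(.8, 0), c(.75, 0), c(.7, 0), c(.65, 0),
             c(0, .8), c(0, .75), c(0, .7), c(0, .65))
  Phi <- matrix(c(1, .4, .4, 1), 2)
  X <- exact_cor_data(400, factor_model_sigma(L, Phi), seed = 51)
  sel <- select_model(X)
  expect_equal(sel$status, "found")
  expect_equal(sel$k, 2L)

  set.seed(52)
  noise <- matrix(stats::rnorm(200 * 10), 200, 10)
  sel2 <- select_model(noise)
  expect_equal(sel2$status, "no_model")
  expect_null(sel2$model)
})
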