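# Shared fixtures: tiny series builders and a default two-item config.

make_ts <- function(values, scale_min = 0, scale_max = 8, ids = NULL) {
  values <- as.matrix(values)
  if (is.null(ids)) ids <- colnames(values)
  if (is.null(ids)) ids <- paste0("item", seq_len(ncol(values)))
  stamps <- as.POSIXct("2026-01-05 08:00:00", tz = "UTC") +
    21600 * (seq_len(nrow(values)) - 1)
  symptom_ts(values, stamps, ids, scale_min = scale_min, scale_max = scale_max)
}

two_item_config <- function(scale_min = 0, scale_max = 8) {
  patient_config("PT-TEST",
                 data.frame(id = c("a", "b"), text = c("Item A", "Item B")),
                 scale_min, scale_max)
}

csv_lines <- function(header, ...) c(header, unlist(list(...)))

# exact-moment multivariate normal data for a target correlation matrix
exact_cor_data <- function(n, Sigma, seed = 1) {
  set.seed(seed)
  X <- MASS::mvrnorm(n, rep(0, nrow(Sigma)), Sigma, empirical = TRUE)
  colnames(X) <- rownames(Sigma)
  X
}

# population-style draw from a factor model correlation structure
factor_model_sigma <- function(L, Phi, theta = NULL) {
  L <- as.matrix(L)
  if (is.null(theta)) theta <- pmax(1 - rowSums((L %*% Phi) * L), 0.2)
  S <- L %*% Phi %*% t(L) + diag(theta)
  dimnames(S) <- list(rownames(L), rownames(L))
  S
}
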