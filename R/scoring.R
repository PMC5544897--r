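#' Within-time explained variance per factor
#'
#' Step 4, first half: the share of synchronous (within-time) item variance
#' each confirmatory factor explains. For factor `j` with confirmatory
#' loadings \eqn{\lambda_{ij}}, the default share is
#' \eqn{\sum_i \lambda_{ij}^2 / k^2} where `k` is the number of factors:
#' summed squared loadings scaled by the factor count twice, once for each
#' normalization step of the published worked example. The literal
#' "divide by the number of factors" reading (\eqn{\sum_i \lambda_{ij}^2/k})
#' is available via `divisor = "k"`.
#'
#' @param cfa a fitted `cfa_model`, or any list with a `loadings` matrix.
#' @param divisor `"k2"` (default) or `"k"`.
#' @return Numeric vector of `k` variance shares (fractions).
#' @export
within_time_variance <- function(cfa, divisor = c("k2", "k")) {
  divisor <- match.arg(divisor)
  L <- cfa$loadings
  k <- ncol(L)
  shares <- colSums(L^2) / if (divisor == "k2") k^2 else k
  stats::setNames(as.numeric(shares), colnames(L))
}

#' Combine within- and between-time variance into factor scores
#'
#' Step 4, second half: each factor's within-time share is multiplied by
#' its between-time share (the trend-adjusted lagged R-squared from the
#' VAR stage) and the products are normalized by the largest product, so
#' the highest-scoring factor receives exactly 1.
#'
#' @param within,between numeric vectors of `k` variance shares (fractions
#'   or percentages; only the ratio matters, but both must use the same
#'   units).
#' @return An object of class `planning_scores`: `within`, `between`,
#'   `raw_factor` (the products), `factor_score` (normalized, max 1).
#' @export
factor_scores <- function(within, between) {
  if (length(within) != length(between))
    stop("factor_scores: within and between must have equal length", call. = FALSE)
  if (any(within < 0) || any(between < 0))
    stop("factor_scores: variance shares must be non-negative", call. = FALSE)
  raw <- within * between
  if (all(raw == 0))
    stop("factor_scores: all factor products are zero; scores degenerate",
         call. = FALSE)
  structure(
    list(within = within, between = between, raw_factor = raw,
         factor_score = raw / max(raw)),
    class = "planning_scores")
}

#' @export
print.planning_scores <- function(x, ...) {
  df <- data.frame(within = x$within, between = x$between,
                   product = x$raw_factor, score = x$factor_score)
  print(round(df, 4))
  invisible(x)
}

#' Per-symptom treatment-priority scores
#'
#' Step 5: raw item means (in scale units, computed on the cleaned series)
#' are normalized by the largest mean among the modeled items; each item's
#' confirmatory loading is multiplied by the score of the factor it loads
#' on (summed over all factors the item loads on), and the product with the
#' normalized mean is rescaled so the top item scores exactly 100. Items
#' the confirmatory pattern excluded receive no score and are listed in the
#' `excluded` attribute.
#'
#' @param ts cleaned [symptom_ts()] (raw ratings; means are taken on the
#'   original scale, not on standardized values).
#' @param cfa a fitted `cfa_model`.
#' @param fscores a [factor_scores()] result from the same run.
#' @return A `priority_table`: data frame with columns `item_id`,
#'   `item_text`, `mean_rating`, `norm_mean`, one contribution column per
#'   factor, and `symptom_score`, sorted by descending score.
#' @export
symptom_scores <- function(ts, cfa, fscores) {
  stopifnot(inherits(ts, "symptom_ts"), inherits(fscores, "planning_scores"))
  items <- cfa$items
  idx <- match(items, ts$item_ids)
  if (anyNA(idx))
    stop("symptom_scores: series lacks modeled items", call. = FALSE)
  m <- colMeans(ts$values[, idx, drop = FALSE])
  if (all(m == 0))
    stop("symptom_scores: all item means are zero; priorities degenerate",
         call. = FALSE)
  norm_mean <- m / max(m)
  contrib <- sweep(cfa$loadings, 2L, fscores$factor_score, `*`)
  q <- norm_mean * rowSums(contrib)
  score <- 100 * q / max(q)
  tab <- data.frame(item_id = items,
                    item_text = ts$item_texts[idx],
                    mean_rating = as.numeric(m),
                    norm_mean = as.numeric(norm_mean),
                    stringsAsFactors = FALSE)
  for (j in seq_len(ncol(contrib)))
    tab[[paste0("contrib_", colnames(contrib)[j])]] <- as.numeric(contrib[, j])
  tab$symptom_score <- as.numeric(score)
  tab <- tab[order(-tab$symptom_score), ]
  rownames(tab) <- NULL
  structure(tab, excluded = cfa$pattern$excluded_items,
            class = c("priority_table", "data.frame"))
}

#' @export
print.priority_table <- function(x, ...) {
  if (!all(c("item_id", "item_text", "symptom_score") %in% names(x)))
    return(print(as.data.frame(x), ...))
  cat("Symptom priority scores (descending):\n")
  print(data.frame(item = x$item_id,
                   score = round(x$symptom_score, 2),
                   text = substr(x$item_text, 1, 50)), row.names = FALSE)
  excl <- attr(x, "excluded")
  if (length(excl) > 0L)
    cat("Not modeled (insufficient loadings):", paste(excl, collapse = ", "), "\n")
  invisible(x)
}

#' Run the full treatment-planning pipeline
#'
#' Orchestrates the five planning steps on a cleaned symptom time series:
#' exploratory model selection (2-4 factors, Hu-Bentler gate), confirmatory
#' pattern and fit (gate), factor-score extraction, VAR with AIC lag
#' selection, between-time lagged R-squared, and the Step 4/5 scoring
#' algebra. Any gate failure yields `status = "no_model"` with the failed
#' gate named in `diagnostics`; a series shorter than `min_measurements`
#' is an error (insufficient data is distinct from a failed model search).
#'
#' The run is deterministic: identical input and options give identical
#' results.
#'
#' @param ts a [symptom_ts()]; cleaned internally via [clean_timeseries()]
#'   if it still contains missing values.
#' @param config optional [patient_config()] (carried into the report).
#' @param min_measurements minimum number of assessments, default 40.
#' @param k_max largest exploratory factor count, default 4.
#' @param tli_min,rms_max,srmr_max fit-gate cutoffs (Hu-Bentler defaults).
#' @param loading_threshold confirmatory inclusion cutoff, default 0.30.
#' @param max_lag largest VAR lag candidate, default 5.
#' @param within_divisor `"k2"` (default) or `"k"`, see
#'   [within_time_variance()].
#' @param weights_type factor-score weighting, see [fit_cfa()].
#' @param max_gap cleaning interpolation limit, see [clean_timeseries()].
#' @return An object of class `planning_result` with fields `status`
#'   (`"found"`/`"no_model"`), `efa` (an `efa_selection`), `cfa`, `var`,
#'   `lag`, `scores`, `priorities`, `cleaning`, `diagnostics` (data frame
#'   of gate decisions), `options`.
#' @export
run_planning <- function(ts, config = NULL, min_measurements = 40L,
                         k_max = 4L, tli_min = 0.95, rms_max = 0.08,
                         srmr_max = 0.08, loading_threshold = 0.30,
                         max_lag = 5L, within_divisor = c("k2", "k"),
                         weights_type = c("loading", "regression"),
                         max_gap = 1L) {
  within_divisor <- match.arg(within_divisor)
  weights_type <- match.arg(weights_type)
  stopifnot(inherits(ts, "symptom_ts"))
  cleaning <- NULL
  if (anyNA(ts$values)) {
    cl <- clean_timeseries(ts, max_gap = max_gap)
    ts <- cl$ts
    cleaning <- cl$report
  }
  if (nrow(ts$values) < min_measurements)
    stop("run_planning: insufficient data: ", nrow(ts$values),
         " assessments, minimum is ", min_measurements, call. = FALSE)
  diag_rows <- list()
  gate <- function(stage, passed, detail) {
    diag_rows[[length(diag_rows) + 1L]] <<-
      data.frame(stage = stage, passed = passed, detail = detail)
  }
  fail <- function(stage, detail) {
    gate(stage, FALSE, detail)
    structure(list(status = "no_model", efa = sel, cfa = NULL, var = NULL,
                   lag = NA_integer_, scores = NULL, priorities = NULL,
                   cleaning = cleaning, config = config,
                   diagnostics = do.call(rbind, diag_rows),
                   options = opts),
              class = "planning_result")
  }
  opts <- list(min_measurements = min_measurements, k_max = k_max,
               tli_min = tli_min, rms_max = rms_max, srmr_max = srmr_max,
               loading_threshold = loading_threshold, max_lag = max_lag,
               within_divisor = within_divisor, weights_type = weights_type,
               max_gap = max_gap)
  sel <- select_model(ts, k_max = k_max, tli_min = tli_min, rms_max = rms_max)
  if (sel$status != "found")
    return(fail("efa", "no exploratory candidate reached TLI/RMS cutoffs"))
  gate("efa", TRUE, sprintf("k = %d (TLI = %.3f, RMS = %.3f)",
                            sel$k, sel$model$fit$tli, sel$model$fit$rms))
  pattern <- tryCatch(build_pattern(sel$model, threshold = loading_threshold),
                      error = identity)
  if (inherits(pattern, "error"))
    return(fail("pattern", conditionMessage(pattern)))
  gate("pattern", TRUE, paste(pattern_terms(pattern), collapse = "; "))
  cfa <- tryCatch(
    suppressWarnings(fit_cfa(ts, pattern, start = sel$model,
                             weights_type = weights_type)),
    error = identity)
  if (inherits(cfa, "error")) return(fail("cfa", conditionMessage(cfa)))
  if (!cfa_passes(cfa, tli_min = tli_min, srmr_max = srmr_max))
    return(fail("cfa", sprintf("confirmatory fit rejected (TLI = %.3f, SRMR = %.3f)",
                               cfa$fit$tli, cfa$fit$srmr)))
  gate("cfa", TRUE, sprintf("TLI = %.3f, SRMR = %.3f", cfa$fit$tli, cfa$fit$srmr))
  fs <- factor_score_series(ts, cfa)
  lag <- tryCatch(select_lag(fs, max_lag = max_lag), error = identity)
  if (inherits(lag, "error")) return(fail("var", conditionMessage(lag)))
  var <- tryCatch(fit_var(fs, p = as.integer(lag)), error = identity)
  if (inherits(var, "error")) return(fail("var", conditionMessage(var)))
  gate("var", TRUE, sprintf("p = %d, R^2 = %s", var$p,
                            paste(sprintf("%.3f", var$r2), collapse = "/")))
  between <- lagged_block_r2(fs, var)
  within <- within_time_variance(cfa, divisor = within_divisor)
  scores <- tryCatch(factor_scores(within, between), error = identity)
  if (inherits(scores, "error")) return(fail("scores", conditionMessage(scores)))
  priorities <- tryCatch(symptom_scores(ts, cfa, scores), error = identity)
  if (inherits(priorities, "error"))
    return(fail("scores", conditionMessage(priorities)))
  gate("scores", TRUE, sprintf("factor scores: %s",
                               paste(sprintf("%.3f", scores$factor_score),
                                     collapse = ", ")))
  structure(
    list(status = "found", efa = sel, cfa = cfa, var = var,
         lag = as.integer(lag), scores = scores, priorities = priorities,
         cleaning = cleaning, config = config,
         diagnostics = do.call(rbind, diag_rows), options = opts),
    class = "planning_result")
}

#' @export
print.planning_result <- function(x, ...) {
  cat(sprintf("<planning_result> status: %s\n", x$status))
  print(x$diagnostics, row.names = FALSE)
  if (x$status == "found") print(x$priorities)
  invisible(x)
}

#' Render a planning report
#'
#' Produces a plain-text summary and a JSON document for a planning run.
#' The JSON round-trips losslessly (numbers at full precision) and names
#' the failed gate when no model was found.
#'
#' @param result a [run_planning()] result.
#' @param text_path,json_path optional output file paths.
#' @return Invisibly, a list with `text` (character vector of lines) and
#'   `json` (a single JSON string).
#' @export
render_report <- function(result, text_path = NULL, json_path = NULL) {
  stopifnot(inherits(result, "planning_result"))
  lines <- c(sprintf("Treatment planning report (status: %s)", result$status),
             "")
  payload <- list(status = result$status,
                  diagnostics = result$diagnostics,
                  options = result$options)
  if (!is.null(result$config))
    payload$patient_code <- result$config$patient_code
  if (!is.null(result$cleaning)) payload$cleaning <- unclass(result$cleaning)
  if (result$status == "found") {
    lines <- c(lines,
               sprintf("Factor model: %d factors (EFA TLI = %.3f, RMS = %.3f; CFA TLI = %.3f, SRMR = %.3f)",
                       result$efa$k, result$efa$model$fit$tli,
                       result$efa$model$fit$rms, result$cfa$fit$tli,
                       result$cfa$fit$srmr),
               pattern_terms(result$cfa$pattern),
               sprintf("VAR: %d lag(s), per-equation R^2 = %s", result$var$p,
                       paste(sprintf("%.3f", result$var$r2), collapse = ", ")),
               sprintf("Factor scores: %s",
                       paste(sprintf("%.3f", result$scores$factor_score),
                             collapse = ", ")),
               "", "Symptom priorities (descending):",
               sprintf("  %6.2f  %s", result$priorities$symptom_score,
                       result$priorities$item_text))
    excl <- attr(result$priorities, "excluded")
    if (length(excl) > 0L)
      lines <- c(lines, "", paste("Not modeled:", paste(excl, collapse = ", ")))
    payload$factor_model <- list(
      k = result$efa$k,
      efa_fit = unclass(result$efa$model$fit),
      cfa_fit = unclass(result$cfa$fit),
      pattern = result$cfa$pattern$included,
      excluded_items = result$cfa$pattern$excluded_items,
      cfa_loadings = result$cfa$loadings,
      factor_correlations = result$cfa$Phi)
    payload$var <- list(p = result$var$p, r2 = result$var$r2,
                        aic = result$var$aic,
                        coefficients = var_coef_table(result$var),
                        residual_correlations = result$var$residual_cor)
    payload$scores <- unclass(result$scores)
    payload$priorities <- as.data.frame(result$priorities)
  } else {
    failed <- result$diagnostics[!result$diagnostics$passed, , drop = FALSE]
    lines <- c(lines, "No satisfactory model was identified.",
               sprintf("Failed gate: %s (%s)", failed$stage[1], failed$detail[1]))
  }
  json <- jsonlite::toJSON(payload, dataframe = "columns", matrix = "rowmajor",
                           digits = NA, auto_unbox = TRUE, null = "null")
  if (!is.null(text_path)) writeLines(lines, text_path)
  if (!is.null(json_path)) writeLines(json, json_path)
  invisible(list(text = lines, json = as.character(json)))
}
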