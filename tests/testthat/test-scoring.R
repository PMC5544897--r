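test_that("within-time variance reproduces the worked example's shares", {
  shares <- within_time_variance(list(loadings = example_cfa_loadings()))
  expect_equal(unname(shares[1]) * 100, 34.27, tolerance = 0.1)
  expect_equal(unname(shares[2]) * 100, 47.27, tolerance = 0.1)

  # one factor with a single unit loading explains everything
  L1 <- matrix(c(1, 0, 0), 3, 1)
  expect_equal(unname(within_time_variance(list(loadings = L1))), 1)

  # literal divide-by-k reading stays available and differs by factor k
  lit <- within_time_variance(list(loadings = example_cfa_loadings()),
                              divisor = "k")
  expect_equal(unname(lit), unname(shares) * 2)
})

test_that("factor-score normalization reproduces the printed example", {
  sh <- example_variance_shares()
  ps <- factor_scores(sh$within, sh$between)
  expect_equal(unname(ps$factor_score[1]), 1)
  expect_equal(unname(ps$factor_score[2]), 0.367, tolerance = 0.005)

  expect_equal(unname(factor_scores(c(.3, .3), c(.2, .2))$factor_score),
               c(1, 1))
  expect_equal(unname(factor_scores(c(.4, .1), c(.5, 0))$factor_score),
               c(1, 0))
  expect_error(factor_scores(c(0, 0), c(0, .5)), "degenerate")
  expect_error(factor_scores(c(-.1, .2), c(.2, .2)), "non-negative")
})

test_that("symptom scores follow the Step-5 algebra by hand", {
  ts <- make_ts(cbind(item1 = c(4, 4, 4), item2 = c(2, 2, 2)))
  cfa <- list(items = c("item1", "item2"),
              loadings = matrix(c(0.8, 0.5), 2, 1,
                                dimnames = list(c("item1", "item2"), "F1")),
              pattern = list(excluded_items = character(0)))
  fs <- factor_scores(c(F1 = .4), c(F1 = .3))  # single factor, score 1
  tab <- symptom_scores(ts, cfa, fs)
  # normalized means (1, .5); q = (.8, .25); scores (100, 31.25)
  expect_equal(tab$symptom_score, c(100, 31.25))
  expect_equal(tab$item_id, c("item1", "item2"))
  expect_equal(tab$norm_mean, c(1, .5))

  # symmetric items all score 100
  ts2 <- make_ts(cbind(a = c(3, 5), b = c(3, 5)))
  cfa2 <- list(items = c("a", "b"),
               loadings = matrix(c(.6, .6), 2, 1,
                                 dimnames = list(c("a", "b"), "F1")),
               pattern = list(excluded_items = character(0)))
  expect_equal(symptom_scores(ts2, cfa2, fs)$symptom_score, c(100, 100))
})

test_that("multi-factor items sum their contributions across factors", {
  ts <- make_ts(cbind(i1 = rep(4, 3), i2 = rep(4, 3), i3 = rep(4, 3)))
  L <- rbind(i1 = c(.5, .4), i2 = c(.6, 0), i3 = c(0, .6))
  colnames(L) <- c("F1", "F2")
  cfa <- list(items = rownames(L), loadings = L,
              pattern = list(excluded_items = character(0)))
  fs <- factor_scores(c(.4, .2), c(.5, .4))  # scores (1, .4)
  tab <- symptom_scores(ts, cfa, fs)
  q <- c(.5 * 1 + .4 * .4, .6 * 1, .6 * .4)  # equal means cancel
  expect_equal(tab$symptom_score[match(rownames(L), tab$item_id)],
               100 * q / max(q))
})

test_that("priority scores are invariant to rescaling the response scale", {
  sim <- simulate_patient(patient_preset("two-factor-dominant"),
                          T_len = 120, seed = 82)
  r1 <- run_planning(sim$ts)
  expect_equal(r1$status, "found")
  scaled <- symptom_ts(sim$ts$values * 2.5, sim$ts$timestamps,
                       sim$ts$item_ids, sim$ts$item_texts,
                       sim$ts$scale_min * 2.5, sim$ts$scale_max * 2.5)
  r2 <- run_planning(scaled)
  expect_equal(r2$status, "found")
  expect_equal(r2$priorities$symptom_score, r1$priorities$symptom_score,
               tolerance = 1e-6)
  expect_equal(r2$priorities$item_id, r1$priorities$item_id)
})

test_that("normalization invariants hold on successful runs", {
  sim <- simulate_patient(patient_preset("two-factor-dominant"),
                          T_len = 120, seed = 82)
  r <- run_planning(sim$ts)
  expect_equal(r$status, "found")
  expect_equal(max(r$scores$factor_score), 1)
  expect_equal(max(r$priorities$symptom_score), 100)
  expect_false(is.unsorted(rev(r$priorities$symptom_score)))
  expect_true(all(r$diagnostics$passed))
})

test_that("too little data is an error, distinct from a failed model search", {
  sim <- simulate_patient(patient_preset("two-factor-dominant"),
                          T_len = 20, seed = 83)
  expect_error(run_planning(sim$ts, min_measurements = 40), "insufficient")
  # a failed search returns a result object instead
  noise <- simulate_patient(patient_preset("pure-noise"), T_len = 120, seed = 84)
  r <- run_planning(noise$ts)
  expect_s3_class(r, "planning_result")
  expect_equal(r$status, "no_model")
  expect_true(any(!r$diagnostics$passed))
})

test_that("reports round-trip through JSON and are bitwise deterministic", {
  sim <- simulate_patient(patient_preset("two-factor-dominant"),
                          T_len = 120, seed = 85)
  r <- run_planning(sim$ts)
  rep1 <- render_report(r)
  rep2 <- render_report(r)
  expect_identical(rep1$json, rep2$json)
  parsed <- jsonlite::fromJSON(rep1$json)
  expect_equal(parsed$status, "found")
  expect_equal(parsed$priorities$symptom_score, r$priorities$symptom_score)
  expect_equal(unname(unlist(parsed$scores$factor_score)),
               unname(r$scores$factor_score))
  expect_equal(parsed$var$p, r$var$p)

  # identical input and options give identical reports end to end
  r2 <- run_planning(sim$ts)
  expect_identical(render_report(r2)$json, rep1$json)

  # a failed run names the failed gate
  noise <- simulate_patient(patient_preset("pure-noise"), T_len = 120, seed = 86)
  repn <- render_report(run_planning(noise$ts))
  expect_true(any(grepl("Failed gate", repn$text)))
  expect_equal(jsonlite::fromJSON(repn$json)$status, "no_model")
})
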