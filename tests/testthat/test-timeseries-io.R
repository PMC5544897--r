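test_that("CSV parsing preserves values, masks empty cells, enforces bounds", {
  cfg <- two_item_config()
  lines <- csv_lines("timestamp,a,b",
                     "2026-01-05T08:00:00,2,3",
                     "2026-01-05T14:00:00,4,5",
                     "2026-01-05T20:00:00,6,7")
  ts <- read_timeseries(lines, cfg)
  expect_equal(dim(ts$values), c(3L, 2L))
  expect_equal(ts$values[, "a"], c(2, 4, 6))
  expect_false(any(missing_mask(ts)))

  with_gap <- csv_lines("timestamp,a,b",
                        "2026-01-05T08:00:00,2,3",
                        "2026-01-05T14:00:00,,5",
                        "2026-01-05T20:00:00,6,7")
  ts2 <- read_timeseries(with_gap, cfg)
  expect_true(missing_mask(ts2)[2, 1])
  expect_equal(sum(missing_mask(ts2)), 1L)
  expect_equal(unname(ts2$values[2, 2]), 5)

  out_of_range <- csv_lines("timestamp,a,b",
                            "2026-01-05T08:00:00,9,3",
                            "2026-01-05T14:00:00,4,5")
  expect_error(read_timeseries(out_of_range, cfg), "row 1.*'a'")
})

test_that("format errors name the offending column or timestamp", {
  cfg <- two_item_config()
  expect_error(read_timeseries(csv_lines("timestamp,a", "2026-01-05,1"), cfg),
               "missing item columns: b")
  expect_error(
    read_timeseries(csv_lines("timestamp,a,b,c", "2026-01-05,1,2,3"), cfg),
    "unknown columns: c")
  expect_error(
    read_timeseries(csv_lines("timestamp,a,b", "not-a-date,1,2"), cfg),
    "timestamp")
})

test_that("write/read round trip reproduces values, mask and timestamps", {
  cfg <- two_item_config()
  vals <- matrix(c(1, NA, 3, 8, 0, NA), ncol = 2,
                 dimnames = list(NULL, c("a", "b")))
  ts <- make_ts(vals)
  path <- tempfile(fileext = ".csv")
  write_timeseries(ts, path)
  ts2 <- read_timeseries(path, cfg)
  expect_identical(ts2$values, ts$values)
  expect_identical(missing_mask(ts2), missing_mask(ts))
  expect_equal(as.numeric(ts2$timestamps), as.numeric(ts$timestamps))
})

test_that("patient config YAML round trip preserves all fields", {
  cfg <- patient_config("PT42",
                        data.frame(id = c("x1", "x2"),
                                   text = c("first", "second")),
                        0, 4, schedule = c("09:00", "21:00"))
  path <- tempfile(fileext = ".yml")
  write_patient_config(cfg, path)
  cfg2 <- read_patient_config(path)
  expect_equal(cfg2$patient_code, "PT42")
  expect_equal(cfg2$items$id, c("x1", "x2"))
  expect_equal(cfg2$scale_max, 4)
  expect_equal(cfg2$schedule, c("09:00", "21:00"))
})

test_that("cleaning interpolates short internal gaps and drops the rest", {
  # midpoint interpolation of a single internal gap
  ts <- make_ts(cbind(a = c(2, NA, 4), b = c(1, 1, 1)))
  cl <- clean_timeseries(ts, max_gap = 1)
  expect_equal(cl$ts$values[, "a"], c(2, 3, 4))
  expect_equal(cl$report$interpolated_cells, 1L)
  expect_equal(cl$report$dropped_rows, 0L)

  # complete series is untouched
  ts2 <- make_ts(cbind(a = 1:5, b = 5:1))
  cl2 <- clean_timeseries(ts2)
  expect_identical(cl2$ts$values, ts2$values)
  expect_equal(cl2$report$missing_rate, 0)

  # runs longer than max_gap are dropped row-wise
  ts3 <- make_ts(cbind(a = c(1, 2, NA, NA, NA, 6, 7), b = rep(2, 7)))
  cl3 <- clean_timeseries(ts3, max_gap = 2)
  expect_equal(cl3$report$dropped_rows, 3L)
  expect_equal(nrow(cl3$ts$values), 4L)

  # leading/trailing gaps cannot be interpolated
  ts4 <- make_ts(cbind(a = c(NA, 2, 3, 4), b = c(1, 2, 3, NA)))
  cl4 <- clean_timeseries(ts4, max_gap = 3)
  expect_equal(nrow(cl4$ts$values), 2L)
  expect_false(anyNA(cl4$ts$values))

  expect_error(clean_timeseries(make_ts(cbind(a = c(1, NA, NA), b = 1:3))),
               "fewer than 2")
})

test_that("cleaned output never contains missing values and keeps observed rows", {
  set.seed(11)
  for (rep in 1:8) {
    vals <- matrix(sample(0:8, 60, replace = TRUE), ncol = 3)
    vals[sample(length(vals), 8)] <- NA
    colnames(vals) <- c("a", "b", "c")
    ts <- make_ts(vals)
    cl <- tryCatch(clean_timeseries(ts, max_gap = 1), error = identity)
    if (inherits(cl, "error")) next
    expect_false(anyNA(cl$ts$values))
    fully_observed <- sum(stats::complete.cases(vals))
    expect_gte(nrow(cl$ts$values), fully_observed)
  }
})

test_that("schedules split the waking window into equal parts", {
  expect_equal(make_schedule("08:00", "20:00", 3),
               c("08:00:00", "14:00:00", "20:00:00"))
  expect_equal(make_schedule("08:00", "20:00", 1), "14:00:00")
  expect_equal(make_schedule("08:00", "22:00", 2), c("08:00:00", "22:00:00"))
  expect_error(make_schedule("20:00", "08:00", 3), "later than wake")

  # equal spacing to within one second for arbitrary valid windows
  set.seed(3)
  for (rep in 1:20) {
    w <- sample(0:10, 1) * 3600 + sample(0:59, 1) * 60
    s <- w + sample(3600:50000, 1)
    n <- sample(2:8, 1)
    sch <- make_schedule(sprintf("%02d:%02d:%02d", w %/% 3600,
                                 (w %% 3600) %/% 60, w %% 60),
                         sprintf("%02d:%02d:%02d", s %/% 3600,
                                 (s %% 3600) %/% 60, s %% 60), n)
    secs <- vapply(strsplit(sch, ":"), function(p)
      sum(as.numeric(p) * c(3600, 60, 1)), numeric(1))
    expect_true(all(diff(secs) > 0))
    expect_lte(max(abs(diff(secs) - (s - w) / (n - 1))), 1)
  }
})

test_that("irregular timestamp gaps trigger the equal-spacing warning", {
  cfg <- two_item_config()
  lines <- csv_lines("timestamp,a,b",
                     "2026-01-05T08:00:00,1,1",
                     "2026-01-05T14:00:00,2,2",
                     "2026-01-05T20:00:00,3,3",
                     "2026-01-08T20:00:00,4,4")
  expect_warning(read_timeseries(lines, cfg), "modal gap")
})
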