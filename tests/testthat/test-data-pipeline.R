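test_that("min-max normalisation extrema, degenerate detection and unit mapping", {
  gs <- greenhouse_series(day = 0:2, yield = c(0, 1, 3), co2 = c(2, 4, 6),
                          temperature = c(17, 18, 16),
                          humidity_deficit = c(2, 3, 2.5),
                          relative_humidity = c(80, 82, 81),
                          radiation = c(40, 45, 42))
  np <- fit_normalization(gs)
  expect_equal(unname(np$co2), c(2, 6))
  expect_equal(normalize_value(2, np, "co2"), 0)
  expect_equal(normalize_value(6, np, "co2"), 1)

  gs$co2 <- c(5, 5, 5)
  expect_error(fit_normalization(gs), "degenerate factor 'co2'")

  # greenhouse-typical CO2 scaling: mean of a real one-year record maps
  # near 0.2276 under that record's extrema
  np2 <- structure(list(co2 = c(min = 535.97, max = 1634.10)),
                   class = "norm_params")
  expect_equal(normalize_value(785.95, np2, "co2"), 0.2276416,
               tolerance = 1e-6)
  # values outside the fitted range map outside [0, 1]: no clipping
  expect_true(normalize_value(1700, np2, "co2") > 1)
})

test_that("normalisation round-trips exactly and serialises to JSON", {
  gs <- make_fixture_series()
  np <- fit_normalization(gs)
  for (f in greenhouse_factors()) {
    x <- gs[[f]]
    expect_equal(denormalize_value(normalize_value(x, np, f), np, f), x,
                 tolerance = 1e-9)
  }
  path <- withr::local_tempfile(fileext = ".json")
  write_norm_params(np, path)
  np2 <- read_norm_params(path)
  expect_equal(unclass(np2), unclass(np), tolerance = 1e-12)
})

test_that("series validation rejects gaps, negatives and bad humidity", {
  base <- as.data.frame(make_fixture_series(n_days = 20))
  gap <- base; gap$day[10:20] <- gap$day[10:20] + 1L
  expect_error(do.call(greenhouse_series, gap), "increase by exactly 1")
  neg <- base; neg$yield[5] <- -1
  expect_error(do.call(greenhouse_series, neg), "non-negative")
  rh <- base; rh$relative_humidity[3] <- 104
  expect_error(do.call(greenhouse_series, rh), "relative humidity")
})

test_that("CSV round-trip preserves the series", {
  gs <- make_fixture_series(n_days = 40)
  path <- withr::local_tempfile(fileext = ".csv")
  write_greenhouse_csv(gs, path)
  gs2 <- read_greenhouse_csv(path)
  expect_equal(as.data.frame(gs2), as.data.frame(gs), tolerance = 1e-6)
})

test_that("window counts match brute-force anchor enumeration", {
  for (N in c(1L, 2L, 3L, 7L)) {
    for (H in c(1L, 3L, 7L)) {
      for (step in 1:3) {
        for (L in seq(N + H, 50L, by = 3L)) {
          gs <- make_fixture_series(n_days = L)
          np <- fit_normalization(gs)
          cfg <- window_config(N, H, step)
          ws <- make_windows(gs, cfg, np)
          expect_identical(length(ws$target), oracle_window_count(L, N, H, step))
        }
      }
    }
  }
  # one-year series, one-week window and horizon
  gs365 <- make_fixture_series(n_days = 365)
  ws <- make_windows(gs365, window_config(7, 7, 1), fit_normalization(gs365))
  expect_identical(length(ws$target), 352L)
  # exactly one window at the minimum length, error below it
  gs14 <- make_fixture_series(n_days = 14)
  expect_identical(
    length(make_windows(gs14, window_config(7, 7, 1),
                        fit_normalization(gs14))$target), 1L)
  gs13 <- make_fixture_series(n_days = 13)
  expect_error(make_windows(gs13, window_config(7, 7, 1),
                            fit_normalization(gs13)), "too short")
})

test_that("window contents reconstruct the normalised series rows without off-by-one", {
  gs <- make_fixture_series(n_days = 60)
  np <- fit_normalization(gs)
  cfg <- window_config(5, 3, 2)
  ws <- make_windows(gs, cfg, np)
  norm <- vapply(greenhouse_factors(), function(f)
    normalize_value(gs[[f]], np, f), numeric(nrow(gs)))
  for (k in seq_along(ws$target)) {
    anchor_row <- match(ws$anchor_day[k], gs$day)
    rows <- (anchor_row - cfg$window_length + 1L):anchor_row
    expect_equal(ws$inputs[k, , ], norm[rows, ], ignore_attr = TRUE)
    expect_equal(ws$target[k], unname(norm[anchor_row + cfg$horizon, "yield"]))
    expect_true(all(ws$inputs[k, , ] >= 0 & ws$inputs[k, , ] <= 1))
  }
})

test_that("splits respect the ratio, ordering and seeded reproducibility", {
  gs <- make_fixture_series(n_days = 40)
  ws <- make_windows(gs, window_config(7, 7, 1), fit_normalization(gs))
  n <- length(ws$target)

  sp <- split_samples(ws, ratio = 0.7)
  expect_identical(length(sp$train$target), as.integer(round(0.7 * n)))
  expect_identical(length(sp$train$target) + length(sp$test$target), n)
  expect_lt(max(sp$train$anchor_day), min(sp$test$anchor_day))

  # 100 samples at 70/30
  gs2 <- make_fixture_series(n_days = 113)
  ws2 <- make_windows(gs2, window_config(7, 7, 1), fit_normalization(gs2))
  expect_identical(length(ws2$target), 100L)
  sp2 <- split_samples(ws2, 0.7)
  expect_identical(length(sp2$train$target), 70L)
  expect_identical(length(sp2$test$target), 30L)

  r1 <- split_samples(ws, 0.7, mode = "random", seed = 42)
  r2 <- split_samples(ws, 0.7, mode = "random", seed = 42)
  expect_identical(r1$train$inputs, r2$train$inputs)
  expect_identical(r1$test$anchor_day, r2$test$anchor_day)
  r3 <- split_samples(ws, 0.7, mode = "random", seed = 43)
  expect_false(identical(r1$train$anchor_day, r3$train$anchor_day))
  # disjoint and exhaustive in both modes
  expect_length(intersect(r1$train$anchor_day, r1$test$anchor_day), 0)

  expect_error(split_samples(ws, 1.2), "ratio")
})

test_that("leakage-aware preparation fits scaling on the training period only", {
  gs <- make_fixture_series(n_days = 120)
  sp <- prepare_split(gs, window_config(7, 7, 1), normalize_on = "train")
  n_train <- length(sp$train$target)
  last_train_row <- (n_train - 1L) + 7L + 7L  # target row of the last train window
  train_days <- gs$day[seq_len(last_train_row)]
  np_train <- fit_normalization(gs, days = train_days)
  expect_equal(unclass(sp$params), unclass(np_train))
  # yield grows past the training period, so late test targets exceed 1
  expect_gt(max(sp$test$target), 1)
  sp_all <- prepare_split(gs, window_config(7, 7, 1), normalize_on = "all")
  expect_lte(max(sp_all$test$target), 1)
})
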