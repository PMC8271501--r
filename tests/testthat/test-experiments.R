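# Experiment harness tests run at deliberately tiny scale (120-day
# series, 4-unit networks, a few epochs): they check protocol logic, not
# forecasting quality.

exp_series <- function() list(simA = make_fixture_series(seed = 301),
                              simB = make_fixture_series(seed = 302))

test_that("a degenerate 1x1 grid reproduces a single repeated evaluation", {
  sets <- exp_series()[1]
  tc <- tiny_train_cfg(epochs = 3, seed = 9)
  gr <- grid_search(sets, grid_spec(4L, 4L), model_cfg = tiny_model_cfg(),
                    train_cfg = tc, n_runs = 2)
  expect_identical(nrow(gr$table), 2L)  # one cell + its average row
  cell_seed <- yieldnet:::seed_for(9, "grid_LN4_FN4_simA")
  tc2 <- tc; tc2$seed <- cell_seed
  direct <- evaluate_repeated(sets[[1]], tiny_model_cfg(), tc2, n_runs = 2)
  expect_equal(gr$table$mean[1], direct$mean, tolerance = 1e-12)
  expect_equal(gr$table$sd[1], direct$sd, tolerance = 1e-12)
})

test_that("grid search flags the exhaustive argmin of the average mean RMSE", {
  sets <- exp_series()
  gr <- grid_search(sets, grid_spec(c(2L, 4L), c(2L, 4L)),
                    model_cfg = tiny_model_cfg(),
                    train_cfg = tiny_train_cfg(epochs = 2, seed = 21),
                    n_runs = 1)
  avg <- gr$table[gr$table$dataset == "average", ]
  expect_identical(nrow(avg), 4L)                       # 2 x 2 grid
  expect_identical(nrow(gr$table), 12L)                 # 2 datasets + average
  winner <- avg[which.min(avg$mean), ]
  expect_identical(gr$best$lstm_units, winner$lstm_units)
  expect_identical(gr$best$filters, winner$filters)
  # the average row is the mean over datasets of the per-dataset cells
  for (i in seq_len(nrow(avg))) {
    cells <- gr$table[gr$table$dataset != "average" &
                      gr$table$lstm_units == avg$lstm_units[i] &
                      gr$table$filters == avg$filters[i], ]
    expect_equal(avg$mean[i], mean(cells$mean))
    expect_equal(avg$sd[i], mean(cells$sd))
  }
})

test_that("experiment tables are bit-identical under the master seed and cacheable", {
  sets <- exp_series()[1]
  tc <- tiny_train_cfg(epochs = 2, seed = 13)
  g1 <- grid_search(sets, grid_spec(4L, c(2L, 4L)), model_cfg = tiny_model_cfg(),
                    train_cfg = tc, n_runs = 2)
  g2 <- grid_search(sets, grid_spec(4L, c(2L, 4L)), model_cfg = tiny_model_cfg(),
                    train_cfg = tc, n_runs = 2)
  expect_identical(g1$table, g2$table)

  cache <- withr::local_tempdir()
  g3 <- grid_search(sets, grid_spec(4L, c(2L, 4L)), model_cfg = tiny_model_cfg(),
                    train_cfg = tc, n_runs = 2, cache_dir = cache)
  expect_length(list.files(cache, pattern = "^grid_.*json$"), 2L)
  # cached cells are reloaded, not recomputed: corrupt one and rerun
  files <- list.files(cache, full.names = TRUE)
  marker <- jsonlite::read_json(files[1], simplifyVector = TRUE)
  marker$rmse <- c(123, 123)
  jsonlite::write_json(marker, files[1], auto_unbox = TRUE, digits = NA)
  g4 <- grid_search(sets, grid_spec(4L, c(2L, 4L)), model_cfg = tiny_model_cfg(),
                    train_cfg = tc, n_runs = 2, cache_dir = cache)
  expect_true(any(abs(g4$table$mean - 123) < 1e-9))
})

test_that("depth study covers the candidate lattice and matches direct reruns", {
  sets <- exp_series()[1]
  tc <- tiny_train_cfg(epochs = 2, seed = 31)
  dp <- depth_study(sets, layer_candidates = c(1L, 2L),
                    block_candidates = c(1L, 2L),
                    model_cfg = tiny_model_cfg(), train_cfg = tc, n_runs = 1)
  expect_identical(nrow(dp$table), 4L)
  cell <- dp$table[dp$table$lstm_layers == 2 & dp$table$tcn_blocks == 1, ]
  cfg2 <- tiny_model_cfg(); cfg2$lstm_layers <- 2L
  tc2 <- tc; tc2$seed <- yieldnet:::seed_for(31, "depth_L2_B1_simA")
  direct <- evaluate_repeated(sets[[1]], cfg2, tc2, n_runs = 1)
  expect_equal(cell$mean, direct$mean, tolerance = 1e-12)
})

test_that("ablation drops exactly one of the six channels per run", {
  sets <- exp_series()[1]
  ab <- ablation_study(sets, model_cfg = tiny_model_cfg(),
                       train_cfg = tiny_train_cfg(epochs = 2, seed = 41),
                       n_runs = 1)
  expect_identical(ab$table$excluded, greenhouse_factors())
  expect_identical(ab$table$label[ab$table$excluded == "yield"],
                   "historical yield information")
  expect_true(all(is.finite(ab$table$mean)))
  # the ablated windows really have five channels
  ws <- make_windows(sets[[1]], window_config(),
                     fit_normalization(sets[[1]]))
  ws5 <- yieldnet:::drop_factor(ws, "co2")
  expect_identical(dim(ws5$inputs)[3], 5L)
  expect_error(yieldnet:::drop_factor(ws, "sunspots"), "unknown factor")
})

test_that("method comparison shares byte-identical splits and LR has zero spread", {
  skip_if_not_installed("ranger")
  skip_if_not_installed("e1071")
  skip_if_not_installed("rpart")
  skip_if_not_installed("nnet")
  sets <- exp_series()[1]
  methods <- c("lr", "svr", "dt", "mlann", "lstm", "tcn", "hybrid")
  cp <- suppressWarnings(
    compare_methods(sets, methods = methods, model_cfg = tiny_model_cfg(),
                    train_cfg = tiny_train_cfg(epochs = 2, seed = 51),
                    n_runs = 2, mlann_hidden = 4L))
  expect_identical(sort(unique(cp$table$method)), sort(methods))
  expect_identical(length(unique(cp$table$split_checksum)), 1L)
  expect_identical(cp$table$sd[cp$table$method == "lr"], 0)
  expect_true(all(is.finite(cp$table$mean)))
  expect_error(compare_methods(sets, methods = "kriging"), "unknown method")
})
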