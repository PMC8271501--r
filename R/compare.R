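# Classical-vs-deep comparison. Classical regressors consume each window
# flattened to a feature vector (N days x channels, normalised); deep
# models consume the sequence. Every method sees byte-identical splits,
# guarded by a checksum of the windowed samples.
#
# The classical baselines are comparison plumbing, so they use the
# established R implementations: lm, ranger, e1071::svm, rpart, xgboost
# and nnet. The deep baselines (LSTM-only, TCN-only) are variants of the
# package's own network.

#' Methods available to [compare_methods()]
#'
#' `lr` linear regression, `rf` random forest, `svr` support vector
#' regression (RBF), `dt` decision tree, `gbr` gradient boosting,
#' `mlann` feed-forward neural network, `lstm`/`lstm_multi` LSTM-only
#' (1 / 2 layers), `tcn`/`tcn_multi` TCN-only (1 / 2 blocks), `hybrid`
#' the full model.
#'
#' @return Character vector of method names.
#' @export
method_registry <- function() {
  c("lr", "rf", "svr", "dt", "gbr", "mlann",
    "lstm", "lstm_multi", "tcn", "tcn_multi", "hybrid")
}

need_pkg <- function(pkg, method) {
  if (!requireNamespace(pkg, quietly = TRUE))
    stop("method '", method, "' needs package '", pkg, "'", call. = FALSE)
}

flatten_features <- function(ws) {
  d <- dim(ws$inputs)
  X <- matrix(ws$inputs, d[1], d[2] * d[3])
  colnames(X) <- paste0("f", sprintf("%03d", seq_len(ncol(X))))
  X
}

# Fit one classical regressor on (X, y); returns a prediction closure.
# `hidden` sizes the mlann hidden layer.
classical_fit <- function(method, X, y, seed, hidden = 16L) {
  df <- data.frame(y = y, X)
  switch(method,
    lr = {
      fit <- stats::lm(y ~ ., data = df)
      function(Xn) {
        unname(stats::predict(fit, data.frame(Xn)))
      }
    },
    rf = {
      need_pkg("ranger", "rf")
      fit <- ranger::ranger(y ~ ., data = df, num.trees = 300L,
                            seed = seed, num.threads = 1L)
      function(Xn) stats::predict(fit, data.frame(Xn),
                                  num.threads = 1L)$predictions
    },
    svr = {
      need_pkg("e1071", "svr")
      fit <- e1071::svm(x = X, y = y, type = "eps-regression")
      function(Xn) unname(stats::predict(fit, Xn))
    },
    dt = {
      need_pkg("rpart", "dt")
      fit <- with_seed(seed, rpart::rpart(y ~ ., data = df, method = "anova"))
      function(Xn) unname(stats::predict(fit, data.frame(Xn)))
    },
    gbr = {
      need_pkg("xgboost", "gbr")
      fit <- with_seed(seed, xgboost::xgboost(
        data = X, label = y, nrounds = 100L, verbose = 0,
        params = list(objective = "reg:squarederror", max_depth = 3L,
                      eta = 0.1, nthread = 1L, seed = seed)))
      function(Xn) stats::predict(fit, Xn)
    },
    mlann = {
      need_pkg("nnet", "mlann")
      fit <- with_seed(seed, nnet::nnet(x = X, y = y, size = hidden,
                                        linout = TRUE, maxit = 500L,
                                        trace = FALSE, MaxNWts = 100000L))
      function(Xn) as.numeric(stats::predict(fit, Xn))
    },
    stop("unknown classical method '", method, "'", call. = FALSE))
}

deep_config <- function(method, base_cfg) {
  cfg <- base_cfg
  switch(method,
    hybrid = cfg$variant <- "hybrid",
    lstm = { cfg$variant <- "lstm"; cfg$lstm_layers <- 1L },
    lstm_multi = { cfg$variant <- "lstm"; cfg$lstm_layers <- 2L },
    tcn = { cfg$variant <- "tcn"; cfg$tcn_blocks <- 1L },
    tcn_multi = { cfg$variant <- "tcn"; cfg$tcn_blocks <- 2L },
    stop("unknown deep method '", method, "'", call. = FALSE))
  cfg
}

classical_eval <- function(split, method, n_runs, master_seed, hidden = 16L) {
  Xtr <- flatten_features(split$train); ytr <- split$train$target
  Xte <- flatten_features(split$test); yte <- split$test$target
  yr <- norm_factor(split$params, "yield")
  span <- yr[["max"]] - yr[["min"]]
  seeds <- derive_seeds(master_seed, n_runs)
  vals <- vapply(seq_len(n_runs), function(r) {
    predict_fun <- classical_fit(method, Xtr, ytr, seed = seeds[r],
                                 hidden = hidden)
    rmse(predict_fun(Xte), yte) * span
  }, numeric(1))
  eval_report(vals, mode = split$mode,
              split_checksum = split_checksum(split))
}

#' Compare forecasting methods on identical splits
#'
#' Runs every requested method on every series. All methods (classical
#' and deep) share the same normalisation, windows and 70/30 split per
#' dataset; the report carries a checksum of the split each method saw
#' so identity is verifiable. If the hybrid does not achieve the
#' smallest mean RMSE among the deep variants a warning (not an error)
#' is raised: relative rankings on synthetic data need not match
#' restricted real data.
#'
#' @inheritParams grid_search
#' @param methods subset of [method_registry()].
#' @param mlann_hidden hidden-layer size of the `mlann` baseline.
#' @return A `comparison_report` with `table` (dataset x method rows) and
#'   `reports`.
#' @export
compare_methods <- function(series_set, methods = method_registry(),
                            window = window_config(),
                            model_cfg = model_config(),
                            train_cfg = training_config(), n_runs = 5L,
                            mode = "chronological", mlann_hidden = 16L,
                            cache_dir = NULL) {
  series_set <- as_series_set(series_set)
  unknown <- setdiff(methods, method_registry())
  if (length(unknown))
    stop("unknown method(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  classical <- c("lr", "rf", "svr", "dt", "gbr", "mlann")
  rows <- list(); reports <- list()
  for (ds in names(series_set)) {
    split <- prepare_split(series_set[[ds]], window, mode = mode,
                           seed = train_cfg$seed)
    for (m in methods) {
      tag <- sprintf("compare_%s_%s", m, ds)
      rep <- cell_eval(tag, cache_dir, function() {
        if (m %in% classical) {
          classical_eval(split, m, n_runs, seed_for(train_cfg$seed, tag),
                         hidden = mlann_hidden)
        } else {
          tc <- train_cfg; tc$seed <- seed_for(train_cfg$seed, tag)
          evaluate_repeated(series_set[[ds]], deep_config(m, model_cfg), tc,
                            n_runs = n_runs, window = window, mode = mode,
                            split_seed = train_cfg$seed)
        }
      })
      reports[[tag]] <- rep
      rows[[tag]] <- data.frame(dataset = ds, method = m, mean = rep$mean,
                                sd = rep$sd,
                                split_checksum = rep$split_checksum)
    }
  }
  tab <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  # split identity guard: within a dataset every deep/classical method
  # must have seen the same windowed samples
  for (ds in unique(tab$dataset)) {
    cks <- unique(tab$split_checksum[tab$dataset == ds])
    if (length(cks) != 1L)
      stop("methods saw different splits for ", ds, call. = FALSE)
  }
  deep <- intersect(methods, c("lstm", "lstm_multi", "tcn", "tcn_multi"))
  if ("hybrid" %in% methods && length(deep)) {
    hm <- mean(tab$mean[tab$method == "hybrid"])
    dm <- vapply(deep, function(m) mean(tab$mean[tab$method == m]), numeric(1))
    if (any(dm < hm))
      warning("hybrid mean RMSE (", sprintf("%.2f", hm),
              ") is not the best among deep variants on this data; ",
              "rankings on synthetic data need not match real records",
              call. = FALSE)
  }
  structure(list(table = tab, reports = reports,
                 master_seed = train_cfg$seed),
            class = "comparison_report")
}

#' @export
print.comparison_report <- function(x, ...) {
  cat("<comparison_report> RMSE (g/m2) by method and dataset\n")
  print(x$table[c("dataset", "method", "mean", "sd")], row.names = FALSE)
  invisible(x)
}
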