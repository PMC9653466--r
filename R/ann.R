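#' Configuration for the breeding-value network
#'
#' Hyperparameters of the small feed-forward predictor: four hidden layers
#' of ten tanh units feeding a linear output, trained by mini-batch Adam
#' (learning rate 0.001, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) for 500
#' epochs with batches of 10 and a 20% validation split.
#'
#' @param hidden_layers,units_per_layer network shape.
#' @param learning_rate,beta1,beta2,eps Adam settings.
#' @param epochs,batch_size,validation_split training schedule.
#' @param restore_best keep the weights of the epoch with the lowest
#'   validation MSE rather than the final-epoch weights (the validation
#'   split's purpose; guards against late-stage overfitting).
#' @param seed integer seed governing weight initialization, shuffling and
#'   the validation split.
#' @return List of class `mlp_config`.
#' @export
mlp_config <- function(hidden_layers = 4L, units_per_layer = 10L,
                       learning_rate = 0.001, beta1 = 0.9, beta2 = 0.999,
                       eps = 1e-8, epochs = 500L, batch_size = 10L,
                       validation_split = 0.2, restore_best = TRUE,
                       seed = 1L) {
  stopifnot(hidden_layers >= 1, units_per_layer >= 1, learning_rate > 0,
            epochs >= 1, batch_size >= 1,
            validation_split > 0, validation_split < 1)
  structure(as.list(environment()), class = "mlp_config")
}

#' Prepare features and labels for network training
#'
#' Cleaning and split protocol: rows with any missing field are dropped;
#' constant feature columns are dropped with a warning; rows with any
#' feature or label beyond 3 standard deviations of its column are removed
#' as outliers; the survivors are shuffled with the seed and split into
#' train and held-out test sets; z-score scalers for features and label are
#' fit on the training portion only and applied to both.
#'
#' @param data data frame holding feature columns and the label column.
#' @param label_col name of the label (EBV) column.
#' @param feature_cols feature column names (default: all others).
#' @param test_split held-out fraction (default 0.2).
#' @param seed integer seed for the shuffle.
#' @return List of class `mlp_data` with `train` and `test` (each `X`
#'   scaled matrix, `y` scaled vector, `y_raw`), `scaler`, `feature_names`,
#'   `n_dropped` (missing + outlier rows removed).
#' @export
prepare_dataset <- function(data, label_col,
                            feature_cols = setdiff(names(data), label_col),
                            test_split = 0.2, seed = 1L) {
  stopifnot(is.data.frame(data), label_col %in% names(data),
            all(feature_cols %in% names(data)))
  if (nrow(data) < 50) stop("need at least 50 rows", call. = FALSE)
  df <- data[c(feature_cols, label_col)]
  n0 <- nrow(df)
  df <- df[stats::complete.cases(df), , drop = FALSE]

  sds <- vapply(df[feature_cols], sd, numeric(1))
  if (any(sds == 0)) {
    warning("dropping constant feature column(s): ",
            paste(feature_cols[sds == 0], collapse = ", "), call. = FALSE)
    feature_cols <- feature_cols[sds > 0]
    df <- df[c(feature_cols, label_col)]
  }
  z <- scale(as.matrix(df))
  keep <- apply(abs(z) <= 3, 1, all)
  df <- df[keep, , drop = FALSE]
  if (nrow(df) < 20) stop("fewer than 20 rows survive cleaning", call. = FALSE)

  set.seed(seed)
  ord <- sample.int(nrow(df))
  n_test <- floor(nrow(df) * test_split)
  test_idx <- ord[seq_len(n_test)]
  train_idx <- ord[-seq_len(n_test)]

  Xtr <- as.matrix(df[train_idx, feature_cols, drop = FALSE])
  Xte <- as.matrix(df[test_idx, feature_cols, drop = FALSE])
  ytr <- df[[label_col]][train_idx]
  yte <- df[[label_col]][test_idx]
  scaler <- list(x_mean = colMeans(Xtr), x_sd = apply(Xtr, 2, sd),
                 y_mean = mean(ytr), y_sd = sd(ytr))
  if (any(scaler$x_sd == 0) || scaler$y_sd == 0) {
    stop("zero variance in the training portion", call. = FALSE)
  }
  sc <- function(X) sweep(sweep(X, 2, scaler$x_mean), 2, scaler$x_sd, "/")
  structure(list(
    train = list(X = sc(Xtr), y = (ytr - scaler$y_mean) / scaler$y_sd,
                 y_raw = ytr),
    test = list(X = sc(Xte), y = (yte - scaler$y_mean) / scaler$y_sd,
                y_raw = yte),
    scaler = scaler, feature_names = feature_cols,
    n_dropped = n0 - nrow(df)), class = "mlp_data")
}

glorot_init <- function(fan_in, fan_out) {
  r <- sqrt(6 / (fan_in + fan_out))
  matrix(runif(fan_in * fan_out, -r, r), fan_in, fan_out)
}

#' Train the breeding-value network
#'
#' Trains the feed-forward network on a prepared (scaled) training set by
#' mini-batch Adam. Weights are initialized by a seeded small-uniform
#' scheme; the internal validation split, the initialization and every
#' epoch's shuffle are all driven by `cfg$seed`, so training is
#' bit-reproducible.
#'
#' @param train the `train` element of a [prepare_dataset()] result (or any
#'   list with scaled `X` and `y`), or the `mlp_data` object itself.
#' @param cfg an [mlp_config()].
#' @param scaler optional scaler to embed in the model (taken from the
#'   `mlp_data` object automatically).
#' @return Object of class `mlp_model`: weight matrices `W`, biases `b`,
#'   `scaler`, `config`, `history` (per-epoch training and validation MSE
#'   on the scaled response), `fitted_train` (scaled fitted values at the
#'   final epoch).
#' @export
train_mlp <- function(train, cfg = mlp_config(), scaler = NULL) {
  stopifnot(inherits(cfg, "mlp_config"))
  if (inherits(train, "mlp_data")) {
    scaler <- train$scaler
    feature_names <- train$feature_names
    train <- train$train
  } else {
    feature_names <- colnames(train$X)
  }
  X <- as.matrix(train$X)
  y <- as.numeric(train$y)
  n <- nrow(X)
  p <- ncol(X)

  set.seed(cfg$seed)
  n_val <- floor(n * cfg$validation_split)
  ord <- sample.int(n)
  val_idx <- ord[seq_len(n_val)]
  tr_idx <- if (n_val > 0) ord[-seq_len(n_val)] else ord
  Xtr <- X[tr_idx, , drop = FALSE]; ytr <- y[tr_idx]
  Xval <- X[val_idx, , drop = FALSE]; yval <- y[val_idx]

  sizes <- c(p, rep(cfg$units_per_layer, cfg$hidden_layers), 1L)
  W <- lapply(seq_len(length(sizes) - 1),
              function(l) glorot_init(sizes[l], sizes[l + 1]))
  b <- lapply(seq_len(length(sizes) - 1), function(l) numeric(sizes[l + 1]))
  perms <- t(vapply(seq_len(cfg$epochs), function(e) sample.int(length(tr_idx)),
                    integer(length(tr_idx))))

  res <- .mlp_train_cpp(Xtr, ytr, Xval, yval, W, b, perms,
                        cfg$learning_rate, cfg$beta1, cfg$beta2, cfg$eps,
                        as.integer(cfg$batch_size))
  use_best <- isTRUE(cfg$restore_best)
  Wm <- if (use_best) res$W_best else res$W
  bm <- if (use_best) res$b_best else res$b
  structure(list(W = Wm, b = bm, scaler = scaler, config = cfg,
                 feature_names = feature_names,
                 history = data.frame(epoch = seq_len(cfg$epochs),
                                      train_mse = as.numeric(res$train_mse),
                                      val_mse = as.numeric(res$val_mse)),
                 best_epoch = as.integer(res$best_epoch),
                 fitted_train = as.numeric(.mlp_forward_cpp(Xtr, Wm, bm)),
                 train_index = tr_idx),
            class = "mlp_model")
}

#' @export
print.mlp_model <- function(x, ...) {
  cat(sprintf("mlp_model: %d features -> %s -> 1 (tanh hidden, linear out)\n",
              length(x$feature_names),
              paste(vapply(x$W[-length(x$W)], ncol, integer(1)),
                    collapse = "-")))
  cat(sprintf("final training MSE %.5g, validation MSE %.5g (scaled)\n",
              x$history$train_mse[nrow(x$history)],
              x$history$val_mse[nrow(x$history)]))
  invisible(x)
}

#' Predict breeding values with a trained network
#'
#' Deterministic forward pass. When the model carries a scaler (the normal
#' case), `newdata` is taken on the raw feature scale and predictions are
#' returned in label units; otherwise both are on the training scale.
#'
#' @param object an `mlp_model`.
#' @param newdata matrix or data frame of features (columns matching the
#'   training features).
#' @param scaled set `TRUE` if `newdata` is already scaled (returns scaled
#'   predictions).
#' @param ... unused.
#' @return Numeric vector of predictions.
#' @export
predict.mlp_model <- function(object, newdata, scaled = FALSE, ...) {
  X <- as.matrix(if (is.data.frame(newdata)) newdata[object$feature_names]
                 else newdata)
  if (ncol(X) != length(object$feature_names)) {
    stop("expected ", length(object$feature_names), " feature column(s), got ",
         ncol(X), call. = FALSE)
  }
  if (!scaled && !is.null(object$scaler)) {
    X <- sweep(sweep(X, 2, object$scaler$x_mean), 2, object$scaler$x_sd, "/")
  }
  pred <- as.numeric(.mlp_forward_cpp(X, object$W, object$b))
  if (!scaled && !is.null(object$scaler)) {
    pred <- pred * object$scaler$y_sd + object$scaler$y_mean
  }
  pred
}

#' Prediction accuracy metrics
#'
#' Pearson correlation (also rendered x100, the convention of reporting
#' "testing correlation" as a percentage-like score), mean absolute error,
#' mean squared error and its square root.
#'
#' @param predictions,labels equal-length numeric vectors (>= 2 values);
#'   labels must not be constant.
#' @return List of class `eval_metrics`: `pearson_r`, `r_x100`, `mae`,
#'   `mse`, `rmse`.
#' @export
evaluate_predictions <- function(predictions, labels) {
  stopifnot(length(predictions) == length(labels), length(labels) >= 2)
  if (sd(labels) == 0) {
    stop("correlation undefined: labels are constant", call. = FALSE)
  }
  err <- predictions - labels
  m <- list(pearson_r = cor(predictions, labels),
            mae = mean(abs(err)), mse = mean(err^2),
            rmse = sqrt(mean(err^2)))
  m$r_x100 <- 100 * m$pearson_r
  structure(m, class = "eval_metrics")
}

#' @export
print.eval_metrics <- function(x, ...) {
  cat(sprintf("r = %.4f (x100: %.2f), MAE = %.4g, MSE = %.4g, RMSE = %.4g\n",
              x$pearson_r, x$r_x100, x$mae, x$mse, x$rmse))
  invisible(x)
}

#' Serialize a trained network to JSON
#'
#' Stores the architecture, scaler and weights as plain JSON so models can
#' be moved between machines without binary formats.
#'
#' @param model an `mlp_model`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_mlp_model <- function(model, path) {
  obj <- list(feature_names = model$feature_names,
              W = lapply(model$W, unclass), b = model$b,
              scaler = model$scaler,
              config = unclass(model$config))
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Load a network serialized by [write_mlp_model()]
#'
#' @param path JSON file.
#' @return An `mlp_model` (without training history).
#' @export
read_mlp_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  W <- lapply(obj$W, as.matrix)
  scaler <- obj$scaler
  scaler$x_mean <- unlist(scaler$x_mean)
  scaler$x_sd <- unlist(scaler$x_sd)
  structure(list(W = W, b = lapply(obj$b, as.numeric), scaler = scaler,
                 config = do.call(mlp_config, obj$config[names(obj$config) %in%
                   names(formals(mlp_config))]),
                 feature_names = obj$feature_names),
            class = "mlp_model")
}

#' Synthetic phenotype-to-EBV training table
#'
#' Builds a feature/label table of the shape used for the breeding-value
#' network: five phenotypic features in which the yearling-weight and
#' dam-weight analogues carry most of the signal, and a label that is a
#' linear combination of the features plus noise calibrated to a chosen
#' signal fraction (R-squared).
#'
#' @param n rows (default 2500).
#' @param r2 fraction of label variance explained by the features.
#' @param seed integer seed.
#' @return Data frame with columns `w12m`, `dam_weight`, `wwt`, `gfy`,
#'   `fd`, and label `ebv`.
#' @export
simulate_ann_table <- function(n = 2500L, r2 = 0.7, seed = 1L) {
  stopifnot(n >= 50, r2 > 0, r2 < 1)
  set.seed(seed)
  X <- cbind(w12m = rnorm(n, 30, 5), dam_weight = rnorm(n, 35, 4),
             wwt = rnorm(n, 15, 2.5), gfy = rnorm(n, 2.5, 0.5),
             fd = rnorm(n, 24, 3))
  beta <- c(w12m = 0.15, dam_weight = 0.08, wwt = 0.03, gfy = 0.2, fd = -0.02)
  signal <- as.numeric(X %*% beta)
  noise_sd <- sd(signal) * sqrt((1 - r2) / r2)
  ebv <- signal - mean(signal) + rnorm(n, 0, noise_sd)
  data.frame(X, ebv = ebv)
}
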