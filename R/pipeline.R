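#' Leave-one-subject-out folds
#'
#' One fold per subject: fold i tests on subject i and trains on all others.
#'
#' @param cohort list of `epoched_trials`, each with a distinct `subject_id`.
#' @return list of folds, each a list with `train` (indices into `cohort`),
#'   `test` (one index) and `subject` (the test subject id).
#' @export
make_loso_folds <- function(cohort) {
  if (length(cohort) < 2L) stop_invalid("need at least 2 subjects")
  ids <- vapply(cohort,
                function(tr) as.integer(tr$subject_id %||% NA_integer_), 0L)
  if (anyNA(ids)) stop_invalid("every cohort entry needs a subject_id")
  if (anyDuplicated(ids)) stop_invalid("duplicate subject ids: ",
                                       paste(ids[duplicated(ids)],
                                             collapse = ", "))
  lapply(seq_along(cohort), function(i) {
    list(train = setdiff(seq_along(cohort), i), test = i, subject = ids[i])
  })
}

#' Stratified validation split
#'
#' Holds out `fraction` of the pooled training trials, stratified by class,
#' deterministically under `seed`.
#'
#' @param trials pooled `epoched_trials`.
#' @param fraction held-out fraction in `(0, 1)`.
#' @param seed integer seed.
#' @return list with `fit` and `val`, both `epoched_trials`.
#' @export
split_validation <- function(trials, fraction, seed) {
  validate_trials(trials, require_two_classes = TRUE)
  if (!is_number(fraction) || fraction <= 0 || fraction >= 1) {
    stop_invalid("fraction must be in (0, 1)")
  }
  classes <- sort(unique(trials$y))
  counts <- table(trials$y)
  if (any(counts < 2L)) {
    stop_invalid("every class needs at least 2 trials to split")
  }
  set.seed(seed)
  val_idx <- integer(0)
  for (cl in classes) {
    idx <- which(trials$y == cl)
    n_val <- max(1L, round(fraction * length(idx)))
    val_idx <- c(val_idx, sample(idx, n_val))
  }
  val_idx <- sort(val_idx)
  fit_idx <- setdiff(seq_len(n_trials(trials)), val_idx)
  fit <- subset_trials(trials, fit_idx)
  val <- subset_trials(trials, val_idx)
  attr(fit, "pool_idx") <- fit_idx
  attr(val, "pool_idx") <- val_idx
  list(fit = fit, val = val)
}

#' Accuracy and macro F1 of predictions
#'
#' Accuracy is `100 * correct / N`. F1 is the macro average over classes of
#' `2 * precision * recall / (precision + recall)`, with a class's F1 defined
#' as 0 when `precision + recall = 0`.
#'
#' @param truth,pred integer label vectors (0-based).
#' @param n_classes number of classes (defaults to the labels observed).
#' @return list with `acc` and `f1`, both in percent.
#' @export
evaluate_predictions <- function(truth, pred, n_classes = NULL) {
  if (length(truth) == 0L) stop_invalid("empty test set")
  if (length(truth) != length(pred)) stop_invalid("length mismatch")
  M <- n_classes %||% (max(c(truth, pred)) + 1L)
  acc <- 100 * mean(truth == pred)
  f1s <- vapply(0:(M - 1L), function(cl) {
    tp <- sum(pred == cl & truth == cl)
    fp <- sum(pred == cl & truth != cl)
    fn <- sum(pred != cl & truth == cl)
    prec <- if (tp + fp == 0L) 0 else tp / (tp + fp)
    rec <- if (tp + fn == 0L) 0 else tp / (tp + fn)
    if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
  }, 0)
  list(acc = acc, f1 = 100 * mean(f1s))
}

#' Fit the feature pipeline on a training fold and transform both folds
#'
#' Everything fitted here (band-pass is parameter-free; the CSP bank and the
#' min/max scaler are estimated) depends on the training fold only; the test
#' fold is transformed with the fitted objects. For the `rawdata` variant the
#' CSP/filtering stage is bypassed and the raw epochs are min/max scaled to
#' `[0, 1]` as single-channel `C x T` images.
#'
#' @param train_trials,test_trials `epoched_trials`.
#' @param band [bandpass_spec()].
#' @param target_size feature-image side (`>= U`; ignored for `rawdata`).
#' @param variant model variant name.
#' @return list with `bank`, `scaler`, `x_train`, `x_test` (image tensors)
#'   and `input_dim`.
#' @export
prepare_fold_features <- function(train_trials, test_trials,
                                  band = bandpass_spec(), target_size = 28,
                                  variant = "msaenet") {
  if (variant == "rawdata") {
    rng <- range(train_trials$X)
    scaler <- structure(list(min = rng[1], max = rng[2]),
                        class = "feature_scaler")
    scale_raw <- function(trials) {
      d <- dim(trials$X)
      out <- array(0, c(d[2], d[3], 1, d[1]))
      span <- max(scaler$max - scaler$min, .Machine$double.eps)
      for (i in seq_len(d[1])) {
        out[, , 1, i] <- pmin(pmax((trials$X[i, , ] - scaler$min) / span, 0), 1)
      }
      out
    }
    x_train <- scale_raw(train_trials)
    return(list(bank = NULL, scaler = scaler, x_train = x_train,
                x_test = scale_raw(test_trials),
                input_dim = dim(x_train)[1:2]))
  }
  tr_f <- bandpass_trials(train_trials, band)
  te_f <- bandpass_trials(test_trials, band)
  bank <- fit_csp(tr_f)
  covs_train <- covariance_features(tr_f, bank)
  scaler <- fit_feature_scaler(covs_train)
  list(bank = bank, scaler = scaler,
       x_train = trials_to_images(tr_f, bank, target_size, scaler),
       x_test = trials_to_images(te_f, bank, target_size, scaler),
       input_dim = c(target_size, target_size))
}

#' Leave-one-subject-out evaluation of the full pipeline
#'
#' For each fold: band-pass and CSP fitted on the S-1 training subjects,
#' feature images built, a fresh model trained with validation-based early
#' stopping, and the held-out subject scored. Per-fold initialization and
#' shuffling seeds are derived deterministically from `train_cfg$seed` and
#' the fold index, so a run is exactly reproducible in single-threaded mode.
#'
#' @param cohort list of `epoched_trials` (one per subject).
#' @param model_cfg [msaenet_config()].
#' @param weights [loss_weights()].
#' @param train_cfg [training_config()].
#' @param band [bandpass_spec()].
#' @param target_size feature-image side; defaults to `model_cfg$input_size`.
#' @param return_features also return the test-set fused features, labels and
#'   predictions of every fold (for visualization and compactness analyses).
#' @param log_file optional path receiving one JSON line per fold
#'   (fold, subject, epochs, final losses, metrics).
#' @param verbose print fold progress.
#' @return an object of class `eval_result`: `per_fold` data frame
#'   (subject, acc, f1), `mean_acc`, `std_acc`, `mean_f1`, `std_f1`
#'   (population std over folds), and optionally `features`.
#' @export
run_loso <- function(cohort, model_cfg = msaenet_config(),
                     weights = loss_weights(),
                     train_cfg = training_config(), band = bandpass_spec(),
                     target_size = NULL, return_features = FALSE,
                     log_file = NULL, verbose = FALSE) {
  folds <- make_loso_folds(cohort)
  target_size <- target_size %||% model_cfg$input_size
  per_fold <- data.frame(subject = integer(), acc = numeric(),
                         f1 = numeric())
  features <- list()
  for (k in seq_along(folds)) {
    fold <- folds[[k]]
    res <- tryCatch({
      train_pool <- concat_trials(cohort[fold$train])
      test_trials <- cohort[[fold$test]]
      feats <- prepare_fold_features(train_pool, test_trials, band,
                                     target_size, model_cfg$variant)
      split_seed <- child_seed(train_cfg$seed, k, 1)
      split <- split_validation(train_pool, train_cfg$val_fraction,
                                split_seed)
      fit_idx <- match_trials(train_pool, split$fit)
      val_idx <- match_trials(train_pool, split$val)
      mv <- make_variant(model_cfg, weights, input_dim = feats$input_dim,
                         seed = child_seed(train_cfg$seed, k, 2))
      fold_cfg <- train_cfg
      fold_cfg$seed <- child_seed(train_cfg$seed, k, 3)
      tr <- train_msaenet(mv$model,
                          feats$x_train[, , , fit_idx, drop = FALSE],
                          train_pool$y[fit_idx],
                          feats$x_train[, , , val_idx, drop = FALSE],
                          train_pool$y[val_idx],
                          mv$weights, fold_cfg)
      model <- tr$model
      model$scaler <- feats$scaler
      pr <- predict(model, feats$x_test)
      met <- evaluate_predictions(test_trials$y, pr$labels,
                                  model_cfg$n_classes)
      fe <- forward_eval_batched(model, feats$x_test)
      list(met = met, history = tr$history, model = model,
           fused = t(fe$fused), pred = pr$labels, truth = test_trials$y)
    }, error = function(e) {
      stop_invalid("fold ", k, " (subject ", fold$subject, ") failed: ",
                   conditionMessage(e))
    })
    per_fold <- rbind(per_fold,
                      data.frame(subject = fold$subject, acc = res$met$acc,
                                 f1 = res$met$f1))
    if (return_features) {
      features[[k]] <- list(subject = fold$subject, fused = res$fused,
                            truth = res$truth, pred = res$pred)
    }
    if (!is.null(log_file)) {
      line <- jsonlite::toJSON(
        list(fold = k, subject = fold$subject,
             epochs = nrow(res$history),
             train_loss = res$history$train_loss[nrow(res$history)],
             val_loss = min(res$history$val_loss),
             acc = res$met$acc, f1 = res$met$f1),
        auto_unbox = TRUE)
      cat(line, "\n", sep = "", file = log_file, append = TRUE)
    }
    if (verbose) {
      message(sprintf("fold %d (subject %d): acc %.1f%%  f1 %.1f%%",
                      k, fold$subject, res$met$acc, res$met$f1))
    }
  }
  pop_sd <- function(x) sqrt(mean((x - mean(x))^2))
  out <- structure(
    list(per_fold = per_fold,
         mean_acc = mean(per_fold$acc), std_acc = pop_sd(per_fold$acc),
         mean_f1 = mean(per_fold$f1), std_f1 = pop_sd(per_fold$f1)),
    class = "eval_result")
  if (return_features) out$features <- features
  out
}

# Indices of split trials inside the pooled set. split_validation subsets by
# index, so we recover positions from the subset bookkeeping instead of
# comparing data; the split returns disjoint covering subsets in pool order.
match_trials <- function(pool, subset) {
  attr(subset, "pool_idx")
}

#' @export
print.eval_result <- function(x, ...) {
  cat("Leave-one-subject-out evaluation\n")
  print(x$per_fold, row.names = FALSE)
  cat(sprintf("mean ACC %.2f +- %.2f %%   mean F1 %.2f +- %.2f %%\n",
              x$mean_acc, x$std_acc, x$mean_f1, x$std_f1))
  invisible(x)
}

#' Write an evaluation report
#'
#' Per-fold metrics as CSV and the aggregate summary as JSON.
#'
#' @param result an `eval_result`.
#' @param csv_path,json_path output files (`NULL` to skip either).
#' @return `result`, invisibly.
#' @export
write_report <- function(result, csv_path = NULL, json_path = NULL) {
  if (!is.null(csv_path)) {
    write.csv(result$per_fold, csv_path, row.names = FALSE)
  }
  if (!is.null(json_path)) {
    jsonlite::write_json(list(mean_acc = result$mean_acc,
                              std_acc = result$std_acc,
                              mean_f1 = result$mean_f1,
                              std_f1 = result$std_f1),
                         json_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(result)
}

#' Two-dimensional t-SNE embedding of learned features
#'
#' Embeds the fused-layer features into two dimensions for visualization,
#' deterministically under `seed` (exact t-SNE, no random PCA).
#'
#' @param features `N x d` numeric matrix (N >= 5).
#' @param seed integer seed.
#' @param perplexity t-SNE perplexity; default `min(30, floor((N - 1) / 3))`.
#' @return `N x 2` coordinate matrix.
#' @export
tsne_embed <- function(features, seed = 1, perplexity = NULL) {
  features <- as.matrix(features)
  if (ncol(features) == 0L) stop_invalid("features have zero dimensions")
  N <- nrow(features)
  if (N < 5L) stop_invalid("need at least 5 samples")
  perplexity <- perplexity %||% min(30, floor((N - 1) / 3))
  set.seed(seed)
  out <- Rtsne::Rtsne(features, dims = 2, perplexity = perplexity,
                      theta = 0, pca = FALSE, max_iter = 500,
                      check_duplicates = FALSE)
  out$Y
}

#' Scatter plot of a t-SNE embedding
#'
#' Colors mark the true class; plotting symbols mark the predicted class, so
#' misclassified trials show a symbol/color mismatch.
#'
#' @param coords `N x 2` matrix from [tsne_embed()].
#' @param truth,pred 0-based label vectors.
#' @param file output PNG path.
#' @return `file`, invisibly.
#' @export
tsne_plot <- function(coords, truth, pred, file) {
  grDevices::png(file, width = 800, height = 700)
  on.exit(grDevices::dev.off(), add = TRUE)
  cols <- truth + 1L
  pchs <- c(17, 19)[pred + 1L]
  graphics::plot(coords[, 1], coords[, 2], col = cols, pch = pchs,
                 xlab = "t-SNE 1", ylab = "t-SNE 2",
                 main = "Fused-feature embedding")
  graphics::legend("topright",
                   legend = c("class 0 (true)", "class 1 (true)",
                              "pred 0", "pred 1"),
                   col = c(1, 2, 1, 1), pch = c(15, 15, 17, 19))
  invisible(file)
}

#' Read a YAML run configuration
#'
#' Maps the documented YAML keys (`data`, `preset`, `band`, `features`,
#' `model`, `loss`, `train`) onto the package's configuration objects,
#' filling unstated keys with the package defaults.
#'
#' @param path YAML file.
#' @return list with `data_path`, `preset`, `band`, `target_size`,
#'   `model_cfg`, `weights`, `train_cfg`.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  band <- do.call(bandpass_spec, cfg$band %||% list())
  model_args <- cfg$model %||% list()
  if (!is.null(model_args$kernels)) {
    model_args$multiscale_kernels <- as.numeric(model_args$kernels)
    model_args$kernels <- NULL
  }
  model_cfg <- do.call(msaenet_config, model_args)
  loss_args <- cfg$loss %||% list()
  center_alpha <- loss_args$center_alpha
  loss_args$center_alpha <- NULL
  weights <- do.call(loss_weights, loss_args)
  if (!is.null(center_alpha)) model_cfg$center_alpha <- center_alpha
  train_args <- cfg$train %||% list()
  if (!is.null(train_args$lr)) {
    train_args$initial_lr <- train_args$lr
    train_args$lr <- NULL
  }
  train_cfg <- do.call(training_config, train_args)
  list(data_path = cfg$data$path %||% NULL,
       preset = if (!is.null(cfg$preset)) dataset_preset(cfg$preset) else NULL,
       band = band,
       target_size = (cfg$features %||% list())$target_size %||%
         model_cfg$input_size,
       model_cfg = model_cfg, weights = weights, train_cfg = train_cfg)
}
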