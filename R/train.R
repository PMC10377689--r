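#' Training schedule configuration
#'
#' Adam with plateau-based learning-rate decay and early stopping: the
#' learning rate halves after `lr_patience` epochs without a validation-loss
#' improvement larger than `min_delta`, and training stops after
#' `stop_patience` such epochs (or `max_epochs`). The parameters (including
#' batch-norm statistics and class centers) are restored to the epoch with
#' the minimum validation loss. The initial learning rate and batch size are
#' conventional Adam defaults and can be overridden.
#'
#' @param initial_lr initial Adam learning rate.
#' @param batch_size mini-batch size (>= 1).
#' @param max_epochs maximum number of epochs.
#' @param lr_decay_factor multiplicative decay on plateau.
#' @param lr_patience epochs of stagnation before a decay step.
#' @param stop_patience epochs of stagnation before stopping.
#' @param val_fraction fraction of pooled training trials held out for
#'   validation (in `(0, 1)`).
#' @param min_delta absolute validation-loss decrease required to count as an
#'   improvement (guards float jitter).
#' @param seed integer seed controlling initialization and batch shuffling.
#' @param precision `"single"` computes the dominant multiscale dense layer's
#'   matrix products in float32 during training (master weights and the
#'   optimizer stay double precision); `"double"` keeps everything double.
#'   Both paths are deterministic in single-threaded mode.
#' @return an object of class `training_config`.
#' @export
training_config <- function(initial_lr = 1e-3, batch_size = 64,
                            max_epochs = 200, lr_decay_factor = 0.5,
                            lr_patience = 5, stop_patience = 20,
                            val_fraction = 0.2, min_delta = 1e-4, seed = 1,
                            precision = c("single", "double")) {
  precision <- match.arg(precision)
  if (!is_count(batch_size, 1L)) stop_invalid("batch_size must be >= 1")
  if (!is_count(max_epochs, 1L)) stop_invalid("max_epochs must be >= 1")
  if (!is_count(lr_patience, 1L) || !is_count(stop_patience, 1L)) {
    stop_invalid("patiences must be >= 1")
  }
  if (!is_number(val_fraction) || val_fraction <= 0 || val_fraction >= 1) {
    stop_invalid("val_fraction must be in (0, 1)")
  }
  structure(list(initial_lr = initial_lr, batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 lr_decay_factor = lr_decay_factor,
                 lr_patience = as.integer(lr_patience),
                 stop_patience = as.integer(stop_patience),
                 val_fraction = val_fraction, min_delta = min_delta,
                 seed = as.integer(seed), precision = precision),
            class = "training_config")
}

snapshot_model <- function(model) {
  list(params = deep_copy(model$params), bn = model$bn,
       centers = model$centers)
}

restore_model <- function(model, snap) {
  model$params <- deep_copy(snap$params)
  model$bn <- snap$bn
  model$centers <- snap$centers
  model
}

eval_loss <- function(model, images, y, weights, batch = 128L) {
  N <- dim(images)[4]
  tot <- 0
  for (at in seq(1L, N, by = batch)) {
    idx <- at:min(at + batch - 1L, N)
    xb <- images[, , , idx, drop = FALSE]
    fo <- forward_msaenet(model, xb, training = FALSE)
    lb <- loss_batch(model, fo, xb, y[idx], weights)
    tot <- tot + lb$total * length(idx)
  }
  tot / N
}

#' Train the network with Adam, plateau decay and early stopping
#'
#' Runs the full schedule of [training_config()]. The class centers are
#' updated by the moving rule after every optimizer step (when the center
#' loss is active). All randomness (shuffling) is governed by `control$seed`;
#' with a single compute thread the run is fully deterministic.
#'
#' @param model an `msaenet_model` from [build_model()] / [make_variant()].
#' @param x_fit,y_fit training images `(H, W, 1, N)` and 0-based labels.
#' @param x_val,y_val validation images and labels monitored for the
#'   schedule.
#' @param weights [loss_weights()].
#' @param control [training_config()].
#' @param verbose print per-epoch progress.
#' @return list with `model` (parameters restored to the best validation
#'   epoch) and `history` (data frame: epoch, train_loss, val_loss, lr).
#' @export
train_msaenet <- function(model, x_fit, y_fit, x_val, y_val,
                          weights = loss_weights(),
                          control = training_config(), verbose = FALSE) {
  set.seed(control$seed)
  N <- dim(x_fit)[4]
  adam_m <- zeros_like(model$params)
  adam_v <- zeros_like(model$params)
  use_mirror <- identical(control$precision %||% "single", "single") &&
    model$use_ms
  if (use_mirror) model$fmirror <- fmirror_make(model$params$msd1_W)
  step <- 0L
  lr <- control$initial_lr
  best_val <- Inf          # strict-improvement tracker for restoration
  plateau_ref <- Inf       # min_delta tracker for the schedule
  best_snap <- snapshot_model(model)
  lr_wait <- 0L
  stop_wait <- 0L
  hist <- data.frame(epoch = integer(), train_loss = numeric(),
                     val_loss = numeric(), lr = numeric())
  pnames <- names(model$params)
  for (epoch in seq_len(control$max_epochs)) {
    ord <- sample.int(N)
    epoch_loss <- 0
    for (at in seq(1L, N, by = control$batch_size)) {
      idx <- ord[at:min(at + control$batch_size - 1L, N)]
      xb <- x_fit[, , , idx, drop = FALSE]
      yb <- y_fit[idx]
      fo <- forward_msaenet(model, xb, training = TRUE)
      model$bn <- fo$bn
      lb <- loss_batch(model, fo, xb, yb, weights)
      g <- backward_msaenet(model, fo, yb, weights)
      step <- step + 1L
      for (nm in pnames) {
        if (use_mirror && nm == "msd1_W") {
          adam_step_mirror(model$params[[nm]], g[[nm]], adam_m[[nm]],
                           adam_v[[nm]], lr, 0.9, 0.999, 1e-8, step,
                           model$fmirror)
        } else {
          adam_step_inplace(model$params[[nm]], g[[nm]], adam_m[[nm]],
                            adam_v[[nm]], lr, 0.9, 0.999, 1e-8, step)
        }
      }
      if (weights$beta3 > 0 && model$cfg$center_alpha > 0) {
        model$centers <- update_centers(model$centers, t(fo$fused), yb,
                                        model$cfg$center_alpha)
      }
      epoch_loss <- epoch_loss + lb$total * length(idx)
    }
    val_loss <- eval_loss(model, x_val, y_val, weights)
    hist <- rbind(hist, data.frame(epoch = epoch,
                                   train_loss = epoch_loss / N,
                                   val_loss = val_loss, lr = lr))
    if (verbose) {
      message(sprintf("epoch %3d  train %.4f  val %.4f  lr %.2e",
                      epoch, epoch_loss / N, val_loss, lr))
    }
    if (val_loss < best_val) {
      best_val <- val_loss
      best_snap <- snapshot_model(model)
    }
    if (val_loss < plateau_ref - control$min_delta) {
      plateau_ref <- val_loss
      lr_wait <- 0L
      stop_wait <- 0L
    } else {
      lr_wait <- lr_wait + 1L
      stop_wait <- stop_wait + 1L
      if (stop_wait >= control$stop_patience) break
      if (lr_wait >= control$lr_patience) {
        lr <- lr * control$lr_decay_factor
        lr_wait <- 0L
      }
    }
  }
  model <- restore_model(model, best_snap)
  model$fmirror <- NULL
  list(model = model, history = hist)
}
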