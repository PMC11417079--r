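#' Training configuration
#'
#' Supervised training settings shared by both architectures: mean squared
#' error against the ground-truth `(S0, T)` maps, the AdamW optimizer at
#' learning rate 0.002, and an 80/20 train/validation split.  The
#' reference recipes are 5 epochs at batch size 10,000 curves for the 1D
#' network and 1000 epochs at batch size 100 series for the CNN; both
#' scale down for CPU-sized experiments.
#'
#' @param epochs Number of passes over the training split (0 is allowed
#'   and returns the initial weights with an empty history).
#' @param batch Batch size: curves for `"nn1d"`, series for `"cnn"`.
#' @param lr Learning rate.
#' @param val_frac Validation fraction of the dataset.
#' @param weight_decay Decoupled weight decay applied to weight matrices.
#' @param seed Integer seed controlling the split, shuffling and any other
#'   training randomness.
#' @return An object of class `train_config`.
#' @export
train_config <- function(epochs, batch, lr = 2e-3, val_frac = 0.2,
                         weight_decay = 0.01, seed = 1L) {
  stopifnot(epochs >= 0L, batch >= 1L, lr > 0, val_frac > 0, val_frac < 1)
  structure(list(epochs = as.integer(epochs), batch = as.integer(batch),
                 lr = lr, val_frac = val_frac, weight_decay = weight_decay,
                 seed = as.integer(seed)),
            class = "train_config")
}

#' Extract per-pixel decay curves from a dataset
#'
#' Flattens every record of a synthetic dataset into single-pixel decay
#' curves with their ground-truth targets, for training the 1D estimator.
#' Order is deterministic: record-major, then row-major within each map.
#'
#' @param dataset A `synth_dataset` or list of `synth_record`.
#' @return A list with `curves` (`n_pixels x n_echo` matrix), `targets`
#'   (`n_pixels x 2` matrix, columns `s0`, `t`) and the common `schedule`.
#' @export
extract_pixel_curves <- function(dataset) {
  records <- if (inherits(dataset, "synth_dataset")) dataset$records else dataset
  if (!length(records)) stop("empty dataset")
  sched <- records[[1]]$series$schedule
  for (rec in records)
    if (!schedules_equal(rec$series$schedule, sched))
      stop("records have mismatched echo schedules")
  rowmajor <- function(m) as.vector(t(m))
  curves <- do.call(rbind, lapply(records, function(rec) {
    d <- dim(rec$series$data)
    matrix(aperm(rec$series$data, c(2, 1, 3)), nrow = d[1] * d[2])
  }))
  targets <- do.call(rbind, lapply(records, function(rec)
    cbind(s0 = rowmajor(rec$truth$s0), t = rowmajor(rec$truth$t))))
  list(curves = curves, targets = targets, schedule = sched)
}

# Stack a dataset into CNN tensors: x (H, W, n_echo, N), y (H, W, 2, N)
stack_series_tensor <- function(records) {
  d <- dim(records[[1]]$series$data)
  n <- length(records)
  x <- array(0, c(d[1], d[2], d[3], n))
  y <- array(0, c(d[1], d[2], 2L, n))
  for (i in seq_len(n)) {
    x[, , , i] <- records[[i]]$series$data
    y[, , 1L, i] <- records[[i]]$truth$s0
    y[, , 2L, i] <- records[[i]]$truth$t
  }
  list(x = x, y = y)
}

#' Train an estimator on a synthetic dataset
#'
#' Supervised training with MSE loss against the ground-truth `(S0, T)`
#' maps.  The 1D network consumes extracted single-pixel curves; the CNN
#' consumes whole series as multi-channel images.  Per-epoch training and
#' validation losses are recorded, and the weights with the best
#' validation loss are restored at the end (the final-epoch weights are
#' kept alongside).  Training is reproducible given the config seed.
#'
#' @param model A `t2_nn` from [build_nn1d()] or [build_cnn()].
#' @param dataset A `synth_dataset` (or, for `"nn1d"`, optionally the
#'   output of [extract_pixel_curves()]).
#' @param config A [train_config()].
#' @return The trained model, with `history` (data frame of epoch losses),
#'   `best_epoch`, and the training `schedule` locked in.
#' @export
train_model <- function(model, dataset, config) {
  stopifnot(inherits(model, "t2_nn"), inherits(config, "train_config"))
  if (model$arch == "nn1d") train_nn1d(model, dataset, config)
  else train_cnn(model, dataset, config)
}

mse_loss <- function(pred, y) mean((pred - y)^2)
mse_grad <- function(pred, y) (2 / length(pred)) * (pred - y)

finish_training <- function(model, net, config, hist, best_state,
                            final_state, sched) {
  model$history <- hist
  model$trained <- TRUE
  model$schedule <- sched
  model$final_state <- final_state
  if (!is.null(best_state)) {
    model$best_epoch <- hist$epoch[which.min(hist$val_loss)]
    set_model_state(net, best_state)
  }
  clear_caches(net)
  model$config <- config
  model
}

train_nn1d <- function(model, dataset, config) {
  data <- if (is.list(dataset) && !is.null(dataset$curves)) dataset
          else extract_pixel_curves(dataset)
  if (ncol(data$curves) != model$spec$n_in)
    stop("curve length does not match the network input size")
  net <- model$net
  refs <- param_refs(net)
  opt <- adamw_new(refs, lr = config$lr, weight_decay = config$weight_decay)
  ntot <- nrow(data$curves)
  hist <- data.frame(epoch = integer(), train_loss = numeric(),
                     val_loss = numeric())
  best <- NULL; best_loss <- Inf
  with_seed(config$seed, {
    idx <- sample.int(ntot)
    nval <- max(1L, floor(config$val_frac * ntot))
    val_idx <- idx[seq_len(nval)]
    tr_idx <- idx[-seq_len(nval)]
    xval <- data$curves[val_idx, , drop = FALSE]
    yval <- data$targets[val_idx, , drop = FALSE]
    for (ep in seq_len(config$epochs)) {
      ord <- sample(tr_idx)
      losses <- c()
      for (b in split(ord, ceiling(seq_along(ord) / config$batch))) {
        xb <- data$curves[b, , drop = FALSE]
        yb <- data$targets[b, , drop = FALSE]
        zero_grads(net)
        pred <- nn_forward(net, xb, training = TRUE)
        losses <- c(losses, mse_loss(pred, yb))
        nn_backward(net, mse_grad(pred, yb))
        adamw_step(opt)
      }
      vl <- mse_loss(nn_forward(net, xval, training = FALSE), yval)
      if (!is.finite(vl)) stop("training diverged (non-finite validation loss)")
      hist[nrow(hist) + 1L, ] <- list(ep, mean(losses), vl)
      if (vl < best_loss) { best_loss <- vl; best <- get_model_state(net) }
    }
  })
  finish_training(model, net, config, hist, best, get_model_state(net),
                  data$schedule)
}

train_cnn <- function(model, dataset, config) {
  records <- if (inherits(dataset, "synth_dataset")) dataset$records else dataset
  sched <- records[[1]]$series$schedule
  dv <- model$spec$divisor
  d <- dim(records[[1]]$series$data)
  if (d[1] %% dv != 0 || d[2] %% dv != 0)
    stop("spatial dimensions must be divisible by ", dv)
  if (d[3] != model$spec$in_channels)
    stop("echo count does not match the network input channels")
  tensors <- stack_series_tensor(records)
  net <- model$net
  refs <- param_refs(net)
  opt <- adamw_new(refs, lr = config$lr, weight_decay = config$weight_decay)
  ntot <- length(records)
  hist <- data.frame(epoch = integer(), train_loss = numeric(),
                     val_loss = numeric())
  best <- NULL; best_loss <- Inf
  with_seed(config$seed, {
    idx <- sample.int(ntot)
    nval <- max(1L, floor(config$val_frac * ntot))
    val_idx <- idx[seq_len(nval)]
    tr_idx <- idx[-seq_len(nval)]
    for (ep in seq_len(config$epochs)) {
      ord <- sample(tr_idx)
      losses <- c()
      for (b in split(ord, ceiling(seq_along(ord) / config$batch))) {
        xb <- tensors$x[, , , b, drop = FALSE]
        yb <- tensors$y[, , , b, drop = FALSE]
        zero_grads(net)
        pred <- nn_forward(net, xb, training = TRUE)
        losses <- c(losses, mse_loss(pred, yb))
        nn_backward(net, mse_grad(pred, yb))
        adamw_step(opt)
      }
      vpred <- nn_forward(net, tensors$x[, , , val_idx, drop = FALSE],
                          training = FALSE)
      vl <- mse_loss(vpred, tensors$y[, , , val_idx, drop = FALSE])
      if (!is.finite(vl)) stop("training diverged (non-finite validation loss)")
      hist[nrow(hist) + 1L, ] <- list(ep, mean(losses), vl)
      if (vl < best_loss) { best_loss <- vl; best <- get_model_state(net) }
    }
  })
  finish_training(model, net, config, hist, best, get_model_state(net), sched)
}

#' Predict parameter maps with a trained estimator
#'
#' Runs the network in evaluation mode (no dropout, frozen normalization
#' statistics) on one series and returns the two output channels as an
#' `(S0, T)` [parameter_map()].  The series must be sampled on the exact
#' schedule the model was trained on -- these architectures are tied to a
#' specific set of `eta` values, so a mismatch is an error, never an
#' interpolation.
#'
#' @param model A trained `t2_nn`.
#' @param series An [image_series()].
#' @return A [parameter_map()] (no clipping applied to the outputs).
#' @export
predict_map <- function(model, series) {
  stopifnot(inherits(model, "t2_nn"), inherits(series, "image_series"))
  if (is.null(model$schedule))
    stop("model has no training schedule; train it first")
  if (!schedules_equal(series$schedule, model$schedule))
    stop("series schedule does not match the model's training schedule")
  d <- dim(series$data)
  if (model$arch == "nn1d") {
    Y <- series_to_curves(series)
    out <- nn_forward(model$net, Y, training = FALSE)
    parameter_map(matrix(out[, 1], d[1], d[2]), matrix(out[, 2], d[1], d[2]))
  } else {
    dv <- model$spec$divisor
    if (d[1] %% dv != 0 || d[2] %% dv != 0)
      stop("spatial dimensions must be divisible by ", dv)
    x <- array(series$data, c(d[1], d[2], d[3], 1L))
    out <- nn_forward(model$net, x, training = FALSE)
    parameter_map(out[, , 1, 1], out[, , 2, 1])
  }
}
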