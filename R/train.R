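#' Training configuration
#'
#' Defaults follow the published training recipe: 400 epochs, batch size
#' 32, learning rate 1e-4, Adam optimizer, cross-entropy loss.
#'
#' @param epochs number of passes over the dataset.
#' @param batch_size images per gradient step (clipped to the dataset size).
#' @param learning_rate Adam step size.
#' @param seed integer seed controlling shuffling (and nothing else; model
#'   initialization is seeded in [build_network()]).
#' @param validation_fraction fraction of the dataset held out for per-epoch
#'   validation loss (default 0: validation data is supplied externally).
#' @return a `training_config` list.
#' @export
training_config <- function(epochs = 400L, batch_size = 32L,
                            learning_rate = 1e-4, seed = 1L,
                            validation_fraction = 0) {
  if (epochs < 0 || batch_size < 1 || learning_rate < 0 ||
      validation_fraction < 0 || validation_fraction >= 1) {
    stop_input("invalid training configuration")
  }
  structure(
    list(
      epochs = as.integer(epochs),
      batch_size = as.integer(batch_size),
      learning_rate = learning_rate,
      optimizer = "adam",
      loss = "cross-entropy",
      seed = as.integer(seed),
      validation_fraction = validation_fraction
    ),
    class = "training_config"
  )
}

# Per-pixel cross-entropy of a probability map against an integer mask
# (0-based classes); also returns the pre-softmax gradient.
ce_loss_grad <- function(prob, mask) {
  h <- dim(prob)[1]; w <- dim(prob)[2]; k <- dim(prob)[3]
  idx <- cbind(seq_len(h * w), as.integer(mask) + 1L)
  pm <- matrix(prob, h * w, k)
  eps <- 1e-12
  loss <- -mean(log(pmax(pm[idx], eps)))
  onehot <- matrix(0, h * w, k)
  onehot[idx] <- 1
  dscores <- array((pm - onehot) / (h * w), c(h, w, k))
  list(loss = loss, dscores = dscores)
}

#' Train the segmentation network
#'
#' Minimizes mean per-pixel cross-entropy with Adam. The dataset is
#' shuffled every epoch under the training seed; the batch size is clipped
#' to the dataset size. Optimizer state lives in the model, so successive
#' calls continue training where the previous call stopped.
#'
#' @param model an `fcn_model` from [build_network()].
#' @param dataset nonempty list of `list(image, mask)` pairs: images
#'   H x W x 3 in `[0, 1]` matching the model input size, masks
#'   [label_mask()]s.
#' @param config a [training_config()].
#' @return list `model` (trained) and `loss_history` (data frame with one
#'   row per epoch: `epoch`, `loss`, and `val_loss` when a validation split
#'   is configured).
#' @export
train <- function(model, dataset, config = training_config()) {
  if (length(dataset) == 0) stop_input("empty training dataset")
  for (d in dataset) {
    if (!all(dim(d$image)[1:2] == dim(d$mask))) {
      stop_input("image / mask dimension mismatch in dataset")
    }
  }
  n_val <- floor(config$validation_fraction * length(dataset))
  val <- if (n_val > 0) dataset[seq_len(n_val)] else list()
  trn <- if (n_val > 0) dataset[-seq_len(n_val)] else dataset
  if (length(trn) == 0) stop_input("validation split leaves no training data")
  bs <- min(config$batch_size, length(trn))

  if (is.null(model$opt)) {
    model$opt <- list(
      m = lapply(model$params, function(p) p * 0),
      v = lapply(model$params, function(p) p * 0),
      t = 0L
    )
  }
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  history <- vector("list", config$epochs)

  epoch_seed <- config$seed + model$epochs_trained
  for (ep in seq_len(config$epochs)) {
    ord <- with_seed(epoch_seed + ep, sample(length(trn)))
    ep_loss <- 0
    n_seen <- 0
    for (start in seq(1, length(trn), by = bs)) {
      batch <- trn[ord[start:min(start + bs - 1, length(trn))]]
      grads <- NULL
      batch_loss <- 0
      for (d in batch) {
        fw <- fcn_forward(model, d$image, keep_cache = TRUE)
        lg <- ce_loss_grad(fw$prob, d$mask)
        if (!is.finite(lg$loss)) {
          stop_input(
            "NaN/Inf loss at epoch %d after %d images; learning rate %.3g may be too high",
            ep, n_seen, config$learning_rate
          )
        }
        batch_loss <- batch_loss + lg$loss
        g <- fcn_backward(model, fw$cache, lg$dscores)
        if (is.null(grads)) {
          grads <- g
        } else {
          for (nm in names(g)) grads[[nm]] <- grads[[nm]] + g[[nm]]
        }
      }
      nb <- length(batch)
      ep_loss <- ep_loss + batch_loss
      n_seen <- n_seen + nb
      # Adam step on the batch-mean gradient
      model$opt$t <- model$opt$t + 1L
      lr_t <- config$learning_rate *
        sqrt(1 - b2^model$opt$t) / (1 - b1^model$opt$t)
      for (nm in names(grads)) {
        gr <- grads[[nm]] / nb
        model$opt$m[[nm]] <- b1 * model$opt$m[[nm]] + (1 - b1) * gr
        model$opt$v[[nm]] <- b2 * model$opt$v[[nm]] + (1 - b2) * gr^2
        model$params[[nm]] <- model$params[[nm]] -
          lr_t * model$opt$m[[nm]] / (sqrt(model$opt$v[[nm]]) + eps)
      }
    }
    val_loss <- if (length(val) > 0) {
      mean(vapply(val, function(d) {
        ce_loss_grad(fcn_forward(model, d$image)$prob, d$mask)$loss
      }, 0))
    } else {
      NA_real_
    }
    history[[ep]] <- data.frame(
      epoch = model$epochs_trained + ep,
      loss = ep_loss / n_seen,
      val_loss = val_loss
    )
  }
  model$epochs_trained <- model$epochs_trained + config$epochs
  list(
    model = model,
    loss_history = if (config$epochs > 0) {
      do.call(rbind, history)
    } else {
      data.frame(epoch = integer(), loss = numeric(), val_loss = numeric())
    }
  )
}

#' Wheal-class intersection-over-union between two masks
#'
#' Convenience metric for training smoke tests: IoU of the `wheal` class
#' over the whole image.
#'
#' @param predicted,expected [label_mask()]s of equal size.
#' @return IoU in `[0, 1]` (1 when both masks have no wheal pixels).
#' @export
mask_iou <- function(predicted, expected) {
  p <- unclass(predicted) == 1L
  e <- unclass(expected) == 1L
  u <- sum(p | e)
  if (u == 0) return(1)
  sum(p & e) / u
}
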