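# Seeded train/evaluate loop: Adam on binary cross-entropy (or soft-Dice)
# with per-epoch history, best-loss checkpointing and metric reports.

#' Training configuration
#'
#' Defaults follow the published recipe: Adam, learning rate 0.001 and 150
#' epochs (the weight-initialization scheme lives in [model_config()]).
#' Batch size and loss are not stated by the protocol; defaults 8 and binary
#' cross-entropy.
#'
#' @param optimizer only `"adam"` is implemented.
#' @param learning_rate positive step size (default 0.001).
#' @param epochs positive integer (default 150).
#' @param batch_size positive integer (default 8).
#' @param loss `"bce"`, `"dice"` or `"bce+dice"`.
#' @param seed integer master seed controlling data order and dropout.
#' @param threshold probability cut for binarizing predictions, in (0,1).
#' @param checkpoint optional path; best-loss weights are written there.
#' @param shuffle shuffle sample order each epoch (default TRUE).
#' @param verbose print one line per epoch.
#' @return object of class `train_config`.
#' @export
train_config <- function(optimizer = "adam", learning_rate = 0.001,
                         epochs = 150L, batch_size = 8L,
                         loss = c("bce", "dice", "bce+dice"), seed = 1L,
                         threshold = 0.5, checkpoint = NULL, shuffle = TRUE,
                         verbose = FALSE) {
  loss <- match.arg(loss)
  if (optimizer != "adam") stop("only the adam optimizer is implemented")
  if (learning_rate <= 0) stop("learning_rate must be > 0")
  if (epochs < 1) stop("epochs must be >= 1")
  if (threshold <= 0 || threshold >= 1) stop("threshold must be in (0,1)")
  structure(list(optimizer = optimizer, learning_rate = learning_rate,
                 epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), loss = loss,
                 seed = as.integer(seed), threshold = threshold,
                 checkpoint = checkpoint, shuffle = isTRUE(shuffle),
                 verbose = isTRUE(verbose)),
            class = "train_config")
}

adam_state <- function(params) {
  list(m = lapply(params, function(p) array(0, dim(p) %||% length(p))),
       v = lapply(params, function(p) array(0, dim(p) %||% length(p))),
       t = 0L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(grads)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mhat <- state$m[[nm]] / bc1
    vhat <- state$v[[nm]] / bc2
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

stack_batch <- function(items, field) {
  arrs <- lapply(items, function(it) as_t4(it[[field]]))
  d <- dim(arrs[[1]])
  out <- array(0, c(d[1], d[2], d[3], length(arrs)))
  for (i in seq_along(arrs)) out[, , , i] <- arrs[[i]]
  out
}

loss_node <- function(tape, out, target, loss) {
  switch(loss,
    bce = ad_bce_logits(tape, out$logits, target),
    dice = ad_dice_loss(tape, out$prob, target),
    `bce+dice` = ad_add(tape, ad_bce_logits(tape, out$logits, target),
                        ad_dice_loss(tape, out$prob, target)))
}

#' Train the segmentation model
#'
#' Adam optimization of the configured loss with full seeding (data order and
#' dropout; build the model under the same seed for end-to-end determinism).
#' History records per-epoch mean training loss and pixelwise binary
#' accuracy. If `config$checkpoint` is set, the weights with the best epoch
#' loss are saved there. A non-finite loss aborts with a diagnostic.
#'
#' @param model a [build_model()] result.
#' @param dataset list of `list(image=, mask=)` pairs (e.g. from
#'   [make_dataset()]), images `H x W x C` in `[0,1]`, masks `H x W` binary.
#' @param config a [train_config()].
#' @return list with the trained `model` and `history` (data.frame with
#'   columns `epoch`, `loss`, `accuracy`).
#' @export
train <- function(model, dataset, config = train_config()) {
  stopifnot(inherits(config, "train_config"))
  if (length(dataset) == 0L) stop("dataset is empty")
  d <- dim(dataset[[1]]$image)
  if (d[1] != model$config$input_size || d[3] != model$config$in_channels) {
    stop("dataset shape does not match model config")
  }
  set.seed(config$seed)
  opt <- adam_state(model$params)
  n <- length(dataset)
  history <- data.frame(epoch = integer(0), loss = numeric(0),
                        accuracy = numeric(0))
  best <- Inf
  for (ep in seq_len(config$epochs)) {
    ord <- if (config$shuffle) sample.int(n) else seq_len(n)
    batches <- split(ord, ceiling(seq_along(ord) / config$batch_size))
    ep_loss <- 0; ep_acc <- 0; npix <- 0
    for (b in batches) {
      x <- stack_batch(dataset[b], "image")
      y <- stack_batch(dataset[b], "mask")
      tape <- ad_tape(training = TRUE)
      out <- net_forward(model, ad_input(tape, x), tape, as_params = TRUE)
      ln <- loss_node(tape, out, y, config$loss)
      if (!is.finite(ln$value)) {
        stop(sprintf("non-finite loss at epoch %d (loss=%s); aborting", ep,
                     format(ln$value)))
      }
      grads <- ad_backward(tape, ln)
      upd <- adam_step(model$params, grads, opt, config$learning_rate)
      model$params <- upd$params
      opt <- upd$state
      w <- length(b)
      ep_loss <- ep_loss + ln$value * w
      ep_acc <- ep_acc + sum((out$prob$value >= config$threshold) == (y == 1))
      npix <- npix + length(y)
    }
    ep_loss <- ep_loss / n
    history <- rbind(history, data.frame(epoch = ep, loss = ep_loss,
                                         accuracy = ep_acc / npix))
    if (config$verbose) {
      message(sprintf("epoch %d/%d loss %.5f acc %.4f", ep, config$epochs,
                      ep_loss, ep_acc / npix))
    }
    if (!is.null(config$checkpoint) && ep_loss < best) {
      best <- ep_loss
      save_model(model, config$checkpoint)
    }
  }
  list(model = model, history = history)
}

#' Predict binary masks
#'
#' Forward pass in inference mode, thresholded at `threshold`.
#'
#' @param model a `lesionseg_model`.
#' @param images single `H x W x C` image or list of them.
#' @param threshold probability cut in (0,1).
#' @return binary `H x W` matrix, or list of matrices for a list input.
#' @export
predict_masks <- function(model, images, threshold = 0.5) {
  one <- function(img) {
    (model_forward(model, img, training = FALSE) >= threshold) * 1
  }
  if (is.list(images)) lapply(images, one) else one(images)
}

#' Evaluate a model on a dataset
#'
#' Predicts, binarizes and scores against ground truth with
#' [averaged_scores()].
#'
#' @param model a `lesionseg_model`.
#' @param dataset list of `list(image=, mask=)` pairs.
#' @param mode averaging mode: `"none"`, `"micro"` or `"macro"`.
#' @param threshold probability cut.
#' @return a `metric_report`.
#' @export
evaluate <- function(model, dataset, mode = "none", threshold = 0.5) {
  if (any(!vapply(dataset, function(d) !is.null(d$mask), logical(1)))) {
    stop("dataset entries must carry ground-truth masks")
  }
  preds <- predict_masks(model, lapply(dataset, `[[`, "image"), threshold)
  averaged_scores(preds, lapply(dataset, `[[`, "mask"), mode)
}

#' Draw a mask contour onto an image
#'
#' Marks the mask boundary (mask pixels with a 4-neighbour outside the mask)
#' in red for qualitative panels.
#'
#' @param image `H x W x 3` array in `[0,1]`.
#' @param mask `H x W` binary matrix.
#' @return image with boundary pixels set to red.
#' @export
contour_overlay <- function(image, mask) {
  if (!identical(dim(image)[1:2], dim(mask)[1:2])) stop("shape mismatch")
  H <- nrow(mask); W <- ncol(mask)
  pad <- matrix(0, H + 2, W + 2)
  pad[2:(H + 1), 2:(W + 1)] <- mask
  inner <- pad[2:(H + 1), 1:W] & pad[2:(H + 1), 3:(W + 2)] &
    pad[1:H, 2:(W + 1)] & pad[3:(H + 2), 2:(W + 1)]
  border <- mask == 1 & !inner
  out <- image
  r <- out[, , 1]; g <- out[, , 2]; b <- out[, , 3]
  r[border] <- 1; g[border] <- 0; b[border] <- 0
  out[, , 1] <- r; out[, , 2] <- g; out[, , 3] <- b
  out
}
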