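# The segmentation network: a 4-level encoder of parallel branches
# {1x1 regular conv + 3x3 max-pool (ReLU), depthwise-separable conv (DSC)
# block, multi-dilated conv (MDC) block} concatenated and 2x2 max-pooled with
# dropout, a bottleneck of the same three branches at the lowest resolution,
# and a 4-level decoder of stride-2 transposed convolutions with skip
# connections to the encoder's pre-pool features, ending in a 1x1 convolution
# and sigmoid. All layers are bias-free, matching the parameter accounting.

#' Model configuration
#'
#' @param input_size square input side in pixels; must be divisible by
#'   `2^length(filter_ladder)` (256/2^4 = 16 by default).
#' @param in_channels input channels (3 for RGB).
#' @param filter_ladder per-stage branch widths; each encoder stage's three
#'   branches all use `filter_ladder[i]` output channels, so the
#'   concatenated stage width is `3*filter_ladder[i]`.
#' @param dilation_rates dilation rates of the three MDC convolutions
#'   (default 1, 2, 3 with 3x3 kernels).
#' @param mdc_mode `"rates"` (3x3 kernels at dilation rates 1/2/3, default) or
#'   `"sizes"` (literal kernel sizes 1/2/3 at rate 1) — two readings of the
#'   "dilated filters of size 1, 2, 3" wiring.
#' @param dropout_rate dropout after every encoder max-pool (default 0.05).
#' @param bottleneck_filters branch width at the bottleneck; default
#'   `2 * max(filter_ladder)`, the natural continuation of the ladder.
#' @param init_scheme `"paper"` = He-normal for regular/dilated/transposed
#'   convolutions and Glorot uniform for separable ones; `"glorot_all"`
#'   forces Glorot everywhere (the all-Xavier variant).
#' @param use_separable `FALSE` swaps every DSC block for a standard 3x3
#'   convolution of the same topology (used to demonstrate the parameter
#'   economy of the separable form).
#' @param loss training loss: `"bce"` (default), `"dice"` or `"bce+dice"`.
#' @return object of class `model_config`.
#' @export
model_config <- function(input_size = 256L, in_channels = 3L,
                         filter_ladder = c(16L, 32L, 64L, 128L),
                         dilation_rates = c(1L, 2L, 3L),
                         mdc_mode = c("rates", "sizes"),
                         dropout_rate = 0.05,
                         bottleneck_filters = NULL,
                         init_scheme = c("paper", "glorot_all"),
                         use_separable = TRUE,
                         loss = c("bce", "dice", "bce+dice")) {
  mdc_mode <- match.arg(mdc_mode)
  init_scheme <- match.arg(init_scheme)
  loss <- match.arg(loss)
  input_size <- as.integer(input_size)
  filter_ladder <- as.integer(filter_ladder)
  nlev <- length(filter_ladder)
  if (input_size %% (2^nlev) != 0L) {
    stop("input_size must be divisible by 2^length(filter_ladder)")
  }
  if (dropout_rate < 0 || dropout_rate >= 1) stop("dropout_rate in [0,1)")
  if (is.null(bottleneck_filters)) {
    bottleneck_filters <- 2L * max(filter_ladder)
  }
  structure(list(input_size = input_size, in_channels = as.integer(in_channels),
                 filter_ladder = filter_ladder,
                 dilation_rates = as.integer(dilation_rates),
                 mdc_mode = mdc_mode, dropout_rate = dropout_rate,
                 bottleneck_filters = as.integer(bottleneck_filters),
                 pool_size = 2L, transposed_kernel = 3L, transposed_stride = 2L,
                 init_scheme = init_scheme, use_separable = use_separable,
                 loss = loss),
            class = "model_config")
}

# ---- weight initialization --------------------------------------------------

init_conv_w <- function(k, M, F, scheme) {
  if (scheme == "he_normal") {
    w <- he_normal_sample(init_spec("he_normal", fan_in = k * k * M),
                          c(k * k * M, F))
  } else {
    w <- glorot_uniform_sample(
      init_spec("glorot_uniform", fan_in = k * k * M, fan_out = k * k * F),
      c(k * k * M, F))
  }
  matrix(w, k * k * M, F)
}

init_dw_w <- function(k, M, scheme) {
  if (scheme == "he_normal") {
    w <- he_normal_sample(init_spec("he_normal", fan_in = k * k), c(k * k, M))
  } else {
    w <- glorot_uniform_sample(
      init_spec("glorot_uniform", fan_in = k * k, fan_out = k * k),
      c(k * k, M))
  }
  matrix(w, k * k, M)
}

# ---- blocks -----------------------------------------------------------------

#' Build a depthwise-separable convolution (DSC) block
#'
#' A 3x3 depthwise convolution applied to every channel independently,
#' followed by a 1x1 pointwise projection to `out_channels` ("same" padding,
#' bias-free, Glorot/Xavier initialized). The block itself is linear; the
#' network applies a swish activation after it.
#'
#' @param in_channels,out_channels positive integers.
#' @param kernel_size depthwise kernel size (default 3).
#' @param init_scheme initializer for both factors.
#' @return object of class `dsc_block` with `params` (`dw`: `k*k x M`
#'   depthwise weights, `pw`: `M x N` pointwise weights) and a `layers`
#'   description of the op sequence.
#' @export
build_dsc_block <- function(in_channels, out_channels, kernel_size = 3L,
                            init_scheme = "glorot_uniform") {
  M <- as.integer(in_channels); N <- as.integer(out_channels)
  k <- as.integer(kernel_size)
  if (M < 1 || N < 1) stop("invalid channel counts")
  dw <- init_dw_w(k, M, init_scheme)
  pw <- if (init_scheme == "he_normal") {
    matrix(he_normal_sample(init_spec("he_normal", fan_in = M), c(M, N)), M, N)
  } else {
    matrix(glorot_uniform_sample(
      init_spec("glorot_uniform", fan_in = M, fan_out = N), c(M, N)), M, N)
  }
  structure(list(params = list(dw = dw, pw = pw),
                 in_channels = M, out_channels = N, kernel_size = k,
                 layers = c(sprintf("depthwise_conv(%dx%d)", k, k),
                            "pointwise_conv(1x1)")),
            class = "dsc_block")
}

#' Forward pass of a DSC block
#'
#' @param block a [build_dsc_block()] result.
#' @param x `H x W x M` array or `H x W x M x N` batch.
#' @return array with `out_channels` channels, same spatial size.
#' @export
dsc_block_forward <- function(block, x) {
  squeeze <- length(dim(x)) == 3L
  x <- as_t4(x)
  h <- cpp_dwconv_fw(x, block$params$dw, block$kernel_size, 1L)
  y <- cpp_conv2d_fw(h, block$params$pw, 1L, 1L)
  if (squeeze) {
    d <- dim(y)
    y <- array(y, d[1:3])
  }
  y
}

#' Parameter count of a DSC block
#'
#' @param block a `dsc_block`.
#' @return integer number of trainable weights (bias-free).
#' @export
dsc_block_params <- function(block) {
  length(block$params$dw) + length(block$params$pw)
}

mdc_geometry <- function(mdc_mode, dilation_rates) {
  if (mdc_mode == "rates") {
    list(k = c(3L, 3L, 3L), r = as.integer(dilation_rates))
  } else {
    list(k = c(1L, 2L, 3L), r = c(1L, 1L, 1L))
  }
}

#' Build a multi-dilated convolution (MDC) block
#'
#' Three chained 3x3 dilated convolutions at increasing rates (default
#' 1, 2, 3), each followed by batch normalization and a swish activation.
#' The first convolution reads the block input; the second and third read the
#' concatenation of the block input with the previous dilated convolution's
#' output. He-normal initialized, bias-free.
#'
#' @param in_channels,out_channels positive integers.
#' @param rates dilation rates of the three convolutions.
#' @param mdc_mode see [model_config()].
#' @param init_scheme initializer name.
#' @return object of class `mdc_block` with `params`, per-conv batch-norm
#'   state, and a `layers` op-sequence description.
#' @export
build_mdc_block <- function(in_channels, out_channels, rates = c(1L, 2L, 3L),
                            mdc_mode = "rates", init_scheme = "he_normal") {
  M <- as.integer(in_channels); F <- as.integer(out_channels)
  if (M < 1 || F < 1 || length(rates) < 1) stop("invalid MDC config")
  geo <- mdc_geometry(mdc_mode, rates)
  sch <- if (init_scheme == "he_normal") "he_normal" else "glorot_uniform"
  params <- list()
  states <- list()
  layers <- character(0)
  for (i in 1:3) {
    cin <- if (i == 1L) M else M + F
    params[[sprintf("c%d.w", i)]] <- init_conv_w(geo$k[i], cin, F, sch)
    params[[sprintf("bn%d.g", i)]] <- rep(1, F)
    params[[sprintf("bn%d.b", i)]] <- rep(0, F)
    st <- new.env(parent = emptyenv())
    st$mean <- rep(0, F); st$var <- rep(1, F)
    states[[sprintf("bn%d", i)]] <- st
    layers <- c(layers,
                sprintf("dilated_conv(%dx%d, rate=%d)", geo$k[i], geo$k[i],
                        geo$r[i]),
                "batch_norm", "swish")
  }
  structure(list(params = params, states = states,
                 in_channels = M, out_channels = F,
                 kernels = geo$k, rates = geo$r, layers = layers),
            class = "mdc_block")
}

#' Forward pass of an MDC block (inference mode)
#'
#' @param block a [build_mdc_block()] result.
#' @param x `H x W x M` array or `H x W x M x N` batch.
#' @return array with `out_channels` channels, same spatial size.
#' @export
mdc_block_forward <- function(block, x) {
  squeeze <- length(dim(x)) == 3L
  x <- as_t4(x)
  tape <- ad_tape(training = FALSE)
  xn <- ad_input(tape, x)
  h <- mdc_wire(tape, xn, block$params, block$states, block$kernels,
                block$rates, name_prefix = NULL)
  y <- h$value
  if (squeeze) y <- array(y, dim(y)[1:3])
  y
}

# wire an MDC block onto a tape; params fetched from `params` (plain list) or
# recorded as tape params when name_prefix is given via `getp`
mdc_wire <- function(tape, xn, params, states, kernels, rates,
                     name_prefix = NULL, getp = NULL) {
  if (is.null(getp)) {
    getp <- function(nm) ad_input(tape, params[[nm]])
  }
  h <- NULL
  for (i in 1:3) {
    inp <- if (i == 1L) xn else ad_concat(tape, list(xn, h))
    z <- ad_conv2d(tape, inp, getp(sprintf("c%d.w", i)), kernels[i], rates[i])
    z <- ad_batchnorm(tape, z, getp(sprintf("bn%d.g", i)),
                      getp(sprintf("bn%d.b", i)), states[[sprintf("bn%d", i)]])
    h <- ad_swish(tape, z)
  }
  h
}

# ---- full model -------------------------------------------------------------

enc_in_channels <- function(config) {
  nlev <- length(config$filter_ladder)
  ins <- integer(nlev)
  ins[1] <- config$in_channels
  if (nlev > 1) {
    for (i in 2:nlev) ins[i] <- 3L * config$filter_ladder[i - 1]
  }
  ins
}

#' Build the full segmentation model
#'
#' Instantiates all weights (drawn from R's RNG: a fixed global seed makes
#' two freshly built models identical) and the batch-normalization running
#' state. See the package vignette for the wiring.
#'
#' @param config a [model_config()].
#' @return object of class `lesionseg_model` with `params` (flat named list
#'   of weight arrays), `bn` (running batch-norm states) and the config.
#' @export
build_model <- function(config = model_config()) {
  stopifnot(inherits(config, "model_config"))
  reg_sch <- if (config$init_scheme == "paper") "he_normal" else "glorot_uniform"
  sep_sch <- "glorot_uniform"
  ladder <- config$filter_ladder
  nlev <- length(ladder)
  ins <- enc_in_channels(config)
  geo <- mdc_geometry(config$mdc_mode, config$dilation_rates)

  params <- list()
  bn <- list()
  add_mdc <- function(prefix, M, F) {
    blk <- build_mdc_block(M, F, config$dilation_rates, config$mdc_mode,
                           reg_sch)
    for (nm in names(blk$params)) params[[paste0(prefix, ".", nm)]] <<-
      blk$params[[nm]]
    for (nm in names(blk$states)) bn[[paste0(prefix, ".", nm)]] <<-
      blk$states[[nm]]
  }
  add_dsc <- function(prefix, M, F) {
    if (config$use_separable) {
      blk <- build_dsc_block(M, F, 3L, sep_sch)
      params[[paste0(prefix, ".dw")]] <<- blk$params$dw
      params[[paste0(prefix, ".pw")]] <<- blk$params$pw
    } else {
      params[[paste0(prefix, ".w")]] <<- init_conv_w(3L, M, F, reg_sch)
    }
  }
  stage_widths <- 3L * ladder
  for (i in seq_len(nlev)) {
    pre <- sprintf("enc%d", i)
    params[[paste0(pre, ".rc.w")]] <- init_conv_w(1L, ins[i], ladder[i],
                                                  reg_sch)
    add_dsc(paste0(pre, ".dsc"), ins[i], ladder[i])
    add_mdc(paste0(pre, ".mdc"), ins[i], ladder[i])
  }
  bin <- stage_widths[nlev]
  bf <- config$bottleneck_filters
  params[["bott.rc.w"]] <- init_conv_w(1L, bin, bf, reg_sch)
  add_dsc("bott.dsc", bin, bf)
  add_mdc("bott.mdc", bin, bf)

  up_in <- 3L * bf
  for (i in rev(seq_len(nlev))) {
    pre <- sprintf("dec%d", i)
    params[[paste0(pre, ".up.w")]] <- init_conv_w(3L, up_in, ladder[i],
                                                  reg_sch)
    cat_w <- ladder[i] + stage_widths[i]
    add_mdc(paste0(pre, ".mdc"), cat_w, ladder[i])
    add_dsc(paste0(pre, ".dsc"), ladder[i], ladder[i])
    up_in <- ladder[i]
  }
  params[["head.w"]] <- init_conv_w(1L, ladder[1], 1L, reg_sch)

  structure(list(config = config, params = params, bn = bn,
                 mdc_kernels = geo$k, mdc_rates = geo$r),
            class = "lesionseg_model")
}

# wire the whole network on a tape; returns prob/logits nodes and layer shapes
net_forward <- function(model, xnode, tape, as_params = FALSE) {
  cfg <- model$config
  ladder <- cfg$filter_ladder
  nlev <- length(ladder)
  kk <- model$mdc_kernels; rr <- model$mdc_rates
  shapes <- list()
  getp <- function(nm) {
    if (as_params) ad_param(tape, model$params[[nm]], nm)
    else ad_input(tape, model$params[[nm]])
  }
  branch3 <- function(x, prefix) {
    a <- ad_maxpool3(tape, ad_relu(tape, ad_conv2d(
      tape, x, getp(paste0(prefix, ".rc.w")), 1L)))
    d <- if (cfg$use_separable) {
      ad_conv2d(tape, ad_dwconv(tape, x, getp(paste0(prefix, ".dsc.dw")), 3L),
                getp(paste0(prefix, ".dsc.pw")), 1L)
    } else {
      ad_conv2d(tape, x, getp(paste0(prefix, ".dsc.w")), 3L)
    }
    d <- ad_swish(tape, d)
    st <- stats::setNames(model$bn[paste0(prefix, ".mdc.bn", 1:3)],
                          paste0("bn", 1:3))
    m <- mdc_wire(tape, x, NULL, st, kk, rr,
                  getp = function(nm) getp(paste0(prefix, ".mdc.", nm)))
    ad_concat(tape, list(a, d, m))
  }
  x <- xnode
  skips <- vector("list", nlev)
  for (i in seq_len(nlev)) {
    pre <- sprintf("enc%d", i)
    s <- branch3(x, pre)
    skips[[i]] <- s
    shapes[[paste0(pre, ".concat")]] <- dim(s$value)
    x <- ad_dropout(tape, ad_maxpool2(tape, s), cfg$dropout_rate)
    shapes[[paste0(pre, ".pool")]] <- dim(x$value)
  }
  x <- branch3(x, "bott")
  shapes[["bottleneck"]] <- dim(x$value)
  for (i in rev(seq_len(nlev))) {
    pre <- sprintf("dec%d", i)
    up <- ad_tconv(tape, x, getp(paste0(pre, ".up.w")))
    shapes[[paste0(pre, ".up")]] <- dim(up$value)
    cat <- ad_concat(tape, list(up, skips[[i]]))
    st <- stats::setNames(model$bn[paste0(pre, ".mdc.bn", 1:3)],
                          paste0("bn", 1:3))
    m <- mdc_wire(tape, cat, NULL, st, kk, rr,
                  getp = function(nm) getp(paste0(pre, ".mdc.", nm)))
    d <- if (cfg$use_separable) {
      ad_conv2d(tape, ad_dwconv(tape, m, getp(paste0(pre, ".dsc.dw")), 3L),
                getp(paste0(pre, ".dsc.pw")), 1L)
    } else {
      ad_conv2d(tape, m, getp(paste0(pre, ".dsc.w")), 3L)
    }
    x <- ad_swish(tape, d)
    shapes[[paste0(pre, ".out")]] <- dim(x$value)
  }
  logits <- ad_conv2d(tape, x, getp("head.w"), 1L)
  prob <- ad_sigmoid(tape, logits)
  shapes[["head"]] <- dim(prob$value)
  list(prob = prob, logits = logits, shapes = shapes)
}

#' Forward pass of the segmentation model
#'
#' @param model a [build_model()] result.
#' @param x `H x W x C` image or `H x W x C x N` batch with values in `[0,1]`.
#' @param training use batch statistics and dropout (default FALSE).
#' @return per-pixel lesion probability map(s): `H x W` matrix for a single
#'   image, `H x W x 1 x N` array for a batch.
#' @export
model_forward <- function(model, x, training = FALSE) {
  squeeze <- length(dim(x)) == 3L
  tape <- ad_tape(training = training)
  out <- net_forward(model, ad_input(tape, as_t4(x)), tape)
  p <- out$prob$value
  if (squeeze) p <- matrix(p, dim(p)[1], dim(p)[2])
  p
}

#' Count trainable parameters of a model
#'
#' @param model a `lesionseg_model`.
#' @return integer total weight count (bias-free layers throughout).
#' @export
count_params <- function(model) {
  sum(vapply(model$params, length, integer(1)))
}

#' Summarize a built model
#'
#' Runs a forward pass on a zero input at the configured size and reports
#' per-layer output shapes, the bottleneck spatial size and the total
#' trainable parameter count; asserts that the decoder restores the input
#' resolution.
#'
#' @param model a `lesionseg_model`.
#' @return object of class `network_summary`.
#' @export
summarize <- function(model) {
  cfg <- model$config
  s <- cfg$input_size
  x <- array(0, c(s, s, cfg$in_channels, 1L))
  tape <- ad_tape(training = FALSE)
  out <- net_forward(model, ad_input(tape, x), tape)
  shp <- out$shapes
  stopifnot(identical(shp$head[1:2], c(s, s)))
  structure(list(shapes = shp,
                 total_parameters = count_params(model),
                 bottleneck_spatial = shp$bottleneck[1:2],
                 n_pool_layers = length(cfg$filter_ladder)),
            class = "network_summary")
}

#' @export
print.network_summary <- function(x, ...) {
  cat("layer\tshape\n")
  for (nm in names(x$shapes)) {
    cat(sprintf("%s\t%s\n", nm, paste(x$shapes[[nm]], collapse = "x")))
  }
  cat(sprintf("total_parameters\t%d\n", x$total_parameters))
  cat(sprintf("bottleneck_spatial\t%s\n",
              paste(x$bottleneck_spatial, collapse = "x")))
  invisible(x)
}

#' Save / load model weights
#'
#' Serializes the weights, batch-norm running state and config to an `.rds`
#' checkpoint.
#'
#' @param model a `lesionseg_model`.
#' @param path file path.
#' @return `save_model` returns `path` invisibly; `load_model` the model.
#' @export
save_model <- function(model, path) {
  bn <- lapply(model$bn, function(st) list(mean = st$mean, var = st$var))
  saveRDS(list(config = model$config, params = model$params, bn = bn,
               mdc_kernels = model$mdc_kernels, mdc_rates = model$mdc_rates),
          path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  obj <- readRDS(path)
  bn <- lapply(obj$bn, function(st) {
    e <- new.env(parent = emptyenv())
    e$mean <- st$mean; e$var <- st$var
    e
  })
  structure(list(config = obj$config, params = obj$params, bn = bn,
                 mdc_kernels = obj$mdc_kernels, mdc_rates = obj$mdc_rates),
            class = "lesionseg_model")
}
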