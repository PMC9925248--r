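#' Convolution specification
#'
#' Describes one square-kernel convolution applied to an `H x W` feature map
#' with `M` input and `N` output channels, optionally dilated at rate `r`.
#' Drives the parameter and multiply-add accounting that motivates the use of
#' depthwise-separable convolutions in the network.
#'
#' @param kernel_size positive integer `k` (kernel is `k x k`).
#' @param in_channels positive integer `M`.
#' @param out_channels positive integer `N`.
#' @param height,width positive integers; spatial extent of the input map.
#' @param stride positive integer (default 1).
#' @param dilation_rate positive integer `r` (default 1). The effective kernel
#'   extent `k + (k-1)(r-1)` must fit inside `min(height, width)`.
#' @return object of class `conv_spec`.
#' @export
conv_spec <- function(kernel_size, in_channels, out_channels,
                      height = 256L, width = 256L, stride = 1L,
                      dilation_rate = 1L) {
  f <- c(kernel_size = kernel_size, in_channels = in_channels,
         out_channels = out_channels, height = height, width = width,
         stride = stride, dilation_rate = dilation_rate)
  if (any(!is.finite(f)) || any(f < 1) || any(f != round(f))) {
    stop("invalid conv spec: all fields must be positive integers")
  }
  k <- kernel_size; r <- dilation_rate
  if (k + (k - 1) * (r - 1) > min(height, width)) {
    stop("invalid conv spec: effective kernel extent exceeds input")
  }
  structure(as.list(as.integer(f)), class = "conv_spec",
            names = names(f))
}

new_param_count <- function(parameters, mult_adds) {
  structure(list(parameters = parameters, mult_adds = mult_adds),
            class = "param_count")
}

#' @export
print.param_count <- function(x, ...) {
  cat(sprintf("parameters\t%.0f\nmult_adds\t%.0f\n", x$parameters,
              x$mult_adds))
  invisible(x)
}

#' Parameter and cost accounting for a standard convolution
#'
#' For a `k x k` convolution with `M` input and `N` output channels on an
#' `H x W` map: `k*k*M*N` weights and `k*k*M*N*H*W` multiply-adds. Bias terms
#' are excluded (only kernel weights are counted).
#'
#' @param spec a [conv_spec()].
#' @return a `param_count` with fields `parameters` and `mult_adds`.
#' @export
standard_conv_params <- function(spec) {
  stopifnot(inherits(spec, "conv_spec"))
  p <- with(spec, kernel_size^2 * in_channels * out_channels)
  new_param_count(p, p * spec$height * spec$width)
}

#' Parameter and cost accounting for a depthwise-separable convolution
#'
#' Depthwise (`k*k*M` weights) plus pointwise (`M*N` weights); multiply-adds
#' `k*k*M*H*W + M*N*H*W`. Bias-free, as for [standard_conv_params()].
#'
#' @inheritParams standard_conv_params
#' @return a `param_count`.
#' @export
separable_conv_params <- function(spec) {
  stopifnot(inherits(spec, "conv_spec"))
  hw <- spec$height * spec$width
  pd <- spec$kernel_size^2 * spec$in_channels
  pp <- spec$in_channels * spec$out_channels
  new_param_count(pd + pp, (pd + pp) * hw)
}

#' Separable-to-standard parameter ratio
#'
#' Returns `(k^2 M + M N)/(k^2 M N) = 1/N + 1/k^2`, the fraction of a standard
#' convolution's weights that the separable factorization needs. For `k = 3`
#' its reciprocal approaches 9 from below as `N` grows, i.e. the separable
#' form has "about 8 to 9 times" fewer parameters.
#'
#' @inheritParams standard_conv_params
#' @return a single numeric fraction.
#' @export
param_ratio <- function(spec) {
  stopifnot(inherits(spec, "conv_spec"))
  1 / spec$out_channels + 1 / spec$kernel_size^2
}

as_grid3 <- function(x) {
  d <- dim(x)
  if (is.null(d)) stop("input must be a matrix or 3-d array")
  if (length(d) == 2L) dim(x) <- c(d, 1L)
  if (length(dim(x)) != 3L) stop("input must be H x W (x C)")
  x
}

#' Naive depthwise convolution reference
#'
#' Brute-force nested-loop cross-correlation: channel `m` of the output is
#' channel `m` of the input filtered with `kernels[, , m]` under "same" zero
#' padding and stride 1. Deliberately simple; serves as the oracle for the
#' fast network layers.
#'
#' @param input `H x W x M` array (an `H x W` matrix is treated as 1 channel).
#' @param kernels `k x k x M` array of per-channel kernels (or `k x k` matrix
#'   when `M = 1`), `k` odd.
#' @param rate dilation rate (default 1).
#' @return array of the same shape as `input`.
#' @export
depthwise_conv_ref <- function(input, kernels, rate = 1L) {
  x <- as_grid3(input)
  kk <- as_grid3(kernels)
  H <- dim(x)[1]; W <- dim(x)[2]; M <- dim(x)[3]
  k <- dim(kk)[1]
  if (dim(kk)[2] != k || k %% 2L == 0L) stop("kernels must be odd square")
  if (dim(kk)[3] != M) stop("kernel count must equal input channel count")
  if (k + (k - 1) * (rate - 1) > min(H, W)) stop("kernel extent exceeds input")
  c0 <- (k - 1) %/% 2
  out <- array(0, dim(x))
  for (m in seq_len(M)) {
    for (i in seq_len(H)) {
      for (j in seq_len(W)) {
        acc <- 0
        for (ki in seq_len(k)) {
          for (kj in seq_len(k)) {
            ii <- i + rate * (ki - 1L - c0)
            jj <- j + rate * (kj - 1L - c0)
            if (ii >= 1 && ii <= H && jj >= 1 && jj <= W) {
              acc <- acc + kk[ki, kj, m] * x[ii, jj, m]
            }
          }
        }
        out[i, j, m] <- acc
      }
    }
  }
  if (length(dim(input)) == 2L) out <- out[, , 1]
  out
}

#' Naive pointwise (1x1) convolution reference
#'
#' Each pixel's channel vector is multiplied by the `M x N` weight matrix;
#' spatial dimensions preserved.
#'
#' @param input `H x W x M` array.
#' @param weights `M x N` matrix.
#' @return `H x W x N` array.
#' @export
pointwise_conv_ref <- function(input, weights) {
  x <- as_grid3(input)
  w <- as.matrix(weights)
  H <- dim(x)[1]; W <- dim(x)[2]; M <- dim(x)[3]
  if (nrow(w) != M) stop("weights first dimension must equal input channels")
  N <- ncol(w)
  out <- array(0, c(H, W, N))
  for (i in seq_len(H)) {
    for (j in seq_len(W)) {
      out[i, j, ] <- as.numeric(x[i, j, ] %*% w)
    }
  }
  out
}

#' Naive dilated (atrous) convolution reference
#'
#' Single `k x k` kernel with taps spaced `rate` pixels apart
#' (`y[i] = sum_k x[i + r k] w[k]`), applied to every channel independently,
#' "same" zero padding. `rate = 1` reproduces a standard convolution exactly.
#'
#' @param input `H x W` matrix or `H x W x C` array.
#' @param kernel `k x k` matrix, `k` odd.
#' @param rate positive integer dilation rate.
#' @return same shape as `input`.
#' @export
dilated_conv_ref <- function(input, kernel, rate) {
  x <- as_grid3(input)
  M <- dim(x)[3]
  kk <- array(kernel, c(dim(kernel), M))
  for (m in seq_len(M)) kk[, , m] <- kernel
  out <- depthwise_conv_ref(x, kk, rate = rate)
  if (length(dim(input)) == 2L) out <- out[, , 1]
  out
}

#' Naive depthwise-separable convolution reference
#'
#' Depthwise filtering followed by pointwise projection, fully nested-loop.
#'
#' @param input `H x W x M` array.
#' @param kernels `k x k x M` depthwise kernels.
#' @param weights `M x N` pointwise weights.
#' @return `H x W x N` array.
#' @export
separable_conv_ref <- function(input, kernels, weights) {
  pointwise_conv_ref(depthwise_conv_ref(input, kernels), weights)
}

#' Effective extent of a dilated kernel
#'
#' `k + (k-1)(r-1)`: the span in input pixels covered by a `k x k` kernel
#' dilated at rate `r`.
#'
#' @param kernel_size positive integer `k`.
#' @param rate positive integer `r`.
#' @return integer extent.
#' @export
effective_kernel_extent <- function(kernel_size, rate) {
  as.integer(kernel_size + (kernel_size - 1) * (rate - 1))
}
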