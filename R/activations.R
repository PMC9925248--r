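#' Sigmoid function
#'
#' \eqn{\sigma(x) = 1/(1+e^{-x})}, computed in a numerically stable split so
#' large negative inputs do not overflow `exp`.
#'
#' @param x numeric vector/array.
#' @return same shape as `x`.
#' @export
sigmoid <- function(x) {
  out <- x
  pos <- !is.na(x) & x >= 0
  out[pos] <- 1 / (1 + exp(-x[pos]))
  ex <- exp(x[!pos])
  out[!pos] <- ex / (1 + ex)
  out
}

#' Swish activation
#'
#' \eqn{f(x) = x\,\sigma(x)}. Smooth, non-monotonic (it dips below zero for
#' moderately negative inputs), bounded below and unbounded above. Used after
#' every dilated convolution in the MDC blocks and after the separable
#' convolution blocks of the segmentation network.
#'
#' @param x numeric vector or array; applied elementwise.
#' @return same shape as `x`.
#' @examples
#' swish(0)        # 0
#' swish(1)        # ~0.731
#' @export
swish <- function(x) x * sigmoid(x)

#' Derivative of the swish activation
#'
#' Closed form \eqn{f'(x) = f(x) + \sigma(x)(1 - f(x))} with
#' \eqn{f(x) = x\sigma(x)}; equals 0.5 at the origin and tends to 1 as
#' \eqn{x \to +\infty}. This exact form is what the network's backward pass
#' uses; tests check it against finite differences.
#'
#' @inheritParams swish
#' @return same shape as `x`.
#' @export
swish_derivative <- function(x) {
  s <- sigmoid(x)
  f <- x * s
  f + s * (1 - f)
}

#' Weight-initialization specification
#'
#' Bundles the scheme and fan sizes for the two initializers used by the
#' network: He-normal (regular and dilated convolutions) and Glorot/Xavier
#' uniform (depthwise-separable convolutions).
#'
#' @param scheme `"he_normal"` or `"glorot_uniform"`.
#' @param fan_in positive integer; number of inputs feeding one unit.
#' @param fan_out positive integer; number of outputs (used by Glorot only).
#' @param seed optional integer seed for reproducible draws.
#' @return an object of class `init_spec`.
#' @export
init_spec <- function(scheme = c("he_normal", "glorot_uniform"),
                      fan_in, fan_out = fan_in, seed = NULL) {
  scheme <- match.arg(scheme)
  fan_in <- as.integer(fan_in); fan_out <- as.integer(fan_out)
  if (is.na(fan_in) || fan_in < 1L) stop("fan_in must be a positive integer")
  if (is.na(fan_out) || fan_out < 1L) stop("fan_out must be a positive integer")
  structure(list(scheme = scheme, fan_in = fan_in, fan_out = fan_out,
                 seed = seed), class = "init_spec")
}

with_opt_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}

#' He-normal weight sample
#'
#' Draws i.i.d. Gaussian weights with mean 0 and standard deviation
#' \eqn{\sqrt{2/n}} where `n` is the fan-in; the scheme used for the regular
#' and multi-dilated convolutions of the network.
#'
#' @param spec an [init_spec()] with `scheme = "he_normal"`.
#' @param shape integer vector of array dimensions.
#' @return numeric array of dimension `shape`.
#' @export
he_normal_sample <- function(spec, shape) {
  stopifnot(inherits(spec, "init_spec"))
  if (spec$scheme != "he_normal") stop("spec scheme is not he_normal")
  n <- prod(shape)
  v <- with_opt_seed(spec$seed, stats::rnorm(n, 0, sqrt(2 / spec$fan_in)))
  array(v, dim = shape)
}

#' Glorot (Xavier) uniform weight sample
#'
#' Draws i.i.d. uniform weights on \eqn{[-L, L]} with
#' \eqn{L = \sqrt{6/(F_{in}+F_{out})}}; the scheme used for the
#' depthwise-separable convolutions of the network.
#'
#' @param spec an [init_spec()] with `scheme = "glorot_uniform"`.
#' @param shape integer vector of array dimensions.
#' @return numeric array of dimension `shape`.
#' @export
glorot_uniform_sample <- function(spec, shape) {
  stopifnot(inherits(spec, "init_spec"))
  if (spec$scheme != "glorot_uniform") stop("spec scheme is not glorot_uniform")
  lim <- sqrt(6 / (spec$fan_in + spec$fan_out))
  n <- prod(shape)
  v <- with_opt_seed(spec$seed, stats::runif(n, -lim, lim))
  array(v, dim = shape)
}
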