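# Shared test utilities: brute-force oracles kept deliberately independent of
# the package's fast code paths.

ns <- asNamespace("lesionseg")

# full standard convolution reference built from nested loops only:
# y[,,f] = sum_m correlate(x[,,m], w[,,m,f]) at the given dilation rate
full_conv_ref <- function(x, w, rate = 1L) {
  d <- dim(w) # k, k, M, F
  M <- d[3]; F <- d[4]
  out <- array(0, c(dim(x)[1], dim(x)[2], F))
  for (f in seq_len(F)) {
    dc <- depthwise_conv_ref(x, w[, , , f, drop = TRUE], rate = rate)
    if (length(dim(dc)) == 2L) dc <- array(dc, c(dim(dc), 1L))
    out[, , f] <- apply(dc, c(1, 2), sum)
  }
  out
}

# batch-norm inference transform with fresh running state (mean 0, var 1)
bn_fresh_ref <- function(x, gamma, beta, eps = 1e-3) {
  out <- x
  for (c in seq_len(dim(x)[3])) {
    out[, , c] <- gamma[c] * x[, , c] / sqrt(1 + eps) + beta[c]
  }
  out
}

rand_image <- function(h, w, c, seed) {
  set.seed(seed)
  array(stats::runif(h * w * c), c(h, w, c))
}

tiny_model_config <- function() {
  model_config(input_size = 16L, filter_ladder = c(2L, 3L),
                bottleneck_filters = 4L, dropout_rate = 0)
}
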