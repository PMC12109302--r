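# Multi-scale CNN: two parallel branches per modality (a long-kernel,
# large-stride filter bank and a short-kernel, small-stride one), each
# conv -> ReLU -> maxpool(4) -> conv -> ReLU -> maxpool(4); the branch
# outputs are adaptively max-pooled to a common number of time steps and
# concatenated along the channel axis.

#' Output length of a valid strided convolution
#'
#' `floor((L - K) / stride) + 1`, the temporal length after convolving a
#' length-`L` signal with a length-`K` kernel at the given stride.
#'
#' @param L input length. @param K kernel length. @param stride stride.
#' @return Integer output length.
#' @export
conv_out_len <- function(L, K, stride) as.integer((L - K) %/% stride + 1L)

#' Multi-scale CNN configuration
#'
#' @param large,small first-layer filter banks: list with `kernel`,
#'   `stride`, `filters`. Defaults: kernel 50 / stride 20 and kernel
#'   20 / stride 5, 64 filters each.
#' @param pool max-pooling window after every convolution (default 4).
#' @param conv2 shared shape of each branch's second convolution
#'   (default kernel 8, stride 1, 64 filters).
#' @param input_len samples per epoch (default 3000 = 30 s at 100 Hz).
#' @return List of class `mscnn_config`. The derived per-branch lengths and
#'   the aligned length `t_out` are precomputed.
#' @export
mscnn_config <- function(large = list(kernel = 50L, stride = 20L, filters = 64L),
                         small = list(kernel = 20L, stride = 5L, filters = 64L),
                         pool = 4L,
                         conv2 = list(kernel = 8L, stride = 1L, filters = 64L),
                         input_len = 3000L) {
  branch_len <- function(br) {
    l1 <- conv_out_len(input_len, br$kernel, br$stride)
    p1 <- l1 %/% pool
    l2 <- conv_out_len(p1, conv2$kernel, conv2$stride)
    c(conv1 = l1, pool1 = p1, conv2 = l2, pool2 = l2 %/% pool)
  }
  lens <- list(large = branch_len(large), small = branch_len(small))
  structure(list(large = large, small = small, pool = as.integer(pool),
                 conv2 = conv2, input_len = as.integer(input_len),
                 lengths = lens,
                 t_out = min(lens$large["pool2"], lens$small["pool2"]),
                 channels_out = 2L * conv2$filters),
            class = "mscnn_config")
}

mscnn_branch_params <- function(br, conv2) {
  he <- function(cin, k, cout) {
    array(stats::rnorm(cin * k * cout, 0, sqrt(2 / (cin * k))), c(cin, k, cout))
  }
  list(conv1 = list(w = he(1L, br$kernel, br$filters), b = numeric(br$filters)),
       conv2 = list(w = he(br$filters, conv2$kernel, conv2$filters),
                    b = numeric(conv2$filters)))
}

mscnn_params <- function(cfg) {
  list(large = mscnn_branch_params(cfg$large, cfg$conv2),
       small = mscnn_branch_params(cfg$small, cfg$conv2))
}

# fused in C++: conv -> ReLU -> pool -> conv -> ReLU -> pool -> adaptive
# pool; intermediate activations stay on the C++ side between passes
mscnn_branch_forward <- function(x, bp, br, cfg, keep_cache = TRUE) {
  branch_fwd_cpp(x, bp$conv1$w, bp$conv1$b, br$stride,
                 bp$conv2$w, bp$conv2$b, cfg$conv2$stride,
                 cfg$pool, cfg$t_out, keep_cache)
}

# the input gradient is not propagated past the first convolution (signals
# are the network input), so only parameter gradients come back
mscnn_branch_backward <- function(dy, cache, bp, br, cfg) {
  g <- branch_bwd_cpp(dy, cache$cache, bp$conv1$w, br$stride, bp$conv2$w,
                      cfg$conv2$stride)
  list(grads = list(conv1 = list(w = g$dw1, b = g$db1),
                    conv2 = list(w = g$dw2, b = g$db2)))
}

#' Multi-scale CNN forward pass for one modality
#'
#' @param x batch of epoch signals: a `B x input_len` matrix (one row per
#'   epoch) or a `1 x input_len x B` cube.
#' @param params branch parameters as produced by the model initialiser.
#' @param cfg an [mscnn_config()].
#' @return Feature cube `channels_out x t_out x B` (scales concatenated
#'   along the channel axis). Use the internal cache-returning variant for
#'   training.
#' @export
mscnn_forward <- function(x, params, cfg = mscnn_config()) {
  if (is.matrix(x)) {
    if (ncol(x) != cfg$input_len) stop("epoch length ", ncol(x),
                                       " != expected ", cfg$input_len)
    x <- as_cube(t(x), 1L, cfg$input_len, nrow(x))
  }
  mscnn_forward_cached(x, params, cfg)$y
}

mscnn_forward_cached <- function(x, params, cfg) {
  bl <- mscnn_branch_forward(x, params$large, cfg$large, cfg)
  bs <- mscnn_branch_forward(x, params$small, cfg$small, cfg)
  cl <- dim(bl$y)[1]
  y <- array(0, c(cl + dim(bs$y)[1], cfg$t_out, dim(x)[3]))
  y[seq_len(cl), , ] <- bl$y
  y[cl + seq_len(dim(bs$y)[1]), , ] <- bs$y
  list(y = y, large = bl, small = bs, c_large = cl)
}

mscnn_backward <- function(dy, cache, params, cfg) {
  cl <- cache$c_large
  gl <- mscnn_branch_backward(dy[seq_len(cl), , , drop = FALSE],
                              cache$large, params$large, cfg$large, cfg)
  gs <- mscnn_branch_backward(dy[cl + seq_len(dim(dy)[1] - cl), , , drop = FALSE],
                              cache$small, params$small, cfg$small, cfg)
  list(grads = list(large = gl$grads, small = gs$grads))
}
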