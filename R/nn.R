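# Small neural-network primitives on channels x time x batch cubes and
# features x batch matrices, each with a matching backward pass. The heavy
# convolution / pooling kernels live in src/layers.cpp; everything here is
# cheap glue.

as_cube <- function(x, d1, d2, d3) { dim(x) <- c(d1, d2, d3); x }

conv1d_forward <- function(x, w, b, stride) conv1d_fwd_cpp(x, w, b, stride)
conv1d_backward <- function(x, w, dy, stride) conv1d_bwd_cpp(x, w, dy, stride)

relu_forward <- function(x) {
  y <- x
  y[y < 0] <- 0
  y
}
relu_backward <- function(dy, x) {
  dy[x <= 0] <- 0
  dy
}

# max-pool over time with non-overlapping windows; remainder steps dropped
maxpool_forward <- function(x, window) {
  s <- dim(x)[2] %/% window
  starts <- as.integer((seq_len(s) - 1L) * window + 1L)
  segment_pool_fwd_cpp(x, starts, starts + as.integer(window) - 1L)
}

# pool to a fixed number of output steps with near-equal segments
adaptive_maxpool_forward <- function(x, t_out) {
  t_in <- dim(x)[2]
  starts <- as.integer(floor((seq_len(t_out) - 1L) * t_in / t_out)) + 1L
  ends <- as.integer(ceiling(seq_len(t_out) * t_in / t_out))
  segment_pool_fwd_cpp(x, starts, ends)
}

pool_backward <- function(dy, idx, t_in) segment_pool_bwd_cpp(dy, idx, t_in)

dense_forward <- function(x, w, b) w %*% x + as.vector(b)
dense_backward <- function(dy, x, w) {
  list(dx = crossprod(w, dy), dw = tcrossprod(dy, x), db = rowSums(dy))
}

sigmoid <- function(x) 1 / (1 + exp(-x))

# layer normalisation over the feature axis (rows) of a D x N matrix,
# with learnable affine gamma/beta
layernorm_forward <- function(x, gamma, beta, eps = 1e-5) {
  mu <- colMeans(x)
  xc <- sweep(x, 2, mu)
  v <- colMeans(xc^2)
  inv <- 1 / sqrt(v + eps)
  xhat <- sweep(xc, 2, inv, `*`)
  list(y = xhat * gamma + beta, xhat = xhat, inv = inv)
}
layernorm_backward <- function(dy, cache, gamma) {
  xhat <- cache$xhat
  d <- nrow(xhat)
  dxhat <- dy * gamma
  # standard layer-norm gradient: project out the mean and the xhat component
  dx <- sweep(dxhat - rep(colMeans(dxhat), each = d) -
                xhat * rep(colMeans(dxhat * xhat), each = d),
              2, cache$inv, `*`)
  list(dx = dx, dgamma = rowSums(dy * xhat), dbeta = rowSums(dy))
}

softmax_cols <- function(z) {
  z <- sweep(z, 2, apply(z, 2, max))
  e <- exp(z)
  sweep(e, 2, colSums(e), `/`)
}

# class-weighted cross-entropy on logits (K x B); labels are 0-based codes.
# Loss is the weighted mean  sum_b w[y_b] * (-log p[y_b]) / sum_b w[y_b].
weighted_ce_forward <- function(logits, labels, class_weights) {
  p <- softmax_cols(logits)
  b <- ncol(logits)
  sel <- cbind(labels + 1L, seq_len(b))
  w <- class_weights[labels + 1L]
  wsum <- sum(w)
  loss <- sum(w * -log(pmax(p[sel], 1e-12))) / wsum
  dlogits <- p
  dlogits[sel] <- dlogits[sel] - 1
  dlogits <- sweep(dlogits, 2, w / wsum, `*`)
  list(loss = loss, probs = p, dlogits = dlogits)
}

dropout_forward <- function(x, rate, training) {
  if (!training || rate <= 0) return(list(y = x, mask = NULL))
  mask <- (stats::runif(length(x)) >= rate) / (1 - rate)
  dim(mask) <- dim(x)
  list(y = x * mask, mask = mask)
}
dropout_backward <- function(dy, mask) if (is.null(mask)) dy else dy * mask

# ---- parameter containers -------------------------------------------------

flatten_params <- function(p) unlist(p, use.names = FALSE)

unflatten_params <- function(vec, skeleton) {
  pos <- 0L
  walk <- function(node) {
    if (is.list(node)) return(lapply(node, walk))
    n <- length(node)
    out <- vec[(pos + 1L):(pos + n)]
    pos <<- pos + n
    attributes(out) <- attributes(node)
    out
  }
  out <- walk(skeleton)
  stopifnot(pos == length(vec))
  out
}

n_params <- function(p) length(flatten_params(p))

# map over all leaf arrays of two parameter trees
map2_params <- function(a, b, f) {
  if (is.list(a)) return(mapply(map2_params, a, b, MoreArgs = list(f = f),
                                SIMPLIFY = FALSE))
  out <- f(a, b)
  attributes(out) <- attributes(a)
  out
}

zeros_like <- function(p) {
  if (is.list(p)) return(lapply(p, zeros_like))
  out <- numeric(length(p))
  attributes(out) <- attributes(p)
  out
}
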