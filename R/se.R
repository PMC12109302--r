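# Squeeze-and-excitation channel attention on channels x time x batch
# feature cubes: global average pooling over time (squeeze), a two-layer
# bottleneck gating network (excite), then per-channel rescaling.

#' Squeeze: global average pooling over time
#'
#' Compresses each channel of a feature map to its temporal mean, the 1-D
#' specialisation of spatial global average pooling.
#'
#' @param U feature cube, channels x time x batch.
#' @return Matrix channels x batch of per-channel means.
#' @export
se_squeeze <- function(U) {
  d <- dim(U)
  colSums(aperm(U, c(2, 1, 3))) / d[2]
}

#' Excite: channel gating weights
#'
#' `s = sigmoid(W2 %*% relu(W1 %*% z))`: a bottleneck of width `C / r`
#' followed by re-expansion, producing a weight strictly in (0, 1) per
#' channel.
#'
#' @param z squeeze output, channels x batch.
#' @param p list with matrices `W1` (`C/r x C`) and `W2` (`C x C/r`).
#' @return Matrix channels x batch of gating weights in (0, 1).
#' @export
se_excite <- function(z, p) {
  sigmoid(p$W2 %*% relu_forward(p$W1 %*% z))
}

#' Recalibrate: per-channel feature rescaling
#'
#' Multiplies every time step of channel `c` by its gating weight `s_c`.
#'
#' @param U feature cube, channels x time x batch.
#' @param s gating weights, channels x batch.
#' @return Cube of the same shape as `U`.
#' @export
se_recalibrate <- function(U, s) {
  U * expand_ct(s, dim(U)[2])
}

# expand a C x B matrix to a C x T x B cube by repeating over time
expand_ct <- function(s, t) {
  out <- s[, rep(seq_len(ncol(s)), each = t), drop = FALSE]
  dim(out) <- c(nrow(s), t, ncol(s))
  out
}

#' Construct SE parameters
#'
#' @param C channel count; must be divisible by `r`.
#' @param r reduction ratio (default 16).
#' @param init_sd standard deviation of the random normal initialisation;
#'   0 gives zero weights.
#' @return List with `W1` (`C/r x C`) and `W2` (`C x C/r`).
#' @export
se_params <- function(C, r = 16L, init_sd = NULL) {
  if (C %% r != 0) stop("channel count ", C, " not divisible by reduction ratio ", r)
  h <- C %/% r
  w <- function(nr, nc, sd) matrix(stats::rnorm(nr * nc, 0, sd), nr, nc)
  list(W1 = w(h, C, init_sd %||% sqrt(2 / C)),
       W2 = w(C, h, init_sd %||% sqrt(1 / h)))
}

se_forward <- function(U, p) {
  z <- se_squeeze(U)
  a1 <- p$W1 %*% z
  h <- relu_forward(a1)
  a2 <- p$W2 %*% h
  s <- sigmoid(a2)
  list(X = se_recalibrate(U, s), z = z, a1 = a1, h = h, s = s)
}

se_backward <- function(dX, U, p, cache) {
  d <- dim(U)
  s3 <- expand_ct(cache$s, d[2])
  dU <- dX * s3
  ds <- colSums(aperm(dX * U, c(2, 1, 3)))
  da2 <- ds * cache$s * (1 - cache$s)
  dW2 <- tcrossprod(da2, cache$h)
  dh <- crossprod(p$W2, da2)
  da1 <- relu_backward(dh, cache$a1)
  dW1 <- tcrossprod(da1, cache$z)
  dz <- crossprod(p$W1, da1)
  dU <- dU + expand_ct(dz / d[2], d[2])
  list(dU = dU, dW1 = dW1, dW2 = dW2)
}
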