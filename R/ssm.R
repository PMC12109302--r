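# State-space multimodal coupling. Each modality carries a hidden state
# through time; at every step the layer-normalised input is projected into
# the state space, states are first updated from the sum of all previous
# modality states (pre-activation pass), attention weights between the
# fresh states pick how much each modality listens to the others, and the
# update is recomputed with attention-weighted cross-modal mixing. The
# final states are projected to the output space and fused with learned
# per-modality weights.

#' Construct coupling-module parameters
#'
#' @param M number of modalities.
#' @param D input feature dimension (per time step).
#' @param H hidden state dimension.
#' @param d_out output dimension (default `D`).
#' @param use_A include an explicit per-modality self-transition through a
#'   shared state matrix `A` (default FALSE: the printed update uses only
#'   the modal correlation matrices).
#' @return List with `S` (list of `M` matrices `H x H`), `B` (`H x D`),
#'   `E` (`H x d_out`), `W` (length-`M` fusion weights), layer-norm
#'   affines `gamma` / `beta` (lists of length-`D` vectors) and optional `A`.
#' @export
ssm_params <- function(M, D, H, d_out = D, use_A = FALSE) {
  mat <- function(nr, nc, sd) matrix(stats::rnorm(nr * nc, 0, sd), nr, nc)
  p <- list(S = lapply(seq_len(M), function(i) mat(H, H, 0.5 / sqrt(H))),
            B = mat(H, D, sqrt(2 / (D + H))),
            E = mat(H, d_out, sqrt(2 / (H + d_out))),
            W = rep(1, M),
            gamma = lapply(seq_len(M), function(i) rep(1, D)),
            beta = lapply(seq_len(M), function(i) rep(0, D)))
  if (use_A) p$A <- mat(H, H, 0.5 / sqrt(H))
  p
}

#' Cross-modal attention weights
#'
#' Scaled-dot-product attention between the current hidden states of the
#' modalities: `alpha[n, m, b] = softmax_m(h_n . h_m / sqrt(H))`. Each row
#' over `m` sums to 1.
#'
#' @param h list of `M` hidden-state matrices (`H x B`).
#' @param score `"scaled_dot"` (default) or `"dot"`.
#' @return Array `M x M x B` of attention weights.
#' @export
ssm_attention_weights <- function(h, score = "scaled_dot") {
  M <- length(h)
  B <- ncol(h[[1]])
  scale <- if (score == "scaled_dot") 1 / sqrt(nrow(h[[1]])) else 1
  sc <- array(0, c(M, M, B))
  for (n in seq_len(M)) {
    for (m in seq_len(M)) sc[n, m, ] <- colSums(h[[n]] * h[[m]]) * scale
  }
  a <- array(0, c(M, M, B))
  for (n in seq_len(M)) {
    row <- matrix(sc[n, , ], M, B)
    e <- exp(sweep(row, 2, apply(row, 2, max)))
    a[n, , ] <- sweep(e, 2, colSums(e), `/`)
  }
  a
}

#' One coupling step
#'
#' Advances all modality states by one time step from the layer-normalised
#' inputs: pre-activation states from the summed previous states, attention
#' between the pre-activation states, then the attention-weighted update.
#' All outputs lie in (-1, 1).
#'
#' @param h_prev list of `M` previous hidden states (`H x B`); zeros at
#'   `t = 0`.
#' @param x_t list of `M` layer-normalised inputs (`D x B`).
#' @param p coupling parameters from [ssm_params()].
#' @param literal_update if TRUE, use each modality's own previous state
#'   inside the attention-weighted sum (the degenerate self-coupling
#'   reading) instead of the cross-modal states.
#' @param score passed to [ssm_attention_weights()].
#' @return List with `h` (list of `M` updated states), `alpha`
#'   (`M x M x B`), and caches (`pre`, `bx`) used by the backward pass.
#' @export
ssm_couple_step <- function(h_prev, x_t, p, literal_update = FALSE,
                            score = "scaled_dot") {
  M <- length(p$S)
  if (length(h_prev) != M || length(x_t) != M) {
    stop("modality count mismatch: parameters have ", M, ", states have ",
         length(h_prev), ", inputs have ", length(x_t))
  }
  bx <- lapply(x_t, function(x) p$B %*% x)
  hsum <- Reduce(`+`, h_prev)
  pre <- lapply(seq_len(M), function(n) {
    u <- crossprod(p$S[[n]], hsum) + bx[[n]]
    if (!is.null(p$A)) u <- u + crossprod(p$A, h_prev[[n]])
    tanh(u)
  })
  alpha <- ssm_attention_weights(pre, score)
  h <- lapply(seq_len(M), function(n) {
    g <- if (literal_update) h_prev[[n]] else g_mix(alpha, h_prev, n)
    z <- crossprod(p$S[[n]], g) + bx[[n]]
    if (!is.null(p$A)) z <- z + crossprod(p$A, h_prev[[n]])
    list(h = tanh(z), g = g)
  })
  list(h = lapply(h, `[[`, "h"), g = lapply(h, `[[`, "g"),
       alpha = alpha, pre = pre, bx = bx, hsum = hsum)
}

# attention-weighted combination of previous states for modality n
g_mix <- function(alpha, h_prev, n) {
  M <- length(h_prev)
  g <- 0
  for (m in seq_len(M)) {
    g <- g + sweep(h_prev[[m]], 2, alpha[n, m, ], `*`)
  }
  g
}

#' Full coupling-module forward pass
#'
#' Iterates [ssm_couple_step()] over the time axis from zero initial
#' states, projects each modality's final state with the output matrix and
#' fuses the modalities: `Y = (1/M) * sum_n W_n * (E' h_n(T))`.
#'
#' @param X list of `M` input cubes (`D x T x B`), already layer-normalised
#'   or raw (normalisation happens inside using the module's affines).
#' @param p coupling parameters from [ssm_params()].
#' @param literal_update,score see [ssm_couple_step()].
#' @return List with `Y` (`d_out x B`) and the per-step caches (for
#'   training); use `$Y` for inference.
#' @export
ssm_couple_forward <- function(X, p, literal_update = FALSE,
                               score = "scaled_dot") {
  M <- length(X)
  Tn <- unique(vapply(X, function(x) dim(x)[2], integer(1)))
  if (length(Tn) != 1) stop("modalities disagree on time steps: ",
                            paste(Tn, collapse = " vs "))
  B <- dim(X[[1]])[3]
  H <- nrow(p$B)
  h <- lapply(seq_len(M), function(n) matrix(0, H, B))
  steps <- vector("list", Tn)
  lns <- vector("list", Tn)
  for (t in seq_len(Tn)) {
    ln <- lapply(seq_len(M), function(n)
      layernorm_forward(matrix(X[[n]][, t, ], nrow = dim(X[[n]])[1]),
                        p$gamma[[n]], p$beta[[n]]))
    st <- ssm_couple_step(h, lapply(ln, `[[`, "y"), p,
                          literal_update = literal_update, score = score)
    st$h_prev <- h
    h <- st$h
    steps[[t]] <- st
    lns[[t]] <- ln
  }
  Yn <- lapply(seq_len(M), function(n) crossprod(p$E, h[[n]]))
  Y <- Reduce(`+`, lapply(seq_len(M), function(n) p$W[n] * Yn[[n]])) / M
  list(Y = Y, Yn = Yn, h_final = h, steps = steps, lns = lns)
}

ssm_couple_backward <- function(dY, X, p, cache, literal_update = FALSE,
                                score = "scaled_dot") {
  M <- length(X)
  Tn <- length(cache$steps)
  B <- ncol(dY)
  H <- nrow(p$B)
  scale <- if (score == "scaled_dot") 1 / sqrt(H) else 1
  g <- list(S = lapply(seq_len(M), function(n) matrix(0, H, H)),
            B = matrix(0, H, ncol(p$B)),
            E = matrix(0, nrow(p$E), ncol(p$E)),
            W = numeric(M),
            gamma = lapply(p$gamma, function(v) numeric(length(v))),
            beta = lapply(p$beta, function(v) numeric(length(v))))
  if (!is.null(p$A)) g$A <- matrix(0, H, H)
  dX <- lapply(X, function(x) array(0, dim(x)))

  # output fusion
  dh <- vector("list", M)
  for (n in seq_len(M)) {
    dYn <- (p$W[n] / M) * dY
    g$W[n] <- sum(cache$Yn[[n]] * dY) / M
    g$E <- g$E + cache$h_final[[n]] %*% t(dYn)
    dh[[n]] <- p$E %*% dYn
  }

  for (t in rev(seq_len(Tn))) {
    st <- cache$steps[[t]]
    ln <- cache$lns[[t]]
    h_prev <- st$h_prev
    dh_prev <- lapply(seq_len(M), function(n) matrix(0, H, B))
    dbx <- vector("list", M)
    dpre <- lapply(seq_len(M), function(n) matrix(0, H, B))
    dalpha <- array(0, c(M, M, B))

    for (n in seq_len(M)) {
      hn <- st$h[[n]]
      dz <- dh[[n]] * (1 - hn^2)
      g$S[[n]] <- g$S[[n]] + st$g[[n]] %*% t(dz)
      dg <- p$S[[n]] %*% dz
      dbx[[n]] <- dz
      if (!is.null(p$A)) {
        g$A <- g$A + h_prev[[n]] %*% t(dz)
        dh_prev[[n]] <- dh_prev[[n]] + p$A %*% dz
      }
      if (literal_update) {
        dh_prev[[n]] <- dh_prev[[n]] + dg
      } else {
        for (m in seq_len(M)) {
          dalpha[n, m, ] <- colSums(h_prev[[m]] * dg)
          dh_prev[[m]] <- dh_prev[[m]] + sweep(dg, 2, st$alpha[n, m, ], `*`)
        }
      }
    }

    if (!literal_update) {
      # softmax rows -> score gradients -> pre-activation state gradients
      for (n in seq_len(M)) {
        an <- matrix(st$alpha[n, , ], M, B)
        dan <- matrix(dalpha[n, , ], M, B)
        dsc <- an * sweep(dan, 2, colSums(an * dan))
        for (m in seq_len(M)) {
          dpre[[n]] <- dpre[[n]] + sweep(st$pre[[m]], 2, dsc[m, ], `*`) * scale
          dpre[[m]] <- dpre[[m]] + sweep(st$pre[[n]], 2, dsc[m, ], `*`) * scale
        }
      }
    }

    dhsum <- matrix(0, H, B)
    for (n in seq_len(M)) {
      du <- dpre[[n]] * (1 - st$pre[[n]]^2)
      g$S[[n]] <- g$S[[n]] + st$hsum %*% t(du)
      dhsum <- dhsum + p$S[[n]] %*% du
      dbx[[n]] <- dbx[[n]] + du
      if (!is.null(p$A)) {
        g$A <- g$A + h_prev[[n]] %*% t(du)
        dh_prev[[n]] <- dh_prev[[n]] + p$A %*% du
      }
    }
    for (m in seq_len(M)) dh_prev[[m]] <- dh_prev[[m]] + dhsum

    for (n in seq_len(M)) {
      g$B <- g$B + dbx[[n]] %*% t(ln[[n]]$y)
      dln <- crossprod(p$B, dbx[[n]])
      lb <- layernorm_backward(dln, ln[[n]], p$gamma[[n]])
      g$gamma[[n]] <- g$gamma[[n]] + lb$dgamma
      g$beta[[n]] <- g$beta[[n]] + lb$dbeta
      dX[[n]][, t, ] <- lb$dx
    }
    dh <- dh_prev
  }
  list(dX = dX, grads = g)
}
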