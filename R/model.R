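#' Model configuration
#'
#' Architecture hyperparameters of the full network and its ablation
#' variants.
#'
#' @param variant `"multisess"` (multi-scale CNN + SE + state-space
#'   coupling), `"mscnn_se"` (coupling module bypassed: per-modality
#'   features are temporally pooled and concatenated straight into the
#'   head) or `"ssm_only"` (raw epochs are cut into patches and fed
#'   directly to the coupling module).
#' @param mscnn an [mscnn_config()].
#' @param se_reduction SE bottleneck reduction ratio `r` (default 16).
#' @param ssm_hidden hidden state dimension `H` of the coupling module
#'   (default 64).
#' @param head_hidden width of the first fully connected layer (default 64).
#' @param dropout dropout rate between the two head layers during training
#'   (default 0.5; set 0 to disable).
#' @param score attention score function between modality states:
#'   `"scaled_dot"` (default) or `"dot"`.
#' @param literal_update use the degenerate self-coupling state update in
#'   the attention-weighted pass (default FALSE: cross-modal mixing).
#' @param use_A add an explicit state-transition matrix `A` to the update
#'   (default FALSE, matching the update as usually written).
#' @param ssm_only_patch patch length (samples) for the `ssm_only` variant
#'   (default 100, i.e. 30 time steps per 3000-sample epoch).
#' @param n_modalities number of input modalities (2: EEG, EOG).
#' @param n_classes number of stages (5).
#' @return List of class `model_config`.
#' @export
model_config <- function(variant = c("multisess", "mscnn_se", "ssm_only"),
                         mscnn = mscnn_config(), se_reduction = 16L,
                         ssm_hidden = 64L, head_hidden = 64L, dropout = 0.5,
                         score = "scaled_dot", literal_update = FALSE,
                         use_A = FALSE, ssm_only_patch = 100L,
                         n_modalities = 2L, n_classes = 5L) {
  variant <- match.arg(variant)
  cfg <- list(variant = variant, mscnn = mscnn,
              se_reduction = as.integer(se_reduction),
              ssm_hidden = as.integer(ssm_hidden),
              head_hidden = as.integer(head_hidden), dropout = dropout,
              score = score, literal_update = literal_update, use_A = use_A,
              ssm_only_patch = as.integer(ssm_only_patch),
              n_modalities = as.integer(n_modalities),
              n_classes = as.integer(n_classes))
  C <- mscnn$channels_out
  cfg$head_in <- switch(variant,
    multisess = C,                       # coupling output, d_out = D = C
    mscnn_se = n_modalities * C,         # pooled features, concatenated
    ssm_only = as.integer(ssm_only_patch))
  structure(cfg, class = "model_config")
}

#' Initialise model parameters
#'
#' He/Glorot random initialisation of every learnable tensor, deterministic
#' under `seed`.
#'
#' @param cfg a [model_config()].
#' @param seed integer seed.
#' @return Nested list of parameter arrays.
#' @export
init_params <- function(cfg, seed = 1L) {
  with_seed(derive_seed(seed, "init"), {
    M <- cfg$n_modalities
    C <- cfg$mscnn$channels_out
    p <- list()
    if (cfg$variant != "ssm_only") {
      p$mscnn <- lapply(seq_len(M), function(m) mscnn_params(cfg$mscnn))
      p$se <- lapply(seq_len(M), function(m) se_params(C, cfg$se_reduction))
    }
    if (cfg$variant != "mscnn_se") {
      D <- if (cfg$variant == "multisess") C else cfg$ssm_only_patch
      p$ssm <- ssm_params(M, D, cfg$ssm_hidden, d_out = D, use_A = cfg$use_A)
    }
    he <- function(nr, nc) matrix(stats::rnorm(nr * nc, 0, sqrt(2 / nc)), nr, nc)
    p$head <- list(W1 = he(cfg$head_hidden, cfg$head_in),
                   b1 = numeric(cfg$head_hidden),
                   W2 = he(cfg$n_classes, cfg$head_hidden),
                   b2 = numeric(cfg$n_classes))
    p
  })
}

# split a B x 2 x L batch array into per-modality cubes (1 x L x B)
batch_to_modalities <- function(x, cfg) {
  if (length(dim(x)) != 3 || dim(x)[2] != cfg$n_modalities) {
    stop("expected a batch of shape B x ", cfg$n_modalities, " x L, got ",
         paste(dim(x), collapse = " x "))
  }
  L <- dim(x)[3]
  lapply(seq_len(cfg$n_modalities), function(m)
    as_cube(t(matrix(x[, m, ], nrow = dim(x)[1])), 1L, L, dim(x)[1]))
}

# modality cube (1 x 3000 x B) -> patch cube (P x T x B) for ssm_only
to_patches <- function(xc, patch) {
  d <- dim(xc)
  as_cube(xc, patch, d[2] %/% patch, d[3])
}

head_forward <- function(f, p, cfg, training) {
  a1 <- dense_forward(f, p$head$W1, p$head$b1)
  h1 <- relu_forward(a1)
  dr <- dropout_forward(h1, cfg$dropout, training)
  logits <- dense_forward(dr$y, p$head$W2, p$head$b2)
  list(logits = logits, f = f, a1 = a1, h1 = h1, dr = dr)
}

head_backward <- function(dlogits, cache, p) {
  g2 <- dense_backward(dlogits, cache$dr$y, p$head$W2)
  dh1 <- dropout_backward(g2$dx, cache$dr$mask)
  da1 <- relu_backward(dh1, cache$a1)
  g1 <- dense_backward(da1, cache$f, p$head$W1)
  list(df = g1$dx,
       grads = list(W1 = g1$dw, b1 = g1$db, W2 = g2$dw, b2 = g2$db))
}

# full forward pass with caches; x_mod is the per-modality cube list
network_forward <- function(x_mod, p, cfg, training = FALSE) {
  M <- cfg$n_modalities
  cache <- list()
  if (cfg$variant == "ssm_only") {
    X <- lapply(x_mod, to_patches, patch = cfg$ssm_only_patch)
    ssm <- ssm_couple_forward(X, p$ssm, cfg$literal_update, cfg$score)
    f <- ssm$Y
    cache <- list(X = X, ssm = ssm)
  } else {
    ms <- lapply(seq_len(M), function(m)
      mscnn_forward_cached(x_mod[[m]], p$mscnn[[m]], cfg$mscnn))
    se <- lapply(seq_len(M), function(m) se_forward(ms[[m]]$y, p$se[[m]]))
    if (cfg$variant == "multisess") {
      X <- lapply(se, `[[`, "X")
      ssm <- ssm_couple_forward(X, p$ssm, cfg$literal_update, cfg$score)
      f <- ssm$Y
      cache <- list(ms = ms, se = se, X = X, ssm = ssm)
    } else {
      pooled <- lapply(se, function(s) {
        d <- dim(s$X)
        colSums(aperm(s$X, c(2, 1, 3))) / d[2]   # mean over time -> C x B
      })
      f <- do.call(rbind, pooled)
      cache <- list(ms = ms, se = se, pooled = pooled)
    }
  }
  hd <- head_forward(f, p, cfg, training)
  c(cache, list(head = hd))
}

network_backward <- function(dlogits, x_mod, p, cfg, cache) {
  M <- cfg$n_modalities
  hb <- head_backward(dlogits, cache$head, p)
  g <- list(head = hb$grads)
  df <- hb$df
  if (cfg$variant == "ssm_only") {
    sb <- ssm_couple_backward(df, cache$X, p$ssm, cache$ssm,
                              cfg$literal_update, cfg$score)
    g$ssm <- sb$grads
    return(g)
  }
  if (cfg$variant == "multisess") {
    sb <- ssm_couple_backward(df, cache$X, p$ssm, cache$ssm,
                              cfg$literal_update, cfg$score)
    g$ssm <- sb$grads
    dse <- sb$dX
  } else {
    C <- cfg$mscnn$channels_out
    dse <- lapply(seq_len(M), function(m) {
      dp <- df[(m - 1L) * C + seq_len(C), , drop = FALSE]
      Tt <- dim(cache$se[[m]]$X)[2]
      expand_ct(dp / Tt, Tt)
    })
  }
  g$se <- vector("list", M)
  g$mscnn <- vector("list", M)
  for (m in seq_len(M)) {
    seb <- se_backward(dse[[m]], cache$ms[[m]]$y, p$se[[m]], cache$se[[m]])
    g$se[[m]] <- list(W1 = seb$dW1, W2 = seb$dW2)
    msb <- mscnn_backward(seb$dU, cache$ms[[m]], p$mscnn[[m]], cfg$mscnn)
    g$mscnn[[m]] <- msb$grads
  }
  g
}

#' Forward pass: class probabilities for a batch of epochs
#'
#' Runs the configured variant end to end and returns softmax
#' probabilities. Rows sum to 1.
#'
#' @param x batch array `B x 2 x 3000` (modalities in EEG, EOG order).
#' @param params parameters from [init_params()] or a trained model.
#' @param cfg the matching [model_config()].
#' @return Matrix `B x n_classes` of class probabilities.
#' @export
model_forward <- function(x, params, cfg = model_config()) {
  x_mod <- batch_to_modalities(x, cfg)
  cache <- network_forward(x_mod, params, cfg, training = FALSE)
  t(softmax_cols(cache$head$logits))
}

#' Predict stage codes for a batch of epochs
#'
#' @inheritParams model_forward
#' @param batch_size minibatch size used internally (default 128).
#' @return Integer vector of predicted stage codes (0--4).
#' @export
model_predict <- function(x, params, cfg = model_config(), batch_size = 128L) {
  n <- dim(x)[1]
  out <- integer(n)
  for (i in seq(1L, n, by = batch_size)) {
    j <- min(i + batch_size - 1L, n)
    probs <- model_forward(x[i:j, , , drop = FALSE], params, cfg)
    out[i:j] <- max.col(probs, ties.method = "first") - 1L
  }
  out
}

# loss + gradients for one minibatch; used by the trainer and the
# finite-difference gradient checks
model_loss_grads <- function(x_mod, labels, params, cfg, class_weights,
                             training = TRUE) {
  cache <- network_forward(x_mod, params, cfg, training = training)
  ce <- weighted_ce_forward(cache$head$logits, labels, class_weights)
  grads <- network_backward(ce$dlogits, x_mod, params, cfg, cache)
  # same component order as the parameter tree, so both flatten identically
  grads <- grads[names(params)]
  list(loss = ce$loss, grads = grads, probs = ce$probs)
}

model_loss <- function(x_mod, labels, params, cfg, class_weights) {
  cache <- network_forward(x_mod, params, cfg, training = FALSE)
  weighted_ce_forward(cache$head$logits, labels, class_weights)$loss
}
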