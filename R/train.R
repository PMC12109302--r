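#' Training configuration
#'
#' @param learning_rate Adam learning rate (default 0.001).
#' @param batch_size minibatch size (default 128).
#' @param epochs training epochs (default 100).
#' @param folds cross-validation folds (default 5).
#' @param seed master seed driving splits, initialisation and shuffling.
#' @param beta1,beta2,eps Adam moment decay rates and stabiliser.
#' @return List of class `train_config`.
#' @export
train_config <- function(learning_rate = 0.001, batch_size = 128L,
                         epochs = 100L, folds = 5L, seed = 1L,
                         beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  stopifnot(learning_rate > 0, batch_size >= 1, epochs >= 0, folds >= 2)
  structure(list(learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), folds = as.integer(folds),
                 seed = as.integer(seed), beta1 = beta1, beta2 = beta2,
                 eps = eps),
            class = "train_config")
}

#' Inverse-frequency class weights
#'
#' `w_c = N / (K * N_c)` over the `K` classes present, then normalised to
#' mean one over the present classes; absent classes get weight 0 with a
#' warning. Used by the weighted cross-entropy loss to counter stage
#' imbalance (N1 in particular is rare).
#'
#' @param label_counts counts per class (length 5 vector).
#' @return Numeric weight vector of the same length.
#' @export
class_weights <- function(label_counts) {
  label_counts <- as.numeric(label_counts)
  if (all(label_counts == 0)) stop("all class counts are zero")
  present <- label_counts > 0
  if (any(!present)) {
    warning("classes absent from training data get weight 0: ",
            paste(stage_names()[!present], collapse = ", "))
  }
  w <- numeric(length(label_counts))
  k <- sum(present)
  w[present] <- sum(label_counts) / (k * label_counts[present])
  w[present] <- w[present] / mean(w[present])
  w
}

#' Stack a list of recordings into one flat epoch set
#'
#' @param recordings list of `recording` objects.
#' @return List with `x` (array `N x channels x samples`), `y` (integer
#'   stage codes) and `subject` (subject id per epoch).
#' @export
dataset_flatten <- function(recordings) {
  x <- do.call(abind_first, lapply(recordings, `[[`, "x"))
  list(x = x,
       y = unlist(lapply(recordings, `[[`, "labels")),
       subject = unlist(lapply(recordings, function(r)
         rep(r$subject_id, length(r$labels)))))
}

abind_first <- function(...) {
  parts <- list(...)
  d <- dim(parts[[1]])
  out <- array(NA_real_, c(sum(vapply(parts, function(p) dim(p)[1], numeric(1))),
                           d[2], d[3]))
  at <- 0L
  for (p in parts) {
    out[at + seq_len(dim(p)[1]), , ] <- p
    at <- at + dim(p)[1]
  }
  out
}

# precompute per-modality L x N matrices once, so minibatch assembly is a
# column gather instead of an array slice copy
modality_matrices <- function(x) {
  lapply(seq_len(dim(x)[2]), function(m) t(matrix(x[, m, ], nrow = dim(x)[1])))
}

gather_batch <- function(mods, idx) {
  lapply(mods, function(mm) as_cube(mm[, idx, drop = FALSE], 1L, nrow(mm),
                                    length(idx)))
}

adam_init <- function(theta) {
  list(m = numeric(length(theta)), v = numeric(length(theta)), t = 0L)
}

adam_step <- function(theta, grad, state, cfg) {
  state$t <- state$t + 1L
  state$m <- cfg$beta1 * state$m + (1 - cfg$beta1) * grad
  state$v <- cfg$beta2 * state$v + (1 - cfg$beta2) * grad^2
  mhat <- state$m / (1 - cfg$beta1^state$t)
  vhat <- state$v / (1 - cfg$beta2^state$t)
  list(theta = theta - cfg$learning_rate * mhat / (sqrt(vhat) + cfg$eps),
       state = state)
}

#' Train the model on one training set
#'
#' Minibatch Adam with class-weighted cross-entropy on shuffled data for a
#' fixed epoch budget. Initialisation, shuffling and dropout all derive
#' from `cfg$seed`, so identical data + config + seed reproduce the run
#' exactly.
#'
#' @param train_set list with `x` (array `N x 2 x 3000`) and `y` (integer
#'   stage codes), e.g. from [dataset_flatten()].
#' @param cfg a [train_config()].
#' @param model_cfg a [model_config()] selecting the variant.
#' @param params optional starting parameters (default: fresh
#'   [init_params()] from the seed).
#' @param verbose print per-epoch loss.
#' @return List with `params` (trained), `loss_history` (mean minibatch
#'   loss per epoch), `class_weights`, `model_cfg`.
#' @export
train_fold <- function(train_set, cfg = train_config(),
                       model_cfg = model_config(), params = NULL,
                       verbose = FALSE) {
  y <- as.integer(train_set$y)
  counts <- tabulate(y + 1L, nbins = model_cfg$n_classes)
  if (sum(counts > 0) < 2) stop("training set must contain at least 2 classes")
  w <- class_weights(counts)
  if (is.null(params)) params <- init_params(model_cfg, cfg$seed)
  skeleton <- params
  theta <- flatten_params(params)
  opt <- adam_init(theta)
  n <- length(y)
  history <- numeric(cfg$epochs)
  mods <- modality_matrices(train_set$x)

  if (cfg$epochs > 0) {
    for (ep in seq_len(cfg$epochs)) {
      perm <- with_seed(derive_seed(cfg$seed, "shuffle", ep), sample.int(n))
      set.seed(derive_seed(cfg$seed, "dropout", ep))
      losses <- c()
      for (i in seq(1L, n, by = cfg$batch_size)) {
        idx <- perm[i:min(i + cfg$batch_size - 1L, n)]
        xb <- gather_batch(mods, idx)
        res <- model_loss_grads(xb, y[idx], params, model_cfg, w,
                                training = TRUE)
        gvec <- flatten_params(res$grads)
        st <- adam_step(theta, gvec, opt, cfg)
        theta <- st$theta
        opt <- st$state
        params <- unflatten_params(theta, skeleton)
        losses <- c(losses, res$loss)
      }
      history[ep] <- mean(losses)
      if (verbose) {
        message(sprintf("epoch %3d/%d  loss %.4f", ep, cfg$epochs, history[ep]))
      }
    }
  }
  list(params = params, loss_history = history, class_weights = w,
       model_cfg = model_cfg)
}
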