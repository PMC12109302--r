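#' Finite-difference gradient check
#'
#' Compares the analytic parameter gradients of the training loss against
#' central finite differences on a (small) batch, reporting the maximum
#' relative discrepancy. Mainly used to verify the hand-derived backward
#' passes on tiny configurations.
#'
#' @param x_mod per-modality input cube list (as built internally from a
#'   `B x 2 x L` batch).
#' @param labels integer stage codes for the batch.
#' @param params model parameters.
#' @param cfg the matching [model_config()].
#' @param class_weights per-class loss weights.
#' @param eps finite-difference step (default 1e-5).
#' @param n_checked number of randomly chosen parameters to difference
#'   (default 300; differencing all parameters is quadratic in model size).
#' @return List with `max_rel_err`, and vectors `analytic` / `numeric` for
#'   the checked coordinates. Dropout is disabled during the check (the
#'   loss must be deterministic for differencing).
#' @export
gradient_check <- function(x_mod, labels, params, cfg, class_weights,
                           eps = 1e-5, n_checked = 300L) {
  cfg$dropout <- 0
  res <- model_loss_grads(x_mod, labels, params, cfg, class_weights,
                          training = FALSE)
  ga <- flatten_params(res$grads)
  theta <- flatten_params(params)
  skeleton <- params
  idx <- if (length(theta) <= n_checked) seq_along(theta) else
    sort(sample.int(length(theta), n_checked))
  gn <- vapply(idx, function(i) {
    tp <- theta; tp[i] <- tp[i] + eps
    lp <- model_loss(x_mod, labels, unflatten_params(tp, skeleton), cfg,
                     class_weights)
    tm <- theta; tm[i] <- tm[i] - eps
    lm <- model_loss(x_mod, labels, unflatten_params(tm, skeleton), cfg,
                     class_weights)
    (lp - lm) / (2 * eps)
  }, numeric(1))
  rel <- abs(ga[idx] - gn) / pmax(abs(ga[idx]) + abs(gn), 1e-8)
  # coordinates where both gradients vanish are exact matches
  rel[abs(ga[idx]) < 1e-10 & abs(gn) < 1e-10] <- 0
  list(max_rel_err = max(rel), analytic = ga[idx], numeric = gn, idx = idx)
}
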