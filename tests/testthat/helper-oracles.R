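# Independent reference implementations used as oracles. These deliberately
# use naive loops over the one-vs-rest decompositions, not the package's
# vectorised code paths.

ref_confusion <- function(y_true, y_pred, k = 5L) {
  cm <- matrix(0L, k, k)
  for (i in seq_along(y_true)) {
    cm[y_true[i] + 1L, y_pred[i] + 1L] <- cm[y_true[i] + 1L, y_pred[i] + 1L] + 1L
  }
  cm
}

ref_metrics <- function(cm) {
  k <- nrow(cm)
  total <- sum(cm)
  acc <- 100 * sum(diag(cm)) / total
  f1 <- sen <- spec <- pre <- numeric(k)
  for (c in seq_len(k)) {
    tp <- cm[c, c]
    fn <- sum(cm[c, ]) - tp
    fp <- sum(cm[, c]) - tp
    tn <- total - tp - fn - fp
    p <- if (tp + fp > 0) tp / (tp + fp) else 0
    r <- if (tp + fn > 0) tp / (tp + fn) else 0
    f1[c] <- if (p + r > 0) 2 * p * r / (p + r) else 0
    sen[c] <- if (tp + fn > 0) tp / (tp + fn) else 0
    spec[c] <- if (tn + fp > 0) tn / (tn + fp) else 0
    pre[c] <- p
  }
  po <- sum(diag(cm)) / total
  pe <- 0
  for (c in seq_len(k)) pe <- pe + sum(cm[c, ]) * sum(cm[, c]) / total^2
  kappa <- if (pe < 1) 100 * (po - pe) / (1 - pe) else 0
  list(acc = acc, mf1 = 100 * mean(f1), kappa = kappa,
       sen = 100 * mean(sen), spec = 100 * mean(spec), pre = 100 * mean(pre))
}

random_cm <- function(k = 5L, max_count = 50L) {
  matrix(sample.int(max_count + 1L, k * k, replace = TRUE) - 1L, k, k)
}

# small model configuration used across model tests (fast, all paths active)
tiny_mscnn <- function() {
  mscnn_config(large = list(kernel = 20L, stride = 10L, filters = 6L),
               small = list(kernel = 8L, stride = 4L, filters = 6L),
               pool = 2L,
               conv2 = list(kernel = 3L, stride = 1L, filters = 6L),
               input_len = 240L)
}

tiny_model_config <- function(variant = "multisess", ...) {
  model_config(variant = variant, mscnn = tiny_mscnn(), se_reduction = 4L,
               ssm_hidden = 5L, head_hidden = 8L, ssm_only_patch = 24L, ...)
}

tiny_batch <- function(B = 4L, len = 240L) {
  array(stats::rnorm(B * 2L * len), c(B, 2L, len))
}
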