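#' Subject-wise k-fold split
#'
#' Randomly partitions subjects (never epochs) into `k` folds of sizes
#' differing by at most one, deterministically under `seed`.
#'
#' @param subject_ids character vector of distinct subject ids.
#' @param k number of folds.
#' @param seed integer seed.
#' @return Named integer vector mapping subject id to fold index in
#'   `1..k`.
#' @export
kfold_split_subjects <- function(subject_ids, k = 5L, seed = 1L) {
  subject_ids <- unique(subject_ids)
  n <- length(subject_ids)
  if (n < k) stop("need at least ", k, " subjects for ", k, "-fold CV, got ", n)
  perm <- with_seed(derive_seed(seed, "split"), sample(subject_ids))
  # cycle fold indices over the shuffled order, then map back to input order
  stats::setNames(rep(seq_len(k), length.out = n)[match(subject_ids, perm)],
                  subject_ids)
}

#' Five-fold cross-subject training and evaluation
#'
#' For each fold, trains the selected variant on the other folds' subjects
#' and evaluates on the held-out subjects; train and test subject sets are
#' asserted disjoint. Class weights are recomputed on each fold's training
#' labels. Metrics are reported per fold, pooled over all test epochs, and
#' as the across-fold mean.
#'
#' @param recordings list of `recording` objects (one per subject).
#' @param cfg a [train_config()] (`folds`, seed, optimizer settings).
#' @param model_cfg a [model_config()] selecting the variant.
#' @param verbose print progress.
#' @return List of class `cv_result`: `fold_reports` (per-fold
#'   [metrics_report()]s), `pooled` (report over all test epochs),
#'   `mean_metrics` (across-fold means of the overall metrics), `split`,
#'   `predictions` (data frame with subject, true and predicted codes) and
#'   `loss_histories`.
#' @export
cross_validate <- function(recordings, cfg = train_config(),
                           model_cfg = model_config(), verbose = FALSE) {
  subjects <- vapply(recordings, `[[`, character(1), "subject_id")
  if (anyDuplicated(subjects)) stop("duplicate subject ids in dataset")
  split <- kfold_split_subjects(subjects, cfg$folds, cfg$seed)
  fold_reports <- list()
  losses <- list()
  preds <- list()
  for (f in seq_len(cfg$folds)) {
    test_sub <- names(split)[split == f]
    train_sub <- names(split)[split != f]
    if (length(intersect(train_sub, test_sub))) {
      stop("train/test subject leakage in fold ", f)
    }
    train_set <- dataset_flatten(recordings[subjects %in% train_sub])
    test_set <- dataset_flatten(recordings[subjects %in% test_sub])
    stopifnot(!any(test_set$subject %in% train_set$subject))
    if (verbose) message("fold ", f, ": ", length(train_sub), " train / ",
                         length(test_sub), " test subjects")
    fit <- train_fold(train_set, cfg, model_cfg, verbose = verbose)
    yhat <- model_predict(test_set$x, fit$params, model_cfg)
    cm <- confusion_matrix(test_set$y, yhat, model_cfg$n_classes)
    fold_reports[[f]] <- metrics_report(cm, warn = FALSE)
    losses[[f]] <- fit$loss_history
    preds[[f]] <- data.frame(fold = f, subject = test_set$subject,
                             y_true = test_set$y, y_pred = yhat)
  }
  predictions <- do.call(rbind, preds)
  pooled <- metrics_report(
    confusion_matrix(predictions$y_true, predictions$y_pred,
                     model_cfg$n_classes), warn = FALSE)
  overall <- c("acc", "mf1", "kappa", "sen", "spec", "pre")
  mean_metrics <- vapply(overall, function(m)
    mean(vapply(fold_reports, `[[`, numeric(1), m)), numeric(1))
  structure(list(fold_reports = fold_reports, pooled = pooled,
                 mean_metrics = mean_metrics, split = split,
                 predictions = predictions, loss_histories = losses),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  reports <- c(stats::setNames(x$fold_reports,
                               paste0("fold", seq_along(x$fold_reports))),
               list(pooled = x$pooled))
  cat(format_metrics_table(reports), sep = "\n")
  invisible(x)
}

#' Run the ablation comparison
#'
#' Cross-validates the requested variants on the same dataset and seed,
#' so accuracies are directly comparable.
#'
#' @param recordings list of `recording` objects.
#' @param cfg a [train_config()].
#' @param variants character vector of variant names.
#' @param verbose print progress.
#' @return Named list of `cv_result` objects.
#' @export
run_ablation <- function(recordings, cfg = train_config(),
                         variants = c("multisess", "mscnn_se", "ssm_only"),
                         verbose = FALSE) {
  stats::setNames(lapply(variants, function(v) {
    if (verbose) message("variant: ", v)
    cross_validate(recordings, cfg, model_config(variant = v),
                   verbose = verbose)
  }), variants)
}
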