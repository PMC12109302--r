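#' Confusion matrix for sleep stage predictions
#'
#' Rows are true classes, columns predicted classes, both in the fixed
#' stage order W, N1, N2, N3, REM (codes 0--4).
#'
#' @param y_true,y_pred integer vectors of stage codes in 0..(n_classes-1).
#' @param n_classes number of classes (default 5).
#' @return An integer `n_classes x n_classes` matrix with dimnames,
#'   of class `"confusion_matrix"`.
#' @export
confusion_matrix <- function(y_true, y_pred, n_classes = n_stages()) {
  if (length(y_true) != length(y_pred)) {
    stop("length mismatch: y_true has ", length(y_true),
         ", y_pred has ", length(y_pred))
  }
  y_true <- as.integer(y_true)
  y_pred <- as.integer(y_pred)
  if (anyNA(y_true) || anyNA(y_pred) ||
      any(y_true < 0L | y_true >= n_classes) ||
      any(y_pred < 0L | y_pred >= n_classes)) {
    stop("labels must be integers in [0, ", n_classes - 1L, "]")
  }
  cm <- matrix(0L, n_classes, n_classes)
  # tabulate on the compound index true*K + pred
  idx <- tabulate(y_true * n_classes + y_pred + 1L, nbins = n_classes^2)
  cm[] <- as.integer(matrix(idx, n_classes, n_classes, byrow = TRUE))
  nm <- if (n_classes == n_stages()) stage_names() else as.character(seq_len(n_classes) - 1L)
  dimnames(cm) <- list(true = nm, pred = nm)
  class(cm) <- c("confusion_matrix", class(cm))
  cm
}

#' One-vs-rest binary decomposition of a confusion matrix
#'
#' @param cm a square count matrix (rows = true, cols = predicted).
#' @param class class index, 1-based.
#' @return Named numeric vector with elements `TP`, `FN`, `FP`, `TN`;
#'   these always sum to `sum(cm)`.
#' @export
binary_decomposition <- function(cm, class) {
  cm <- unclass(cm)
  tp <- cm[class, class]
  fn <- sum(cm[class, ]) - tp
  fp <- sum(cm[, class]) - tp
  tn <- sum(cm) - tp - fn - fp
  c(TP = tp, FN = fn, FP = fp, TN = tn)
}

#' Overall accuracy
#'
#' Proportion of correctly staged epochs, `100 * trace / total`.
#'
#' @inheritParams binary_decomposition
#' @return Percentage in \[0, 100\].
#' @export
accuracy <- function(cm) {
  cm <- unclass(cm)
  total <- sum(cm)
  if (total == 0) stop("empty confusion matrix")
  100 * sum(diag(cm)) / total
}

#' Macro-averaged F1 score
#'
#' Unweighted mean over classes of the per-class F1 score (harmonic mean
#' of one-vs-rest precision and recall). A class with zero precision and
#' recall contributes an F1 of 0.
#'
#' @inheritParams binary_decomposition
#' @return Percentage in \[0, 100\].
#' @export
macro_f1 <- function(cm) {
  cm <- unclass(cm)
  if (sum(cm) == 0) stop("empty confusion matrix")
  k <- nrow(cm)
  f1 <- vapply(seq_len(k), function(c) {
    d <- binary_decomposition(cm, c)
    prec <- if (d["TP"] + d["FP"] > 0) d["TP"] / (d["TP"] + d["FP"]) else 0
    rec  <- if (d["TP"] + d["FN"] > 0) d["TP"] / (d["TP"] + d["FN"]) else 0
    if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
  }, numeric(1))
  100 * mean(f1)
}

#' Cohen's kappa
#'
#' Chance-corrected agreement `(p_o - p_e) / (1 - p_e)` between predicted
#' and true stages, reported on a 0--100 scale to match the other metrics.
#' `p_o` is the observed agreement (trace / total) and `p_e` the expected
#' agreement from the row and column marginals.
#'
#' @inheritParams binary_decomposition
#' @return Kappa times 100 (so perfect agreement is 100).
#' @export
cohens_kappa <- function(cm) {
  cm <- unclass(cm)
  total <- sum(cm)
  if (total == 0) stop("empty confusion matrix")
  po <- sum(diag(cm)) / total
  pe <- sum(rowSums(cm) * colSums(cm)) / total^2
  if (pe >= 1) {
    warning("expected agreement p_e = 1; kappa undefined, returning 0")
    return(0)
  }
  100 * (po - pe) / (1 - pe)
}

#' Sensitivity, specificity and precision
#'
#' Per-class one-vs-rest sensitivity (recall), specificity and precision,
#' plus their unweighted macro-averages across classes. Ratios with a zero
#' denominator are reported as 0 with a warning (this happens for classes
#' that are never predicted or never occur).
#'
#' @inheritParams binary_decomposition
#' @param warn emit a warning on zero denominators (default TRUE).
#' @return List with `sen`, `spec`, `pre` (macro-averaged percentages) and
#'   `per_class` (3 x K matrix of percentages, rows sen/spec/pre).
#' @export
sensitivity_specificity_precision <- function(cm, warn = TRUE) {
  cm <- unclass(cm)
  if (sum(cm) == 0) stop("empty confusion matrix")
  k <- nrow(cm)
  safe_ratio <- function(num, den, what, class) {
    if (den > 0) return(num / den)
    if (warn) warning("zero denominator for ", what, " of class ", class,
                      "; reporting 0")
    0
  }
  per <- vapply(seq_len(k), function(c) {
    d <- binary_decomposition(cm, c)
    c(sen  = safe_ratio(d[["TP"]], d[["TP"]] + d[["FN"]], "sensitivity", c),
      spec = safe_ratio(d[["TN"]], d[["TN"]] + d[["FP"]], "specificity", c),
      pre  = safe_ratio(d[["TP"]], d[["TP"]] + d[["FP"]], "precision", c))
  }, numeric(3))
  per <- 100 * per
  colnames(per) <- if (k == n_stages()) stage_names() else NULL
  list(sen = mean(per["sen", ]), spec = mean(per["spec", ]),
       pre = mean(per["pre", ]), per_class = per)
}

#' Full metrics report from a confusion matrix
#'
#' Bundles all overall metrics (ACC, MF1, Kappa, Sen, Spec, Pre) and the
#' per-class precisions into one object.
#'
#' @inheritParams binary_decomposition
#' @param warn passed to [sensitivity_specificity_precision()].
#' @return A list of class `"metrics_report"` with elements `acc`, `mf1`,
#'   `kappa`, `sen`, `spec`, `pre` (percentages), `per_class_precision`
#'   (named 5-vector), `per_class` (3 x 5 matrix), `n_epochs` and `cm`.
#' @export
metrics_report <- function(cm, warn = TRUE) {
  ssp <- sensitivity_specificity_precision(cm, warn = warn)
  out <- list(
    acc = accuracy(cm), mf1 = macro_f1(cm), kappa = cohens_kappa(cm),
    sen = ssp$sen, spec = ssp$spec, pre = ssp$pre,
    per_class_precision = ssp$per_class["pre", ],
    per_class = ssp$per_class,
    n_epochs = sum(unclass(cm)), cm = cm
  )
  class(out) <- "metrics_report"
  out
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(format_metrics_table(list(model = x)), sep = "\n")
  invisible(x)
}

#' Format metrics reports as an aligned text table
#'
#' One row per report, columns ACC / MF1 / Kappa / Sen / Spec / Pre plus
#' the per-class precisions, mirroring the usual layout of sleep-staging
#' results tables.
#'
#' @param reports named list of `metrics_report` objects.
#' @return Character vector of table lines.
#' @export
format_metrics_table <- function(reports) {
  hdr <- c("Model", "ACC", "MF1", "Kappa", "Sen", "Spec", "Pre",
           paste0("Pre(", stage_names(), ")"))
  rows <- lapply(names(reports), function(nm) {
    r <- reports[[nm]]
    c(nm, sprintf("%.2f", c(r$acc, r$mf1, r$kappa, r$sen, r$spec, r$pre,
                            r$per_class_precision)))
  })
  tab <- rbind(hdr, do.call(rbind, rows))
  widths <- apply(nchar(tab), 2, max)
  apply(tab, 1, function(row)
    paste(mapply(formatC, row, width = widths), collapse = "  "))
}

#' Write per-fold and aggregate metrics to CSV
#'
#' @param reports named list of `metrics_report` objects (e.g. one per fold
#'   plus a pooled aggregate).
#' @param path output CSV path.
#' @return The data frame written, invisibly.
#' @export
write_metrics_csv <- function(reports, path) {
  df <- do.call(rbind, lapply(names(reports), function(nm) {
    r <- reports[[nm]]
    d <- data.frame(model = nm, n_epochs = r$n_epochs,
                    acc = r$acc, mf1 = r$mf1, kappa = r$kappa,
                    sen = r$sen, spec = r$spec, pre = r$pre)
    pc <- as.data.frame(as.list(r$per_class_precision))
    names(pc) <- paste0("pre_", stage_names())
    cbind(d, pc)
  }))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(df)
}
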