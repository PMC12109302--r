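test_that("confusion matrix counts match a loop-based tally", {
  y <- c(0L, 1L, 2L, 3L, 4L)
  expect_equal(unclass(confusion_matrix(y, y)),
               diag(1L, 5), ignore_attr = TRUE)
  cm <- confusion_matrix(c(0L, 0L), c(1L, 1L))
  expect_equal(cm[1, 2], 2L)
  expect_equal(sum(unclass(cm)), 2L)

  set.seed(11)
  yt <- sample(0:4, 1000, replace = TRUE)
  yp <- sample(0:4, 1000, replace = TRUE)
  expect_equal(unclass(confusion_matrix(yt, yp)), ref_confusion(yt, yp),
               ignore_attr = TRUE)

  expect_error(confusion_matrix(0:2, 0:3), "length mismatch")
  expect_error(confusion_matrix(c(0L, 5L), c(0L, 0L)), "labels")
})

test_that("binary decomposition partitions the total", {
  cm <- matrix(c(20, 10, 5, 15), 2, 2)  # rows true, cols pred
  d <- binary_decomposition(cm, 1)
  expect_equal(d, c(TP = 20, FN = 5, FP = 10, TN = 15))
  set.seed(2)
  for (i in 1:20) {
    m <- random_cm()
    for (c in 1:5) expect_equal(sum(binary_decomposition(m, c)), sum(m))
  }
})

test_that("accuracy, macro-F1 and kappa reproduce hand-computed examples", {
  cm <- matrix(c(20, 10, 5, 15), 2, 2)
  expect_equal(accuracy(cm), 70)
  # class 0: precision 2/3, recall 0.8; class 1: precision 0.75, recall 0.6
  f1_0 <- 2 * (2 / 3 * 0.8) / (2 / 3 + 0.8)
  f1_1 <- 2 * (0.75 * 0.6) / (0.75 + 0.6)
  expect_equal(macro_f1(cm), 100 * (f1_0 + f1_1) / 2)
  expect_equal(cohens_kappa(cm), 40)  # po = .7, pe = .5

  chance <- matrix(25, 2, 2)
  expect_equal(cohens_kappa(chance), 0)
  perfect <- diag(10, 5)
  expect_equal(accuracy(perfect), 100)
  expect_equal(macro_f1(perfect), 100)
  expect_equal(cohens_kappa(perfect), 100)
  expect_equal(accuracy(matrix(c(0, 3, 4, 0), 2, 2)), 0)
})

test_that("sensitivity/specificity/precision match direct ratios", {
  cm <- matrix(c(20, 10, 5, 15), 2, 2)
  s <- sensitivity_specificity_precision(cm)
  expect_equal(unname(s$per_class["sen", 1]), 80)
  expect_equal(unname(s$per_class["spec", 1]), 60)
  expect_equal(unname(s$per_class["pre", 1]), 100 * 2 / 3)
  # a class never predicted gets precision 0 with a warning
  cm2 <- matrix(c(10, 3, 0, 0), 2, 2)  # class 2 occurs, never predicted
  expect_warning(s2 <- sensitivity_specificity_precision(cm2),
                 "zero denominator for precision of class 2")
  expect_equal(unname(s2$per_class["pre", 2]), 0)
  # degenerate matrices with several empty classes report 0s quietly on request
  cm3 <- matrix(0, 5, 5); cm3[1, 1] <- 10; cm3[2, 1] <- 3
  s3 <- sensitivity_specificity_precision(cm3, warn = FALSE)
  expect_true(all(s3$per_class["pre", 2:5] == 0))
})

test_that("all metrics agree with the loop-based reference on random matrices", {
  set.seed(42)
  for (i in 1:200) {
    cm <- random_cm()
    if (sum(cm) == 0) next
    ref <- ref_metrics(cm)
    expect_equal(accuracy(cm), ref$acc, tolerance = 1e-12)
    expect_equal(macro_f1(cm), ref$mf1, tolerance = 1e-12)
    expect_equal(cohens_kappa(cm), ref$kappa, tolerance = 1e-12)
    s <- sensitivity_specificity_precision(cm, warn = FALSE)
    expect_equal(s$sen, ref$sen, tolerance = 1e-12)
    expect_equal(s$spec, ref$spec, tolerance = 1e-12)
    expect_equal(s$pre, ref$pre, tolerance = 1e-12)
  }
})

test_that("accuracy equals the count-weighted mean of per-class recall and bounds kappa", {
  set.seed(7)
  for (i in 1:50) {
    cm <- random_cm()
    if (sum(cm) == 0 || any(rowSums(cm) == 0)) next
    rec <- vapply(1:5, function(c) cm[c, c] / sum(cm[c, ]), numeric(1))
    expect_equal(accuracy(cm), 100 * sum(rowSums(cm) * rec) / sum(cm),
                 tolerance = 1e-10)
    expect_lte(cohens_kappa(cm), accuracy(cm) + 1e-10)  # kappa <= p_o when pe >= 0
  }
})

test_that("report writer produces the tabular layout and CSV round-trips", {
  cm <- confusion_matrix(rep(0:4, each = 10), rep(0:4, 10))
  rep1 <- metrics_report(cm, warn = FALSE)
  expect_s3_class(rep1, "metrics_report")
  expect_equal(rep1$n_epochs, 50)
  lines <- format_metrics_table(list(model_a = rep1))
  expect_match(lines[1], "ACC.*MF1.*Kappa.*Sen.*Spec.*Pre")
  expect_length(lines, 2)
  csv <- file.path(tempdir(), "metrics.csv")
  df <- write_metrics_csv(list(a = rep1, b = rep1), csv)
  back <- read.csv(csv)
  expect_equal(nrow(back), 2)
  expect_equal(back$acc, df$acc)
  unlink(csv)
})
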