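# serial fusion, classifier variants, and the evaluation metric suite

test_that("serial fusion concatenates values in order and adds lengths", {
  a <- feature_vector(1:400, "deep")
  b <- feature_vector(rep(0.5, 320), "vht")
  f <- fuse(a, b)
  expect_equal(length(f), 720)
  expect_equal(f$source, "fused")
  expect_equal(f$values[1:400], as.numeric(1:400))
  expect_equal(length(fuse(feature_vector(1:100, "deep"),
                           feature_vector(1:100, "vht"))), 200)
  # identity element and associativity
  empty <- feature_vector(numeric(0), "vht")
  expect_equal(fuse(empty, b)$values, b$values)
  x <- feature_vector(1:3, "vht"); y <- feature_vector(4:5, "deep")
  z <- feature_vector(6:9, "vht")
  expect_equal(fuse(fuse(x, y), z)$values, fuse(x, fuse(y, z))$values)
})

test_that("classifier variants train, reject bad input, and differ where they should", {
  expect_error(train_classifier(matrix(rnorm(20), 10), rep(c("a", "b"), 5),
                                "royal-svm"),
               "linear-svm")
  expect_error(train_classifier(matrix(rnorm(20), 10), rep("a", 10),
                                "cubic-svm"),
               "2 classes")

  # separable two-class toy: perfect training accuracy for the cubic SVM
  X <- rbind(matrix(rnorm(40, mean = -2, sd = 0.3), 20),
             matrix(rnorm(40, mean = 2, sd = 0.3), 20))
  y <- rep(c("neg", "pos"), each = 20)
  m <- train_classifier(X, y, "cubic-svm")
  expect_equal(mean(predict(m, X)$label == y), 1.0)

  # fine vs coarse Gaussian draw different boundaries on 4-class blobs
  bd <- blob_data(25, p = 2, sep = 2.5, seed = 3)
  fine <- train_classifier(bd$X, bd$y, "fine-gaussian-svm")
  coarse <- train_classifier(bd$X, bd$y, "coarse-gaussian-svm")
  grid <- as.matrix(expand.grid(seq(-4, 4, length.out = 15),
                                seq(-4, 4, length.out = 15)))
  expect_gt(sum(predict(fine, grid)$label != predict(coarse, grid)$label), 0)

  # every variant fits and predicts on the blob set
  for (v in classifier_variants()) {
    mv <- train_classifier(bd$X, bd$y, v)
    pr <- predict(mv, bd$X[1:5, , drop = FALSE])
    expect_length(pr$label, 5)
    expect_equal(dim(pr$scores), c(5, 4))
  }
})

test_that("metric suite reproduces hand-computed values from a fixed confusion matrix", {
  cm <- matrix(c(2496, 1, 0, 0,
                 0, 2483, 0, 0,
                 0, 0, 2478, 0,
                 0, 0, 1, 2498), 4, 4, byrow = TRUE,
               dimnames = list(wbc_classes(), wbc_classes()))
  rep <- metrics_from_confusion(cm)
  expect_equal(rep$n, 9957)
  expect_equal(rep$overall_accuracy, 9955 / 9957)
  expect_equal(rep$error, 2 / 9957)
  expect_equal(rep$per_class$sensitivity,
               c(2496 / 2497, 1, 1, 2498 / 2499))
  # per-class one-vs-rest counts always partition the total
  for (i in 1:4) {
    tp <- cm[i, i]; fn <- sum(cm[i, ]) - tp; fp <- sum(cm[, i]) - tp
    expect_equal(tp + fn + fp + (rep$n - tp - fn - fp), rep$n)
  }

  perfect <- metrics_from_confusion(diag(c(5, 5, 5, 5)))
  expect_equal(perfect$overall_accuracy, 1)
  expect_equal(perfect$error, 0)
  expect_true(all(as.matrix(perfect$per_class[, -1]) == 1))

  # all-one-class predictor on balanced truth: macro sensitivity 1/4
  lazy <- matrix(0, 4, 4); lazy[, 1] <- 10
  lrep <- metrics_from_confusion(lazy)
  expect_equal(unname(lrep$macro[["sensitivity"]]), 0.25)
  # 0/0 conventions: classes never predicted and never true
  expect_equal(lrep$per_class$ppv, c(0.25, 0, 0, 0))

  # class absent from both truth and prediction: NA, excluded from macro
  ghost <- matrix(0, 3, 3); ghost[1, 1] <- 4; ghost[2, 2] <- 6
  grep_ <- metrics_from_confusion(ghost)
  expect_true(all(is.na(grep_$per_class[3, -1])))
  expect_equal(unname(grep_$macro[["sensitivity"]]), 1)
})

test_that("one-vs-rest AUC behaves like trapezoidal ROC integration", {
  pos <- rep(c(TRUE, FALSE), each = 50)
  # perfect ranker
  expect_equal(vhtrellis:::ovr_auc(c(rnorm(50) + 10, rnorm(50)), pos), 1.0)
  # random scores: near 0.5 on average over seeds
  aucs <- sapply(1:10, function(s) {
    vhtrellis:::with_seed(s, vhtrellis:::ovr_auc(rnorm(100), pos))
  })
  expect_lt(abs(mean(aucs) - 0.5), 0.05)
  # agreement with an independent ROC implementation, ties included
  skip_if_not_installed("pROC")
  vhtrellis:::with_seed(3, {
    score <- sample(seq(0, 1, 0.05), 100, replace = TRUE)
    truth <- sample(c(0, 1), 100, replace = TRUE)
    ours <- vhtrellis:::ovr_auc(score, truth == 1)
    ref <- as.numeric(pROC::auc(pROC::roc(truth, score, quiet = TRUE,
                                          direction = "<")))
    expect_equal(ours, ref, tolerance = 1e-12)
  })
})

test_that("model evaluation report is internally consistent", {
  bd <- blob_data(30, p = 4, sep = 3, seed = 5)
  tr <- vhtrellis:::with_seed(1, vhtrellis:::stratified_train_mask(bd$y, 0.75))
  m <- train_classifier(bd$X[tr, ], bd$y[tr], "linear-svm")
  rep <- evaluate_model(m, bd$X[!tr, ], bd$y[!tr])
  expect_equal(sum(rep$confusion), sum(!tr))
  expect_equal(rep$overall_accuracy, sum(diag(rep$confusion)) / sum(!tr))
  expect_equal(rep$overall_accuracy + rep$error, 1)
  expect_true(all(rep$per_class$sensitivity >= 0 &
                    rep$per_class$sensitivity <= 1))
  expect_true(all(rep$auc >= 0 & rep$auc <= 1))
  # separable blobs: strong AUCs
  expect_true(all(rep$auc > 0.9))
  # ROC points span (0,0) to (1,1) monotonically
  pts <- roc_points(predict(m, bd$X[!tr, ])$scores[, 1],
                    bd$y[!tr] == wbc_classes()[1])
  expect_equal(pts$fpr[1], 0)
  expect_equal(pts$tpr[1], 0)
  expect_equal(pts$fpr[nrow(pts)], 1)
  expect_equal(pts$tpr[nrow(pts)], 1)
  expect_true(all(diff(pts$fpr) >= 0) && all(diff(pts$tpr) >= 0))
})

test_that("fusion grid reports the fused sizes and reproduces under its seed", {
  set.seed(10)
  bd <- blob_data(20, p = 30, sep = 2, seed = 7)
  vht_like <- bd$X[, 1:12] + matrix(rnorm(length(bd$X[, 1:12]), 0, 0.2),
                                    nrow(bd$X))
  out <- run_fusion_grid(bd$X, vht_like, bd$y,
                         grid = list(c(5, 5), c(8, 10)),
                         variants = c("cubic-svm", "coarse-gaussian-svm"),
                         seed = 2, aco = list(ants = 3, iterations = 2))
  expect_equal(out$fused, c(10, 10, 18, 18))
  expect_equal(nrow(out), 4)
  expect_named(attr(out, "reports"),
               c("fused10_cubic-svm", "fused10_coarse-gaussian-svm",
                 "fused18_cubic-svm", "fused18_coarse-gaussian-svm"))
  out2 <- run_fusion_grid(bd$X, vht_like, bd$y,
                          grid = list(c(5, 5), c(8, 10)),
                          variants = c("cubic-svm", "coarse-gaussian-svm"),
                          seed = 2, aco = list(ants = 3, iterations = 2))
  expect_identical(out$Acc, out2$Acc)

  empty <- run_fusion_grid(bd$X, vht_like, bd$y, grid = list())
  expect_equal(nrow(empty), 0)
  expect_named(empty, c("k_deep", "k_vht", "fused", "variant", "Acc", "Sen",
                        "Sp", "PPV", "NPV", "Error"))

  expect_error(run_fusion_grid(bd$X, vht_like, bd$y, grid = list(c(100, 5))),
               "exceeds")
})
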