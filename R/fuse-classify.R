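# Serial feature fusion, the SVM/KNN classifier variant harness, and the
# one-vs-rest evaluation metric suite (confusion matrix, Acc/Sen/Sp/PPV/NPV,
# F- and G-measure, ROC AUC).

#' Serial feature fusion
#'
#' Concatenates two feature vectors, `a`'s values followed by `b`'s, order
#' preserved exactly; the result has source `"fused"` and length
#' `length(a) + length(b)`.
#'
#' @param a,b [feature_vector()] objects (or bare numeric vectors).
#' @return A fused [feature_vector()].
#' @export
fuse <- function(a, b) {
  va <- if (inherits(a, "feature_vector")) a$values else as.numeric(a)
  vb <- if (inherits(b, "feature_vector")) b$values else as.numeric(b)
  feature_vector(c(va, vb), "fused")
}

#' Column-wise serial fusion of two feature tables
#'
#' @param a,b numeric matrices with equal row counts.
#' @return Matrix `[a | b]` with prefixed column names.
#' @export
fuse_tables <- function(a, b) {
  stopifnot(nrow(a) == nrow(b))
  out <- cbind(a, b)
  colnames(out) <- c(paste0("a_", seq_len(ncol(a))),
                     paste0("b_", seq_len(ncol(b))))
  out
}

SVM_VARIANTS <- c("linear-svm", "quadratic-svm", "cubic-svm",
                  "fine-gaussian-svm", "medium-gaussian-svm",
                  "coarse-gaussian-svm")
KNN_VARIANTS <- c("fine-knn", "coarse-knn", "cosine-knn")

#' Supported classifier variants
#'
#' Six SVM variants (linear; polynomial degree 2 and 3; Gaussian RBF with
#' fine/medium/coarse kernel scale `sqrt(d)/4`, `sqrt(d)`, `4*sqrt(d)` for
#' `d` features) and three nearest-neighbour variants (fine `k=1` and
#' coarse `k=100` Euclidean, cosine `k=10`).
#'
#' @return Character vector of variant names.
#' @export
classifier_variants <- function() c(SVM_VARIANTS, KNN_VARIANTS)

#' Train a multiclass classifier variant
#'
#' Features are standardized to zero mean / unit variance using training
#' statistics only; SVM variants use one-vs-one multiclass decomposition
#' with box constraint 1.
#'
#' @param X numeric training matrix (samples x features).
#' @param y training labels; at least 2 classes.
#' @param variant one of [classifier_variants()].
#' @param seed RNG seed for the (deterministic up to ties) fit.
#' @return An object of class `wbc_model`.
#' @export
train_classifier <- function(X, y, variant, seed = 1L) {
  if (!variant %in% classifier_variants()) {
    stop("unknown variant '", variant, "'; supported: ",
         paste(classifier_variants(), collapse = ", "))
  }
  y <- droplevels(as.factor(y))
  if (nlevels(y) < 2) stop("training labels must contain at least 2 classes")
  X <- as.matrix(X)
  ctr <- colMeans(X)
  scl <- apply(X, 2, stats::sd)
  scl[!is.finite(scl) | scl <= 0] <- 1
  Xs <- scale(X, ctr, scl)
  d <- ncol(X)
  model <- list(variant = variant, center = ctr, scale = scl,
                classes = levels(y))
  if (variant %in% SVM_VARIANTS) {
    args <- switch(variant,
      "linear-svm" = list(kernel = "linear"),
      "quadratic-svm" = list(kernel = "polynomial", degree = 2,
                             gamma = 1 / d, coef0 = 1),
      "cubic-svm" = list(kernel = "polynomial", degree = 3,
                         gamma = 1 / d, coef0 = 1),
      "fine-gaussian-svm" = list(kernel = "radial", gamma = 16 / d),
      "medium-gaussian-svm" = list(kernel = "radial", gamma = 1 / d),
      "coarse-gaussian-svm" = list(kernel = "radial", gamma = 1 / (16 * d)))
    fit <- with_seed(seed, do.call(e1071::svm, c(
      list(x = Xs, y = y, cost = 1, scale = FALSE), args)))
    model$type <- "svm"
    model$fit <- fit
  } else {
    model$type <- "knn"
    model$k <- switch(variant, "fine-knn" = 1L, "coarse-knn" = 100L,
                      "cosine-knn" = 10L)
    model$cosine <- variant == "cosine-knn"
    model$train_x <- Xs
    model$train_y <- y
  }
  class(model) <- "wbc_model"
  model
}

#' @export
print.wbc_model <- function(x, ...) {
  cat(sprintf("<wbc_model> %s over %d classes\n", x$variant,
              length(x$classes)))
  invisible(x)
}

# L2-normalize rows (for cosine distance via Euclidean ranking)
row_unit <- function(m) {
  n <- sqrt(rowSums(m^2))
  n[n == 0] <- 1
  m / n
}

#' Predict labels and one-vs-rest decision scores
#'
#' SVM variants aggregate the one-vs-one decision values into per-class
#' scores (signed margin votes); KNN variants score each class by its vote
#' fraction among the k nearest training samples.
#'
#' @param object a [train_classifier()] model.
#' @param newdata numeric matrix of test samples.
#' @param ... unused.
#' @return List with `label` (factor over the model's classes) and `scores`
#'   (samples x classes numeric matrix).
#' @export
predict.wbc_model <- function(object, newdata, ...) {
  X <- scale(as.matrix(newdata), object$center, object$scale)
  cls <- object$classes
  scores <- matrix(0, nrow(X), length(cls), dimnames = list(NULL, cls))
  if (object$type == "svm") {
    pred <- stats::predict(object$fit, X, decision.values = TRUE)
    dv <- attr(pred, "decision.values")
    for (j in seq_len(ncol(dv))) {
      pair <- strsplit(colnames(dv)[j], "/", fixed = TRUE)[[1]]
      scores[, pair[1]] <- scores[, pair[1]] + dv[, j]
      scores[, pair[2]] <- scores[, pair[2]] - dv[, j]
    }
    label <- factor(as.character(pred), levels = cls)
  } else {
    tr <- object$train_x
    te <- X
    if (object$cosine) {
      tr <- row_unit(tr)
      te <- row_unit(te)
    }
    k <- min(object$k, nrow(tr))
    # squared Euclidean distances test x train
    d2 <- outer(rowSums(te^2), rowSums(tr^2), "+") - 2 * te %*% t(tr)
    lab_int <- as.integer(object$train_y)
    votes <- t(apply(d2, 1, function(row) {
      nn <- lab_int[order(row)[seq_len(k)]]
      tabulate(nn, nbins = length(cls)) / k
    }))
    scores[] <- votes
    label <- factor(cls[max.col(votes, ties.method = "first")], levels = cls)
  }
  list(label = label, scores = scores)
}

# tie-corrected rank (Mann-Whitney) form of trapezoidal ROC integration
ovr_auc <- function(score, positive) {
  n_pos <- sum(positive)
  n_neg <- sum(!positive)
  if (n_pos == 0 || n_neg == 0) return(NA_real_)
  r <- rank(score)
  (sum(r[positive]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Metric suite from a multiclass confusion matrix
#'
#' Rows are true classes, columns predicted.  Per class (one-vs-rest):
#' sensitivity TP/(TP+FN), specificity TN/(TN+FP), PPV TP/(TP+FP),
#' NPV TN/(TN+FN), accuracy (TP+TN)/total, F-measure
#' `2*PPV*Sen/(PPV+Sen)`, G-measure `sqrt(PPV*Sen)`; every 0/0 is defined
#' as 0.  A class absent from both truth and prediction gets `NA` metrics
#' and is excluded from the macro averages.  The overall accuracy is
#' `trace/total` and `error = 1 - overall_accuracy`.
#'
#' @param confusion square count matrix with identical row/col class order.
#' @return An object of class `eval_report` (without AUCs).
#' @export
metrics_from_confusion <- function(confusion) {
  confusion <- as.matrix(confusion)
  stopifnot(nrow(confusion) == ncol(confusion), all(confusion >= 0))
  cls <- rownames(confusion)
  if (is.null(cls)) {
    cls <- paste0("class", seq_len(nrow(confusion)))
    dimnames(confusion) <- list(cls, cls)
  }
  total <- sum(confusion)
  div0 <- function(num, den) ifelse(den == 0, 0, num / den)
  per <- do.call(rbind, lapply(seq_along(cls), function(i) {
    tp <- confusion[i, i]
    fn <- sum(confusion[i, ]) - tp
    fp <- sum(confusion[, i]) - tp
    tn <- total - tp - fn - fp
    if (tp + fn + fp == 0) {
      return(data.frame(class = cls[i], accuracy = NA_real_,
                        sensitivity = NA_real_, specificity = NA_real_,
                        ppv = NA_real_, npv = NA_real_,
                        f_measure = NA_real_, g_measure = NA_real_))
    }
    sen <- div0(tp, tp + fn)
    ppv <- div0(tp, tp + fp)
    data.frame(class = cls[i],
               accuracy = div0(tp + tn, total),
               sensitivity = sen,
               specificity = div0(tn, tn + fp),
               ppv = ppv,
               npv = div0(tn, tn + fn),
               f_measure = div0(2 * ppv * sen, ppv + sen),
               g_measure = sqrt(ppv * sen))
  }))
  rownames(per) <- NULL
  macro <- colMeans(per[, -1], na.rm = TRUE)
  overall <- if (total == 0) 0 else sum(diag(confusion)) / total
  structure(list(confusion = confusion, per_class = per, macro = macro,
                 overall_accuracy = overall, error = 1 - overall,
                 n = total, auc = NULL),
            class = "eval_report")
}

#' Evaluate a fitted model on a test set
#'
#' Builds the confusion matrix and the full metric suite of
#' [metrics_from_confusion()], plus per-class one-vs-rest AUCs computed by
#' trapezoidal ROC integration of the decision scores.
#'
#' @param model a [train_classifier()] model.
#' @param X_test,y_test test features and labels.
#' @return An `eval_report` with an `auc` component (one value per class).
#' @export
evaluate_model <- function(model, X_test, y_test) {
  stopifnot(nrow(X_test) > 0)
  pred <- predict(model, X_test)
  cls <- model$classes
  y_test <- factor(as.character(y_test), levels = cls)
  confusion <- table(true = y_test, predicted = pred$label)
  report <- metrics_from_confusion(unclass(as.matrix(confusion)))
  report$auc <- vapply(cls, function(cl) {
    ovr_auc(pred$scores[, cl], y_test == cl)
  }, numeric(1))
  report$per_class$auc <- report$auc
  report
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> n=%d overall accuracy=%.4f error=%.4f\n",
              x$n, x$overall_accuracy, x$error))
  print(x$confusion)
  print(x$per_class, digits = 4)
  invisible(x)
}

#' ROC curve points for one class
#'
#' @param score one-vs-rest decision scores.
#' @param positive logical vector, `TRUE` for the positive class.
#' @return data.frame with `threshold`, `fpr`, `tpr` (descending
#'   thresholds).
#' @export
roc_points <- function(score, positive) {
  ord <- order(score, decreasing = TRUE)
  tp <- cumsum(positive[ord])
  fp <- cumsum(!positive[ord])
  keep <- c(diff(score[ord]) != 0, TRUE)  # one point per distinct threshold
  data.frame(threshold = c(Inf, score[ord][keep]),
             fpr = c(0, fp[keep]) / max(sum(!positive), 1),
             tpr = c(0, tp[keep]) / max(sum(positive), 1))
}

#' Run the fusion experiment grid
#'
#' For each `(k_deep, k_vht)` grid point: ACO-selects `k_deep` deep
#' features on the training split, truncates the VHT table to its first
#' `k_vht` columns (layout order), serially fuses them, and fits and
#' evaluates every requested classifier variant on a seeded stratified
#' 75/25 train/test split.
#'
#' @param deep feature table ([featurize()] output) or numeric matrix.
#' @param vht feature table ([extract_vht_features()] output) or matrix.
#' @param y labels (taken from the tables when omitted).
#' @param grid list of `c(k_deep, k_vht)` pairs.
#' @param variants classifier variants to fit.
#' @param seed split and selection seed.
#' @param train_frac training fraction (default 0.75).
#' @param aco ACO parameters (list; see [aco_select()]).
#' @return data.frame with one row per grid point x variant and columns
#'   `k_deep, k_vht, fused, variant, Acc, Sen, Sp, PPV, NPV, Error`
#'   (percent scale for the rates, matching the reporting convention).
#'   Full `eval_report`s are attached as attribute `"reports"`.
#' @export
run_fusion_grid <- function(deep, vht, y = NULL, grid,
                            variants = "cubic-svm", seed = 1L,
                            train_frac = 0.75, aco = list()) {
  if (is.data.frame(deep)) {
    fm <- feature_matrix(deep)
    if (is.null(y)) y <- fm$y
    deep <- fm$X
  }
  if (is.data.frame(vht)) {
    fm <- feature_matrix(vht)
    if (is.null(y)) y <- fm$y
    vht <- fm$X
  }
  y <- as.factor(y)
  stopifnot(nrow(deep) == nrow(vht), nrow(deep) == length(y))
  aco_def <- list(ants = 20, iterations = 30, alpha = 1, beta = 1,
                  rho = 0.2, cv_folds = 3)
  aco <- utils::modifyList(aco_def, aco)
  cols <- c("k_deep", "k_vht", "fused", "variant", "Acc", "Sen", "Sp",
            "PPV", "NPV", "Error")
  if (length(grid) == 0) {
    out <- as.data.frame(matrix(numeric(0), 0, length(cols)))
    names(out) <- cols
    attr(out, "reports") <- list()
    return(out)
  }
  train <- with_seed(seed, stratified_train_mask(y, train_frac))
  rows <- list()
  reports <- list()
  selections <- list()
  for (gi in seq_along(grid)) {
    k_deep <- grid[[gi]][1]
    k_vht <- grid[[gi]][2]
    if (k_deep > ncol(deep) || k_vht > ncol(vht)) {
      stop("grid point (", k_deep, ", ", k_vht,
           ") exceeds available features (", ncol(deep), ", ", ncol(vht), ")")
    }
    sel <- aco_select(deep[train, , drop = FALSE], y[train], k_deep,
                      ants = aco$ants, iterations = aco$iterations,
                      alpha = aco$alpha, beta = aco$beta, rho = aco$rho,
                      cv_folds = aco$cv_folds,
                      seed = child_seed(seed, gi))
    selections[[sprintf("deep%d", k_deep)]] <- sel
    Xf <- fuse_tables(deep[, sel$best_subset, drop = FALSE],
                      vht[, seq_len(k_vht), drop = FALSE])
    for (v in variants) {
      m <- train_classifier(Xf[train, , drop = FALSE], y[train], v,
                            seed = child_seed(seed, 1000 + gi))
      rep <- evaluate_model(m, Xf[!train, , drop = FALSE], y[!train])
      key <- sprintf("fused%d_%s", k_deep + k_vht, v)
      reports[[key]] <- rep
      rows[[length(rows) + 1]] <- data.frame(
        k_deep = k_deep, k_vht = k_vht, fused = k_deep + k_vht, variant = v,
        Acc = 100 * rep$overall_accuracy,
        Sen = 100 * rep$macro[["sensitivity"]],
        Sp = 100 * rep$macro[["specificity"]],
        PPV = 100 * rep$macro[["ppv"]],
        NPV = 100 * rep$macro[["npv"]],
        Error = rep$error)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "reports") <- reports
  attr(out, "selections") <- selections
  out
}
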