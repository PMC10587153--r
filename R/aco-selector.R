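# Ant colony optimization wrapper feature selection.
#
# Each ant constructs a k-feature subset by sampling without replacement
# with probability proportional to tau^alpha * eta^beta, where tau is the
# learned pheromone and eta a Fisher-ratio heuristic of per-feature class
# separation.  Subsets are scored by stratified cross-validated accuracy of
# a linear SVM; pheromone evaporates each iteration and the iteration-best
# subset deposits proportionally to its fitness.

#' Fisher discriminant heuristic scores
#'
#' For each feature, the ratio of between-class variance of the class means
#' to pooled within-class variance (plus a small epsilon).  A feature that
#' is constant across all samples scores 0; sample order is irrelevant.
#'
#' @param X numeric matrix (samples x features).
#' @param y labels; at least 2 classes with at least 2 samples each.
#' @param eps stabilizer added to the within-class variance.
#' @return Nonnegative finite numeric vector, one score per feature.
#' @export
heuristic_scores <- function(X, y, eps = 1e-12) {
  y <- as.factor(y)
  if (nlevels(y) < 2) stop("heuristic needs at least 2 classes")
  if (any(table(y) < 2)) stop("each class needs at least 2 samples")
  n <- nrow(X)
  mu <- colMeans(X)
  between <- numeric(ncol(X))
  within <- numeric(ncol(X))
  for (cl in levels(y)) {
    idx <- which(y == cl)
    mu_c <- colMeans(X[idx, , drop = FALSE])
    v_c <- apply(X[idx, , drop = FALSE], 2, stats::var)
    w <- length(idx) / n
    between <- between + w * (mu_c - mu)^2
    within <- within + w * v_c
  }
  between / (within + eps)
}

# fresh selection state
new_selection_state <- function(n_features, eta, tau0 = 1,
                                tau_bounds = c(0.01, 10)) {
  structure(list(pheromone = rep(tau0, n_features), heuristic = eta,
                 tau_bounds = tau_bounds, best_subset = integer(0),
                 best_fitness = -Inf, history = numeric(0)),
            class = "aco_state")
}

#' Construct one ant's feature subset
#'
#' Samples `k` distinct feature indices with probability proportional to
#' `pheromone^alpha * heuristic^beta`.  With `alpha = beta = 0` this is
#' uniform sampling without replacement.
#'
#' @param state an `aco_state` (see [aco_select()]), or any list with
#'   `pheromone` and `heuristic` vectors.
#' @param k subset size, at most the number of features.
#' @param alpha pheromone exponent.
#' @param beta heuristic exponent.
#' @return Sorted integer vector of `k` distinct indices.
#' @export
construct_subset <- function(state, k, alpha = 1, beta = 1) {
  p <- length(state$pheromone)
  if (k > p) stop("k (", k, ") exceeds the number of features (", p, ")")
  if (k == p) return(seq_len(p))
  w <- state$pheromone^alpha * state$heuristic^beta
  if (!any(w > 0) || any(!is.finite(w))) w <- rep(1, p)
  sort(sample.int(p, k, prob = w))
}

# mean stratified k-fold CV accuracy of a linear SVM on a feature subset
subset_fitness <- function(X, y, subset, folds) {
  acc <- numeric(max(folds))
  for (f in seq_len(max(folds))) {
    tr <- folds != f
    m <- train_classifier(X[tr, subset, drop = FALSE], y[tr], "linear-svm")
    pred <- predict(m, X[!tr, subset, drop = FALSE])$label
    acc[f] <- mean(pred == y[!tr])
  }
  mean(acc)
}

#' ACO feature selection
#'
#' Runs `ants x iterations` subset constructions.  Fitness is the mean
#' stratified `cv_folds`-fold cross-validated accuracy of a linear SVM
#' restricted to the subset.  After each iteration the pheromone evaporates
#' by `1 - rho` and the iteration-best subset receives a deposit
#' proportional to its fitness; pheromone is clamped to `tau_bounds`.
#' The best-so-far subset and fitness history (monotone non-decreasing) are
#' tracked across iterations.
#'
#' @param X numeric matrix (samples x features).
#' @param y class labels.
#' @param k exact number of features to select.
#' @param ants subset constructions per iteration.
#' @param iterations number of iterations.
#' @param alpha,beta sampling exponents (see [construct_subset()]).
#' @param rho evaporation rate in (0, 1).
#' @param tau0 initial pheromone.
#' @param tau_bounds pheromone clamp `[tau_min, tau_max]`.
#' @param cv_folds stratified folds for the fitness classifier.
#' @param seed RNG seed; identical inputs and seed give an identical
#'   selection.
#' @return An `aco_state` with `best_subset` (size exactly `k`, sorted),
#'   `best_fitness`, per-iteration `history`, and the final `pheromone` and
#'   `heuristic` vectors.
#' @export
aco_select <- function(X, y, k, ants = 20, iterations = 30,
                       alpha = 1, beta = 1, rho = 0.2, tau0 = 1,
                       tau_bounds = c(0.01, 10), cv_folds = 3, seed = 1L) {
  y <- as.factor(y)
  stopifnot(k >= 1, rho > 0, rho < 1)
  if (k > ncol(X)) stop("k exceeds the number of features")
  eta <- heuristic_scores(X, y)
  state <- new_selection_state(ncol(X), eta, tau0, tau_bounds)
  with_seed(seed, {
    folds <- stratified_folds(y, cv_folds)
    if (k == ncol(X)) {
      # only one subset exists; its CV accuracy is the answer
      fit <- subset_fitness(X, y, seq_len(ncol(X)), folds)
      state$best_subset <- seq_len(ncol(X))
      state$best_fitness <- fit
      state$history <- rep(fit, iterations)
      return(state)
    }
    for (it in seq_len(iterations)) {
      it_best <- NULL
      it_fit <- -Inf
      for (a in seq_len(ants)) {
        subset <- construct_subset(state, k, alpha, beta)
        fit <- subset_fitness(X, y, subset, folds)
        if (fit > it_fit) {
          it_fit <- fit
          it_best <- subset
        }
      }
      if (it_fit > state$best_fitness) {
        state$best_fitness <- it_fit
        state$best_subset <- it_best
      }
      state$history[it] <- state$best_fitness
      state$pheromone <- state$pheromone * (1 - rho)
      state$pheromone[it_best] <- state$pheromone[it_best] + rho * it_fit
      state$pheromone <- pmin(pmax(state$pheromone, tau_bounds[1]),
                              tau_bounds[2])
    }
    state
  })
}

#' @export
print.aco_state <- function(x, ...) {
  cat(sprintf("<aco_state> k=%d best_fitness=%.4f iterations=%d\n",
              length(x$best_subset), x$best_fitness, length(x$history)))
  invisible(x)
}

#' Write an ACO selection to JSON
#'
#' @param state an `aco_state` from [aco_select()].
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_selection <- function(state, path) {
  jsonlite::write_json(
    list(selected = state$best_subset, best_fitness = state$best_fitness,
         history = state$history),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
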