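# shared internals: seeded evaluation, luminance, 3x3 filtering, splits

# run code under a temporary RNG state; restores the caller's stream
#' @keywords internal
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# derive a well-spread child seed from (seed, index), kept below 2^31
#' @keywords internal
child_seed <- function(seed, index) {
  (seed * 48271 + index * 16807) %% 2147483587
}

#' Grayscale luminance of a smear image
#'
#' Standard Rec. 601 weights (0.299, 0.587, 0.114) on the 0-255 scale.
#'
#' @param img a [smear_image()] or an H x W x 3 array.
#' @return Numeric H x W matrix.
#' @export
luminance <- function(img) {
  px <- if (inherits(img, "smear_image")) img$pixels else img
  if (is.matrix(px)) return(px + 0)
  stopifnot(length(dim(px)) == 3)
  0.299 * px[, , 1] + 0.587 * px[, , 2] + 0.114 * px[, , 3]
}

# 3x3 sliding dot product (cross-correlation) with reflect-101 border
# padding, so the output has the input's size.  kernel[1,1] multiplies the
# top-left neighbour, matching the symbolic f1..f9 layout.
#' @keywords internal
filter3x3 <- function(mat, kernel) {
  h <- nrow(mat); w <- ncol(mat)
  if (h < 3 || w < 3) stop("image must be at least 3x3 for 3x3 filtering")
  ri <- c(2, seq_len(h), h - 1)
  ci <- c(2, seq_len(w), w - 1)
  p <- mat[ri, ci]
  out <- matrix(0, h, w)
  for (i in 1:3) {
    for (j in 1:3) {
      if (kernel[i, j] != 0) {
        out <- out + kernel[i, j] * p[i:(i + h - 1), j:(j + w - 1)]
      }
    }
  }
  out
}

# stratified fold assignment (1..k per sample), shuffled within class
#' @keywords internal
stratified_folds <- function(y, k) {
  y <- as.factor(y)
  if (any(table(y) < k)) stop("each class needs at least ", k, " samples for ",
                              k, "-fold stratification")
  folds <- integer(length(y))
  for (cl in levels(y)) {
    idx <- sample(which(y == cl))
    folds[idx] <- rep_len(seq_len(k), length(idx))
  }
  folds
}

# stratified train/test split; returns logical TRUE for training rows
#' @keywords internal
stratified_train_mask <- function(y, train_frac) {
  y <- as.factor(y)
  mask <- logical(length(y))
  for (cl in levels(y)) {
    idx <- which(y == cl)
    n_tr <- round(length(idx) * train_frac)
    mask[sample(idx)[seq_len(n_tr)]] <- TRUE
  }
  mask
}

# clamp to [0,255] and round to 8-bit integers
#' @keywords internal
clamp255 <- function(x) {
  x[x < 0] <- 0
  x[x > 255] <- 255
  round(x)
}
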