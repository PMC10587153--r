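# Pluggable deep-feature backend.  The pipeline treats any image ->
# fixed-length vector transform as a "deep" feature source; the default is
# a deterministic surrogate that pools multiscale patch statistics and maps
# them through a fixed seeded random projection.  A trained CNN can be
# plugged in behind the same contract.

#' Construct a feature backend
#'
#' @param name identifier.
#' @param dim output feature count.
#' @param transform function taking a [smear_image()] (or array) and
#'   returning a numeric vector of length `dim`; must be deterministic.
#' @return An object of class `feature_backend`.
#' @export
feature_backend <- function(name, dim, transform) {
  stopifnot(is.function(transform), dim >= 1)
  structure(list(name = name, dim = as.integer(dim), transform = transform),
            class = "feature_backend")
}

#' @export
print.feature_backend <- function(x, ...) {
  cat(sprintf("<feature_backend> %s (dim=%d)\n", x$name, x$dim))
  invisible(x)
}

# per-block mean and sd over a g x g partition of a matrix
block_stats <- function(mat, g = 8) {
  rb <- round(seq(0, nrow(mat), length.out = g + 1))
  cb <- round(seq(0, ncol(mat), length.out = g + 1))
  out <- numeric(2 * g * g)
  k <- 0
  for (a in seq_len(g)) {
    for (b in seq_len(g)) {
      v <- as.vector(mat[(rb[a] + 1):rb[a + 1], (cb[b] + 1):cb[b + 1]])
      s <- stats::sd(v)
      out[k + 1] <- mean(v)
      out[k + 2] <- if (is.na(s)) 0 else s
      k <- k + 2
    }
  }
  out
}

#' Deterministic surrogate deep-feature backend
#'
#' Computes 8x8 block means and standard deviations of the luminance image
#' and of the four VHT gradient response maps (640 raw statistics), then
#' maps them through a fixed Gaussian random projection drawn once from
#' `seed`.  Two backends built with the same seed are identical forever;
#' the default output length is 4096, matching the fully-connected feature
#' width of the CNN the contract stands in for.
#'
#' @param seed projection seed.
#' @param dim output feature count (default 4096).
#' @return A [feature_backend()] named `"surrogate"`.
#' @export
surrogate_backend <- function(seed = 1L, dim = 4096) {
  stopifnot(dim >= 1)
  g <- 8
  n_raw <- 5 * 2 * g * g
  proj <- with_seed(seed,
                    matrix(stats::rnorm(dim * n_raw), dim, n_raw) / sqrt(n_raw))
  transform <- function(img) {
    lum <- luminance(img)
    maps <- gradient_responses(lum)
    raw <- c(block_stats(lum, g),
             unlist(lapply(maps, block_stats, g = g), use.names = FALSE))
    as.vector(proj %*% raw)
  }
  feature_backend(sprintf("surrogate(seed=%d)", as.integer(seed)), dim,
                  transform)
}

#' Compute backend features for every image of a manifest
#'
#' @param manifest manifest data.frame or CSV path.
#' @param backend a [feature_backend()].
#' @param out_file optional CSV output (`path,label,deep_0000..`).
#' @return data.frame with `path`, `label` and `dim` feature columns, rows
#'   in manifest order.
#' @export
featurize <- function(manifest, backend = surrogate_backend(),
                      out_file = NULL) {
  if (is.character(manifest)) manifest <- read_manifest(manifest)
  stopifnot(inherits(backend, "feature_backend"))
  cols <- sprintf("deep_%04d", seq_len(backend$dim) - 1)
  if (nrow(manifest) == 0) {
    out <- as.data.frame(matrix(numeric(0), 0, 2 + backend$dim))
    names(out) <- c("path", "label", cols)
  } else {
    feats <- lapply(seq_len(nrow(manifest)), function(i) {
      if (!file.exists(manifest$path[i])) {
        stop("cannot read image: ", manifest$path[i])
      }
      v <- backend$transform(read_smear(manifest$path[i]))
      if (length(v) != backend$dim) {
        stop("backend '", backend$name, "' returned ", length(v),
             " values, expected ", backend$dim)
      }
      v
    })
    out <- cbind(data.frame(path = manifest$path, label = manifest$label),
                 stats::setNames(as.data.frame(do.call(rbind, feats)), cols))
  }
  rownames(out) <- NULL
  if (!is.null(out_file)) data.table::fwrite(out, out_file)
  out
}

#' Split a feature table into matrix and labels
#'
#' @param tab data.frame from [featurize()] / [extract_vht_features()].
#' @return list with `X` (numeric matrix of the feature columns) and `y`
#'   (factor of labels).
#' @export
feature_matrix <- function(tab) {
  keep <- setdiff(names(tab), c("path", "label", "provenance"))
  list(X = as.matrix(tab[, keep, drop = FALSE]), y = factor(tab$label))
}
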