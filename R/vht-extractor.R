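# The VHT texture feature extractor: the four trellis gradient kernels are
# slid over the grayscale image and intensity/energy/correlation statistics
# are pooled over a fixed grid of cells, giving a 320-value descriptor
# (4 directions x 16 cells x 5 statistics) at the standard 200x200 side.

#' Construct a feature vector
#'
#' @param values numeric vector, all finite.
#' @param source one of `"vht"`, `"deep"`, `"fused"`.
#' @return An object of class `feature_vector`.
#' @export
feature_vector <- function(values, source = c("vht", "deep", "fused")) {
  source <- match.arg(source)
  values <- stats::setNames(as.numeric(values), names(values))
  if (any(!is.finite(values))) stop("feature values must all be finite")
  structure(list(values = values, source = source, length = length(values)),
            class = "feature_vector")
}

#' @export
print.feature_vector <- function(x, ...) {
  cat(sprintf("<feature_vector> source=%s length=%d\n", x$source, x$length))
  invisible(x)
}

#' @export
length.feature_vector <- function(x) x$length

#' Directional gradient response maps
#'
#' Converts the image to luminance and slides each of the four VHT kernels
#' over it (sliding dot product, reflect-101 border padding), giving one
#' same-sized response map per direction.  Zero-sum kernels guarantee a
#' zero map on constant input.
#'
#' @param img a [smear_image()], H x W x 3 array, or numeric matrix
#'   (already-grayscale), at least 3x3.
#' @param kernels a [canonical_kernels()] `kernel_set`.
#' @return Named list of numeric matrices `x, y, d45, d135`.
#' @export
gradient_responses <- function(img, kernels = canonical_kernels()) {
  lum <- luminance(img)
  if (nrow(lum) < 3 || ncol(lum) < 3) stop("image must be at least 3x3")
  lapply(kernel_matrices(kernels), function(k) filter3x3(lum, k))
}

# five pooled statistics of one grid cell of one response map
cell_stats <- function(resp, lum) {
  v <- as.vector(resp)
  l <- as.vector(lum)
  s <- stats::sd(v)
  if (is.na(s)) s <- 0
  corr <- if (s == 0 || stats::sd(l) == 0) 0 else stats::cor(v, l)
  c(mean = mean(v), absmean = mean(abs(v)), energy = mean(v^2),
    sd = s, cor = corr)
}

#' Extract the VHT feature vector of one image
#'
#' The image must be square at the standard side (preprocess first with
#' [resize_to_standard()]).  For each of the 4 response maps and each cell
#' of the `grid x grid` partition, five statistics are pooled: mean
#' response, mean absolute response, energy (mean squared response),
#' standard deviation, and the Pearson correlation between the cell's
#' response and luminance values (defined as 0 for a zero-variance cell).
#' Features are concatenated map-major, cells row-major, statistics in the
#' order listed, giving `4 * grid^2 * 5` values — 320 at the default 4x4
#' grid.
#'
#' @param img a [smear_image()] or H x W x 3 array.
#' @param grid cells per side of the pooling partition (default 4).
#' @param side required image side (default 200).
#' @param kernels a `kernel_set`.
#' @return A [feature_vector()] with source `"vht"` and named values
#'   `vht_000 ...`.
#' @export
vht_extract <- function(img, grid = 4, side = 200,
                        kernels = canonical_kernels()) {
  lum <- luminance(img)
  if (nrow(lum) != ncol(lum) || nrow(lum) != side) {
    stop("expected a ", side, "x", side, " square image (got ",
         nrow(lum), "x", ncol(lum),
         "); preprocess with resize_to_standard() first")
  }
  maps <- gradient_responses(lum, kernels)
  bounds <- round(seq(0, side, length.out = grid + 1))
  vals <- numeric(0)
  for (m in maps) {
    for (a in seq_len(grid)) {
      ri <- (bounds[a] + 1):bounds[a + 1]
      for (b in seq_len(grid)) {
        ci <- (bounds[b] + 1):bounds[b + 1]
        vals <- c(vals, cell_stats(m[ri, ci], lum[ri, ci]))
      }
    }
  }
  names(vals) <- sprintf("vht_%03d", seq_along(vals) - 1)
  feature_vector(vals, "vht")
}

#' Extract VHT features for every image of a manifest
#'
#' @param manifest manifest data.frame or CSV path (`path,label,...`).
#' @param grid,side,kernels passed to [vht_extract()].
#' @param out_file optional CSV output (`path,label,vht_000..`).
#' @return data.frame: one row per image with `path`, `label` and the
#'   feature columns.
#' @export
extract_vht_features <- function(manifest, grid = 4, side = 200,
                                 kernels = canonical_kernels(),
                                 out_file = NULL) {
  if (is.character(manifest)) manifest <- read_manifest(manifest)
  feats <- lapply(seq_len(nrow(manifest)), function(i) {
    img <- read_smear(manifest$path[i])
    vht_extract(img, grid = grid, side = side, kernels = kernels)$values
  })
  out <- cbind(data.frame(path = manifest$path, label = manifest$label),
               as.data.frame(do.call(rbind, feats)))
  rownames(out) <- NULL
  if (!is.null(out_file)) data.table::fwrite(out, out_file)
  out
}
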