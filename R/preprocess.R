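# Pre-processing: dark-border autocrop, resize to the standard square side,
# and the four dataset augmentations (right 90-degree rotation, horizontal
# flip, vertical flip, salt-and-pepper noise) used to balance classes.

#' Crop away the dark background border
#'
#' Returns the tight bounding box of all pixels whose maximum channel
#' intensity reaches `dark_threshold`; if no pixel qualifies the image is
#' returned unchanged.  Idempotent.
#'
#' @param img a [smear_image()].
#' @param dark_threshold intensity (0-255) below which a pixel counts as
#'   dark background.
#' @return A cropped [smear_image()].
#' @export
autocrop <- function(img, dark_threshold = 20) {
  stopifnot(inherits(img, "smear_image"))
  bright <- pmax(img$pixels[, , 1], img$pixels[, , 2], img$pixels[, , 3]) >=
    dark_threshold
  if (!any(bright)) return(img)
  rows <- range(which(rowSums(bright) > 0))
  cols <- range(which(colSums(bright) > 0))
  smear_image(img$pixels[rows[1]:rows[2], cols[1]:cols[2], , drop = FALSE],
              label = img$label, provenance = img$provenance)
}

#' Resize to the standard square side
#'
#' Bilinear interpolation to `side x side`; an image already at the target
#' size is returned pixel-identical.
#'
#' @param img a [smear_image()].
#' @param side target side in pixels (default 200).
#' @return A [smear_image()] of size `side x side`.
#' @export
resize_to_standard <- function(img, side = 200) {
  stopifnot(inherits(img, "smear_image"), side >= 3)
  d <- dim(img$pixels)
  if (d[1] == side && d[2] == side) return(img)
  px <- EBImage::resize(img$pixels, w = side, h = side)
  smear_image(clamp255(px), label = img$label, provenance = img$provenance)
}

AUGMENT_OPS <- c("rot90_right", "flip_horizontal", "flip_vertical",
                 "salt_pepper")

#' Dataset augmentation operations
#'
#' The four augmentations applied when balancing the dataset, in their fixed
#' cycling order: right 90-degree rotation, horizontal flip, vertical flip,
#' and salt-and-pepper impulse noise.
#'
#' @return Character vector of operation names.
#' @export
augment_ops <- function() AUGMENT_OPS

#' Apply one augmentation operation
#'
#' Geometric operations are exact (pure index permutations).
#' `salt_pepper` sets exactly `floor(density * H * W)` seeded pixel
#' positions to pure black or white, half each.
#'
#' @param img a [smear_image()].
#' @param op one of [augment_ops()].
#' @param density salt-and-pepper pixel fraction in (0, 1).
#' @param seed seed for the salt-and-pepper positions.
#' @return The augmented [smear_image()] with provenance `"augmented:<op>"`.
#' @export
augment_image <- function(img, op, density = 0.02, seed = 1L) {
  stopifnot(inherits(img, "smear_image"))
  op <- match.arg(op, AUGMENT_OPS)
  px <- img$pixels
  h <- dim(px)[1]; w <- dim(px)[2]
  out <- switch(op,
    rot90_right = {
      o <- array(0, c(w, h, 3))
      for (ch in 1:3) o[, , ch] <- t(px[h:1, , ch])
      o
    },
    flip_horizontal = px[, w:1, , drop = FALSE],
    flip_vertical = px[h:1, , , drop = FALSE],
    salt_pepper = {
      stopifnot(density > 0, density < 1)
      n <- floor(density * h * w)
      with_seed(seed, {
        at <- sample(h * w, n)
        val <- rep(c(255, 0), length.out = n)
        for (ch in 1:3) {
          plane <- px[, , ch]
          plane[at] <- val
          px[, , ch] <- plane
        }
        px
      })
    })
  smear_image(out, label = img$label,
              provenance = paste0("augmented:", op))
}

#' Balance a dataset by cyclic augmentation
#'
#' Grows every class to exactly `target_per_class` rows by augmenting
#' uniformly sampled originals, cycling through `ops` in order.  Original
#' rows are never removed; augmented images are written next to the class
#' directories of `out_dir` and their provenance records the operation.
#'
#' @param manifest manifest data.frame or CSV path with columns
#'   `path,label,provenance`.
#' @param target_per_class target rows per class; must be at least the
#'   current size of every class.
#' @param ops operation cycle (default [augment_ops()] order).
#' @param seed seed controlling the sampled originals and noise positions.
#' @param out_dir directory for augmented images (default: alongside the
#'   manifest paths).
#' @param manifest_file if non-`NULL`, the balanced manifest is written
#'   there as CSV.
#' @param sp_density salt-and-pepper density.
#' @return The balanced manifest data.frame.
#' @export
balance_dataset <- function(manifest, target_per_class,
                            ops = augment_ops(), seed = 1L,
                            out_dir = NULL, manifest_file = NULL,
                            sp_density = 0.02) {
  if (is.character(manifest)) manifest <- read_manifest(manifest)
  stopifnot(all(c("path", "label", "provenance") %in% names(manifest)))
  counts <- table(manifest$label)
  if (any(counts == 0) || length(counts) == 0) stop("empty class in manifest")
  if (target_per_class < max(counts)) {
    stop("target_per_class (", target_per_class,
         ") is below the largest current class size (", max(counts), ")")
  }
  if (is.null(out_dir)) out_dir <- dirname(dirname(manifest$path[1]))
  new_rows <- list()
  for (cl in names(counts)) {
    need <- target_per_class - counts[[cl]]
    if (need == 0) next
    cl_rows <- which(manifest$label == cl)
    cl_dir <- file.path(out_dir, cl)
    dir.create(cl_dir, showWarnings = FALSE, recursive = TRUE)
    picks <- with_seed(child_seed(seed, match(cl, names(counts))),
                       sample(cl_rows, need, replace = TRUE))
    for (j in seq_len(need)) {
      op <- ops[[(j - 1) %% length(ops) + 1]]
      src <- manifest[picks[j], ]
      img <- read_smear(src$path, label = src$label,
                        provenance = src$provenance)
      aug <- augment_image(img, op, density = sp_density,
                           seed = child_seed(seed, j))
      path <- file.path(cl_dir, sprintf("%s_aug_%05d.png", cl, j))
      write_smear(aug, path)
      new_rows[[length(new_rows) + 1]] <-
        data.frame(path = path, label = cl, provenance = aug$provenance)
    }
  }
  out <- rbind(manifest, do.call(rbind, new_rows))
  rownames(out) <- NULL
  if (!is.null(manifest_file)) data.table::fwrite(out, manifest_file)
  out
}

#' Read a manifest CSV
#'
#' @param path CSV with header `path,label,provenance`.
#' @return data.frame.
#' @export
read_manifest <- function(path) {
  as.data.frame(data.table::fread(path, colClasses = "character"))
}

#' Preprocess every image of a manifest
#'
#' Applies [autocrop()] then [resize_to_standard()] to each image and writes
#' the results to `out_dir`, preserving the class-directory layout.
#'
#' @inheritParams balance_dataset
#' @param side standard side (default 200).
#' @param dark_threshold passed to [autocrop()].
#' @return The new manifest data.frame pointing at the processed images.
#' @export
preprocess_manifest <- function(manifest, out_dir, side = 200,
                                dark_threshold = 20, manifest_file = NULL) {
  if (is.character(manifest)) manifest <- read_manifest(manifest)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- manifest
  for (i in seq_len(nrow(manifest))) {
    row <- manifest[i, ]
    img <- read_smear(row$path, label = row$label, provenance = row$provenance)
    img <- resize_to_standard(autocrop(img, dark_threshold), side)
    cl_dir <- file.path(out_dir, row$label)
    dir.create(cl_dir, showWarnings = FALSE)
    path <- file.path(cl_dir, basename(row$path))
    write_smear(img, path)
    out$path[i] <- path
  }
  if (!is.null(manifest_file)) data.table::fwrite(out, manifest_file)
  out
}
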