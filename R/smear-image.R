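# SmearImage container and PNG I/O

WBC_CLASSES <- c("eosinophil", "lymphocyte", "monocyte", "neutrophil")

#' White blood cell classes
#'
#' The four leukocyte classes handled by the pipeline, in the fixed order
#' used everywhere (manifests, confusion matrices, reports).
#'
#' @return Character vector `eosinophil, lymphocyte, monocyte, neutrophil`.
#' @export
wbc_classes <- function() WBC_CLASSES

#' Construct a smear image
#'
#' An 8-bit RGB blood-smear image with its class label and provenance
#' (`synthetic`, `real`, or `augmented:<op>`).
#'
#' @param pixels H x W x 3 numeric array, values in `[0, 255]`.
#' @param label one of [wbc_classes()], or `NA` for unlabeled images.
#' @param provenance free-form provenance tag.
#' @return An object of class `smear_image`.
#' @export
smear_image <- function(pixels, label = NA_character_, provenance = "real") {
  if (is.matrix(pixels)) pixels <- array(rep(pixels, 3), c(dim(pixels), 3))
  stopifnot(length(dim(pixels)) == 3, dim(pixels)[3] == 3)
  storage.mode(pixels) <- "double"
  if (any(pixels < 0 | pixels > 255)) stop("pixel intensities must lie in [0, 255]")
  if (!is.na(label) && !label %in% WBC_CLASSES) {
    stop("label must be one of: ", paste(WBC_CLASSES, collapse = ", "))
  }
  structure(list(pixels = pixels, label = label, provenance = provenance),
            class = "smear_image")
}

#' @export
print.smear_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<smear_image> %dx%d  label=%s  provenance=%s\n",
              d[1], d[2], x$label, x$provenance))
  invisible(x)
}

#' Read / write a smear image as PNG
#'
#' @param path file path.
#' @param label,provenance metadata attached to the loaded image.
#' @return `read_smear()` returns a [smear_image()]; `write_smear()` returns
#'   `path` invisibly.
#' @export
read_smear <- function(path, label = NA_character_, provenance = "real") {
  px <- png::readPNG(path)
  if (is.matrix(px)) px <- array(rep(px, 3), c(dim(px), 3))
  if (dim(px)[3] == 4) px <- px[, , 1:3, drop = FALSE]
  smear_image(round(px * 255), label = label, provenance = provenance)
}

#' @rdname read_smear
#' @param img a [smear_image()].
#' @export
write_smear <- function(img, path) {
  stopifnot(inherits(img, "smear_image"))
  png::writePNG(img$pixels / 255, target = path)
  invisible(path)
}
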