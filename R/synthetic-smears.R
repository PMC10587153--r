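# Synthetic blood-smear generator.
#
# Emulates the acquisition conditions of stained leukocyte smear crops:
# a dark, irregular background with an illumination gradient, a pink-stained
# cell with low-contrast cytoplasm, and a purple nucleus whose morphology is
# class-specific -- the single large round nucleus of a lymphocyte, the
# kidney-shaped indented nucleus of a monocyte, the two lobes and granular
# cytoplasm of an eosinophil, and the 3-5 small lobes of a neutrophil.
# The nucleus shape is the discriminative signal, exactly what the gradient
# texture features are designed to measure.

#' Synthetic smear generator configuration
#'
#' @param image_size side of the square output image in pixels.
#' @param cell_radius_range min/max cell radius in pixels.
#' @param background_level_range min/max background base intensity (0-255).
#' @param illumination_gradient_strength relative strength of the linear
#'   illumination gradient across the frame (0 = flat lighting).
#' @param noise_density fraction of pixels hit by impulse (salt/pepper)
#'   sensor noise.
#' @param seed base seed; the same configuration and seed always reproduce
#'   the same images, byte for byte.
#' @return An object of class `smear_config`.
#' @export
smear_config <- function(image_size = 200,
                         cell_radius_range = c(55, 75),
                         background_level_range = c(8, 30),
                         illumination_gradient_strength = 0.35,
                         noise_density = 0.002,
                         seed = 1L) {
  stopifnot(image_size >= 32, length(cell_radius_range) == 2,
            length(background_level_range) == 2,
            illumination_gradient_strength >= 0,
            noise_density >= 0, noise_density < 1)
  structure(list(image_size = image_size,
                 cell_radius_range = cell_radius_range,
                 background_level_range = background_level_range,
                 illumination_gradient_strength = illumination_gradient_strength,
                 noise_density = noise_density,
                 seed = as.integer(seed)),
            class = "smear_config")
}

# soft-edged disc indicator on the pixel grid (1 inside, 0 outside,
# linear ramp across the boundary pixel for a faint anti-aliased rim)
soft_disc <- function(rr, cc, centre_r, centre_c, radius) {
  d <- sqrt((rr - centre_r)^2 + (cc - centre_c)^2)
  pmin(pmax(radius - d + 0.5, 0), 1)
}

# class-specific nucleus mask; returns a soft [0,1] matrix
render_nucleus <- function(label, rr, cc, ctr_r, ctr_c, R) {
  switch(label,
    lymphocyte = {
      # one large round nucleus filling most of the cell
      soft_disc(rr, cc, ctr_r, ctr_c, 0.82 * R)
    },
    monocyte = {
      # kidney shape: disc with a deep round indentation bitten out
      theta <- stats::runif(1, 0, 2 * pi)
      body <- soft_disc(rr, cc, ctr_r, ctr_c, 0.75 * R)
      bite <- soft_disc(rr, cc, ctr_r + 0.62 * R * sin(theta),
                        ctr_c + 0.62 * R * cos(theta), 0.50 * R)
      pmax(body - bite, 0)
    },
    eosinophil = {
      # bilobed nucleus: two distinct lobes on opposite sides of the centre
      theta <- stats::runif(1, 0, 2 * pi)
      off <- 0.48 * R
      l1 <- soft_disc(rr, cc, ctr_r + off * sin(theta),
                      ctr_c + off * cos(theta), 0.40 * R)
      l2 <- soft_disc(rr, cc, ctr_r - off * sin(theta),
                      ctr_c - off * cos(theta), 0.40 * R)
      pmax(l1, l2)
    },
    neutrophil = {
      # 3-5 small separated lobes on a ring (multi-lobed nucleus)
      n_lobes <- sample(3:5, 1)
      phase <- stats::runif(1, 0, 2 * pi)
      m <- matrix(0, nrow(rr), ncol(rr))
      for (i in seq_len(n_lobes)) {
        a <- phase + 2 * pi * (i - 1) / n_lobes
        m <- pmax(m, soft_disc(rr, cc, ctr_r + 0.52 * R * sin(a),
                               ctr_c + 0.52 * R * cos(a),
                               stats::runif(1, 0.22, 0.26) * R))
      }
      m
    },
    stop("invalid label: ", label)
  )
}

#' Render one synthetic smear image
#'
#' Deterministic for a fixed `(label, cfg, seed)` triple.  The generator's
#' ground-truth cell and nucleus masks are attached as attributes
#' `cell_mask` and `nucleus_mask` for generator self-tests; they are not
#' part of the pipeline contract.
#'
#' @param label one of [wbc_classes()].
#' @param cfg a [smear_config()].
#' @param seed integer seed for this image (defaults to `cfg$seed`).
#' @return A [smear_image()] with provenance `"synthetic"`.
#' @export
render_cell <- function(label, cfg = smear_config(), seed = cfg$seed) {
  if (!label %in% WBC_CLASSES) {
    stop("invalid label '", label, "'; must be one of: ",
         paste(WBC_CLASSES, collapse = ", "))
  }
  stopifnot(inherits(cfg, "smear_config"))
  S <- cfg$image_size
  with_seed(seed, {
    rr <- matrix(seq_len(S), S, S)
    cc <- matrix(seq_len(S), S, S, byrow = TRUE)

    # dark background with blotches and a linear illumination gradient
    base <- stats::runif(1, cfg$background_level_range[1],
                         cfg$background_level_range[2])
    bg <- matrix(base, S, S)
    for (i in 1:3) {
      blotch <- soft_disc(rr, cc, stats::runif(1, 1, S), stats::runif(1, 1, S),
                          stats::runif(1, S / 8, S / 3))
      bg <- bg * (1 - 0.45 * blotch)
    }
    theta <- stats::runif(1, 0, 2 * pi)
    proj <- ((cc - S / 2) * cos(theta) + (rr - S / 2) * sin(theta)) / S
    illum <- 1 + cfg$illumination_gradient_strength * proj

    # cell geometry
    R <- stats::runif(1, cfg$cell_radius_range[1], cfg$cell_radius_range[2])
    ctr_r <- S / 2 + stats::runif(1, -8, 8)
    ctr_c <- S / 2 + stats::runif(1, -8, 8)
    cell <- soft_disc(rr, cc, ctr_r, ctr_c, R)
    nucleus <- render_nucleus(label, rr, cc, ctr_r, ctr_c, R)
    nucleus <- nucleus * cell
    cyto <- pmax(cell - nucleus, 0)

    # stain palette: low-contrast pink cytoplasm, purple nucleus
    shade <- 1 - 0.15 * sqrt((rr - ctr_r)^2 + (cc - ctr_c)^2) / R
    cyto_rgb <- list(225 * shade, 186 * shade, 205 * shade)
    nuc_rgb <- list(105 * shade, 58 * shade, 150 * shade)

    # eosinophil granules: dense red-staining speckle in the cytoplasm
    if (label == "eosinophil") {
      gr <- (matrix(stats::runif(S * S), S, S) < 0.30) * cyto
      cyto_rgb <- list(cyto_rgb[[1]] - 70 * gr,
                       cyto_rgb[[2]] - 110 * gr,
                       cyto_rgb[[3]] - 95 * gr)
    }

    px <- array(0, c(S, S, 3))
    for (ch in 1:3) {
      px[, , ch] <- illum * (bg * (1 - cell) +
                             cyto_rgb[[ch]] * cyto +
                             nuc_rgb[[ch]] * nucleus) +
                    matrix(stats::rnorm(S * S, 0, 3), S, S)
    }

    # impulse sensor noise
    n_imp <- floor(cfg$noise_density * S * S)
    if (n_imp > 0) {
      at <- sample(S * S, n_imp)
      val <- rep(c(0, 255), length.out = n_imp)
      for (ch in 1:3) {
        plane <- px[, , ch]
        plane[at] <- val
        px[, , ch] <- plane
      }
    }

    img <- smear_image(clamp255(px), label = label, provenance = "synthetic")
    attr(img, "cell_mask") <- cell >= 0.5
    attr(img, "nucleus_mask") <- nucleus >= 0.5
    img
  })
}

#' Generate a labeled synthetic dataset on disk
#'
#' Writes `n_per_class` PNG images per class under `out_dir/<class>/` plus a
#' manifest CSV (`path,label,provenance`).  Fully reproducible: the same
#' `(cfg, n_per_class)` produce identical images and manifest.
#'
#' @param n_per_class images per class (>= 1).
#' @param cfg a [smear_config()]; `cfg$seed` drives every image.
#' @param out_dir output directory (created if missing).
#' @param manifest_file manifest path (default `out_dir/manifest.csv`).
#' @return The manifest as a data.frame (invisibly written to
#'   `manifest_file`).
#' @export
generate_dataset <- function(n_per_class, cfg = smear_config(), out_dir,
                             manifest_file = file.path(out_dir, "manifest.csv")) {
  stopifnot(n_per_class >= 1)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  rows <- vector("list", 4 * n_per_class)
  k <- 0
  for (ci in seq_along(WBC_CLASSES)) {
    cl <- WBC_CLASSES[ci]
    cl_dir <- file.path(out_dir, cl)
    dir.create(cl_dir, showWarnings = FALSE)
    for (i in seq_len(n_per_class)) {
      img <- render_cell(cl, cfg, seed = child_seed(cfg$seed, ci * 1000003 + i))
      path <- file.path(cl_dir, sprintf("%s_%04d.png", cl, i))
      write_smear(img, path)
      k <- k + 1
      rows[[k]] <- data.frame(path = path, label = cl,
                              provenance = "synthetic")
    }
  }
  manifest <- do.call(rbind, rows)
  data.table::fwrite(manifest, manifest_file)
  invisible(manifest)
}
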