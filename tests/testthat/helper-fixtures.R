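# shared fixtures, all generated in code

# flat-colour smear image
flat_image <- function(value = 120, h = 200, w = h) {
  smear_image(array(value, c(h, w, 3)))
}

# seeded random-noise smear image
noise_image <- function(seed = 1, h = 200, w = h) {
  vhtrellis:::with_seed(seed,
    smear_image(array(sample(0:255, h * w * 3, replace = TRUE), c(h, w, 3))))
}

# grayscale ramp/pattern as smear image from a matrix generator f(r, c)
pattern_image <- function(f, h = 40, w = h) {
  m <- outer(seq_len(h), seq_len(w), f)
  m <- m - min(m)
  m <- m / max(max(m), 1) * 255
  smear_image(array(rep(m, 3), c(h, w, 3)))
}

# tiny on-disk synthetic dataset; memoised per (n, seed) within a run
local_dataset <- local({
  cache <- new.env(parent = emptyenv())
  function(n_per_class = 4, seed = 1, size = 64) {
    key <- paste(n_per_class, seed, size, sep = "_")
    if (is.null(cache[[key]])) {
      dir <- file.path(tempdir(), paste0("vht_fix_", key))
      cfg <- smear_config(image_size = size,
                          cell_radius_range = round(size * c(0.28, 0.36)),
                          seed = seed)
      manifest <- generate_dataset(n_per_class, cfg, dir)
      cache[[key]] <- list(dir = dir, manifest = manifest, cfg = cfg)
    }
    cache[[key]]
  }
})

# 4-class gaussian-blob feature data (no images), for classifier tests
blob_data <- function(n_per_class = 30, p = 6, sep = 3, seed = 1) {
  vhtrellis:::with_seed(seed, {
    centers <- matrix(stats::rnorm(4 * p, sd = sep), 4, p)
    X <- do.call(rbind, lapply(1:4, function(ci) {
      matrix(stats::rnorm(n_per_class * p), n_per_class, p) +
        matrix(centers[ci, ], n_per_class, p, byrow = TRUE)
    }))
    list(X = X, y = factor(rep(wbc_classes(), each = n_per_class)))
  })
}

# planted-signal data: informative features have class-dependent means +-delta
planted_data <- function(n = 200, p = 100, informative = 5, delta = 2,
                         seed = 1) {
  vhtrellis:::with_seed(seed, {
    y <- factor(rep(c("a", "b"), length.out = n))
    X <- matrix(stats::rnorm(n * p), n, p)
    sign <- ifelse(y == "a", 1, -1)
    for (j in seq_len(informative)) X[, j] <- X[, j] + sign * delta
    list(X = X, y = y, informative = seq_len(informative))
  })
}
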