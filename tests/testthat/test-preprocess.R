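# autocrop, standard resize, augmentations, dataset balancing

test_that("autocrop finds the tight bright bounding box and is idempotent", {
  px <- array(0, c(200, 200, 3))
  px[76:125, 61:110, ] <- 180  # bright 50x50 block
  img <- smear_image(px)
  cropped <- autocrop(img)
  expect_equal(dim(cropped$pixels)[1:2], c(50, 50))
  expect_true(all(cropped$pixels == 180))

  again <- autocrop(cropped)
  expect_identical(again$pixels, cropped$pixels)

  bright <- flat_image(200, 30)
  expect_equal(dim(autocrop(bright)$pixels), dim(bright$pixels))
  # nothing above threshold: returned unchanged
  dark <- flat_image(5, 30)
  expect_identical(autocrop(dark)$pixels, dark$pixels)
})

test_that("resize_to_standard yields the standard side and preserves constants", {
  rect <- smear_image(array(runif(320 * 240 * 3) * 255, c(320, 240, 3)))
  out <- resize_to_standard(rect, 200)
  expect_equal(dim(out$pixels), c(200, 200, 3))
  expect_true(all(out$pixels >= 0 & out$pixels <= 255))

  std <- noise_image(4, 200)
  expect_identical(resize_to_standard(std, 200)$pixels, std$pixels)

  const <- flat_image(88, 57, 91)
  expect_true(all(resize_to_standard(const, 64)$pixels == 88))
})

test_that("geometric augmentations are the expected involutions/cycles", {
  img <- noise_image(7, 31, 31)
  r1 <- augment_image(img, "rot90_right")
  expect_equal(r1$provenance, "augmented:rot90_right")
  r4 <- Reduce(function(x, .) augment_image(x, "rot90_right"), 1:4,
               accumulate = FALSE, init = img)
  expect_identical(r4$pixels, img$pixels)
  expect_false(identical(r1$pixels, img$pixels))

  for (op in c("flip_horizontal", "flip_vertical")) {
    once <- augment_image(img, op)
    expect_false(identical(once$pixels, img$pixels))
    expect_identical(augment_image(once, op)$pixels, img$pixels)
  }
})

test_that("salt and pepper hits exactly the prescribed pixel count, seeded", {
  img <- flat_image(120, 50)
  sp <- augment_image(img, "salt_pepper", density = 0.02, seed = 3)
  changed <- which(sp$pixels[, , 1] != 120)
  expect_length(changed, floor(0.02 * 50 * 50))
  expect_true(all(sp$pixels[, , 1][changed] %in% c(0, 255)))
  # half salt, half pepper
  expect_equal(sum(sp$pixels[, , 1][changed] == 255), 25)
  # impulse hits all three channels at the same positions
  expect_identical(sp$pixels[, , 1][changed], sp$pixels[, , 2][changed])
  # seeded determinism
  sp2 <- augment_image(img, "salt_pepper", density = 0.02, seed = 3)
  expect_identical(sp$pixels, sp2$pixels)
  expect_false(identical(
    augment_image(img, "salt_pepper", density = 0.02, seed = 4)$pixels,
    sp$pixels))
})

test_that("balance_dataset grows every class to the target and keeps originals", {
  fix <- local_dataset(n_per_class = 3, seed = 5)
  out_dir <- withr::local_tempdir()
  bal <- balance_dataset(fix$manifest, 7, seed = 2, out_dir = out_dir)
  expect_equal(nrow(bal), 28)
  expect_equal(as.vector(table(bal$label)), rep(7L, 4))
  expect_true(all(fix$manifest$path %in% bal$path))
  added <- bal[!(bal$path %in% fix$manifest$path), ]
  expect_true(all(grepl("^augmented:", added$provenance)))
  # cycle order: first added row per class used the first op
  first_ops <- tapply(added$provenance, added$label, function(x) x[1])
  expect_true(all(first_ops == "augmented:rot90_right"))
  expect_true(all(file.exists(added$path)))

  # target equal to current size leaves the manifest unchanged
  same <- balance_dataset(fix$manifest, 3, out_dir = out_dir)
  expect_identical(same, fix$manifest)

  # determinism: rerun adds the same augmented rows
  out_dir2 <- withr::local_tempdir()
  bal2 <- balance_dataset(fix$manifest, 7, seed = 2, out_dir = out_dir2)
  expect_identical(bal$provenance, bal2$provenance)
  expect_identical(unname(tools::md5sum(added$path)),
                   unname(tools::md5sum(
                     bal2$path[!(bal2$path %in% fix$manifest$path)])))

  expect_error(balance_dataset(fix$manifest, 2, out_dir = out_dir),
               "below the largest")
})

test_that("preprocess_manifest standardizes every image", {
  fix <- local_dataset(n_per_class = 2, seed = 8, size = 72)
  out_dir <- withr::local_tempdir()
  m <- preprocess_manifest(fix$manifest, out_dir, side = 48)
  expect_equal(nrow(m), nrow(fix$manifest))
  d <- dim(read_smear(m$path[1])$pixels)
  expect_equal(d, c(48, 48, 3))
})
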