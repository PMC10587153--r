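# symbolic trellis kernel derivation

coef_of <- function(expr, sym) expr$num[[sym]] / expr$den[[sym]]

test_that("virtual elements average one corner pixel with the centre", {
  h <- build_virtual_elements()
  expect_named(h, c("h1", "h2", "h3", "h4"))
  corners <- c(h1 = "f1", h2 = "f3", h3 = "f7", h4 = "f9")
  for (nm in names(h)) {
    expect_equal(coef_of(h[[nm]], corners[[nm]]), 1 / 2)
    expect_equal(coef_of(h[[nm]], "fc"), 1 / 2)
    # averaging preserves constants: coefficients sum to 1
    expect_equal(sum(h[[nm]]$num / h[[nm]]$den), 1)
  }
})

test_that("directional expansions match the derived pixel combinations", {
  ex <- expand_directional_difference("x")
  want_x <- c(f1 = -1/2, f3 = 1/2, f4 = -1, f6 = 1, f7 = -1/2, f9 = 1/2,
              f2 = 0, f8 = 0, fc = 0)
  for (s in names(want_x)) expect_equal(coef_of(ex, s), want_x[[s]], info = s)

  ey <- expand_directional_difference("y")
  want_y <- c(f1 = -1/2, f3 = -1/2, f7 = 1/2, f9 = 1/2,
              f2 = 0, f4 = 0, f6 = 0, f8 = 0, fc = 0)
  for (s in names(want_y)) expect_equal(coef_of(ey, s), want_y[[s]], info = s)

  # the centre pixel cancels exactly in both directions
  expect_identical(ex$num[["fc"]], 0)
  expect_identical(ey$num[["fc"]], 0)

  # gradient of a constant neighbourhood is zero
  const <- matrix(137, 3, 3)
  expect_equal(ve_evaluate(ex, const), 0)
  expect_equal(ve_evaluate(ey, const), 0)

  expect_error(expand_directional_difference("z"))
})

test_that("expression -> kernel mapping reproduces the x kernel and inverts", {
  kx <- kernel_from_expression(expand_directional_difference("x"))
  expect_equal(rational_as_numeric(kx),
               matrix(c(-1, 0, 1, -2, 0, 2, -1, 0, 1), 3, 3, byrow = TRUE) / 2)

  zero <- kernel_from_expression(ve_expression())
  expect_equal(rational_as_numeric(zero), matrix(0, 3, 3))

  # round trip expr -> matrix -> expr is the identity for random rationals
  syms <- vhtrellis:::vht_symbols()
  for (i in 1:20) {
    set.seed(i)
    e <- ve_expression(setNames(sample(-5:5, 9, replace = TRUE), syms),
                       sample(1:4, 9, replace = TRUE))
    back <- expression_from_kernel(kernel_from_expression(e))
    expect_identical(back$num, e$num)
    expect_identical(back$den, e$den)
  }
})

test_that("canonical kernels satisfy zero-sum and mirror antisymmetry", {
  km <- kernel_matrices(canonical_kernels())
  for (nm in names(km)) expect_equal(sum(km[[nm]]), 0, info = nm)
  expect_equal(km$x, matrix(c(-1, 0, 1, -2, 0, 2, -1, 0, 1), 3, 3,
                            byrow = TRUE) / 2)
  expect_equal(km$y, matrix(c(1, 2, 1, 0, 0, 0, -1, -2, -1), 3, 3,
                            byrow = TRUE) / 2)
  expect_equal(km$d45, matrix(c(0, 1, 1, -1, 0, 1, -1, -1, 0), 3, 3,
                              byrow = TRUE))
  expect_equal(km$d135, km$d45[, 3:1])
  # x kernel is the negation of its horizontal mirror, y of its vertical
  expect_equal(km$x, -km$x[, 3:1])
  expect_equal(km$y, -km$y[3:1, ])
})

test_that("diagonal kernel responds to the 45-degree ramp as the direct dot product says", {
  km <- kernel_matrices(canonical_kernels())
  h <- 20
  ramp45 <- outer(seq_len(h), seq_len(h), function(r, c) c - r)
  ramp135 <- outer(seq_len(h), seq_len(h), function(r, c) r + c)
  # oracle: direct 3x3 dot product on one interior window
  win <- ramp45[9:11, 9:11]
  oracle <- sum(km$d45 * win)
  expect_equal(oracle, 8)
  resp <- vhtrellis:::filter3x3(ramp45, km$d45)
  expect_true(all(abs(resp[5:15, 5:15] - oracle) < 1e-12))
  # the orthogonal ramp draws zero response
  resp135 <- vhtrellis:::filter3x3(ramp135, km$d45)
  expect_true(all(abs(resp135[5:15, 5:15]) < 1e-12))
})

test_that("gcd factoring of combined kernels", {
  s <- mxy_bracket_sum(canonical_kernels())
  expect_equal(s, matrix(c(0, 2, 2, -2, 0, 2, -2, -2, 0), 3, 3, byrow = TRUE))
  expect_equal(gcd_factor(s), 2)
  expect_equal(gcd_factor(diag(3)), 1)
  # brute-force divisor-search oracle on a third matrix
  m <- matrix(c(6, 0, 9, 0, 3, 0, 12, 0, -3), 3, 3, byrow = TRUE)
  nz <- abs(m[m != 0])
  brute <- max(Filter(function(d) all(nz %% d == 0), seq_len(max(nz))))
  expect_equal(gcd_factor(m), brute)
  expect_equal(gcd_factor(m), 3)
  expect_error(gcd_factor(matrix(0, 3, 3)))
})

test_that("symbolic evaluation equals kernel filtering on random neighbourhoods", {
  ex <- expand_directional_difference("x")
  ey <- expand_directional_difference("y")
  kx <- rational_as_numeric(kernel_from_expression(ex))
  ky <- rational_as_numeric(kernel_from_expression(ey))
  set.seed(99)
  for (i in 1:250) {
    nb <- matrix(sample(0:255, 9, replace = TRUE), 3, 3)
    centre_x <- vhtrellis:::filter3x3(nb, kx)[2, 2]
    centre_y <- vhtrellis:::filter3x3(nb, ky)[2, 2]
    expect_equal(ve_evaluate(ex, nb), centre_x)
    expect_equal(ve_evaluate(ey, nb), centre_y)
  }
})

test_that("kernel JSON export carries exact rational entries", {
  j <- kernels_as_json()
  expect_equal(j$kx[1, 1], "-1/2")
  expect_equal(j$k45[1, 2], "1")
  expect_equal(j$bracket_gcd, 2)
  expect_equal(j$mxy_scale, 2)
})
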