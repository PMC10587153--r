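# Symbolic derivation of the virtual hexagonal trellis (VHT) gradient
# kernels.  A hexagonal neighbourhood is overlaid on the native 3x3 square
# pixel grid by introducing four virtual elements, each the average of a
# corner pixel and the central pixel.  Directional intensity differences
# across the trellis expand, after substitution of the virtual elements,
# into ordinary 3x3 convolution kernels.

#' @keywords internal
vht_symbols <- function() c("f1", "f2", "f3", "f4", "fc", "f6", "f7", "f8", "f9")

# symbol -> grid-cell mapping: f1 f2 f3 / f4 fc f6 / f7 f8 f9, row-major,
# origin top-left.  This is the unique layout under which the x-direction
# expansion reproduces the Sobel-like x kernel.
#' @keywords internal
vht_layout <- function() {
  matrix(vht_symbols(), nrow = 3, ncol = 3, byrow = TRUE)
}

#' Construct a symbolic virtual-element expression
#'
#' A `virtual_element_expr` is an exact rational linear combination of the
#' 3x3 neighbourhood symbols `f1..f9` and the centre `fc`.  It is the
#' currency of the symbolic stage of the kernel derivation.
#'
#' @param num named integer vector of numerators (names drawn from
#'   `f1,f2,f3,f4,fc,f6,f7,f8,f9`); omitted symbols have coefficient 0.
#' @param den denominators matching `num` (recycled).
#' @return An object of class `virtual_element_expr` with reduced rational
#'   coefficients over all nine symbols.
#' @examples
#' ve_expression(c(f1 = 1, fc = 1), 2)  # (f1 + fc) / 2
#' @export
ve_expression <- function(num = numeric(0), den = 1) {
  syms <- vht_symbols()
  if (length(num) && (is.null(names(num)) || !all(names(num) %in% syms))) {
    stop("coefficient names must be neighbourhood symbols: ",
         paste(syms, collapse = ", "))
  }
  n <- stats::setNames(numeric(9), syms)
  d <- stats::setNames(rep(1, 9), syms)
  if (length(num)) {
    den <- rep_len(den, length(num))
    n[names(num)] <- num
    d[names(num)] <- den
  }
  r <- rat_reduce(n, d)
  structure(list(num = stats::setNames(r$num, syms),
                 den = stats::setNames(r$den, syms)),
            class = "virtual_element_expr")
}

#' @export
print.virtual_element_expr <- function(x, ...) {
  nz <- which(x$num != 0)
  if (!length(nz)) {
    cat("<virtual_element_expr> 0\n")
    return(invisible(x))
  }
  terms <- paste0(rat_format(x$num[nz], x$den[nz]), "*", names(x$num)[nz])
  cat("<virtual_element_expr>", paste(terms, collapse = " + "), "\n")
  invisible(x)
}

# exact sum of two expressions
#' @keywords internal
ve_add <- function(a, b) {
  r <- rat_add(a$num, a$den, b$num, b$den)
  structure(list(num = r$num, den = r$den), class = "virtual_element_expr")
}

# exact scaling by the rational s_num/s_den
#' @keywords internal
ve_scale <- function(a, s_num, s_den = 1) {
  r <- rat_mul(a$num, a$den, s_num, s_den)
  structure(list(num = r$num, den = r$den), class = "virtual_element_expr")
}

#' Evaluate a symbolic expression on a numeric 3x3 neighbourhood
#'
#' @param expr a [ve_expression()].
#' @param neighborhood numeric 3x3 matrix laid out as the symbol grid
#'   (`f1 f2 f3 / f4 fc f6 / f7 f8 f9`).
#' @return A single numeric value.
#' @export
ve_evaluate <- function(expr, neighborhood) {
  stopifnot(inherits(expr, "virtual_element_expr"),
            is.matrix(neighborhood), all(dim(neighborhood) == c(3, 3)))
  vals <- stats::setNames(as.vector(t(neighborhood)), as.vector(t(vht_layout())))
  sum(expr$num / expr$den * vals[names(expr$num)])
}

#' The four virtual elements of the hexagonal trellis
#'
#' Each virtual element sits between one corner pixel and the centre of the
#' 3x3 neighbourhood and carries the mean of the two intensities:
#' `h1 = (f1 + fc)/2`, `h2 = (f3 + fc)/2`, `h3 = (f7 + fc)/2`,
#' `h4 = (f9 + fc)/2`.
#'
#' @return Named list of four `virtual_element_expr` objects `h1..h4`.
#' @export
build_virtual_elements <- function() {
  list(
    h1 = ve_expression(c(f1 = 1, fc = 1), 2),
    h2 = ve_expression(c(f3 = 1, fc = 1), 2),
    h3 = ve_expression(c(f7 = 1, fc = 1), 2),
    h4 = ve_expression(c(f9 = 1, fc = 1), 2)
  )
}

#' Expand a directional trellis difference into neighbourhood pixels
#'
#' The x-direction difference is `(f6 + h2 + h4) - (f4 + h1 + h3)`; the
#' y-direction difference is `(h3 + h4) - (h1 + h2)`.  Substituting the
#' virtual-element definitions cancels the centre pixel exactly and leaves a
#' rational combination of the real pixels:
#' `x -> (2 f6 + f3 + f9 - 2 f4 - f1 - f7) / 2` and
#' `y -> (f7 + f9 - f1 - f3) / 2`.
#'
#' @param axis `"x"` or `"y"`.
#' @return A `virtual_element_expr` with zero `fc` coefficient.
#' @export
expand_directional_difference <- function(axis = c("x", "y")) {
  axis <- match.arg(axis)
  h <- build_virtual_elements()
  if (axis == "x") {
    pos <- ve_add(ve_add(ve_expression(c(f6 = 1)), h$h2), h$h4)
    neg <- ve_add(ve_add(ve_expression(c(f4 = 1)), h$h1), h$h3)
  } else {
    pos <- ve_add(h$h3, h$h4)
    neg <- ve_add(h$h1, h$h2)
  }
  ve_add(pos, ve_scale(neg, -1))
}

#' Map a symbolic expression onto a 3x3 rational kernel matrix
#'
#' Cell (r, c) of the result is the coefficient of the symbol at that
#' position of the fixed neighbourhood layout.  The mapping is invertible;
#' [expression_from_kernel()] recovers the expression exactly.
#'
#' @param expr a `virtual_element_expr`.
#' @param layout 3x3 character matrix of symbols (default [vht_layout()]).
#' @return A `rational_matrix`: list with integer `num` and `den` 3x3
#'   matrices.
#' @export
kernel_from_expression <- function(expr, layout = vht_layout()) {
  stopifnot(inherits(expr, "virtual_element_expr"))
  num <- matrix(expr$num[layout], 3, 3)
  den <- matrix(expr$den[layout], 3, 3)
  structure(list(num = num, den = den), class = "rational_matrix")
}

#' @rdname kernel_from_expression
#' @param m a `rational_matrix`.
#' @export
expression_from_kernel <- function(m, layout = vht_layout()) {
  stopifnot(inherits(m, "rational_matrix"))
  ve_expression(stats::setNames(as.vector(m$num), as.vector(layout)),
                as.vector(m$den))
}

#' @export
print.rational_matrix <- function(x, ...) {
  cat("<rational_matrix>\n")
  print(matrix(rat_format(x$num, x$den), 3, 3), quote = FALSE)
  invisible(x)
}

#' Numeric value of a rational matrix
#'
#' @param m a `rational_matrix`.
#' @return A numeric 3x3 matrix `num/den`.
#' @export
rational_as_numeric <- function(m) {
  stopifnot(inherits(m, "rational_matrix"))
  m$num / m$den
}

# exact rational matrix from integer numerators over one denominator
#' @keywords internal
rational_matrix <- function(num, den = 1) {
  r <- rat_reduce(as.vector(num), rep_len(den, length(num)))
  structure(list(num = matrix(r$num, 3, 3), den = matrix(r$den, 3, 3)),
            class = "rational_matrix")
}

#' The canonical VHT kernel set
#'
#' The four 3x3 gradient kernels used by the feature extractor, one per
#' direction:
#' \describe{
#'   \item{kx}{`1/2 * [[-1,0,1],[-2,0,2],[-1,0,1]]`, the trellis x-gradient
#'     (identical to the symbolic expansion).}
#'   \item{ky}{`1/2 * [[1,2,1],[0,0,0],[-1,-2,-1]]`, the y-gradient in its
#'     published matrix form.}
#'   \item{k45}{`[[0,1,1],[-1,0,1],[-1,-1,0]]`, the combined diagonal
#'     operator, stored unit-scaled; the factored-out scale 2 of the
#'     published combination step is kept as metadata (`mxy_scale`).}
#'   \item{k135}{column mirror of `k45`, `[[1,1,0],[1,0,-1],[0,-1,-1]]`,
#'     the orthogonal diagonal operator.}
#' }
#' All four sum to zero, so every kernel responds zero on constant input.
#'
#' @return An object of class `kernel_set`.
#' @export
canonical_kernels <- function() {
  kx <- kernel_from_expression(expand_directional_difference("x"))
  ky <- rational_matrix(matrix(c(1, 2, 1, 0, 0, 0, -1, -2, -1), 3, 3,
                               byrow = TRUE), 2)
  k45 <- rational_matrix(matrix(c(0, 1, 1, -1, 0, 1, -1, -1, 0), 3, 3,
                                byrow = TRUE))
  k135 <- rational_matrix(k45$num[, 3:1])
  structure(list(kx = kx, ky = ky, k45 = k45, k135 = k135, mxy_scale = 2),
            class = "kernel_set")
}

#' @export
print.kernel_set <- function(x, ...) {
  cat("<kernel_set> VHT gradient kernels (x, y, 45, 135)\n")
  for (nm in c("kx", "ky", "k45", "k135")) {
    cat(nm, ":\n", sep = "")
    print(matrix(rat_format(x[[nm]]$num, x[[nm]]$den), 3, 3), quote = FALSE)
  }
  invisible(x)
}

#' Numeric kernel matrices of a kernel set
#'
#' @param kernels a [canonical_kernels()] `kernel_set`.
#' @return Named list of four numeric 3x3 matrices in the fixed direction
#'   order `x, y, d45, d135`.
#' @export
kernel_matrices <- function(kernels = canonical_kernels()) {
  stopifnot(inherits(kernels, "kernel_set"))
  list(x = rational_as_numeric(kernels$kx),
       y = rational_as_numeric(kernels$ky),
       d45 = rational_as_numeric(kernels$k45),
       d135 = rational_as_numeric(kernels$k135))
}

#' Integer bracket-matrix sum of the x and y kernels
#'
#' Sums the integer bracket matrices of the x and y kernels (the 1/2
#' prefactors dropped, as in the published combination of the two
#' directions), giving `[[0,2,2],[-2,0,2],[-2,-2,0]]`.  Factoring out
#' [gcd_factor()] of this matrix yields the unit-scaled diagonal kernel.
#'
#' @inheritParams kernel_matrices
#' @return Integer 3x3 matrix.
#' @export
mxy_bracket_sum <- function(kernels = canonical_kernels()) {
  bracket <- function(m) {
    d <- max(m$den)
    m$num * (d / m$den)
  }
  bracket(kernels$kx) + bracket(kernels$ky)
}

#' Greatest common divisor of the nonzero entries of an integer matrix
#'
#' The factor pulled out when reducing a combined kernel to unit scale.
#'
#' @param m integer matrix with at least one nonzero entry.
#' @return Positive integer GCD of the absolute nonzero entries.
#' @export
gcd_factor <- function(m) {
  v <- abs(as.vector(m))
  v <- v[v != 0]
  if (!length(v)) stop("all-zero matrix has no GCD factor")
  if (any(v != round(v))) stop("matrix entries must be integers")
  Reduce(gcd_int, v)
}

#' Kernels as a JSON-ready list with exact rational entries
#'
#' @inheritParams kernel_matrices
#' @return List with one character 3x3 matrix (entries `"num/den"`) per
#'   kernel plus the bracket-matrix sum and its GCD factor.
#' @export
kernels_as_json <- function(kernels = canonical_kernels()) {
  fmt <- function(m) matrix(rat_format(m$num, m$den), 3, 3)
  s <- mxy_bracket_sum(kernels)
  list(kx = fmt(kernels$kx), ky = fmt(kernels$ky),
       k45 = fmt(kernels$k45), k135 = fmt(kernels$k135),
       mxy_scale = kernels$mxy_scale,
       bracket_sum = s, bracket_gcd = gcd_factor(s))
}
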