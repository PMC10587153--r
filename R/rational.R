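# Minimal exact rational arithmetic for the symbolic kernel derivation.
# Coefficients are stored as reduced integer numerator/denominator pairs so
# that the cancellation of the centre pixel in the gradient expansions is
# exact, with no floating-point drift.

gcd_int <- function(a, b) {
  a <- abs(a); b <- abs(b)
  while (b != 0) {
    t <- b
    b <- a %% b
    a <- t
  }
  a
}

# reduce num/den to lowest terms with den > 0
rat_reduce <- function(num, den) {
  stopifnot(all(den != 0))
  g <- mapply(gcd_int, num, den)
  g[g == 0] <- 1
  num <- num / g
  den <- den / g
  neg <- den < 0
  num[neg] <- -num[neg]
  den[neg] <- -den[neg]
  list(num = num, den = den)
}

rat_add <- function(n1, d1, n2, d2) {
  rat_reduce(n1 * d2 + n2 * d1, d1 * d2)
}

rat_mul <- function(n1, d1, n2, d2) {
  rat_reduce(n1 * n2, d1 * d2)
}

# "num/den" (or "num" when den == 1) pretty-printer, vectorised
rat_format <- function(num, den) {
  ifelse(den == 1, as.character(num), paste0(num, "/", den))
}
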