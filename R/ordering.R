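# Weight-vector monomial orderings.
#
# A nonnegative integer weight vector omega, together with a fixed total
# tiebreak order sigma (lexicographic with x1 > x2 > ... > xn), defines the
# monomial ordering:  x^a > x^b  iff  omega.a > omega.b, or the weights tie
# and a > b under sigma. Every point of the Groebner fan encodes such an
# ordering; sampling omega uniformly is how the fan's cone volumes are
# estimated.

#' Weight-vector monomial ordering
#'
#' @param omega Nonnegative integer weight vector, one entry per variable.
#' @param tiebreak Tiebreak order sigma applied on weight ties; currently
#'   \code{"lex"} (x1 > x2 > ... > xn).
#' @return Object of class \code{weight_ordering}.
#' @examples
#' weight_ordering(c(1, 1, 1))
#' @export
weight_ordering <- function(omega, tiebreak = "lex") {
  omega <- as.numeric(omega)
  if (any(omega < 0) || anyNA(omega)) stop("weights must be nonnegative")
  tiebreak <- match.arg(tiebreak, "lex")
  structure(list(omega = omega, tiebreak = tiebreak),
            class = "weight_ordering")
}

#' @export
print.weight_ordering <- function(x, ...) {
  cat("monomial ordering: omega = (", paste(x$omega, collapse = ", "),
      "), tiebreak = ", x$tiebreak, "\n", sep = "")
  invisible(x)
}

# numeric three-way comparison of two exponent vectors; -1 / 0 / +1
cmp_exp <- function(a, b, ord) {
  wa <- sum(ord$omega * a)
  wb <- sum(ord$omega * b)
  if (wa != wb) return(if (wa > wb) 1L else -1L)
  d <- a - b
  nz <- which(d != 0L)
  if (length(nz) == 0L) return(0L)
  if (d[nz[1L]] > 0L) 1L else -1L
}

#' Compare two monomials under a weight ordering
#'
#' @param a,b Exponent vectors of equal length (the alpha of x^alpha).
#' @param ord A \code{\link{weight_ordering}}.
#' @return One of \code{"less"}, \code{"equal"}, \code{"greater"} (a relative
#'   to b). \code{"equal"} occurs only for identical exponent vectors: weight
#'   ties between distinct monomials are resolved by the tiebreak, keeping the
#'   ordering total.
#' @examples
#' compare_monomials(c(2, 0, 0), c(1, 1, 0), weight_ordering(c(1, 1, 1)))
#' @export
compare_monomials <- function(a, b, ord) {
  a <- as.integer(a); b <- as.integer(b)
  if (length(a) != length(b)) stop("exponent vectors differ in length")
  if (length(ord$omega) != length(a)) stop("weight vector has wrong length")
  if (any(a < 0L) || any(b < 0L)) stop("exponents must be nonnegative")
  c("less", "equal", "greater")[cmp_exp(a, b, ord) + 2L]
}

# order() permutation sorting the rows of an exponent matrix ascending under
# ord; vectorised (weight key first, then lex keys with x1 most significant)
monomial_order <- function(exps, ord, decreasing = FALSE) {
  if (nrow(exps) <= 1L) return(seq_len(nrow(exps)))
  w <- as.numeric(exps %*% ord$omega)
  keys <- c(list(w), lapply(seq_len(ncol(exps)), function(j) exps[, j]))
  do.call(order, c(keys, list(decreasing = decreasing)))
}

# index of the leading (ord-maximal) term of a polynomial
leading_index <- function(f, ord) {
  if (is_zero_poly(f)) stop("zero polynomial has no leading term")
  monomial_order(f$exps, ord, decreasing = TRUE)[1L]
}

#' Leading term of a polynomial under an ordering
#'
#' @param f A nonzero \code{gf_poly}.
#' @param ord A \code{\link{weight_ordering}}.
#' @return List with \code{exp} (exponent vector) and \code{coef}.
#' @export
leading_term <- function(f, ord) {
  i <- leading_index(f, ord)
  list(exp = f$exps[i, ], coef = f$coefs[i])
}
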