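# Exact multivariate polynomial arithmetic over a prime field GF(p).
#
# A polynomial is stored in fully expanded form: an integer exponent matrix
# (one row per term) together with an integer coefficient vector, all
# coefficients in 1..p-1 after normalisation. The zero polynomial has zero
# rows. Terms are kept sorted (descending) under a fixed reference ordering
# (all-ones weight vector, lexicographic tiebreak with x1 > x2 > ... > xn),
# which makes the stored form, and hence serialisation, canonical.

#' Prime field descriptor
#'
#' Validates the field order and returns a small descriptor object. Only
#' prime orders are supported: the method targets multistate (e.g. Boolean or
#' ternary) gene expression data where each variable takes values in
#' \{0, ..., p-1\}.
#'
#' @param p Field order, a prime integer >= 2.
#' @return An object of class \code{prime_field} with element \code{p}.
#' @examples
#' prime_field(3)
#' @export
prime_field <- function(p) {
  p <- as.integer(p)
  if (length(p) != 1L || is.na(p) || p < 2L || !is_prime(p)) {
    stop("field order must be a prime integer >= 2, got ", p)
  }
  structure(list(p = p), class = "prime_field")
}

#' @export
print.prime_field <- function(x, ...) {
  cat("GF(", x$p, ")\n", sep = "")
  invisible(x)
}

is_prime <- function(p) {
  if (p < 2L) return(FALSE)
  if (p %in% c(2L, 3L)) return(TRUE)
  if (p %% 2L == 0L) return(FALSE)
  d <- 3L
  while (d * d <= p) {
    if (p %% d == 0L) return(FALSE)
    d <- d + 2L
  }
  TRUE
}

# modular inverse by Fermat: a^(p-2) mod p, a != 0
gf_inv <- function(a, p) {
  a <- a %% p
  stopifnot(all(a != 0L))
  r <- rep(1L, length(a))
  e <- p - 2L
  base <- a
  while (e > 0L) {
    if (e %% 2L == 1L) r <- (r * base) %% p
    base <- (base * base) %% p
    e <- e %/% 2L
  }
  r
}

#' Construct a polynomial over GF(p)
#'
#' @param exps Integer matrix with one row per term and \code{nvars} columns
#'   of nonnegative exponents; may have zero rows for the zero polynomial.
#' @param coefs Integer coefficient vector, one per row of \code{exps}.
#' @param p Prime field order.
#' @param nvars Number of variables; inferred from \code{exps} when possible.
#' @return Object of class \code{gf_poly}. Duplicate exponent rows are
#'   combined and zero coefficients dropped; terms are stored in the canonical
#'   reference order so that equal polynomials have identical representations.
#' @examples
#' f <- gf_poly(rbind(c(0, 1, 0), c(0, 0, 1)), c(1, 2), p = 3)  # x2 - x3
#' poly_format(f)
#' @export
gf_poly <- function(exps, coefs, p, nvars = NULL) {
  p <- as.integer(p)
  if (is.null(dim(exps))) exps <- matrix(as.integer(exps), nrow = length(coefs))
  if (is.null(nvars)) nvars <- ncol(exps)
  nvars <- as.integer(nvars)
  if (nrow(exps) != length(coefs)) stop("one coefficient per term required")
  if (nrow(exps) > 0L && ncol(exps) != nvars) stop("exponent matrix has wrong width")
  exps <- matrix(as.integer(exps), nrow = nrow(exps), ncol = nvars)
  if (any(exps < 0L)) stop("exponents must be nonnegative")
  coefs <- as.integer(coefs) %% p
  keep <- coefs != 0L
  exps <- exps[keep, , drop = FALSE]
  coefs <- coefs[keep]
  if (nrow(exps) > 1L) {
    key <- apply(exps, 1L, paste, collapse = ",")
    if (anyDuplicated(key)) {
      agg <- rowsum(coefs, group = key, reorder = FALSE)
      ukey <- rownames(agg)
      coefs <- as.integer(agg[, 1L] %% p)
      exps <- exps[match(ukey, key), , drop = FALSE]
      keep <- coefs != 0L
      exps <- exps[keep, , drop = FALSE]
      coefs <- coefs[keep]
    }
  }
  f <- structure(list(exps = exps, coefs = coefs, p = p, nvars = nvars),
                 class = "gf_poly")
  sort_terms(f)
}

# reference ordering used only for storage/serialisation: total degree of the
# exponent vector, then lex with x1 most significant; descending.
sort_terms <- function(f) {
  m <- nrow(f$exps)
  if (m <= 1L) return(f)
  w <- rowSums(f$exps)
  keys <- c(list(-w), lapply(seq_len(f$nvars), function(j) -f$exps[, j]))
  o <- do.call(order, keys)
  f$exps <- f$exps[o, , drop = FALSE]
  f$coefs <- f$coefs[o]
  f
}

gf_zero <- function(p, nvars) {
  gf_poly(matrix(0L, 0L, nvars), integer(0), p, nvars)
}

gf_const <- function(c, p, nvars) {
  gf_poly(matrix(0L, 1L, nvars), c, p, nvars)
}

gf_var <- function(i, p, nvars, pow = 1L) {
  e <- matrix(0L, 1L, nvars)
  e[1L, i] <- as.integer(pow)
  gf_poly(e, 1L, p, nvars)
}

is_zero_poly <- function(f) nrow(f$exps) == 0L

check_compatible <- function(f, g) {
  if (f$p != g$p || f$nvars != g$nvars) {
    stop("polynomials live in different rings")
  }
}

#' @rdname gf_poly_arith
#' @export
gf_add <- function(f, g) {
  check_compatible(f, g)
  gf_poly(rbind(f$exps, g$exps), c(f$coefs, g$coefs), f$p, f$nvars)
}

#' @rdname gf_poly_arith
#' @export
gf_sub <- function(f, g) {
  check_compatible(f, g)
  gf_poly(rbind(f$exps, g$exps), c(f$coefs, (f$p - g$coefs) %% f$p), f$p, f$nvars)
}

#' Polynomial ring operations over GF(p)
#'
#' Addition, subtraction, multiplication and scalar multiplication in
#' GF(p)[x1, ..., xn], all exact.
#'
#' @param f,g \code{gf_poly} objects over the same field with equal
#'   \code{nvars}.
#' @param c Integer scalar.
#' @return A \code{gf_poly}.
#' @name gf_poly_arith
#' @export
gf_mul <- function(f, g) {
  check_compatible(f, g)
  if (is_zero_poly(f) || is_zero_poly(g)) return(gf_zero(f$p, f$nvars))
  mf <- nrow(f$exps); mg <- nrow(g$exps)
  i <- rep(seq_len(mf), times = mg)
  j <- rep(seq_len(mg), each = mf)
  exps <- f$exps[i, , drop = FALSE] + g$exps[j, , drop = FALSE]
  coefs <- (f$coefs[i] * g$coefs[j]) %% f$p
  gf_poly(exps, coefs, f$p, f$nvars)
}

#' @rdname gf_poly_arith
#' @export
gf_scale <- function(f, c) {
  gf_poly(f$exps, (f$coefs * (as.integer(c) %% f$p)) %% f$p, f$p, f$nvars)
}

#' Evaluate a polynomial at one or many states
#'
#' Computes f(x) in GF(p) for each row of \code{points}. This is the map a
#' coordinate polynomial of a polynomial dynamical system applies to a network
#' state.
#'
#' @param f A \code{gf_poly}.
#' @param points Integer vector (a single state) or matrix with one state per
#'   row; entries must lie in \code{0:(p-1)}.
#' @return Integer vector of values in \code{0:(p-1)}, one per state.
#' @examples
#' f <- poly_parse("x2 + 2*x3", p = 3, nvars = 3)  # x2 - x3 over GF(3)
#' gf_eval(f, c(2, 1, 0))
#' @export
gf_eval <- function(f, points) {
  if (is.null(dim(points))) points <- matrix(as.integer(points), nrow = 1L)
  points <- matrix(as.integer(points), nrow = nrow(points))
  if (ncol(points) != f$nvars) stop("state length must equal nvars")
  if (any(points < 0L) || any(points >= f$p)) {
    stop("state entries must lie in 0..", f$p - 1L)
  }
  m <- nrow(points)
  if (is_zero_poly(f)) return(integer(m))
  # value of x^e for e in 0..maxe, per point and variable, built by repeated
  # multiplication so everything stays in integer range
  acc <- integer(m)
  for (t in seq_len(nrow(f$exps))) {
    term <- rep(f$coefs[t], m)
    e <- f$exps[t, ]
    for (v in which(e > 0L)) {
      pw <- points[, v]
      r <- rep(1L, m)
      k <- e[v]
      while (k > 0L) {
        if (k %% 2L == 1L) r <- (r * pw) %% f$p
        pw <- (pw * pw) %% f$p
        k <- k %/% 2L
      }
      term <- (term * r) %% f$p
    }
    acc <- (acc + term) %% f$p
  }
  acc
}

#' Reduce exponents modulo the field equations
#'
#' Every element of GF(p) satisfies \eqn{a^p = a}, so the field equations
#' \eqn{x_i^p - x_i} vanish on all of GF(p)^n and any exponent \eqn{e > 0} can
#' be replaced by \eqn{((e - 1) \bmod (p - 1)) + 1} without changing the
#' induced function. The result is the unique representative of f with all
#' exponents at most p - 1, the canonical form in which minimal models are
#' reported.
#'
#' @param f A \code{gf_poly}.
#' @return A \code{gf_poly} with all exponents <= p - 1 inducing the same
#'   function GF(p)^n -> GF(p) as \code{f}.
#' @examples
#' poly_format(canonical_reduce(poly_parse("x1^4", p = 3, nvars = 1)))  # x1^2
#' @export
canonical_reduce <- function(f) {
  if (is_zero_poly(f)) return(f)
  e <- f$exps
  pos <- e > 0L
  e[pos] <- ((e[pos] - 1L) %% (f$p - 1L)) + 1L
  gf_poly(e, f$coefs, f$p, f$nvars)
}

#' Test two polynomials for equality of canonical form
#'
#' @param f,g \code{gf_poly} objects.
#' @return TRUE when the stored canonical representations are identical.
#' @export
poly_equal <- function(f, g) {
  f$p == g$p && f$nvars == g$nvars &&
    identical(f$exps, g$exps) && identical(f$coefs, g$coefs)
}

# stable string key, used to group minimal models
poly_key <- function(f) {
  if (is_zero_poly(f)) return("0")
  paste(paste0(f$coefs, ":", apply(f$exps, 1L, paste, collapse = ",")),
        collapse = ";")
}

#' Format a polynomial as text
#'
#' Serialises to the grammar accepted by \code{\link{poly_parse}}: terms
#' joined by \code{" + "}, each term \code{c*x<i>^<e>*...} with the
#' coefficient omitted when 1 (unless the term is constant) and exponent 1
#' omitted.
#'
#' @param f A \code{gf_poly}.
#' @param varnames Optional variable names; defaults to \code{x1, ..., xn}.
#' @return A single string; \code{"0"} for the zero polynomial.
#' @export
poly_format <- function(f, varnames = NULL) {
  if (is_zero_poly(f)) return("0")
  if (is.null(varnames)) varnames <- paste0("x", seq_len(f$nvars))
  terms <- vapply(seq_len(nrow(f$exps)), function(t) {
    e <- f$exps[t, ]
    c <- f$coefs[t]
    vars <- which(e > 0L)
    if (length(vars) == 0L) return(as.character(c))
    vs <- vapply(vars, function(v) {
      if (e[v] == 1L) varnames[v] else paste0(varnames[v], "^", e[v])
    }, character(1))
    body <- paste(vs, collapse = "*")
    if (c == 1L) body else paste0(c, "*", body)
  }, character(1))
  paste(terms, collapse = " + ")
}

#' Parse a polynomial from text
#'
#' Accepts sums of terms over GF(p): \code{"2*x1^2*x3 + x2 + 1"}. A leading
#' minus or internal \code{"-"} is allowed and mapped to the additive inverse
#' modulo p, so \code{"x2 - x3"} over GF(3) parses to \code{x2 + 2*x3}.
#'
#' @param s Polynomial string.
#' @param p Prime field order.
#' @param nvars Number of variables.
#' @param varnames Optional variable names used in \code{s}; defaults to
#'   \code{x1, ..., xn}.
#' @return A \code{gf_poly} in canonical form.
#' @export
poly_parse <- function(s, p, nvars, varnames = NULL) {
  p <- as.integer(p)
  nvars <- as.integer(nvars)
  if (is.null(varnames)) varnames <- paste0("x", seq_len(nvars))
  s <- gsub("\\s+", "", s)
  if (s == "" ) stop("empty polynomial string")
  if (s == "0") return(gf_zero(p, nvars))
  # split into signed terms
  s2 <- gsub("-", "+-", s, fixed = TRUE)
  parts <- strsplit(s2, "+", fixed = TRUE)[[1]]
  parts <- parts[parts != ""]
  exps <- matrix(0L, 0L, nvars)
  coefs <- integer(0)
  for (part in parts) {
    neg <- startsWith(part, "-")
    if (neg) part <- substring(part, 2L)
    if (part == "") stop("malformed term in '", s, "'")
    factors <- strsplit(part, "*", fixed = TRUE)[[1]]
    coef <- 1L
    e <- integer(nvars)
    for (fac in factors) {
      if (grepl("^[0-9]+$", fac)) {
        coef <- (coef * (as.integer(fac) %% p)) %% p
      } else {
        m <- regmatches(fac, regexec("^(.+?)(\\^([0-9]+))?$", fac))[[1]]
        vname <- m[2]
        pow <- if (m[4] == "") 1L else as.integer(m[4])
        vi <- match(vname, varnames)
        if (is.na(vi)) stop("unknown variable '", vname, "' in '", s, "'")
        e[vi] <- e[vi] + pow
      }
    }
    if (neg) coef <- (p - coef) %% p
    exps <- rbind(exps, e)
    coefs <- c(coefs, coef)
  }
  dimnames(exps) <- NULL
  gf_poly(exps, coefs, p, nvars)
}

#' @export
print.gf_poly <- function(x, ...) {
  cat(poly_format(x), "  [GF(", x$p, "), ", x$nvars, " vars]\n", sep = "")
  invisible(x)
}

#' Variables appearing in a polynomial
#'
#' Reported on the canonical (exponent-reduced) form, as used when reading
#' regulatory dependencies off a coordinate polynomial.
#'
#' @param f A \code{gf_poly}.
#' @return Integer vector of variable indices with a positive exponent in
#'   some term.
#' @export
poly_support <- function(f) {
  f <- canonical_reduce(f)
  if (is_zero_poly(f)) return(integer(0))
  which(colSums(f$exps > 0L) > 0L)
}
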