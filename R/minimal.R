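# From transition data to minimal polynomial dynamical systems: an
# interpolating system, its reduction modulo the ideal of the observed input
# states, and the per-ordering minimal model.

#' Interpolating coordinate polynomial
#'
#' Builds one polynomial fitting coordinate \code{i} of the observed
#' transitions by summing point indicators: for input state s with observed
#' next value y, the indicator \eqn{\prod_l (1 - (x_l - s_l)^{p-1})} is 1 at
#' s and 0 at every other state, so \eqn{\sum_s y_s \prod_l (...)} fits all
#' pairs. The result is canonically exponent-reduced. Any other fitting
#' polynomial differs from this one by an element of the ideal of the input
#' points.
#'
#' @param data A \code{\link{transition_data}}.
#' @param i Coordinate (node) index in 1..n.
#' @return A \code{gf_poly} f with f(input_j) = output_j[i] for every pair.
#' @export
interpolate <- function(data, i) {
  p <- data$p; n <- data$nvars
  i <- as.integer(i)
  if (i < 1L || i > n) stop("coordinate index out of range")
  acc <- gf_zero(p, n)
  one <- gf_const(1L, p, n)
  for (j in seq_len(nrow(data$inputs))) {
    y <- data$outputs[j, i]
    if (y == 0L) next
    ind <- one
    for (l in seq_len(n)) {
      a <- data$inputs[j, l]
      base <- gf_sub(gf_var(l, p, n), gf_const(a, p, n))  # (x_l - a)
      pw <- one
      for (k in seq_len(p - 1L)) pw <- gf_mul(pw, base)
      ind <- gf_mul(ind, gf_sub(one, pw))
    }
    acc <- gf_add(acc, gf_scale(ind, y))
  }
  canonical_reduce(acc)
}

#' Minimal polynomial dynamical system for one monomial ordering
#'
#' For the given weight-vector ordering, computes the unique fitting system
#' whose coordinate polynomials contain no term that vanishes identically on
#' the observed input states. Two equivalent routes are implemented:
#' \code{"solve"} interpolates directly on the standard monomials of the
#' reduced Groebner basis of the ideal of input points (the default, and much
#' faster), while \code{"reduce"} takes the normal form of an interpolating
#' polynomial modulo that basis. Both yield the same canonical polynomials.
#'
#' @param data A \code{\link{transition_data}}.
#' @param ord A \code{\link{weight_ordering}}.
#' @param method \code{"solve"} or \code{"reduce"}.
#' @param gb Optionally a precomputed \code{marked_gb} of the input points
#'   under \code{ord}.
#' @return Object of class \code{minimal_pds}: list of n coordinate
#'   \code{gf_poly}s, the ordering, and the Groebner basis used.
#' @export
minimal_model <- function(data, ord, method = c("solve", "reduce"), gb = NULL) {
  method <- match.arg(method)
  if (is.null(gb)) gb <- ideal_of_points_gb(data$inputs, ord, data$p)
  n <- data$nvars
  coords <- vector("list", n)
  for (i in seq_len(n)) {
    coords[[i]] <- switch(method,
      solve = standard_interpolate(gb, data$outputs[, i]),
      reduce = normal_form(interpolate(data, i), gb, ord))
  }
  structure(list(coords = coords, ordering = ord, gb = gb, p = data$p,
                 nvars = n, varnames = data$varnames),
            class = "minimal_pds")
}

#' @export
print.minimal_pds <- function(x, ...) {
  cat("minimal PDS over GF(", x$p, "):\n", sep = "")
  for (i in seq_along(x$coords)) {
    cat("  f", i, " = ", poly_format(x$coords[[i]], x$varnames), "\n", sep = "")
  }
  invisible(x)
}

# canonical identity key of a PDS = concatenated coordinate keys
pds_key <- function(model) {
  paste(vapply(model$coords, poly_key, character(1)), collapse = "|")
}

#' Apply a deterministic PDS to states
#'
#' @param model A \code{minimal_pds} (or any list with \code{coords}).
#' @param states Integer vector (one state) or matrix of states (rows).
#' @return Matrix of next states, one row per input state.
#' @export
pds_apply <- function(model, states) {
  if (is.null(dim(states))) states <- matrix(as.integer(states), nrow = 1L)
  out <- vapply(model$coords, function(f) gf_eval(f, states),
                integer(nrow(states)))
  matrix(as.integer(out), nrow = nrow(states))
}
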