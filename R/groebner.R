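# Groebner machinery: multivariate division (normal form), the
# Buchberger-Moller algorithm for reduced Groebner bases of ideals of points,
# and a classical Buchberger implementation kept as an independent oracle.

#' Normal form (remainder of multivariate division)
#'
#' Divides \code{f} by the marked basis \code{G} under \code{ord} and returns
#' the remainder: no term of the result is divisible by the initial term of
#' any element of \code{G}. When \code{G} is a Groebner basis of an ideal I,
#' the remainder is the unique normal form of f modulo I, and is 0 exactly
#' when f lies in I. Reducing an interpolating coordinate polynomial modulo
#' the ideal of the observed points yields the minimal model for that
#' ordering.
#'
#' @param f A \code{gf_poly}; it is canonically exponent-reduced first.
#' @param G A \code{marked_gb} (see \code{\link{ideal_of_points_gb}}) or a
#'   list of \code{gf_poly} divisors (marked at their ord-leading terms). An
#'   empty list returns the canonical reduction of \code{f}.
#' @param ord A \code{\link{weight_ordering}}.
#' @return The remainder \code{gf_poly}.
#' @export
normal_form <- function(f, G, ord) {
  polys <- if (inherits(G, "marked_gb")) G$basis else G
  f <- canonical_reduce(f)
  if (length(polys) == 0L) return(f)
  p <- f$p
  inits <- t(vapply(polys, function(g) leading_term(g, ord)$exp,
                    integer(f$nvars)))
  inits <- matrix(as.integer(inits), ncol = f$nvars)
  # stable divisor preference: first in a sort of G by initial term
  pref <- monomial_order(inits, ord)
  rem_exps <- matrix(0L, 0L, f$nvars)
  rem_coefs <- integer(0)
  work <- f
  while (!is_zero_poly(work)) {
    li <- leading_index(work, ord)
    lexp <- work$exps[li, ]
    lcoef <- work$coefs[li]
    div <- NA_integer_
    for (k in pref) {
      if (all(lexp >= inits[k, ])) { div <- k; break }
    }
    if (is.na(div)) {
      rem_exps <- rbind(rem_exps, lexp)
      rem_coefs <- c(rem_coefs, lcoef)
      work$exps <- work$exps[-li, , drop = FALSE]
      work$coefs <- work$coefs[-li]
    } else {
      g <- polys[[div]]
      gi <- leading_index(g, ord)
      factor <- (lcoef * gf_inv(g$coefs[gi], p)) %% p
      quot <- gf_poly(matrix(lexp - inits[div, ], 1L), factor, p, f$nvars)
      work <- gf_sub(work, gf_mul(quot, g))
    }
  }
  dimnames(rem_exps) <- NULL
  gf_poly(rem_exps, rem_coefs, p, f$nvars)
}

new_marked_gb <- function(basis, initials, standard, ordering, p, nvars,
                          points = NULL) {
  structure(list(basis = basis, initials = initials, standard = standard,
                 ordering = ordering, p = p, nvars = nvars, points = points),
            class = "marked_gb")
}

#' @export
print.marked_gb <- function(x, ...) {
  cat("marked reduced Groebner basis over GF(", x$p, "), ", x$nvars,
      " vars\n", sep = "")
  cat("  ", length(x$basis), " basis elements, ",
      nrow(x$standard), " standard monomials\n", sep = "")
  invisible(x)
}

#' Reduced Groebner basis of an ideal of points (Buchberger-Moller)
#'
#' Computes the marked reduced Groebner basis, under a weight-vector
#' ordering, of the ideal I(V) of all polynomials vanishing on the finite
#' point set V in GF(p)^n. Candidate monomials are visited in increasing
#' order; a candidate whose evaluation vector on V is linearly dependent on
#' those of the standard monomials found so far yields a basis element
#' (candidate minus the dependence combination), while an independent
#' candidate becomes a standard monomial. The standard monomials form a basis
#' of the quotient ring, one per point, so every consistent data set has a
#' unique model supported on them.
#'
#' @param points Integer matrix, one point per row, entries in 0..p-1, rows
#'   distinct and nonempty.
#' @param ord A \code{\link{weight_ordering}}.
#' @param p Prime field order.
#' @return A \code{marked_gb}: \code{basis} (list of monic \code{gf_poly}),
#'   \code{initials} and \code{standard} (exponent matrices), plus the
#'   triangular data needed to interpolate on the standard monomials.
#' @examples
#' gb <- ideal_of_points_gb(matrix(c(0, 1, 2), 3, 1), weight_ordering(1), p = 3)
#' poly_format(gb$basis[[1]])  # the field equation x1^3 + 2*x1
#' @export
ideal_of_points_gb <- function(points, ord, p) {
  p <- as.integer(p)
  if (is.null(dim(points))) points <- matrix(as.integer(points), ncol = 1L)
  points <- matrix(as.integer(points), nrow = nrow(points))
  n <- ncol(points)
  m <- nrow(points)
  if (m == 0L) stop("empty point set: the ideal of points would be the whole ring")
  if (any(points < 0L) || any(points >= p)) stop("point entries must lie in 0..", p - 1L)
  if (anyDuplicated(apply(points, 1L, paste, collapse = ","))) {
    stop("points must be pairwise distinct")
  }
  if (length(ord$omega) != n) stop("weight vector length must equal ncol(points)")

  # incremental row echelon over the evaluation vectors of the standard
  # monomials: each row is (pivot, u, a) with u = sum_j a_j * eval(std_j)
  std_exps <- matrix(0L, 0L, n)
  std_evals <- matrix(0L, m, 0L)          # eval vectors of standard monomials
  ech_u <- list(); ech_piv <- integer(0); ech_a <- list()
  basis <- list(); init_exps <- matrix(0L, 0L, n)

  # candidate queue keyed by exponent string
  cand <- list(matrix(0L, 1L, n)[1L, ])
  cand_keys <- paste(cand[[1L]], collapse = ",")

  eval_monomial <- function(e) {
    v <- rep(1L, m)
    for (j in which(e > 0L)) {
      pw <- points[, j]; r <- rep(1L, m); k <- e[j]
      while (k > 0L) {
        if (k %% 2L == 1L) r <- (r * pw) %% p
        pw <- (pw * pw) %% p
        k <- k %/% 2L
      }
      v <- (v * r) %% p
    }
    v
  }

  while (length(cand) > 0L) {
    # pop the ord-minimal candidate
    cm <- do.call(rbind, cand)
    i_min <- monomial_order(cm, ord)[1L]
    t_exp <- cand[[i_min]]
    cand <- cand[-i_min]; cand_keys <- cand_keys[-i_min]
    # skip candidates divisible by a known initial term
    if (nrow(init_exps) > 0L &&
        any(apply(init_exps, 1L, function(ie) all(t_exp >= ie)))) next

    v <- eval_monomial(t_exp)
    a <- integer(ncol(std_evals))
    for (r in seq_along(ech_u)) {
      c0 <- v[ech_piv[r]]
      if (c0 != 0L) {
        v <- (v - c0 * ech_u[[r]]) %% p
        a[seq_along(ech_a[[r]])] <- (a[seq_along(ech_a[[r]])] + c0 * ech_a[[r]]) %% p
      }
    }
    if (all(v == 0L)) {
      # dependent: t - sum a_j std_j vanishes on V -> reduced basis element
      tail_keep <- which(a != 0L)
      g <- gf_poly(rbind(t_exp, std_exps[tail_keep, , drop = FALSE]),
                   c(1L, (p - a[tail_keep]) %% p), p, n)
      basis[[length(basis) + 1L]] <- g
      init_exps <- rbind(init_exps, t_exp)
    } else {
      # independent: standard monomial; extend echelon
      std_exps <- rbind(std_exps, t_exp)
      std_evals <- cbind(std_evals, eval_monomial(t_exp))
      piv <- which(v != 0L)[1L]
      inv <- gf_inv(v[piv], p)
      # normalised residual u = (eval(t) - sum a_j eval(std_j)) / v[piv],
      # recorded as a combination of the original standard eval vectors
      # (t itself included as the newest one)
      comb <- integer(ncol(std_evals))
      comb[length(comb)] <- 1L
      comb[seq_along(a)] <- (comb[seq_along(a)] - a) %% p
      ech_u[[length(ech_u) + 1L]] <- (v * inv) %% p
      ech_a[[length(ech_a) + 1L]] <- (comb * inv) %% p
      ech_piv <- c(ech_piv, piv)
      # enqueue multiples x_j * t (skip those divisible by an initial term)
      for (j in seq_len(n)) {
        e2 <- t_exp; e2[j] <- e2[j] + 1L
        key <- paste(e2, collapse = ",")
        if (key %in% cand_keys) next
        if (nrow(init_exps) > 0L &&
            any(apply(init_exps, 1L, function(ie) all(e2 >= ie)))) next
        cand[[length(cand) + 1L]] <- e2
        cand_keys <- c(cand_keys, key)
      }
    }
    if (ncol(std_evals) > m) stop("internal error: too many standard monomials")
  }
  dimnames(std_exps) <- NULL
  dimnames(init_exps) <- NULL
  res <- new_marked_gb(basis, init_exps, std_exps, ord, p, n, points)
  res$std_evals <- std_evals
  res
}

#' Interpolate output values on the standard monomials
#'
#' Solves for the unique polynomial supported on the standard monomials of a
#' marked reduced Groebner basis of I(points) that takes the prescribed value
#' at each point. This is the "linear solve" route to the minimal model.
#'
#' @param gb A \code{marked_gb} returned by \code{\link{ideal_of_points_gb}}.
#' @param values Integer vector of target values, one per point.
#' @return A \code{gf_poly} in canonical form.
#' @export
standard_interpolate <- function(gb, values) {
  p <- gb$p
  m <- nrow(gb$points)
  values <- as.integer(values) %% p
  if (length(values) != m) stop("need one value per point")
  A <- gb$std_evals %% p          # m x m, invertible over GF(p)
  b <- values
  nstd <- ncol(A)
  # Gaussian elimination
  Ab <- cbind(A, b)
  row <- 1L
  piv_cols <- integer(0)
  for (col in seq_len(nstd)) {
    sel <- which(Ab[row:m, col] != 0L)
    if (length(sel) == 0L) next
    sel <- sel[1L] + row - 1L
    if (sel != row) Ab[c(row, sel), ] <- Ab[c(sel, row), ]
    Ab[row, ] <- (Ab[row, ] * gf_inv(Ab[row, col], p)) %% p
    others <- which(Ab[, col] != 0L & seq_len(m) != row)
    if (length(others) > 0L) {
      Ab[others, ] <- (Ab[others, , drop = FALSE] -
                         outer(Ab[others, col], Ab[row, ])) %% p
    }
    piv_cols <- c(piv_cols, col)
    row <- row + 1L
    if (row > m) break
  }
  coefs <- integer(nstd)
  coefs[piv_cols] <- Ab[seq_along(piv_cols), nstd + 1L]
  gf_poly(gb$standard, coefs, p, gb$nvars)
}

# ---- classical Buchberger (test oracle) ------------------------------------

full_reduce <- function(f, polys, ord) {
  if (length(polys) == 0L) return(canonical_reduce_noop(f))
  normal_form_raw(f, polys, ord)
}

# division without the canonical exponent reduction (Buchberger works in the
# plain polynomial ring; field equations enter as explicit generators)
normal_form_raw <- function(f, polys, ord) {
  p <- f$p
  if (length(polys) == 0L) return(f)
  inits <- t(vapply(polys, function(g) leading_term(g, ord)$exp,
                    integer(f$nvars)))
  inits <- matrix(as.integer(inits), ncol = f$nvars)
  pref <- monomial_order(inits, ord)
  rem_exps <- matrix(0L, 0L, f$nvars)
  rem_coefs <- integer(0)
  work <- f
  while (!is_zero_poly(work)) {
    li <- leading_index(work, ord)
    lexp <- work$exps[li, ]
    lcoef <- work$coefs[li]
    div <- NA_integer_
    for (k in pref) if (all(lexp >= inits[k, ])) { div <- k; break }
    if (is.na(div)) {
      rem_exps <- rbind(rem_exps, lexp)
      rem_coefs <- c(rem_coefs, lcoef)
      work$exps <- work$exps[-li, , drop = FALSE]
      work$coefs <- work$coefs[-li]
    } else {
      g <- polys[[div]]
      gi <- leading_index(g, ord)
      factor <- (lcoef * gf_inv(g$coefs[gi], p)) %% p
      quot <- gf_poly(matrix(lexp - inits[div, ], 1L), factor, p, f$nvars)
      work <- gf_sub(work, gf_mul(quot, g))
    }
  }
  dimnames(rem_exps) <- NULL
  gf_poly(rem_exps, rem_coefs, f$p, f$nvars)
}

canonical_reduce_noop <- function(f) f

s_poly <- function(f, g, ord) {
  p <- f$p
  lf <- leading_term(f, ord); lg <- leading_term(g, ord)
  lcm <- pmax(lf$exp, lg$exp)
  mf <- gf_poly(matrix(lcm - lf$exp, 1L), gf_inv(lf$coef, p), p, f$nvars)
  mg <- gf_poly(matrix(lcm - lg$exp, 1L), gf_inv(lg$coef, p), p, f$nvars)
  gf_sub(gf_mul(mf, f), gf_mul(mg, g))
}

#' Buchberger's algorithm (independent oracle)
#'
#' Computes the reduced Groebner basis of the ideal generated by
#' \code{generators} together with the field equations \eqn{x_i^p - x_i}.
#' Including the field equations makes the ideal the full vanishing ideal of
#' its variety inside GF(p)^n, matching what \code{\link{ideal_of_points_gb}}
#' computes for ideals of points; within the package this classical route
#' serves as a cross-check of the point-based computation.
#'
#' @param generators Nonempty list of \code{gf_poly} over a common ring.
#' @param ord A \code{\link{weight_ordering}}.
#' @return A \code{marked_gb} (without point data).
#' @export
buchberger <- function(generators, ord) {
  if (length(generators) == 0L) stop("need at least one generator")
  p <- generators[[1L]]$p
  n <- generators[[1L]]$nvars
  G <- generators
  for (i in seq_len(n)) {
    fe <- gf_sub(gf_var(i, p, n, pow = p), gf_var(i, p, n))
    G[[length(G) + 1L]] <- fe
  }
  G <- Filter(Negate(is_zero_poly), G)
  pairs <- utils::combn(length(G), 2L, simplify = FALSE)
  while (length(pairs) > 0L) {
    pr <- pairs[[1L]]; pairs <- pairs[-1L]
    sp <- s_poly(G[[pr[1L]]], G[[pr[2L]]], ord)
    r <- normal_form_raw(sp, G, ord)
    if (!is_zero_poly(r)) {
      G[[length(G) + 1L]] <- r
      for (k in seq_len(length(G) - 1L)) {
        pairs[[length(pairs) + 1L]] <- c(k, length(G))
      }
    }
  }
  # minimise: drop g whose initial term is divisible by another's
  inits <- t(vapply(G, function(g) leading_term(g, ord)$exp, integer(n)))
  inits <- matrix(as.integer(inits), ncol = n)
  keep <- rep(TRUE, length(G))
  for (i in seq_along(G)) {
    for (j in seq_along(G)) {
      if (i != j && keep[j] && all(inits[i, ] >= inits[j, ]) &&
          !all(inits[i, ] == inits[j, ])) { keep[i] <- FALSE; break }
      if (i != j && keep[j] && all(inits[i, ] == inits[j, ]) && j < i) {
        keep[i] <- FALSE; break
      }
    }
  }
  G <- G[keep]; inits <- inits[keep, , drop = FALSE]
  # reduce: tail-reduce each element against the others, normalise monic
  repeat {
    changed <- FALSE
    for (i in seq_along(G)) {
      others <- G[-i]
      r <- normal_form_raw(G[[i]], others, ord)
      if (!poly_equal(r, G[[i]])) {
        if (is_zero_poly(r)) stop("internal error: basis element reduced to zero")
        G[[i]] <- r
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  G <- lapply(G, function(g) {
    gf_scale(g, gf_inv(leading_term(g, ord)$coef, p))
  })
  inits <- t(vapply(G, function(g) leading_term(g, ord)$exp, integer(n)))
  inits <- matrix(as.integer(inits), ncol = n)
  o <- monomial_order(inits, ord)
  G <- G[o]; inits <- inits[o, , drop = FALSE]
  # standard monomials: canonical monomials outside the initial ideal
  std <- standard_monomials_under(inits, p, n)
  new_marked_gb(G, inits, std, ord, p, n)
}

# all canonical monomials (exponents <= p-1) not divisible by any initial term
standard_monomials_under <- function(inits, p, n) {
  grids <- rep(list(0:(p - 1L)), n)
  all_exp <- as.matrix(expand.grid(rev(grids)))[, n:1, drop = FALSE]
  dimnames(all_exp) <- NULL
  all_exp <- matrix(as.integer(all_exp), ncol = n)
  if (nrow(inits) == 0L) return(all_exp)
  keep <- vapply(seq_len(nrow(all_exp)), function(i) {
    e <- all_exp[i, ]
    !any(apply(inits, 1L, function(ie) all(e >= ie)))
  }, logical(1))
  all_exp[keep, , drop = FALSE]
}
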