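# Interpolation, ideals of points (Buchberger-Moller), the Buchberger
# oracle, and minimal models.

test_that("interpolation fits every observed pair", {
  data <- ternary3_data()
  f1 <- interpolate(data, 1)
  expect_equal(gf_eval(f1, data$inputs), data$outputs[, 1])
  # single pair
  d1 <- transition_data(c(0, 0), c(2, 1), p = 3)
  expect_equal(gf_eval(interpolate(d1, 1), c(0, 0)), 2L)
  expect_equal(gf_eval(interpolate(d1, 2), c(0, 0)), 1L)
  # random consistent data
  set.seed(5)
  for (rep in 1:5) {
    d <- random_consistent_data(3L, 2L, 5L)
    for (i in 1:2) {
      expect_equal(gf_eval(interpolate(d, i), d$inputs), d$outputs[, i])
    }
  }
})

test_that("inconsistent data is rejected naming the conflict", {
  expect_error(
    transition_data(rbind(c(0, 1), c(0, 1)), rbind(c(1, 0), c(0, 0)), p = 2),
    "0,1")
  # identical duplicated pairs are deduplicated silently
  d <- transition_data(rbind(c(0, 1), c(0, 1)), rbind(c(1, 0), c(1, 0)), p = 2)
  expect_equal(nrow(d$inputs), 1L)
  # majority resolution keeps the most frequent output
  d2 <- transition_data(rbind(c(0, 1), c(0, 1), c(0, 1), c(1, 1)),
                        rbind(c(1, 0), c(0, 0), c(1, 0), c(1, 1)),
                        p = 2, resolve = "majority")
  expect_equal(nrow(d2$inputs), 2L)
  expect_equal(d2$outputs[d2$inputs[, 1] == 0L & d2$inputs[, 2] == 1L, ],
               c(1L, 0L))
})

test_that("ideal of a full coordinate line is the field equation", {
  gb <- ideal_of_points_gb(matrix(0:2, 3, 1), weight_ordering(1), p = 3)
  expect_length(gb$basis, 1L)
  expect_equal(poly_format(gb$basis[[1]]), "x1^3 + 2*x1")  # x^3 - x
  expect_equal(nrow(gb$standard), 3L)  # 1, x, x^2
})

test_that("ideal of one point is the maximal ideal at that point", {
  gb <- ideal_of_points_gb(matrix(2L, 1, 1), weight_ordering(1), p = 3)
  expect_equal(nrow(gb$standard), 1L)
  expect_true(all(vapply(gb$basis,
                         function(g) gf_eval(g, matrix(2L, 1, 1)) == 0L,
                         logical(1))))
  expect_equal(poly_format(gb$basis[[1]]), "x1 + 1")  # x - 2 over GF(3)
})

test_that("Buchberger-Moller bases vanish on their points and are reduced", {
  set.seed(9)
  data <- ternary3_data()
  for (rep in 1:8) {
    ord <- weight_ordering(sample(0:10, 3, replace = TRUE))
    gb <- ideal_of_points_gb(data$inputs, ord, 3)
    expect_equal(nrow(gb$standard), nrow(data$inputs))
    for (g in gb$basis) {
      expect_true(all(gf_eval(g, data$inputs) == 0L))
      # marked initial coefficient is 1
      expect_equal(leading_term(g, ord)$coef, 1L)
    }
    # reduced: no term of any element divisible by another's initial term
    for (a in seq_along(gb$basis)) {
      for (b in seq_along(gb$basis)) {
        if (a == b) next
        ia <- gb$initials[a, ]
        tb <- gb$basis[[b]]$exps
        expect_false(any(apply(tb, 1, function(e) all(e >= ia))))
      }
    }
    # normal form of (random g) * (basis element) is 0
    g <- random_poly(3L, 3L)
    prod <- gf_mul(g, gb$basis[[sample(length(gb$basis), 1)]])
    expect_true(ppdsinfer:::is_zero_poly(normal_form(prod, gb, ord)))
  }
})

test_that("Buchberger oracle agrees with Buchberger-Moller on small ideals", {
  # I(V) generated by the point indicators of the complement (plus field
  # equations): independent classical route to the same reduced GB
  set.seed(13)
  cases <- list(list(p = 2L, n = 2L, m = 2L), list(p = 2L, n = 3L, m = 3L),
                list(p = 3L, n = 2L, m = 3L))
  for (cs in cases) {
    states <- all_states_grid(cs$p, cs$n)
    pts <- states[sample.int(nrow(states), cs$m), , drop = FALSE]
    keyp <- apply(pts, 1, paste, collapse = ",")
    off <- states[!(apply(states, 1, paste, collapse = ",") %in% keyp), ,
                  drop = FALSE]
    # indicator of u: prod_l (1 - (x_l - u_l)^(p-1)); vanishes on V for u off V
    gens <- lapply(seq_len(nrow(off)), function(r) {
      one <- ppdsinfer:::gf_const(1L, cs$p, cs$n)
      ind <- one
      for (l in seq_len(cs$n)) {
        base <- gf_sub(ppdsinfer:::gf_var(l, cs$p, cs$n),
                       ppdsinfer:::gf_const(off[r, l], cs$p, cs$n))
        pw <- one
        for (k in seq_len(cs$p - 1L)) pw <- gf_mul(pw, base)
        ind <- gf_mul(ind, gf_sub(one, pw))
      }
      ind
    })
    ord <- weight_ordering(sample(0:5, cs$n, replace = TRUE))
    gb_bm <- ideal_of_points_gb(pts, ord, cs$p)
    gb_bb <- buchberger(gens, ord)
    key <- function(m) sort(apply(m, 1, paste, collapse = ","))
    expect_equal(key(gb_bb$standard), key(gb_bm$standard))
    expect_equal(key(gb_bb$initials), key(gb_bm$initials))
    # identical reduced basis polynomials
    fmt <- function(gb) sort(vapply(gb$basis, poly_format, character(1)))
    expect_equal(fmt(gb_bb), fmt(gb_bm))
  }
})

test_that("Buchberger reduces generators modulo the field equations", {
  g <- poly_parse("x1 - 1", 3, 1)
  gb <- buchberger(list(g), weight_ordering(1))
  expect_length(gb$basis, 1L)
  expect_equal(poly_format(gb$basis[[1]]), "x1 + 2")
  # S-polynomial of any pair in the final basis reduces to 0
  gb2 <- buchberger(list(poly_parse("x1*x2 + x1", 2, 2),
                         poly_parse("x2 + 1", 2, 2)),
                    weight_ordering(c(1, 1)))
  for (a in seq_along(gb2$basis)) {
    for (b in seq_along(gb2$basis)) {
      if (a >= b) next
      sp <- ppdsinfer:::s_poly(gb2$basis[[a]], gb2$basis[[b]], gb2$ordering)
      r <- ppdsinfer:::normal_form_raw(sp, gb2$basis, gb2$ordering)
      expect_true(ppdsinfer:::is_zero_poly(r))
    }
  }
})

test_that("minimal models fit the data under every sampled ordering", {
  set.seed(17)
  data <- ternary3_data()
  for (rep in 1:10) {
    ord <- weight_ordering(sample(0:20, 3, replace = TRUE))
    mm <- minimal_model(data, ord)
    expect_true(all(pds_apply(mm, data$inputs) == data$outputs))
  }
  for (rep in 1:5) {
    d <- random_consistent_data(2L, 3L, 4L)
    ord <- weight_ordering(sample(0:20, 3, replace = TRUE))
    mm <- minimal_model(d, ord)
    expect_true(all(pds_apply(mm, d$inputs) == d$outputs))
  }
})

test_that("normal-form and linear-solve routes agree", {
  set.seed(19)
  data <- ternary3_data()
  for (rep in 1:6) {
    ord <- weight_ordering(sample(0:10, 3, replace = TRUE))
    m1 <- minimal_model(data, ord, method = "solve")
    m2 <- minimal_model(data, ord, method = "reduce")
    for (i in 1:3) expect_true(poly_equal(m1$coords[[i]], m2$coords[[i]]))
  }
  d <- random_consistent_data(2L, 2L, 3L)
  ord <- weight_ordering(c(3, 1))
  m1 <- minimal_model(d, ord, method = "solve")
  m2 <- minimal_model(d, ord, method = "reduce")
  for (i in 1:2) expect_true(poly_equal(m1$coords[[i]], m2$coords[[i]]))
})

test_that("no sub-sum of a minimal coordinate vanishes on the inputs", {
  # brute-force minimality oracle on small instances: if some nonempty
  # subset of f's terms vanished identically on the inputs, dropping it
  # would leave a smaller fitting polynomial
  set.seed(29)
  for (cs in list(list(p = 2L, n = 2L, m = 3L), list(p = 3L, n = 2L, m = 4L))) {
    d <- random_consistent_data(cs$p, cs$n, cs$m)
    ord <- weight_ordering(sample(0:5, cs$n, replace = TRUE))
    mm <- minimal_model(d, ord)
    for (i in seq_len(cs$n)) {
      f <- mm$coords[[i]]
      nt <- nrow(f$exps)
      if (nt == 0L) next
      for (mask in seq_len(2^nt - 1L)) {
        sel <- which(bitwAnd(mask, bitwShiftL(1L, seq_len(nt) - 1L)) != 0L)
        sub <- gf_poly(f$exps[sel, , drop = FALSE], f$coefs[sel], cs$p)
        expect_false(all(gf_eval(sub, d$inputs) == 0L))
      }
    }
  }
})

test_that("exhaustive data pins down the model for every ordering", {
  set.seed(31)
  p <- 2L; n <- 2L
  truth <- pds_from_strings(c("x1*x2 + x2", "x1 + 1"), p, n)
  states <- all_states_grid(p, n)
  d <- transition_data(states, pds_apply(truth, states), p)
  for (rep in 1:6) {
    ord <- weight_ordering(sample(0:10, n, replace = TRUE))
    mm <- minimal_model(d, ord)
    for (i in seq_len(n)) {
      expect_true(poly_equal(mm$coords[[i]], canonical_reduce(truth$coords[[i]])))
    }
  }
})
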