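# Stochastic state space, fixed points and stabilities, components,
# trajectory simulation.

# small two-option-per-node PPDS used in several tests
two_option_ppds <- function() {
  p <- 2L; n <- 2L
  mk <- function(a, b) list(polys = list(poly_parse(a, p, n),
                                         poly_parse(b, p, n)),
                            counts = c(1L, 1L), total = 2L)
  structure(list(nodes = list(mk("x2", "x1 + 1"), mk("x1*x2", "x2 + 1")),
                 p = p, nvars = n, varnames = c("x1", "x2"),
                 provenance = list()),
            class = "ppds")
}

test_that("state space enumerates p^n states with unit outgoing mass", {
  model <- two_option_ppds()
  sp <- build_state_space(model)
  expect_equal(nrow(sp$states), 4L)
  out <- rowsum(sp$prob, sp$from)
  expect_equal(as.numeric(out), rep(1, 4))
  # 2-node ternary example: 9 vertices
  p3 <- pds_from_strings(c("x1 + x2", "2*x2"), 3L, 2L)
  expect_equal(nrow(build_state_space(p3)$states), 9L)
})

test_that("a deterministic PDS has exactly one outgoing edge per state", {
  truth <- pds_from_strings(c("x2 + 1", "x1*x2"), 2L, 2L)
  sp <- build_state_space(truth)
  expect_equal(length(sp$from), 4L)
  expect_equal(sp$prob, rep(1, 4))
  expect_equal(sort(sp$from), 1:4)
})

test_that("stochastic edges are the union of the deterministic selections", {
  model <- two_option_ppds()
  sp <- build_state_space(model)
  # brute force: enumerate all per-node function choices
  edges <- new.env()
  probs <- list()
  for (j1 in 1:2) {
    for (j2 in 1:2) {
      det <- structure(list(coords = list(model$nodes[[1]]$polys[[j1]],
                                          model$nodes[[2]]$polys[[j2]]),
                            p = 2L, nvars = 2L,
                            varnames = model$varnames),
                       class = "minimal_pds")
      states <- all_states_grid(2L, 2L)
      nxt <- pds_apply(det, states)
      for (r in 1:4) {
        key <- paste(r, paste(nxt[r, ], collapse = ","), sep = "->")
        probs[[key]] <- c(probs[[key]], 0.25)
      }
    }
  }
  got <- split(sp$prob, paste(sp$from,
                              apply(sp$states[sp$to, , drop = FALSE], 1,
                                    paste, collapse = ","), sep = "->"))
  expect_setequal(names(got), names(probs))
  for (k in names(got)) {
    expect_equal(sum(got[[k]]), sum(probs[[k]]))
  }
})

test_that("fixed points carry exact stabilities equal to self-loop mass", {
  model <- two_option_ppds()
  sp <- build_state_space(model)
  fp <- fixed_points(model)
  # identity system: every state fixed and absorbing
  idp <- pds_from_strings(c("x1", "x2"), 2L, 2L)
  fpi <- fixed_points(idp)
  expect_equal(nrow(fpi), 4L)
  expect_true(all(fpi$stability == 1))
  expect_true(all(fpi$absorbing))
  # stability == probability of the self-loop edge, for every fixed point
  self <- sp$prob[sp$from == sp$to]
  names(self) <- sp$from[sp$from == sp$to]
  expect_setequal(as.character(fp$index), names(self))
  for (r in seq_len(nrow(fp))) {
    expect_equal(fp$stability[r], unname(self[as.character(fp$index[r])]))
  }
  # and equals the direct per-node product formula
  for (r in seq_len(nrow(fp))) {
    x <- as.integer(strsplit(fp$state[r], ",")[[1]])
    prodmass <- 1
    for (i in 1:2) {
      nd <- model$nodes[[i]]
      vals <- vapply(nd$polys, function(f) gf_eval(f, x), integer(1))
      prodmass <- prodmass * sum(nd$counts[vals == x[i]]) / nd$total
    }
    expect_equal(fp$stability[r], prodmass)
  }
})

test_that("Monte-Carlo stability concentrates around the exact value", {
  model <- two_option_ppds()
  fp <- fixed_points(model)
  runs <- 4000L
  for (r in seq_len(nrow(fp))) {
    x <- as.integer(strsplit(fp$state[r], ",")[[1]])
    q <- fp$stability[r]
    est <- estimate_stability_mc(model, x, runs = runs, seed = 100 + r)
    expect_lt(abs(est - q), 3 * sqrt(q * (1 - q) / runs) + 1e-12)
  }
  # absorbing state: estimate is exactly 1 at any runs
  idp <- pds_from_strings(c("x1", "x2"), 2L, 2L)
  expect_equal(estimate_stability_mc(idp, c(1, 0), runs = 50, seed = 1), 1)
  # reproducible under seed
  e1 <- estimate_stability_mc(model, c(0, 0), runs = 200, seed = 5)
  e2 <- estimate_stability_mc(model, c(0, 0), runs = 200, seed = 5)
  expect_equal(e1, e2)
})

test_that("weak components partition the state set", {
  idp <- pds_from_strings(c("x1", "x2"), 2L, 2L)
  comps <- state_components(build_state_space(idp))
  expect_length(comps, 4L)
  expect_true(all(vapply(comps, function(c) c$size, numeric(1)) == 1))
  # random PPDSs: sizes sum to p^n and every fixed point is in some component
  set.seed(51)
  for (rep in 1:3) {
    nodes <- lapply(1:2, function(i) {
      polys <- list(random_poly(2L, 2L), random_poly(2L, 2L))
      list(polys = polys, counts = c(1L, 1L), total = 2L)
    })
    model <- structure(list(nodes = nodes, p = 2L, nvars = 2L,
                            varnames = c("x1", "x2"), provenance = list()),
                       class = "ppds")
    sp <- build_state_space(model)
    comps <- state_components(sp)
    expect_equal(sum(vapply(comps, function(c) c$size, numeric(1))), 4)
    fp <- fixed_points(model)
    expect_setequal(unlist(lapply(comps, function(c) c$fixed_points)),
                    fp$index)
  }
})

test_that("simulation follows the per-node option draw", {
  model <- two_option_ppds()
  # deterministic system: trajectory independent of seed
  det <- pds_from_strings(c("x2 + 1", "x1*x2"), 2L, 2L)
  t1 <- simulate_ppds(det, c(0, 1), steps = 5, seed = 1)
  t2 <- simulate_ppds(det, c(0, 1), steps = 5, seed = 99)
  expect_identical(t1, t2)
  expect_equal(nrow(t1), 6L)
  # one-step empirical distribution matches the state-space edges
  sp <- build_state_space(model)
  start <- c(1, 0)
  si <- ppdsinfer:::state_index(matrix(start, 1), 2L)
  runs <- 4000L
  set.seed(52)
  nxt <- replicate(runs, paste(simulate_ppds(model, start, 1)[2, ],
                               collapse = ","))
  emp <- table(nxt) / runs
  sel <- sp$from == si
  lab <- apply(sp$states[sp$to[sel], , drop = FALSE], 1, paste, collapse = ",")
  for (k in seq_along(lab)) {
    q <- sp$prob[sel][k]
    expect_lt(abs(emp[[lab[k]]] - q), 3 * sqrt(q * (1 - q) / runs))
  }
})

test_that("state spaces export to DOT and GraphML", {
  sp <- build_state_space(two_option_ppds())
  dot <- tempfile(fileext = ".dot")
  gml <- tempfile(fileext = ".graphml")
  export_state_space(sp, dot, "dot")
  export_state_space(sp, gml, "graphml")
  expect_true(file.exists(dot) && file.size(dot) > 0)
  expect_true(any(grepl("graphml", readLines(gml))))
})
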