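# Stochastic dynamics of a PPDS: the probabilistic state space on GF(p)^n,
# fixed points with exact and Monte-Carlo stabilities, weakly connected
# components, and trajectory simulation under synchronous update.

# enumerate all p^n states as a matrix (row r = state index r-1 in base p,
# x1 the most significant digit)
all_states <- function(p, n) {
  idx <- 0:(p^n - 1L)
  m <- matrix(0L, length(idx), n)
  rem <- idx
  for (j in n:1) {
    m[, j] <- rem %% p
    rem <- rem %/% p
  }
  m
}

state_index <- function(states, p) {
  if (is.null(dim(states))) states <- matrix(states, nrow = 1L)
  n <- ncol(states)
  as.integer(states %*% p^((n - 1L):0)) + 1L
}

# per node: values of each option polynomial at all states; list of
# (nstates x n_options) matrices
option_values <- function(model, states) {
  lapply(seq_len(model$nvars), function(i) {
    vv <- vapply(model$nodes[[i]]$polys, function(f) gf_eval(f, states),
                 integer(nrow(states)))
    matrix(as.integer(vv), nrow = nrow(states))
  })
}

# normalise a deterministic minimal_pds into the ppds option structure
as_ppds <- function(model) {
  if (inherits(model, "ppds")) return(model)
  if (inherits(model, "minimal_pds")) {
    nodes <- lapply(model$coords, function(f) {
      list(polys = list(f), counts = 1L, total = 1L)
    })
    return(structure(list(nodes = nodes, p = model$p, nvars = model$nvars,
                          varnames = model$varnames,
                          provenance = list(s = 1L, n_models = 1L)),
                     class = "ppds"))
  }
  stop("expected a ppds or minimal_pds")
}

#' Build the stochastic state space of a PPDS
#'
#' Enumerates all p^n states; from each state x the chance of reaching y is
#' the product over nodes of the total probability mass on options whose
#' value at x equals y_i. The edge set is exactly the union of the edge sets
#' of all deterministic systems obtainable by per-node option choices, and
#' outgoing probabilities from each state sum to 1.
#'
#' @param model A \code{ppds} (or deterministic \code{minimal_pds}).
#' @param cap Refuse to enumerate more than this many states (default 2^20);
#'   use \code{\link{simulate_ppds}} beyond that.
#' @return Object of class \code{state_space}: edge list (\code{from},
#'   \code{to} as 1-based state indices, \code{prob}), the state matrix, and
#'   per-state-and-node value distributions.
#' @export
build_state_space <- function(model, cap = 2^20) {
  model <- as_ppds(model)
  p <- model$p; n <- model$nvars
  nstates <- p^n
  if (nstates > cap) {
    stop("state space has ", nstates, " > cap = ", cap,
         " states; raise cap or use simulate_ppds()")
  }
  states <- all_states(p, n)
  vals <- option_values(model, states)
  totals <- vapply(model$nodes, function(nd) nd$total, numeric(1))
  from <- integer(0); to <- integer(0); prob <- numeric(0)
  # per-state distributions over next-state coordinate values
  for (r in seq_len(nstates)) {
    dists <- vector("list", n)
    for (i in seq_len(n)) {
      v <- vals[[i]][r, ]
      cnt <- rowsum(as.numeric(model$nodes[[i]]$counts), group = v)
      dists[[i]] <- list(values = as.integer(rownames(cnt)),
                         mass = unname(cnt[, 1L]) / totals[i])
    }
    sizes <- vapply(dists, function(d) length(d$values), integer(1))
    combos <- as.matrix(expand.grid(lapply(sizes, seq_len)))
    ys <- matrix(0L, nrow(combos), n)
    pr <- rep(1, nrow(combos))
    for (i in seq_len(n)) {
      ys[, i] <- dists[[i]]$values[combos[, i]]
      pr <- pr * dists[[i]]$mass[combos[, i]]
    }
    from <- c(from, rep(r, nrow(combos)))
    to <- c(to, state_index(ys, p))
    prob <- c(prob, pr)
  }
  structure(list(from = from, to = to, prob = prob, states = states,
                 p = p, nvars = n, varnames = model$varnames, model = model),
            class = "state_space")
}

#' @export
print.state_space <- function(x, ...) {
  cat("stochastic state space: ", nrow(x$states), " states, ",
      length(x$from), " edges over GF(", x$p, ")^", x$nvars, "\n", sep = "")
  invisible(x)
}

space_igraph <- function(space) {
  g <- igraph::graph_from_edgelist(cbind(space$from, space$to),
                                   directed = TRUE)
  g <- igraph::add_vertices(g, max(0L, nrow(space$states) -
                                     igraph::vcount(g)))
  igraph::E(g)$p <- space$prob
  igraph::V(g)$label <- apply(space$states, 1L, paste, collapse = "")
  g
}

#' Fixed points of a PPDS with exact stabilities
#'
#' A state is a fixed point (steady state) when it has positive probability
#' of mapping to itself in one synchronous update; its stability is that
#' probability, \eqn{\prod_i \sum_{j: f_{ij}(x) = x_i} p_{ij}}, computed
#' exactly from the option counts. States with stability 1 are absorbing.
#'
#' @param model A \code{ppds} (or \code{minimal_pds}).
#' @param cap State-enumeration cap as in \code{\link{build_state_space}}.
#' @return Data frame with one row per fixed point: the state (as a
#'   comma-separated label and index), exact stability, and whether it is
#'   absorbing; the state matrix is attached as attribute \code{"states"}.
#' @export
fixed_points <- function(model, cap = 2^20) {
  model <- as_ppds(model)
  p <- model$p; n <- model$nvars
  if (p^n > cap) stop("too many states; raise cap")
  states <- all_states(p, n)
  vals <- option_values(model, states)
  stab <- rep(1, nrow(states))
  for (i in seq_len(n)) {
    hit <- vals[[i]] == states[, i]
    mass <- as.numeric(hit %*% model$nodes[[i]]$counts) / model$nodes[[i]]$total
    stab <- stab * mass
  }
  fp <- which(stab > 0)
  res <- data.frame(
    state = vapply(fp, function(r) paste(states[r, ], collapse = ","),
                   character(1)),
    index = fp,
    stability = stab[fp],
    absorbing = stab[fp] == 1,
    stringsAsFactors = FALSE
  )
  attr(res, "states") <- states[fp, , drop = FALSE]
  res
}

#' Monte-Carlo stability of a state
#'
#' Estimates the probability that one synchronous stochastic update leaves
#' \code{state} unchanged: per run, an option is drawn per node with its
#' model probability, and the run counts as fixed when every node reproduces
#' its value. Converges to the exact stability of
#' \code{\link{fixed_points}}.
#'
#' @param model A \code{ppds}.
#' @param state Integer state vector.
#' @param runs Number of simulation runs.
#' @param seed Optional integer seed.
#' @return Proportion of runs in which the state stayed fixed.
#' @export
estimate_stability_mc <- function(model, state, runs = 10000L, seed = NULL) {
  model <- as_ppds(model)
  if (runs < 1L) stop("runs must be >= 1")
  if (!is.null(seed)) set.seed(as.integer(seed))
  state <- as.integer(state)
  fixed <- rep(TRUE, runs)
  for (i in seq_len(model$nvars)) {
    nd <- model$nodes[[i]]
    vi <- vapply(nd$polys, function(f) gf_eval(f, state), integer(1))
    pick <- sample.int(length(nd$polys), runs, replace = TRUE,
                       prob = nd$counts / nd$total)
    fixed <- fixed & (vi[pick] == state[i])
  }
  mean(fixed)
}

#' Weakly connected components of a state space
#'
#' Components of the transition graph with edge direction ignored; under a
#' PPDS inferred from trajectory data these are the basins the dynamics
#' decompose into, and each is annotated with the fixed points it contains.
#'
#' @param space A \code{state_space}.
#' @return List of components, largest first; each has \code{states}
#'   (indices), \code{size}, and \code{fixed_points} (indices of contained
#'   fixed points). Sizes sum to p^n.
#' @export
state_components <- function(space) {
  g <- space_igraph(space)
  comp <- igraph::components(g, mode = "weak")
  fp <- fixed_points(space$model)
  out <- lapply(seq_len(comp$no), function(k) {
    members <- which(comp$membership == k)
    list(states = members, size = length(members),
         fixed_points = intersect(fp$index, members))
  })
  out[order(-vapply(out, function(c) c$size, numeric(1)))]
}

#' Simulate a PPDS trajectory
#'
#' Synchronous stochastic update: at each step and for each node an option
#' is drawn independently with its model probability and applied to the
#' current state.
#'
#' @param model A \code{ppds} (or deterministic \code{minimal_pds}).
#' @param start Integer start state.
#' @param steps Number of update steps (>= 0).
#' @param seed Optional integer seed.
#' @return Integer matrix of steps + 1 rows: the visited states.
#' @export
simulate_ppds <- function(model, start, steps, seed = NULL) {
  model <- as_ppds(model)
  if (steps < 0L) stop("steps must be >= 0")
  if (!is.null(seed)) set.seed(as.integer(seed))
  n <- model$nvars
  traj <- matrix(0L, steps + 1L, n)
  cur <- as.integer(start)
  if (length(cur) != n) stop("start state has wrong length")
  traj[1L, ] <- cur
  for (t in seq_len(steps)) {
    nxt <- integer(n)
    for (i in seq_len(n)) {
      nd <- model$nodes[[i]]
      j <- if (length(nd$polys) == 1L) 1L else {
        sample.int(length(nd$polys), 1L, prob = nd$counts / nd$total)
      }
      nxt[i] <- gf_eval(nd$polys[[j]], cur)
    }
    traj[t + 1L, ] <- nxt
    cur <- nxt
  }
  traj
}

#' Export a state space to DOT or GraphML
#'
#' Writes the transition graph with edge attribute \code{p} (probability)
#' and vertex labels giving the state coordinates.
#'
#' @param space A \code{state_space}.
#' @param path Output path.
#' @param format \code{"dot"} or \code{"graphml"}.
#' @return \code{path}, invisibly.
#' @export
export_state_space <- function(space, path, format = c("dot", "graphml")) {
  format <- match.arg(format)
  g <- space_igraph(space)
  igraph::write_graph(g, path, format = format)
  invisible(path)
}
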