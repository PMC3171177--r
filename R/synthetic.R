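# Synthetic transition data: iterate a known (possibly stochastic)
# polynomial system with optional state-flip observation noise, emulating
# short discretized expression time courses; plus a generic per-variable
# quantile discretizer for real-valued tables.

#' Generate synthetic transition data from a model
#'
#' Iterates the model from each start state for \code{length} synchronous
#' steps and records the consecutive pairs. With \code{noise_rate > 0} each
#' recorded coordinate is independently replaced, with that probability, by
#' a uniformly chosen different field value - emulating discretization or
#' measurement noise. Noisy duplicated starts can therefore produce pairs
#' that no deterministic update function fits; loading such data through
#' \code{\link{transition_data}} raises its consistency error unless
#' majority resolution is requested, which is the designed failure mode.
#'
#' @param model A \code{ppds} or \code{minimal_pds} to iterate.
#' @param start_states Integer matrix of start states (rows), or a single
#'   state vector.
#' @param length Number of update steps recorded per series.
#' @param noise_rate Per-coordinate flip probability in [0, 1).
#' @param seed Optional integer seed.
#' @return A \code{transition_data} of the recorded (possibly noisy) pairs.
#'   With a deterministic model and \code{noise_rate = 0} the data are
#'   exactly consistent with the model.
#' @export
generate_synthetic <- function(model, start_states, length = 1L,
                               noise_rate = 0, seed = NULL) {
  model <- as_ppds(model)
  if (noise_rate < 0 || noise_rate >= 1) stop("noise_rate must lie in [0, 1)")
  if (length < 1L) stop("length must be >= 1")
  if (!is.null(seed)) set.seed(as.integer(seed))
  if (is.null(dim(start_states))) {
    start_states <- matrix(as.integer(start_states), nrow = 1L)
  }
  p <- model$p; n <- model$nvars
  ins <- list(); outs <- list()
  flip <- function(row) {
    hit <- stats::runif(n) < noise_rate
    if (any(hit)) {
      # uniform over the p-1 other values
      row[hit] <- (row[hit] + sample.int(p - 1L, sum(hit), replace = TRUE)) %% p
    }
    row
  }
  for (r in seq_len(nrow(start_states))) {
    traj <- simulate_ppds(model, start_states[r, ], steps = length)
    obs <- t(apply(traj, 1L, flip))
    ins[[r]] <- obs[-nrow(obs), , drop = FALSE]
    outs[[r]] <- obs[-1L, , drop = FALSE]
  }
  transition_data(do.call(rbind, ins), do.call(rbind, outs), p,
                  varnames = model$varnames)
}

#' Quantile discretization of a real-valued table
#'
#' Per-variable rank-based binning into p levels \{0, ..., p-1\} with counts
#' as balanced as the data allow: value with rank r (1-based, ties sharing
#' their minimum rank) gets level floor(p * (r - 1) / N). The map is
#' monotone, and invariant under monotone transforms of a column. A constant
#' column discretizes to all zeros with a warning.
#'
#' @param x Numeric matrix or data frame, one column per variable, one row
#'   per observation; all values finite.
#' @param p Number of levels (>= 2).
#' @return Integer matrix of levels with the input's dimnames.
#' @export
discretize <- function(x, p) {
  p <- as.integer(p)
  if (p < 2L) stop("need at least 2 levels")
  x <- as.matrix(x)
  if (!all(is.finite(x))) stop("values must be finite")
  out <- matrix(0L, nrow(x), ncol(x), dimnames = dimnames(x))
  for (j in seq_len(ncol(x))) {
    col <- x[, j]
    if (length(unique(col)) == 1L) {
      warning("column ", j, " is constant; discretized to all zeros")
      next
    }
    r <- rank(col, ties.method = "min")
    out[, j] <- as.integer(floor(p * (r - 1) / length(col)))
  }
  out
}
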