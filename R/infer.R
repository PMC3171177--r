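# PPDS inference: sample weight vectors uniformly (a box-uniform proxy for
# uniform sampling of the Groebner fan), group samples by the minimal model
# they produce, estimate relative cone volumes by sample frequency, and merge
# the per-cone models into one probabilistic polynomial dynamical system.

#' Sample size for cone-volume estimation
#'
#' Smallest number of sampled orderings s such that a normal-approximation
#' confidence interval for a proportion, at the worst-case proportion 1/2,
#' has half-width at most \code{margin}:
#' \eqn{s \ge z^2_{(1+conf)/2} \cdot 0.25 / margin^2}.
#'
#' @param margin Desired half-width of the interval, in (0, 1).
#' @param confidence Confidence level, in (0, 1).
#' @return Integer sample size (at least 1).
#' @examples
#' required_sample_size(0.05, 0.95)  # 385
#' @export
required_sample_size <- function(margin, confidence) {
  if (!is.finite(margin) || margin <= 0 || margin >= 1) {
    stop("margin must lie strictly between 0 and 1")
  }
  if (!is.finite(confidence) || confidence <= 0 || confidence >= 1) {
    stop("confidence must lie strictly between 0 and 1")
  }
  z <- stats::qnorm((1 + confidence) / 2)
  max(1L, as.integer(ceiling(z^2 * 0.25 / margin^2)))
}

#' Sample weight vectors
#'
#' Draws s weight vectors with entries independent and uniform on the
#' integer box \{0, ..., B\}^n. Groebner cones are scale-invariant polyhedral
#' cones, so the frequency with which the box hits each cone approximates the
#' cone's relative volume.
#'
#' @param n Number of variables.
#' @param s Number of vectors.
#' @param B Box bound (entries in 0..B).
#' @param seed Optional integer seed for reproducibility.
#' @return An s x n integer matrix, one weight vector per row.
#' @export
sample_weight_vectors <- function(n, s, B = 100L, seed = NULL) {
  if (s < 1L || B < 1L) stop("s and B must be at least 1")
  if (!is.null(seed)) set.seed(as.integer(seed))
  matrix(sample.int(B + 1L, size = s * n, replace = TRUE) - 1L,
         nrow = s, ncol = n)
}

#' Map sampled orderings to minimal models (cone-volume estimate)
#'
#' Computes the minimal model for each sampled weight vector and tallies how
#' often each distinct model arises. The relative frequency of a model
#' estimates the relative volume of its Groebner cone, which is the
#' probability weight the assembled PPDS assigns to it.
#'
#' @param data A \code{\link{transition_data}}.
#' @param samples Matrix of weight vectors (rows), e.g. from
#'   \code{\link{sample_weight_vectors}}.
#' @return Object of class \code{cone_sample_batch}: distinct models, their
#'   counts, the per-sample model assignment, and the total s.
#' @export
estimate_cone_volumes <- function(data, samples) {
  if (is.null(dim(samples))) samples <- matrix(samples, nrow = 1L)
  if (ncol(samples) != data$nvars) stop("weight vectors must have length nvars")
  models <- list()
  keys <- character(0)
  counts <- integer(0)
  assignment <- integer(nrow(samples))
  for (k in seq_len(nrow(samples))) {
    ord <- weight_ordering(samples[k, ])
    mod <- minimal_model(data, ord)
    key <- pds_key(mod)
    idx <- match(key, keys)
    if (is.na(idx)) {
      models[[length(models) + 1L]] <- mod
      keys <- c(keys, key)
      counts <- c(counts, 1L)
      idx <- length(models)
    } else {
      counts[idx] <- counts[idx] + 1L
    }
    assignment[k] <- idx
  }
  structure(list(models = models, keys = keys, counts = counts,
                 assignment = assignment, samples = samples,
                 s = nrow(samples), data = data),
            class = "cone_sample_batch")
}

# continue tallying an existing batch over additional weight vectors
extend_batch <- function(batch, extra) {
  data <- batch$data
  for (k in seq_len(nrow(extra))) {
    ord <- weight_ordering(extra[k, ])
    mod <- minimal_model(data, ord)
    key <- pds_key(mod)
    idx <- match(key, batch$keys)
    if (is.na(idx)) {
      batch$models[[length(batch$models) + 1L]] <- mod
      batch$keys <- c(batch$keys, key)
      batch$counts <- c(batch$counts, 1L)
      idx <- length(batch$models)
    } else {
      batch$counts[idx] <- batch$counts[idx] + 1L
    }
    batch$assignment <- c(batch$assignment, idx)
  }
  batch$samples <- rbind(batch$samples, extra)
  batch$s <- nrow(batch$samples)
  batch
}

#' @export
print.cone_sample_batch <- function(x, ...) {
  cat("cone samples: s = ", x$s, ", distinct minimal models = ",
      length(x$models), "\n", sep = "")
  for (i in order(-x$counts)) {
    cat(sprintf("  model %d: %d/%d (%.3f)\n", i, x$counts[i], x$s,
                x$counts[i] / x$s))
  }
  invisible(x)
}

#' Assemble a PPDS from cone samples
#'
#' Collects, per node, the coordinate polynomial of each distinct minimal
#' model with that model's estimated cone volume; equal polynomials are
#' merged by adding their probabilities. Probabilities are kept as exact
#' counts over the common total, so each node's options sum to exactly 1.
#'
#' @param batch A \code{cone_sample_batch}.
#' @return Object of class \code{ppds}: per node a list of options
#'   \code{(poly, count, prob)}, the field, variable names and provenance.
#' @export
assemble_ppds <- function(batch) {
  if (length(batch$models) == 0L) stop("empty sample batch")
  n <- batch$models[[1L]]$nvars
  p <- batch$models[[1L]]$p
  nodes <- vector("list", n)
  for (i in seq_len(n)) {
    keys <- character(0); polys <- list(); cnt <- integer(0)
    for (m in seq_along(batch$models)) {
      f <- batch$models[[m]]$coords[[i]]
      key <- poly_key(f)
      idx <- match(key, keys)
      if (is.na(idx)) {
        keys <- c(keys, key)
        polys[[length(polys) + 1L]] <- f
        cnt <- c(cnt, batch$counts[m])
      } else {
        cnt[idx] <- cnt[idx] + batch$counts[m]
      }
    }
    o <- order(-cnt)
    nodes[[i]] <- list(polys = polys[o], counts = cnt[o], total = batch$s)
  }
  structure(list(nodes = nodes, p = p, nvars = n,
                 varnames = batch$models[[1L]]$varnames,
                 provenance = list(s = batch$s,
                                   n_models = length(batch$models))),
            class = "ppds")
}

#' @export
print.ppds <- function(x, ...) {
  cat("PPDS over GF(", x$p, "), ", x$nvars, " nodes\n", sep = "")
  for (i in seq_len(x$nvars)) {
    nd <- x$nodes[[i]]
    cat("  f_", i, " (", x$varnames[i], "):\n", sep = "")
    for (j in seq_along(nd$polys)) {
      cat(sprintf("    %s   [%d/%d = %.3f]\n",
                  poly_format(nd$polys[[j]], x$varnames),
                  nd$counts[j], nd$total, nd$counts[j] / nd$total))
    }
  }
  invisible(x)
}

#' Most probable deterministic representative of a PPDS
#'
#' Selects, per node, the option with the largest estimated cone volume
#' (ties broken by the stored order, i.e. first encountered). When the
#' Groebner fan of the data is highly fragmented the full stochastic state
#' space is densely connected and uninformative; the representative system
#' summarises the dominant dynamics as a functional graph whose components
#' each end in an attractor, which is how basin and steady-state structure
#' is usually read off.
#'
#' @param model A \code{ppds}.
#' @return A deterministic \code{minimal_pds}-like system (coordinates =
#'   per-node modal options).
#' @export
representative_pds <- function(model) {
  model <- as_ppds(model)
  coords <- lapply(model$nodes, function(nd) nd$polys[[which.max(nd$counts)]])
  structure(list(coords = coords, ordering = NULL, gb = NULL, p = model$p,
                 nvars = model$nvars, varnames = model$varnames),
            class = "minimal_pds")
}

#' Per-node option probabilities
#'
#' @param model A \code{ppds}.
#' @param i Node index.
#' @return Numeric vector of option probabilities (counts / total).
#' @export
node_probs <- function(model, i) {
  nd <- model$nodes[[i]]
  nd$counts / nd$total
}

#' Infer a probabilistic polynomial dynamical system from transitions
#'
#' Full pipeline: sample weight-vector monomial orderings uniformly from an
#' integer box, compute the minimal fitting model for each, estimate relative
#' Groebner cone volumes by sample frequency, and merge everything into one
#' PPDS whose per-node option probabilities are those volumes.
#'
#' @param data A \code{\link{transition_data}}.
#' @param s Number of sampled orderings; default from
#'   \code{\link{required_sample_size}(margin, confidence)}.
#' @param margin,confidence Proportion-test parameters used when \code{s} is
#'   not given (defaults 0.05 and 0.95, giving s = 385).
#' @param B Sampling box bound (entries of omega in 0..B), default 100.
#' @param seed Integer seed for the weight-vector draw.
#' @param mode \code{"fixed"} draws exactly s vectors; \code{"saturate"}
#'   keeps drawing until no new distinct model has appeared for
#'   \code{saturation_window} consecutive draws (at least s draws total, at
#'   most \code{cap}).
#' @param saturation_window Consecutive no-new-model draws required to stop
#'   in saturate mode.
#' @param cap Hard limit on draws in saturate mode; exceeding it flags the
#'   result and warns.
#' @return A \code{ppds} with provenance (seed, s, B, mode, number of
#'   distinct models).
#' @examples
#' series <- rbind(c(2, 1, 0), c(1, 2, 0), c(2, 1, 1), c(0, 0, 1))
#' data <- series_to_transitions(series, p = 3)
#' model <- infer(data, seed = 1, mode = "saturate", s = 200)
#' model
#' @export
infer <- function(data, s = NULL, margin = 0.05, confidence = 0.95,
                  B = 100L, seed = NULL, mode = c("fixed", "saturate"),
                  saturation_window = 500L, cap = 10000L) {
  mode <- match.arg(mode)
  if (is.null(s)) s <- required_sample_size(margin, confidence)
  if (!is.null(seed)) set.seed(as.integer(seed))
  flagged <- FALSE
  samples <- sample_weight_vectors(data$nvars, s, B)
  batch <- estimate_cone_volumes(data, samples)
  if (mode == "saturate") {
    # keep drawing until no new distinct model for saturation_window draws
    last_new <- max(which(!duplicated(batch$assignment)))
    drawn <- s
    while (drawn - last_new < saturation_window && drawn < cap) {
      add <- min(saturation_window, cap - drawn)
      extra <- sample_weight_vectors(data$nvars, add, B)
      batch <- extend_batch(batch, extra)
      drawn <- drawn + add
      last_new <- max(which(!duplicated(batch$assignment)))
    }
    if (drawn - last_new < saturation_window) {
      warning("saturation cap reached before the model set stabilised; ",
              "result may be missing rare models")
      flagged <- TRUE
    }
  }
  model <- assemble_ppds(batch)
  model$provenance <- c(model$provenance,
                        list(seed = seed, B = B, mode = mode,
                             saturated = !flagged))
  model$batch <- batch
  model
}
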