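# Weighted dependency graph of a PPDS and probability-weighted confusion
# scores against a reference wiring.

#' Weighted dependency graph
#'
#' Entry W[i, j] is the strength of dependency of node i on node j: the
#' summed probabilities of node i's options whose canonical form contains
#' x_j in some term. A strength of 1 means every fitting minimal model uses
#' x_j to update x_i; fractional strengths reflect the share of the Groebner
#' fan whose models do.
#'
#' @param model A \code{ppds} (or deterministic \code{minimal_pds}).
#' @return An n x n numeric matrix with entries in [0, 1], rows = targets,
#'   columns = regulators, dimnames = variable names.
#' @export
dependency_graph <- function(model) {
  model <- as_ppds(model)
  n <- model$nvars
  W <- matrix(0, n, n, dimnames = list(model$varnames, model$varnames))
  for (i in seq_len(n)) {
    nd <- model$nodes[[i]]
    cnt <- numeric(n)   # integer option counts per regulator, summed exactly
    for (k in seq_along(nd$polys)) {
      sup <- poly_support(nd$polys[[k]])
      cnt[sup] <- cnt[sup] + nd$counts[k]
    }
    W[i, ] <- cnt / nd$total
  }
  W
}

#' Score a weighted dependency graph against a reference wiring
#'
#' Probability-weighted confusion counts: each true edge contributes its
#' predicted strength W to TP and 1 - W to FN; each true non-edge
#' contributes W to FP and 1 - W to TN. With a binary W these reduce to the
#' classical integer counts. Ratios follow the standard definitions
#' PPV = TP/(TP+FP), Se = TP/(TP+FN), Sp = TN/(TN+FP); a 0/0 ratio is
#' reported as NaN with a warning.
#'
#' @param pred Numeric n x n matrix of predicted strengths in [0, 1], e.g.
#'   from \code{\link{dependency_graph}}.
#' @param truth Binary n x n adjacency matrix of the reference wiring
#'   (truth[i, j] = 1 when node i depends on node j).
#' @param include_diagonal Include self-dependencies in the counts
#'   (default TRUE).
#' @return Object of class \code{score_report} with elements TP, FP, TN, FN,
#'   PPV, Se, Sp and the diagonal flag.
#' @export
score_against_truth <- function(pred, truth, include_diagonal = TRUE) {
  pred <- as.matrix(pred); truth <- as.matrix(truth)
  if (!all(dim(pred) == dim(truth))) stop("dimension mismatch")
  if (any(pred < 0 | pred > 1)) stop("predicted strengths must lie in [0, 1]")
  if (!all(truth %in% c(0, 1))) stop("truth must be a 0/1 adjacency matrix")
  mask <- matrix(TRUE, nrow(pred), ncol(pred))
  if (!include_diagonal) diag(mask) <- FALSE
  e <- truth == 1 & mask
  ne <- truth == 0 & mask
  TP <- sum(pred[e]); FN <- sum(1 - pred[e])
  FP <- sum(pred[ne]); TN <- sum(1 - pred[ne])
  ratio <- function(num, den, name) {
    if (den == 0) {
      warning(name, " undefined (0/0)")
      return(NaN)
    }
    num / den
  }
  structure(list(TP = TP, FP = FP, TN = TN, FN = FN,
                 PPV = ratio(TP, TP + FP, "PPV"),
                 Se = ratio(TP, TP + FN, "Se"),
                 Sp = ratio(TN, TN + FP, "Sp"),
                 include_diagonal = include_diagonal),
            class = "score_report")
}

#' @export
print.score_report <- function(x, ...) {
  cat(sprintf("TP = %.3f  FP = %.3f  TN = %.3f  FN = %.3f%s\n",
              x$TP, x$FP, x$TN, x$FN,
              if (x$include_diagonal) "" else "  (diagonal excluded)"))
  cat(sprintf("PPV = %.3f  Se = %.3f  Sp = %.3f\n", x$PPV, x$Se, x$Sp))
  invisible(x)
}

#' Read a reference adjacency matrix from CSV
#'
#' Expects a header of variable names and one 0/1 row per node (rows =
#' targets, columns = regulators).
#'
#' @param path CSV file path.
#' @return Binary integer matrix with dimnames.
#' @export
read_truth_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  m <- as.matrix(df)
  if (!all(m %in% c(0, 1))) stop("adjacency entries must be 0 or 1")
  storage.mode(m) <- "integer"
  rownames(m) <- colnames(m)
  m
}
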