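# JSON serialisation of inferred PPDS models. Probabilities are written both
# as exact rational strings ("count/total") and rounded decimals so that the
# document round-trips losslessly.

MODEL_SCHEMA <- "ppdsinfer-model/1"

#' Write a PPDS model document (JSON)
#'
#' @param model A \code{ppds}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_model <- function(model, path) {
  model <- as_ppds(model)
  nodes <- lapply(seq_len(model$nvars), function(i) {
    nd <- model$nodes[[i]]
    lapply(seq_along(nd$polys), function(k) {
      list(polynomial = poly_format(nd$polys[[k]], model$varnames),
           probability = paste0(nd$counts[k], "/", nd$total),
           probability_decimal = nd$counts[k] / nd$total)
    })
  })
  doc <- list(schema = MODEL_SCHEMA,
              field = model$p,
              variables = as.list(model$varnames),
              nodes = nodes,
              provenance = model$provenance[!vapply(model$provenance,
                                                    is.null, logical(1))])
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read a PPDS model document (JSON)
#'
#' @param path Path to a document written by \code{\link{write_model}}.
#' @return A \code{ppds}; parse(serialize(x)) equals x on canonical forms.
#' @export
read_model <- function(path) {
  doc <- jsonlite::read_json(path)
  if (is.null(doc$schema) || doc$schema != MODEL_SCHEMA) {
    stop("unrecognised model document schema")
  }
  p <- as.integer(doc$field)
  varnames <- unlist(doc$variables)
  n <- length(varnames)
  nodes <- lapply(doc$nodes, function(opts) {
    counts <- integer(0); totals <- integer(0); polys <- list()
    for (o in opts) {
      frac <- strsplit(o$probability, "/", fixed = TRUE)[[1L]]
      counts <- c(counts, as.integer(frac[1L]))
      totals <- c(totals, as.integer(frac[2L]))
      polys[[length(polys) + 1L]] <-
        poly_parse(o$polynomial, p, n, varnames = varnames)
    }
    if (length(unique(totals)) != 1L) stop("inconsistent probability totals")
    if (sum(counts) != totals[1L]) {
      stop("node probabilities do not sum to 1")
    }
    list(polys = polys, counts = counts, total = totals[1L])
  })
  structure(list(nodes = nodes, p = p, nvars = n, varnames = varnames,
                 provenance = doc$provenance),
            class = "ppds")
}
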