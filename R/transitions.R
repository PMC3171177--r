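# Observed state transitions: the (input state -> output state) pairs that
# the inference consumes. Both one-step pair tables and consecutive time
# series (possibly several independent series) are supported.

#' Transition data over GF(p)^n
#'
#' @param inputs,outputs Integer matrices of equal dimension, one state per
#'   row, entries in 0..p-1; row j records the observed transition
#'   inputs[j, ] -> outputs[j, ].
#' @param p Prime field order.
#' @param varnames Optional variable names (default x1..xn).
#' @param resolve How to handle two pairs sharing an input state but
#'   disagreeing on the output: \code{"error"} (default; a deterministic
#'   update function cannot fit such data) or \code{"majority"} (keep the
#'   most frequent output, ties broken by first occurrence).
#' @return Object of class \code{transition_data} with deduplicated,
#'   consistent pairs.
#' @export
transition_data <- function(inputs, outputs, p, varnames = NULL,
                            resolve = c("error", "majority")) {
  resolve <- match.arg(resolve)
  p <- as.integer(p)
  if (!is_prime(p)) stop("field order must be prime")
  if (is.null(dim(inputs))) inputs <- matrix(as.integer(inputs), nrow = 1L)
  if (is.null(dim(outputs))) outputs <- matrix(as.integer(outputs), nrow = 1L)
  inputs <- matrix(as.integer(as.matrix(inputs)), nrow = nrow(inputs))
  outputs <- matrix(as.integer(as.matrix(outputs)), nrow = nrow(outputs))
  if (!all(dim(inputs) == dim(outputs))) stop("inputs/outputs shape mismatch")
  n <- ncol(inputs)
  if (nrow(inputs) == 0L) stop("no transition pairs supplied")
  rng <- range(c(inputs, outputs))
  if (anyNA(c(inputs, outputs)) || rng[1L] < 0L || rng[2L] >= p) {
    stop("state entries must be integers in 0..", p - 1L)
  }
  if (is.null(varnames)) varnames <- paste0("x", seq_len(n))
  if (length(varnames) != n) stop("need one variable name per column")

  # deduplicate identical pairs silently
  pk <- paste(apply(inputs, 1L, paste, collapse = ","),
              apply(outputs, 1L, paste, collapse = ","), sep = "->")
  keep <- !duplicated(pk)
  inputs <- inputs[keep, , drop = FALSE]
  outputs <- outputs[keep, , drop = FALSE]

  ik <- apply(inputs, 1L, paste, collapse = ",")
  if (anyDuplicated(ik)) {
    bad <- unique(ik[duplicated(ik)])
    if (resolve == "error") {
      stop("inconsistent data: input state (", bad[1L],
           ") maps to more than one output state")
    }
    # majority vote per conflicting input (ties: first occurrence)
    pk <- paste(apply(inputs, 1L, paste, collapse = ","),
                apply(outputs, 1L, paste, collapse = ","), sep = "->")
    keep <- rep(TRUE, length(ik))
    for (b in bad) {
      idx <- which(ik == b)
      tab <- table(factor(pk[idx], levels = unique(pk[idx])))
      winner <- names(tab)[which.max(tab)]
      keep[idx] <- pk[idx] == winner
      keep[idx][duplicated(pk[idx][keep[idx]])] <- FALSE
    }
    inputs <- inputs[keep, , drop = FALSE]
    outputs <- outputs[keep, , drop = FALSE]
  }
  dimnames(inputs) <- NULL; dimnames(outputs) <- NULL
  structure(list(inputs = inputs, outputs = outputs, p = p, nvars = n,
                 varnames = varnames),
            class = "transition_data")
}

#' @export
print.transition_data <- function(x, ...) {
  cat("transition data: ", nrow(x$inputs), " pairs, ", x$nvars,
      " variables over GF(", x$p, ")\n", sep = "")
  invisible(x)
}

#' Convert consecutive time series to transition pairs
#'
#' @param series A single integer matrix (rows = consecutive time points) or
#'   a list of such matrices for independent series.
#' @inheritParams transition_data
#' @return A \code{transition_data}: row t -> row t+1 within each series.
#' @export
series_to_transitions <- function(series, p, varnames = NULL,
                                  resolve = c("error", "majority")) {
  if (!is.list(series)) series <- list(series)
  ins <- list(); outs <- list()
  for (s in series) {
    s <- as.matrix(s)
    if (nrow(s) < 2L) stop("a series needs at least two time points")
    ins[[length(ins) + 1L]] <- s[-nrow(s), , drop = FALSE]
    outs[[length(outs) + 1L]] <- s[-1L, , drop = FALSE]
  }
  transition_data(do.call(rbind, ins), do.call(rbind, outs), p,
                  varnames = varnames, resolve = match.arg(resolve))
}

#' Count steady (fixed) observed transitions
#'
#' @param data A \code{transition_data}.
#' @return Number of pairs whose input equals their output, i.e. observed
#'   steady states.
#' @export
count_steady_pairs <- function(data) {
  sum(rowSums(data$inputs != data$outputs) == 0L)
}

#' Read transition data from a delimited file
#'
#' Two layouts are accepted. \code{format = "pairs"}: a header plus one row
#' per transition with 2n value columns (input columns first, named with an
#' \code{_in} suffix, then output columns with \code{_out}). \code{format =
#' "series"}: a header plus one row per time point with n columns; blank
#' lines separate independent series, and consecutive rows within a series
#' become pairs.
#'
#' @param path File path (TSV or CSV; the separator is sniffed from the
#'   header line).
#' @param format \code{"pairs"} or \code{"series"}.
#' @param p Prime field order.
#' @param resolve Conflict handling, see \code{\link{transition_data}}.
#' @return A \code{transition_data}.
#' @export
read_transitions <- function(path, format = c("pairs", "series"), p,
                             resolve = c("error", "majority")) {
  format <- match.arg(format)
  resolve <- match.arg(resolve)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines)]
  if (length(lines) == 0L || all(trimws(lines) == "")) stop("empty file: ", path)
  sep <- if (grepl("\t", lines[[1L]])) "\t" else ","
  header <- strsplit(lines[[1L]], sep, fixed = TRUE)[[1L]]
  header <- trimws(header)
  body <- lines[-1L]

  parse_block <- function(blk, expect_cols) {
    rows <- lapply(seq_along(blk), function(i) {
      cells <- trimws(strsplit(blk[[i]], sep, fixed = TRUE)[[1L]])
      if (length(cells) != expect_cols) {
        stop("row ", i, ": expected ", expect_cols, " columns, got ",
             length(cells))
      }
      vals <- suppressWarnings(as.integer(cells))
      num <- suppressWarnings(as.numeric(cells))
      bad <- which(is.na(vals) | is.na(num) | vals != num)
      if (length(bad) > 0L) {
        stop("row ", i, ", column ", bad[1L], ": non-integer value '",
             cells[bad[1L]], "'")
      }
      if (any(vals < 0L | vals >= p)) {
        bad <- which(vals < 0L | vals >= p)[1L]
        stop("row ", i, ", column ", bad, ": value ", vals[bad],
             " outside 0..", p - 1L)
      }
      vals
    })
    do.call(rbind, rows)
  }

  if (format == "pairs") {
    if (length(header) %% 2L != 0L) stop("pairs format needs 2n columns")
    n <- length(header) %/% 2L
    varnames <- sub("_in$", "", header[seq_len(n)])
    body <- body[trimws(body) != ""]
    if (length(body) == 0L) stop("no transition rows in ", path)
    m <- parse_block(body, 2L * n)
    transition_data(m[, seq_len(n), drop = FALSE],
                    m[, n + seq_len(n), drop = FALSE],
                    p, varnames = varnames, resolve = resolve)
  } else {
    n <- length(header)
    varnames <- header
    # split body into series at blank lines
    blank <- trimws(body) == ""
    grp <- cumsum(blank)
    series <- list()
    for (g in unique(grp)) {
      blk <- body[grp == g & !blank]
      if (length(blk) == 0L) next
      series[[length(series) + 1L]] <- parse_block(blk, n)
    }
    if (length(series) == 0L) stop("no series rows in ", path)
    series_to_transitions(series, p, varnames = varnames, resolve = resolve)
  }
}

#' Write transition data as a pairs-format TSV
#'
#' @param data A \code{transition_data}.
#' @param path Output file path.
#' @return \code{path}, invisibly.
#' @export
write_transitions <- function(data, path) {
  header <- c(paste0(data$varnames, "_in"), paste0(data$varnames, "_out"))
  m <- cbind(data$inputs, data$outputs)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(header, collapse = "\t"), con)
  utils::write.table(m, con, sep = "\t", row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  invisible(path)
}
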