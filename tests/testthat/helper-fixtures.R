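# Shared fixtures and small oracles used across the test files.

# the 3-gene ternary example series and its transition pairs
ternary3_series <- rbind(c(2, 1, 0), c(1, 2, 0), c(2, 1, 1), c(0, 0, 1))
ternary3_data <- function() series_to_transitions(ternary3_series, p = 3)

ternary3_path <- function() {
  system.file("extdata", "ternary3_series.tsv", package = "ppdsinfer")
}
yeast_path <- function() {
  system.file("extdata", "yeast_cc_transitions_synthetic.tsv",
              package = "ppdsinfer")
}
yeast_wiring_path <- function() {
  system.file("extdata", "yeast_cc_wiring_synthetic.csv",
              package = "ppdsinfer")
}

# all canonical exponent vectors (entries 0..p-1) for n variables
all_canonical_exps <- function(p, n) {
  g <- as.matrix(expand.grid(rep(list(0:(p - 1L)), n)))[, n:1, drop = FALSE]
  dimnames(g) <- NULL
  matrix(as.integer(g), ncol = n)
}

# random canonical polynomial over GF(p) in n vars
random_poly <- function(p, n, density = 0.4) {
  exps <- all_canonical_exps(p, n)
  keep <- stats::runif(nrow(exps)) < density
  gf_poly(exps[keep, , drop = FALSE],
          sample(0:(p - 1L), sum(keep), replace = TRUE), p, n)
}

# random consistent transition data: sample distinct inputs, arbitrary outputs
random_consistent_data <- function(p, n, m) {
  states <- all_states_grid(p, n)
  idx <- sample.int(nrow(states), m)
  transition_data(states[idx, , drop = FALSE],
                  matrix(sample(0:(p - 1L), m * n, replace = TRUE), m, n),
                  p)
}

all_states_grid <- function(p, n) {
  g <- as.matrix(expand.grid(rep(list(0:(p - 1L)), n)))[, n:1, drop = FALSE]
  dimnames(g) <- NULL
  matrix(as.integer(g), ncol = n)
}

# deterministic PDS from explicit polynomial strings
pds_from_strings <- function(strs, p, n) {
  structure(list(coords = lapply(strs, poly_parse, p = p, nvars = n),
                 p = p, nvars = n, varnames = paste0("x", seq_len(n))),
            class = "minimal_pds")
}

# brute-force reference comparator for monomials (direct definition)
oracle_cmp <- function(a, b, omega) {
  wa <- sum(omega * a); wb <- sum(omega * b)
  if (wa != wb) return(sign(wa - wb))
  d <- a - b
  nz <- which(d != 0)
  if (length(nz) == 0) return(0)
  sign(d[nz[1]])
}
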