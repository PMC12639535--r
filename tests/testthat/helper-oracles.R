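# Independent brute-force oracles, deliberately written with explicit set
# arithmetic / loops so they share no code path with the implementation.

# NCR by explicit set enumeration over character gene sets.
ncr_oracle <- function(ref_calls, drug_calls) {
  genes <- names(ref_calls)
  A <- genes[ref_calls != 0]
  O <- character(0)
  for (g in genes) {
    b <- drug_calls[g]
    if (!is.na(b) && b != 0 && ref_calls[g] != 0) O <- c(O, g)
  }
  C <- O[vapply(O, function(g) ref_calls[g] == drug_calls[g], logical(1))]
  D <- setdiff(O, C)
  (length(C) - length(D)) / length(A)
}

# ES by walking the full running sum with an explicit loop, tracking the
# maximal positive and negative excursions separately (tie -> positive).
es_oracle <- function(ranked, members) {
  N <- length(ranked)
  m <- length(members)
  rs <- 0
  hi <- 0
  lo <- 0
  for (i in seq_len(N)) {
    rs <- rs + if (ranked[i] %in% members) 1 / m else -1 / (N - m)
    hi <- max(hi, rs)
    lo <- min(lo, rs)
  }
  if (hi >= -lo - 1e-9) hi else lo
}

# final value of the running sum (must be 0)
es_terminal_oracle <- function(ranked, members) {
  N <- length(ranked); m <- length(members)
  sum(ifelse(ranked %in% members, 1 / m, -1 / (N - m)))
}

# per-gene mode with tie -> 0, via explicit frequency tables
mode_oracle <- function(values) {
  tab <- table(factor(values, levels = c(-1, 0, 1)))
  mx <- max(tab)
  winners <- as.integer(names(tab)[tab == mx])
  if (length(winners) == 1) winners else 0L
}

# Jaccard by an explicit double loop over index sets
jaccard_oracle <- function(profiles) {
  n <- nrow(profiles)
  J <- matrix(NA_real_, n, n, dimnames = list(rownames(profiles), rownames(profiles)))
  for (i in seq_len(n)) {
    for (k in seq_len(n)) {
      si <- which(profiles[i, ] == 1)
      sk <- which(profiles[k, ] == 1)
      uni <- union(si, sk)
      J[i, k] <- if (length(uni) == 0) 1 else length(intersect(si, sk)) / length(uni)
    }
  }
  J
}

# random trinary profile over a gene universe
random_trinary <- function(genes, p_nonzero = 0.4) {
  v <- sample(c(-1L, 0L, 1L), length(genes), replace = TRUE,
              prob = c(p_nonzero / 2, 1 - p_nonzero, p_nonzero / 2))
  stats::setNames(v, genes)
}

# reference profile with prescribed up/down DEG call pattern
make_reference <- function(calls) {
  build_reference(data.frame(
    gene = names(calls),
    log2fc = ifelse(calls == 0, 0.1, 2 * calls),
    pval = ifelse(calls == 0, 0.9, 0.001)))
}

# tiny signature matrix fixture
tiny_matrix <- function() {
  vals <- matrix(c(1.5, -0.2, 0.8, -1.7, 2.2, 0.0),
                 nrow = 3,
                 dimnames = list(c("G1", "G2", "G3"), c("s1", "s2")))
  signature_matrix(vals, data.frame(
    signature_id = c("s1", "s2"), compound_id = c("drugA", "drugB"),
    cell_line = "MCF7", dose = "10 uM", time = "24 h", tas = c(0.55, 0.81)))
}
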