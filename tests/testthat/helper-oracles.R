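# Independent oracles used across the suite.

# Exhaustive local-alignment score via Biostrings (Smith-Waterman, affine
# gaps, same scoring convention as the scanner: a gap of length L costs
# open + L * extend).
sw_oracle_score <- function(a, b, match = 1, mismatch = -2,
                            gap_open = 5, gap_ext = 2) {
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(a), Biostrings::DNAString(b), type = "local",
    substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
      match = match, mismatch = mismatch, baseOnly = TRUE),
    gapOpening = gap_open, gapExtension = gap_ext)
  Biostrings::score(pa)
}

# Brute-force single-linkage connected components under an edge-to-edge
# distance threshold (quadratic all-pairs union-find).
brute_force_clusters <- function(start, end, distance) {
  n <- length(start)
  parent <- seq_len(n)
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i >= j) next
    gap <- max(start[i], start[j]) - min(end[i], end[j]) - 1
    if (gap <= distance) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[ri] <- rj
    }
  }
  vapply(seq_len(n), find, integer(1))
}

# Direct-formula Pearson chi-square for a 2x2 table (no correction):
# N (ad - bc)^2 / (r1 r2 c1 c2).
chisq_2x2_formula <- function(a, b, c_, d) {
  a <- as.numeric(a); b <- as.numeric(b); c_ <- as.numeric(c_); d <- as.numeric(d)
  N <- a + b + c_ + d
  N * (a * d - b * c_)^2 /
    ((a + b) * (c_ + d) * (a + c_) * (b + d))
}

# Direct-formula goodness-of-fit chi-square with size-proportional
# expectations.
chisq_gof_formula <- function(o1, o2, s1, s2) {
  tot <- o1 + o2
  e1 <- tot * s1 / (s1 + s2); e2 <- tot * s2 / (s1 + s2)
  (o1 - e1)^2 / e1 + (o2 - e2)^2 / e2
}

# Match annotated copies to planted truth: same family, >= 90% overlap of
# the truth interval. Returns per-truth-row index into copies (NA = missed).
match_truth <- function(copies, truth) {
  m <- rep(NA_integer_, nrow(truth))
  for (i in seq_len(nrow(truth))) {
    tr <- truth[i, ]
    same <- which(copies$arm == tr$arm & copies$family == tr$family)
    if (!length(same)) next
    ov <- pmin(copies$end[same], tr$end) - pmax(copies$start[same], tr$start) + 1
    best <- which.max(ov)
    if (ov[best] >= 0.9 * (tr$end - tr$start + 1)) m[i] <- same[best]
  }
  m
}

# Expected fragmentation class for a planted proviral copy.
truth_fragmentation <- function(n_indels, has_n_gap) {
  ifelse(n_indels >= 3, "highly-fragmented",
  ifelse(n_indels >= 1, "moderately-fragmented",
  ifelse(has_n_gap, "unknown", "complete")))
}
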