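# Shared fixtures, built once per test run.

fixture_env <- new.env(parent = emptyenv())

# A small family library reused by several files.
small_library <- function() {
  if (is.null(fixture_env$lib))
    fixture_env$lib <- build_family_library(2, ltr_len_range = c(200, 300),
                                            total_len_range = c(5000, 6000),
                                            seed = 3)
  fixture_env$lib
}

# A background sequence reused for planting copies.
background <- function(n = 60000) {
  key <- paste0("bg", n)
  if (is.null(fixture_env[[key]]))
    fixture_env[[key]] <- ltrscape:::random_sequence(n, 0.45)
  fixture_env[[key]]
}

# Plant a fragment into the background at a given site; returns the genome
# and the copy coordinates.
plant <- function(fragment, site = 30000, tsd = "", bg = background()) {
  g <- paste0(substr(bg, 1, site - 1), tsd, fragment, tsd,
              substr(bg, site, nchar(bg)))
  start <- site + nchar(tsd)
  list(genome = c(chr = g), start = start,
       end = start + nchar(fragment) - 1)
}

# Fabricate a gap-free local alignment against a consensus interval with a
# controlled number of mismatches (for rule tests that need exact identity).
fake_alignment <- function(cons, cstart, cend, n_mismatch = 0,
                           gstart = 1000) {
  seg <- substr(cons, cstart, cend)
  chars <- strsplit(seg, "")[[1]]
  if (n_mismatch > 0) {
    idx <- round(seq(1, length(chars), length.out = n_mismatch))
    for (p in idx) chars[p] <- setdiff(c("A", "C", "G", "T"), chars[p])[1]
  }
  g <- paste(chars, collapse = "")
  list(gstart = gstart, gend = gstart + nchar(g) - 1,
       qstart = cstart, qend = cend,
       cstart = cstart, cend = cend,
       score = nchar(g) - 3 * n_mismatch,
       g_aln = g, q_aln = seg,
       identity = 1 - n_mismatch / nchar(g), ncol = nchar(g))
}

fake_candidate <- function(family, alignments, strand = "+", arm = "chr") {
  list(family = family$name, lineage = family$lineage, strand = strand,
       arm = arm,
       gstart = min(vapply(alignments, `[[`, numeric(1), "gstart")),
       gend = max(vapply(alignments, `[[`, numeric(1), "gend")),
       score = sum(vapply(alignments, `[[`, numeric(1), "score")),
       alignments = alignments,
       covered_segments = character(0))
}

# The medium simulation shared by the annotation-accuracy and acceptance
# tests (one build per run: ~1 minute).
shared_sim_run <- function() {
  if (!is.null(fixture_env$run)) return(fixture_env$run)
  lib <- build_family_library(8, seed = 101)
  bps <- default_blueprints(2, 1500000, seed = 102)
  plans <- sample_insertion_plans(bps, lib, 200, seed = 103)
  sim <- synthesize_genome(bps, lib, plans, seed = 104)
  cands <- scan_genome(lib, sim$genome)
  copies <- annotate_copies(cands, lib, sim$genome)
  fixture_env$run <- list(lib = lib, sim = sim, cands = cands,
                          copies = copies,
                          match = match_truth(copies, sim$truth))
  fixture_env$run
}
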