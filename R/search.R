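#' Scanner parameters
#'
#' Scoring approximates contemporary BlastN defaults: match +1, mismatch -2,
#' gap open -5, gap extend -2 (a gap of length L costs open + L x extend),
#' word size 11, x-drop 20, minimum reported score 30. Alignments of the
#' same family and strand are chained into one candidate copy when the gap
#' on both the genome and the consensus axis is at most \code{chain_gap}.
#'
#' @param ... Overrides of the defaults.
#' @return Named list of parameters.
#' @export
scan_params <- function(...) {
  p <- list(k = 11L, match = 1L, mismatch = -2L, gap_open = -5L,
            gap_ext = -2L, x_drop = 20L, min_score = 30L,
            chain_gap = 3500L, chain_overlap = 50L)
  ov <- list(...)
  p[names(ov)] <- ov
  p
}

#' Build an exact k-mer index of a genome
#'
#' Forward-strand k-mers only; any k-mer containing an N (or other ambiguity
#' code) is not indexed.
#'
#' @param genome Named character vector of arm sequences.
#' @param k Word size (8-15).
#' @return Object of class \code{genome_index}.
#' @export
index_genome <- function(genome, k = 11L) {
  if (k < 8) stop("word size k must be >= 8")
  idx <- lapply(genome, cpp_build_index, k = as.integer(k))
  structure(list(arms = idx, k = as.integer(k),
                 lengths = vapply(genome, nchar, integer(1))),
            class = "genome_index")
}

#' Look up the positions of one k-mer in an indexed genome
#'
#' @param index A \code{genome_index}.
#' @param kmer Character string of length k.
#' @param arm Arm name (default: first arm).
#' @return Integer vector of 1-based start positions (empty if absent or if
#'   the k-mer contains N).
#' @export
index_lookup <- function(index, kmer, arm = NULL) {
  if (is.null(arm)) arm <- names(index$arms)[1]
  cpp_index_lookup(index$arms[[arm]], kmer)
}

#' Gapped x-drop extension of an exact seed match
#'
#' Extends in both directions from the seed; each direction stops when the
#' running score falls \code{x_drop} below its running maximum and is
#' trimmed back to its maximum-scoring point.
#'
#' @param genome_seq,query_seq The two sequences (character strings).
#' @param gpos,qpos 1-based start of the exact k-mer seed in each sequence.
#' @param params \code{\link{scan_params}}.
#' @return A local alignment: list with gstart/gend, qstart/qend (1-based
#'   inclusive), score, aligned rows \code{g_aln}/\code{q_aln}, identity and
#'   aligned column count.
#' @export
extend_seed <- function(genome_seq, query_seq, gpos, qpos, params = scan_params()) {
  r <- cpp_xdrop_extend(genome_seq, query_seq, as.integer(gpos), as.integer(qpos),
                        params$k, params$match, params$mismatch,
                        params$gap_open, params$gap_ext, params$x_drop)
  r$identity <- alignment_identity(r$g_aln, r$q_aln)
  r$ncol <- nchar(r$g_aln)
  r
}

# Scan one (arm, query) pair: seed, extend with coverage masking, return
# accepted local alignments. The seed loop runs in C++; identity and column
# counts are annotated here.
scan_pair <- function(arm_idx, arm_seq, query, params) {
  alns <- cpp_scan_pair(arm_idx, arm_seq, query,
                        params$match, params$mismatch,
                        params$gap_open, params$gap_ext,
                        params$x_drop, params$min_score)
  lapply(alns, function(r) {
    r$identity <- alignment_identity(r$g_aln, r$q_aln)
    r$ncol <- nchar(r$g_aln)
    r
  })
}

# Chain collinear alignments (query coordinates in the orientation scanned).
chain_alignments <- function(alns, params) {
  if (length(alns) == 0) return(list())
  ord <- order(vapply(alns, `[[`, numeric(1), "gstart"))
  alns <- alns[ord]
  chains <- list()
  for (a in alns) {
    placed <- FALSE
    if (length(chains) > 0) {
      for (ci in seq_along(chains)) {
        last <- chains[[ci]][[length(chains[[ci]])]]
        ggap <- a$gstart - last$gend - 1
        qgap <- a$qstart - last$qend - 1
        if (ggap >= -params$chain_overlap && ggap <= params$chain_gap &&
            qgap >= -params$chain_overlap && qgap <= params$chain_gap) {
          chains[[ci]][[length(chains[[ci]]) + 1]] <- a
          placed <- TRUE
          break
        }
      }
    }
    if (!placed) chains[[length(chains) + 1]] <- list(a)
  }
  chains
}

#' Scan a genome with a family consensus library
#'
#' Both strands are searched (by scanning with the reverse complement of
#' each consensus); same-family, same-strand, consensus-collinear local
#' alignments are chained into candidate copies when the genome and
#' consensus gaps are each at most \code{chain_gap}. Coordinates are always
#' reported on the forward genome strand, 1-based inclusive. Same-family
#' candidates mostly contained (>= 80%) in a stronger candidate (typically
#' LTR cross-matches of the same locus) are dropped.
#'
#' @param library \code{ltr_library}.
#' @param genome Named character vector of arm sequences.
#' @param params \code{\link{scan_params}}.
#' @param index Optional pre-built \code{\link{index_genome}} result.
#' @return List of candidate copies, class \code{ltr_candidates}. Each
#'   candidate has family, lineage, strand, arm, gstart, gend, score, the
#'   constituent alignments (with consensus-forward coordinates
#'   \code{cstart}/\code{cend}) and the covered consensus segments.
#' @export
scan_genome <- function(library, genome, params = scan_params(), index = NULL) {
  if (length(library) == 0) stop("library must be non-empty")
  if (length(genome) == 0 || all(nchar(genome) == 0)) return(structure(list(), class = "ltr_candidates"))
  if (is.null(index)) index <- index_genome(genome, params$k)
  out <- list()
  for (arm in names(genome)) {
    arm_seq <- genome[[arm]]
    arm_idx <- index$arms[[arm]]
    for (fam in library) {
      cons <- family_consensus(fam)
      Lc <- nchar(cons)
      seg <- family_segments(fam)
      for (strand in c("+", "-")) {
        query <- if (strand == "+") cons else rev_comp(cons)
        alns <- scan_pair(arm_idx, arm_seq, query, params)
        chains <- chain_alignments(alns, params)
        for (ch in chains) {
          # consensus-forward coordinates
          for (k in seq_along(ch)) {
            a <- ch[[k]]
            if (strand == "+") {
              a$cstart <- a$qstart; a$cend <- a$qend
            } else {
              a$cstart <- Lc - a$qend + 1; a$cend <- Lc - a$qstart + 1
            }
            ch[[k]] <- a
          }
          gstart <- min(vapply(ch, `[[`, numeric(1), "gstart"))
          gend <- max(vapply(ch, `[[`, numeric(1), "gend"))
          # segment is covered if any aligned consensus position falls in it
          covered <- seg$segment[vapply(seq_len(nrow(seg)), function(si) {
            any(vapply(ch, function(a)
              max(a$cstart, seg$start[si]) <= min(a$cend, seg$end[si]), logical(1)))
          }, logical(1))]
          out[[length(out) + 1]] <- list(
            family = fam$name, lineage = fam$lineage,
            strand = strand, arm = arm,
            gstart = gstart, gend = gend,
            score = sum(vapply(ch, `[[`, numeric(1), "score")),
            alignments = ch,
            covered_segments = covered)
        }
      }
    }
  }
  out <- drop_contained_candidates(out)
  structure(out, class = "ltr_candidates")
}

# Drop same-family candidates mostly contained in a stronger one (LTR
# cross-matches of one locus produce these).
drop_contained_candidates <- function(cands) {
  if (length(cands) <= 1) return(cands)
  keep <- rep(TRUE, length(cands))
  ord <- order(-vapply(cands, `[[`, numeric(1), "score"))
  for (i in seq_along(ord)) {
    a <- ord[i]
    if (!keep[a]) next
    for (j in seq_along(ord)) {
      if (j <= i) next
      b <- ord[j]
      if (!keep[b]) next
      ca <- cands[[a]]; cb <- cands[[b]]
      if (ca$arm != cb$arm || ca$family != cb$family) next
      ov <- min(ca$gend, cb$gend) - max(ca$gstart, cb$gstart) + 1
      if (ov > 0 && ov >= 0.8 * (cb$gend - cb$gstart + 1)) keep[b] <- FALSE
    }
  }
  cands[keep]
}
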