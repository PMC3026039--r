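#' Annotation thresholds
#'
#' The published classification rules: family assignment needs either a
#' contiguous 400 bp stretch of the internal (gag/pol) region at >= 90%
#' identity, or >= 90% identity over at least half the LTR length;
#' structural-variation events are indels >= 10 bp; a copy is "partial" when
#' its summed deletions exceed 3% of the consensus length; divergence needs
#' >= 50 comparable columns.
#'
#' @param ... Overrides of the defaults.
#' @return Named list of thresholds.
#' @export
annotation_thresholds <- function(...) {
  th <- list(
    family_pol_gag_min_span = 400L,
    family_min_identity = 0.90,
    family_ltr_min_fraction = 0.5,
    sv_min_indel = 10L,
    partial_del_fraction = 0.03,
    recent_identity = 0.99,
    old_divergence = 0.05,
    cluster_distance = 10000L,
    gene_flank = 1000L,
    min_internal_evidence = 30L,
    min_divergence_columns = 50L,
    unreliable_per_column = 0.4,
    dup_search_window = 500L,
    band_margin = 100L)
  ov <- list(...)
  th[names(ov)] <- ov
  th
}

# Column table of one local alignment: consensus-forward position, genome
# char, consensus char per column. For minus-strand candidates the aligned
# strings are against the reverse-complemented consensus; mapping q-space
# positions through Lc - q + 1 restores consensus-forward positions.
alignment_columns <- function(aln, strand, Lc) {
  g <- aln_chars(aln$g_aln); q <- aln_chars(aln$q_aln)
  qpos <- cumsum(q != "-") + aln$qstart - 1L
  qpos[q == "-"] <- NA
  cpos <- if (strand == "+") qpos else Lc - qpos + 1L
  data.frame(cpos = cpos, gchar = g, qchar = q, stringsAsFactors = FALSE)
}

#' Family-assignment rules for one candidate copy
#'
#' Rule 1: a contiguous stretch of >= 400 bp of the internal region aligned
#' at >= 90% identity. Rule 2: >= 90% identity over at least half of the
#' LTR length (either LTR). The satisfied rule is recorded.
#'
#' @param candidate One candidate from \code{\link{scan_genome}}.
#' @param family The \code{ltr_family} the candidate's alignments refer to.
#' @param th \code{\link{annotation_thresholds}}.
#' @return list(accepted, rule) where rule is 1, 2 or NA.
#' @export
assign_family <- function(candidate, family, th = annotation_thresholds()) {
  if (is.null(family$internal) || is.null(family$ltr5))
    stop("family model lacks LTR/internal segmentation")
  seg <- family_segments(family)
  Lc <- seg$end[3]
  internal <- c(seg$start[2], seg$end[2])
  ltr_len <- nchar(family$ltr5)

  # Rule 1: per-alignment maximal runs of consecutive covered internal
  # positions; each run is a contiguous stretch.
  for (aln in candidate$alignments) {
    cols <- alignment_columns(aln, candidate$strand, Lc)
    inside <- !is.na(cols$cpos) & cols$cpos >= internal[1] & cols$cpos <= internal[2]
    if (!any(inside)) next
    idx <- which(inside)
    pos <- cols$cpos[idx]
    runs <- split(idx, cumsum(c(1, abs(diff(pos)) != 1)))
    for (r in runs) {
      span <- abs(cols$cpos[r[length(r)]] - cols$cpos[r[1]]) + 1
      if (span >= th$family_pol_gag_min_span) {
        ident <- {
          gc <- cols$gchar[r]; qc <- cols$qchar[r]
          keep <- gc != "N" & qc != "N"
          sum(keep & gc == qc & gc %in% c("A", "C", "G", "T")) / sum(keep)
        }
        if (!is.nan(ident) && ident >= th$family_min_identity)
          return(list(accepted = TRUE, rule = 1L))
      }
    }
  }

  # Rule 2: aggregate coverage and identity per LTR segment.
  for (si in c(1L, 3L)) {
    cov_pos <- integer(0); match_n <- 0; col_n <- 0
    for (aln in candidate$alignments) {
      cols <- alignment_columns(aln, candidate$strand, Lc)
      inside <- !is.na(cols$cpos) & cols$cpos >= seg$start[si] & cols$cpos <= seg$end[si]
      if (!any(inside)) next
      gc <- cols$gchar[inside]; qc <- cols$qchar[inside]
      keep <- gc != "N" & qc != "N"
      match_n <- match_n + sum(keep & gc == qc & gc %in% c("A", "C", "G", "T"))
      col_n <- col_n + sum(keep)
      cov_pos <- union(cov_pos, cols$cpos[inside])
    }
    if (length(cov_pos) >= th$family_ltr_min_fraction * ltr_len &&
        col_n > 0 && match_n / col_n >= th$family_min_identity)
      return(list(accepted = TRUE, rule = 2L))
  }
  list(accepted = FALSE, rule = NA_integer_)
}

#' Classify the condition of a candidate copy
#'
#' Solo-LTR if all aligned consensus positions fall within the LTR segments;
#' proviral if there is internal-region identity (a minimum number of non-N
#' aligned internal columns guards against chance extension past the
#' LTR/internal junction); unknown when the evidence is LTR-only but
#' unsequenced-gap (N) tracks cover at least half of the genomic span where
#' the internal region would lie.
#'
#' @param candidate One candidate from \code{\link{scan_genome}}.
#' @param family The assigned \code{ltr_family}.
#' @param arm_seq The candidate's arm sequence (for N-track inspection).
#' @param th \code{\link{annotation_thresholds}}.
#' @return One of "proviral", "solo-LTR", "unknown".
#' @export
classify_condition <- function(candidate, family, arm_seq,
                               th = annotation_thresholds()) {
  seg <- family_segments(family)
  Lc <- seg$end[3]
  bases <- c("A", "C", "G", "T")
  internal_evid <- 0; internal_aligned <- 0; internal_n <- 0
  ltr5_g <- NULL; ltr3_g <- NULL
  for (aln in candidate$alignments) {
    cols <- alignment_columns(aln, candidate$strand, Lc)
    inside <- !is.na(cols$cpos) & cols$cpos >= seg$start[2] & cols$cpos <= seg$end[2]
    internal_evid <- internal_evid +
      sum(inside & cols$gchar %in% bases & cols$qchar %in% bases)
    internal_aligned <- internal_aligned + sum(inside)
    internal_n <- internal_n + sum(inside & cols$gchar == "N")
    cmid <- (aln$cstart + aln$cend) / 2
    if (cmid <= seg$end[1]) ltr5_g <- c(aln$gstart, aln$gend)
    if (cmid >= seg$start[3]) ltr3_g <- c(aln$gstart, aln$gend)
  }
  if (internal_evid >= th$min_internal_evidence) return("proviral")

  # internal region aligned but carried by N tracks: masked, not absent
  if (internal_aligned >= th$min_internal_evidence)
    return(if (internal_n / internal_aligned >= 0.5) "unknown" else "solo-LTR")

  # LTR-only evidence: where would the internal region sit in the genome?
  ilen <- nchar(family$internal)
  n_arm <- nchar(arm_seq)
  windows <- list()
  plus <- candidate$strand == "+"
  if (!is.null(ltr5_g) && !is.null(ltr3_g) && !identical(ltr5_g, ltr3_g)) {
    lo <- min(ltr5_g[2], ltr3_g[2]) + 1; hi <- max(ltr5_g[1], ltr3_g[1]) - 1
    if (hi >= lo) windows[[1]] <- c(lo, hi)
  } else if (!is.null(ltr5_g) || !is.null(ltr3_g)) {
    anchor <- if (!is.null(ltr5_g)) ltr5_g else ltr3_g
    is5 <- !is.null(ltr5_g)
    after <- (is5 && plus) || (!is5 && !plus)
    windows[[1]] <- if (after) c(anchor[2] + 1, anchor[2] + ilen)
                    else c(anchor[1] - ilen, anchor[1] - 1)
  } else {
    windows[[1]] <- c(candidate$gstart, candidate$gend)
  }
  n_frac <- 0
  if (length(windows) > 0) {
    w <- windows[[1]]
    w[1] <- max(1, w[1]); w[2] <- min(n_arm, w[2])
    if (w[2] >= w[1]) {
      sub <- aln_chars(substr(arm_seq, w[1], w[2]))
      n_frac <- mean(sub == "N")
    }
  }
  if (n_frac >= 0.5) "unknown" else "solo-LTR"
}

#' End-to-end alignment of a copy against its consensus span
#'
#' The copy-versus-consensus alignment is assembled as a composite of the
#' chained gapped extensions: each extension already terminates exactly at
#' every structural indel (crossing one costs far more than the x-drop
#' allowance), so the segments carry the base-level alignment, and the
#' inter-segment gaps become explicit deletion/insertion blocks. A single
#' global realignment at BlastN-like scoring is deliberately avoided: when
#' a copy carries both a large insertion and a large deletion, the optimal
#' affine path "smears" the alien insertion across the deleted consensus
#' (per-column mismatch cost beats double-gapping), scrambling the event
#' calls — the same pathology that forced the original census to align
#' copies manually.
#'
#' The alignment is unreliable when (i) the score per aligned base-base
#' column — penalizing only sub-structural gap wiggles — falls below
#' \code{unreliable_per_column} times the match score, (ii) fewer than 50
#' such columns exist, or (iii) more than 45\% of the copy's sequence is
#' unalignable to the consensus (mosaic copies spliced from different
#' families). Unreliable copies are excluded from SV and divergence
#' analysis.
#'
#' @param candidate One candidate from \code{\link{scan_genome}}.
#' @param family The assigned \code{ltr_family}.
#' @param arm_seq The candidate's arm sequence.
#' @param th \code{\link{annotation_thresholds}}.
#' @param params \code{\link{scan_params}} (scoring).
#' @return list(copy_aln, cons_aln, score, cons_start, cons_end,
#'   aligned_identity, score_per_column, unaligned_fraction, reliable).
#' @export
align_to_consensus <- function(candidate, family, arm_seq,
                               th = annotation_thresholds(),
                               params = scan_params()) {
  cons <- family_consensus(family)
  copy <- substr(arm_seq, candidate$gstart, candidate$gend)
  if (candidate$strand == "-") copy <- rev_comp(copy)
  copy_chars <- aln_chars(copy)
  cons_chars <- aln_chars(cons)

  # orient every local alignment to (copy-relative, consensus-forward)
  segs <- lapply(candidate$alignments, function(a) {
    if (candidate$strand == "+") {
      list(ags = a$gstart - candidate$gstart + 1,
           age = a$gend - candidate$gstart + 1,
           cs = a$cstart, ce = a$cend,
           arow = aln_chars(a$g_aln), brow = aln_chars(a$q_aln))
    } else {
      comp_rev <- function(x) {
        y <- rev(x)
        chartr("ACGTNacgtn", "TGCANtgcan", paste(y, collapse = ""))
      }
      list(ags = candidate$gend - a$gend + 1,
           age = candidate$gend - a$gstart + 1,
           cs = a$cstart, ce = a$cend,
           arow = aln_chars(comp_rev(aln_chars(a$g_aln))),
           brow = aln_chars(comp_rev(aln_chars(a$q_aln))))
    }
  })
  segs <- segs[order(vapply(segs, `[[`, numeric(1), "cs"))]

  arow <- character(0); brow <- character(0)
  prev_g <- segs[[1]]$ags - 1
  prev_c <- segs[[1]]$cs - 1
  cs0 <- segs[[1]]$cs
  for (s in segs) {
    # drop leading columns that overlap what is already consumed
    gpos <- s$ags - 1; cpos <- s$cs - 1
    keep_from <- 1
    for (k in seq_along(s$arow)) {
      if (s$arow[k] != "-") gpos <- gpos + 1
      if (s$brow[k] != "-") cpos <- cpos + 1
      if (gpos > prev_g && cpos >= s$cs - 1 && cpos >= prev_c &&
          (s$arow[k] == "-" || gpos > prev_g) &&
          (s$brow[k] == "-" || cpos > prev_c)) break
      keep_from <- k + 1
    }
    if (keep_from > length(s$arow)) next
    # first retained column coordinates
    gfirst <- s$ags - 1; cfirst <- s$cs - 1
    if (keep_from > 1) {
      pre_a <- s$arow[seq_len(keep_from - 1)]
      pre_b <- s$brow[seq_len(keep_from - 1)]
      gfirst <- gfirst + sum(pre_a != "-")
      cfirst <- cfirst + sum(pre_b != "-")
    }
    # inter-segment blocks: unaligned copy sequence (insertion), then
    # uncovered consensus (deletion)
    if (gfirst > prev_g) {
      blk <- copy_chars[seq(prev_g + 1, gfirst)]
      arow <- c(arow, blk); brow <- c(brow, rep("-", length(blk)))
    }
    if (cfirst > prev_c) {
      blk <- cons_chars[seq(prev_c + 1, cfirst)]
      arow <- c(arow, rep("-", length(blk))); brow <- c(brow, blk)
    }
    arow <- c(arow, s$arow[keep_from:length(s$arow)])
    brow <- c(brow, s$brow[keep_from:length(s$brow)])
    prev_g <- max(prev_g, s$age); prev_c <- max(prev_c, s$ce)
  }
  cs1 <- prev_c

  bases <- c("A", "C", "G", "T")
  comp <- arow %in% bases & brow %in% bases
  n_match <- sum(comp & arow == brow)
  n_mis <- sum(comp) - n_match
  ident <- if (sum(comp) > 0) n_match / sum(comp) else 0
  # penalize only sub-structural gap wiggles; long runs are called events
  wiggle_pen <- 0
  gap_score <- 0
  for (mask in list(arow == "-", brow == "-")) {
    rl <- rle(mask)
    lens <- rl$lengths[rl$values]
    gap_score <- gap_score - sum(-params$gap_open - lens * params$gap_ext)
    wiggle_pen <- wiggle_pen +
      sum(-params$gap_open - lens[lens < th$sv_min_indel] * params$gap_ext)
  }
  score <- n_match * params$match + n_mis * params$mismatch + gap_score
  per_col <- if (sum(comp) > 0)
    (n_match * params$match + n_mis * params$mismatch - wiggle_pen) / sum(comp)
  else -Inf
  unaligned <- sum(arow != "-" & brow == "-" & arow != "N") / length(copy_chars)

  list(copy_aln = paste(arow, collapse = ""),
       cons_aln = paste(brow, collapse = ""),
       score = score, cons_start = cs0, cons_end = cs1,
       aligned_identity = ident, score_per_column = per_col,
       unaligned_fraction = unaligned,
       reliable = sum(comp) >= 50 &&
         per_col >= th$unreliable_per_column * params$match &&
         unaligned <= 0.45)
}

#' Call structural-variation events from a copy-consensus alignment
#'
#' Maximal gap runs of at least \code{sv_min_indel} bp in the copy row are
#' deletions; in the consensus row, insertions. An insertion whose sequence
#' matches the consensus within \code{dup_search_window} bp of the insertion
#' point at >= 90% identity is re-typed as a duplication. Events touching an
#' LTR segment carry an LTR flag.
#'
#' @param alignment Result of \code{\link{align_to_consensus}}.
#' @param family The assigned \code{ltr_family}.
#' @param th \code{\link{annotation_thresholds}}.
#' @return data.frame(type, size, offset, ltr_flag); offset is the 1-based
#'   consensus position where the event starts (for insertions, the
#'   consensus position after which the inserted sequence sits).
#' @export
call_sv <- function(alignment, family, th = annotation_thresholds()) {
  a <- aln_chars(alignment$copy_aln)
  b <- aln_chars(alignment$cons_aln)
  cpos <- cumsum(b != "-") + alignment$cons_start - 1L
  seg <- family_segments(family)
  cons <- family_consensus(family)

  events <- list()
  rle_runs <- function(mask) {
    r <- rle(mask)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    data.frame(start = starts[r$values], end = ends[r$values],
               len = r$lengths[r$values])
  }
  # deletions: gaps in the copy row
  for (i in seq_len(nrow(dr <- rle_runs(a == "-")))) {
    if (dr$len[i] < th$sv_min_indel) next
    off <- cpos[dr$start[i]]
    events[[length(events) + 1]] <- list(type = "del", size = dr$len[i],
                                         from = off, to = off + dr$len[i] - 1)
  }
  # insertions: gaps in the consensus row
  for (i in seq_len(nrow(ir <- rle_runs(b == "-")))) {
    if (ir$len[i] < th$sv_min_indel) next
    off <- if (ir$start[i] == 1) alignment$cons_start - 1L else cpos[ir$start[i] - 1]
    ins_seq <- paste(a[ir$start[i]:ir$end[i]], collapse = "")
    type <- "ins"
    if (!grepl("N", ins_seq, fixed = TRUE)) {
      wlo <- max(1, off - th$dup_search_window - ir$len[i])
      whi <- min(nchar(cons), off + th$dup_search_window + ir$len[i])
      window <- substr(cons, wlo, whi)
      pa <- Biostrings::pairwiseAlignment(
        Biostrings::DNAString(ins_seq), Biostrings::DNAString(window),
        type = "local",
        substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
          match = 1, mismatch = -2, baseOnly = TRUE),
        gapOpening = 5, gapExtension = 2)
      covered <- nchar(gsub("-", "", as.character(Biostrings::pattern(pa)), fixed = TRUE))
      if (covered >= 0.9 * ir$len[i] && Biostrings::pid(pa) >= 90) type <- "dup"
    }
    events[[length(events) + 1]] <- list(type = type, size = ir$len[i],
                                         from = off, to = off)
  }
  if (length(events) == 0)
    return(data.frame(type = character(0), size = integer(0),
                      offset = integer(0), ltr_flag = character(0),
                      stringsAsFactors = FALSE))
  ev <- do.call(rbind, lapply(events, function(e) {
    flag <- "none"
    if (max(e$from, seg$start[1]) <= min(e$to, seg$end[1])) flag <- "LTR5"
    else if (max(e$from, seg$start[3]) <= min(e$to, seg$end[3])) flag <- "LTR3"
    data.frame(type = e$type, size = as.integer(e$size),
               offset = as.integer(e$from), ltr_flag = flag,
               stringsAsFactors = FALSE)
  }))
  ev[order(ev$offset), , drop = FALSE]
}

#' Partial-element rule
#'
#' A copy is partial when its summed deletion length exceeds 3% of the
#' consensus length (strict inequality). All deletion gap runs count, plus
#' consensus sequence missing beyond the copy ends when the genomic flank is
#' sequenced (non-N) — a truncation, not an assembly gap. Solo-LTRs are
#' partial by construction.
#'
#' @param alignment Result of \code{\link{align_to_consensus}}.
#' @param family The assigned \code{ltr_family}.
#' @param condition Copy condition ("proviral", "solo-LTR", "unknown").
#' @param flanks_sequenced Logical pair: is the genomic flank on the copy's
#'   5'/3' side non-N?
#' @param th \code{\link{annotation_thresholds}}.
#' @return TRUE/FALSE, or NA when the alignment is unreliable.
#' @export
flag_partial <- function(alignment, family, condition = "proviral",
                         flanks_sequenced = c(TRUE, TRUE),
                         th = annotation_thresholds()) {
  if (condition == "solo-LTR") return(TRUE)
  if (!alignment$reliable) return(NA)
  cons_len <- nchar(family_consensus(family))
  a <- aln_chars(alignment$copy_aln)
  del_sum <- sum(a == "-")
  if (flanks_sequenced[1]) del_sum <- del_sum + (alignment$cons_start - 1)
  if (flanks_sequenced[2]) del_sum <- del_sum + (cons_len - alignment$cons_end)
  del_sum > th$partial_del_fraction * cons_len
}

#' Pairwise-deletion divergence of a copy from its consensus
#'
#' The proportion of mismatched sites over alignment columns in which both
#' rows carry a determined base: gap columns and N columns are excluded
#' pairwise. Undetermined (NA) when fewer than \code{min_cols} comparable
#' columns remain.
#'
#' @param copy_aln,cons_aln Aligned rows.
#' @param min_cols Minimum comparable columns.
#' @return Fraction in [0, 1], or NA.
#' @export
compute_divergence <- function(copy_aln, cons_aln, min_cols = 50L) {
  a <- aln_chars(copy_aln); b <- aln_chars(cons_aln)
  bases <- c("A", "C", "G", "T")
  comp <- a %in% bases & b %in% bases
  if (sum(comp) < min_cols) return(NA_real_)
  sum(a[comp] != b[comp]) / sum(comp)
}

#' Detect a target-site duplication at the copy junctions
#'
#' The longest exact word of 4-6 bp that both ends at the 5' junction
#' (suffix of the left flank) and begins at the 3' junction (prefix of the
#' right flank).
#'
#' @param left_flank,right_flank Genomic flanks (>= 10 bp for a determined
#'   call).
#' @param min_len,max_len TSD length bounds.
#' @return The duplicated word, \code{NULL} if absent, or \code{NA} when a
#'   flank is truncated by a contig edge (< 10 bp).
#' @export
detect_tsd <- function(left_flank, right_flank, min_len = 4L, max_len = 6L) {
  if (nchar(left_flank) < 10 || nchar(right_flank) < 10) return(NA_character_)
  for (L in seq(max_len, min_len)) {
    lf <- substr(left_flank, nchar(left_flank) - L + 1, nchar(left_flank))
    rf <- substr(right_flank, 1, L)
    if (identical(lf, rf) && !grepl("N", lf, fixed = TRUE)) return(lf)
  }
  NULL
}

#' Serialize SV events in the supplementary-table dialect
#'
#' "del120(5'), ins45" — comma-separated events, size after the type, LTR
#' flag parenthesized with a prime mark; "No" for none, "ND" for
#' undetermined.
#'
#' @param sv data.frame(type, size[, ltr_flag]) or NULL for undetermined.
#' @return Character string.
#' @export
sv_string <- function(sv) {
  if (is.null(sv)) return("ND")
  if (nrow(sv) == 0) return("No")
  flag <- if ("ltr_flag" %in% names(sv)) sv$ltr_flag else rep("none", nrow(sv))
  tok <- paste0(sv$type, sv$size,
                ifelse(flag == "LTR5", "(5′)",
                       ifelse(flag == "LTR3", "(3′)", "")))
  paste(tok, collapse = ", ")
}

#' Parse an SV annotation string in the supplementary-table dialect
#'
#' @param s Character string (e.g. "del120(5'), ins45-dup30", "No", "ND").
#' @return data.frame(type, size, ltr_flag), or NULL for "ND"; malformed
#'   tokens raise a warning and make the whole string undetermined.
#' @export
parse_sv_string <- function(s) {
  s <- trimws(s)
  if (s == "ND" || s == "") return(NULL)
  empty <- data.frame(type = character(0), size = integer(0),
                      ltr_flag = character(0), stringsAsFactors = FALSE)
  if (s == "No") return(empty)
  # dashes separate events at the same nucleotide position
  toks <- trimws(unlist(strsplit(s, "[,-]")))
  toks <- toks[toks != ""]
  out <- lapply(toks, function(tk) {
    m <- regmatches(tk, regexec("^(del|ins|dup)([0-9]+)(\\((5|3)[′']\\))?$", tk))[[1]]
    if (length(m) == 0) return(NULL)
    flag <- if (m[5] == "5") "LTR5" else if (m[5] == "3") "LTR3" else "none"
    data.frame(type = m[2], size = as.integer(m[3]), ltr_flag = flag,
               stringsAsFactors = FALSE)
  })
  if (any(vapply(out, is.null, logical(1)))) {
    warning("malformed SV token in: ", s)
    return(NULL)
  }
  do.call(rbind, out)
}

#' Annotate candidate copies
#'
#' Applies family assignment, cross-family resolution, condition
#' classification, consensus alignment, SV calling, fragmentation grading,
#' the partial rule, pairwise-deletion divergence, and TSD detection.
#' Every scanned candidate ends in exactly one of: annotated,
#' rejected-by-family-rules, or unreliable-alignment (unreliable copies are
#' still annotated, with SV/divergence undetermined).
#'
#' @param candidates \code{ltr_candidates} from \code{\link{scan_genome}}.
#' @param library \code{ltr_library}.
#' @param genome Named character vector of arm sequences.
#' @param th \code{\link{annotation_thresholds}}.
#' @param params \code{\link{scan_params}}.
#' @return data.frame of annotated copies (one row each) with attributes
#'   \code{counts} (candidates, rejected_family, overlap_dropped,
#'   unreliable, annotated).
#' @export
annotate_copies <- function(candidates, library, genome,
                            th = annotation_thresholds(),
                            params = scan_params()) {
  n_cand <- length(candidates)
  # family rules first
  kept <- list(); n_rejected <- 0
  for (cand in candidates) {
    fam <- library[[cand$family]]
    res <- assign_family(cand, fam, th)
    if (res$accepted) {
      cand$rule <- res$rule
      kept[[length(kept) + 1]] <- cand
    } else n_rejected <- n_rejected + 1
  }
  # cross-family overlap resolution: keep the candidate maximizing
  # identity x aligned length; ties by family name.
  n_overlap_dropped <- 0
  if (length(kept) > 1) {
    weight <- vapply(kept, function(cd) {
      sum(vapply(cd$alignments, function(a) a$identity * a$ncol, numeric(1)))
    }, numeric(1))
    fams <- vapply(kept, `[[`, character(1), "family")
    ord <- order(-weight, fams)
    keep <- rep(TRUE, length(kept))
    for (i in seq_along(ord)) {
      a <- ord[i]
      if (!keep[a]) next
      for (j in seq_along(ord)) {
        if (j <= i) next
        b <- ord[j]
        if (!keep[b]) next
        ca <- kept[[a]]; cb <- kept[[b]]
        if (ca$arm != cb$arm) next
        ov <- min(ca$gend, cb$gend) - max(ca$gstart, cb$gstart) + 1
        if (ov > 0 && ov >= 0.5 * min(ca$gend - ca$gstart + 1,
                                      cb$gend - cb$gstart + 1)) {
          keep[b] <- FALSE
          n_overlap_dropped <- n_overlap_dropped + 1
        }
      }
    }
    kept <- kept[keep]
  }

  rows <- list(); n_unreliable <- 0
  for (i in seq_along(kept)) {
    cand <- kept[[i]]
    fam <- library[[cand$family]]
    arm_seq <- genome[[cand$arm]]
    condition <- classify_condition(cand, fam, arm_seq, th)
    alignment <- align_to_consensus(cand, fam, arm_seq, th, params)
    if (!alignment$reliable) n_unreliable <- n_unreliable + 1

    lf <- substr(arm_seq, max(1, cand$gstart - 10), cand$gstart - 1)
    rf <- substr(arm_seq, cand$gend + 1, min(nchar(arm_seq), cand$gend + 10))
    tsd <- detect_tsd(lf, rf)
    flanks_ok <- c(!grepl("N", lf, fixed = TRUE) && nchar(lf) >= 10,
                   !grepl("N", rf, fixed = TRUE) && nchar(rf) >= 10)

    if (alignment$reliable) {
      sv <- call_sv(alignment, fam, th)
      divergence <- compute_divergence(alignment$copy_aln, alignment$cons_aln,
                                       th$min_divergence_columns)
      partial <- flag_partial(alignment, fam, condition, flanks_ok, th)
      copy_seq <- substr(arm_seq, cand$gstart, cand$gend)
      has_n <- grepl("N", copy_seq, fixed = TRUE)
      frag <- if (condition != "proviral") NA_character_
              else if (nrow(sv) >= 3) "highly-fragmented"
              else if (nrow(sv) >= 1) "moderately-fragmented"
              else if (!has_n) "complete" else "unknown"
      sv_str <- sv_string(sv)
      sv_det <- sv_detail_string(sv)
      n_sv <- nrow(sv)
    } else {
      sv <- NULL; divergence <- NA_real_
      partial <- if (condition == "solo-LTR") TRUE else NA
      frag <- if (condition == "proviral") "unknown" else NA_character_
      sv_str <- "ND"
      sv_det <- NA_character_
      n_sv <- NA_integer_
    }

    rows[[length(rows) + 1]] <- data.frame(
      id = sprintf("CPY%04d", i),
      family = cand$family, lineage = cand$lineage,
      arm = cand$arm, start = cand$gstart, end = cand$gend,
      strand = cand$strand,
      condition = condition,
      divergence = divergence,
      sv = sv_str, sv_detail = sv_det, n_sv = n_sv,
      fragmentation = frag,
      partial = partial,
      tsd = if (is.null(tsd)) "" else tsd,
      rule = cand$rule,
      reliable = alignment$reliable,
      stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(id = character(0), family = character(0), lineage = character(0),
               arm = character(0), start = integer(0), end = integer(0),
               strand = character(0), condition = character(0),
               divergence = numeric(0), sv = character(0),
               sv_detail = character(0), n_sv = integer(0),
               fragmentation = character(0), partial = logical(0),
               tsd = character(0), rule = integer(0), reliable = logical(0),
               stringsAsFactors = FALSE)
  attr(out, "counts") <- c(candidates = n_cand,
                           rejected_family = n_rejected,
                           overlap_dropped = n_overlap_dropped,
                           unreliable = n_unreliable,
                           annotated = nrow(out))
  out
}
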