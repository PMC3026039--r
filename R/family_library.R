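#' Build a random library of LTR retrotransposon family models
#'
#' Each family model is a consensus split into a 5' LTR, an internal
#' (gag/pol-bearing) region, and a 3' LTR identical to the 5' LTR, as a
#' freshly transposed element would be. Total lengths default to the 5-8 kb
#' range typical of Ty3/gypsy elements; lineages are drawn with the relative
#' frequencies observed for the five insect Ty3/gypsy lineages present in
#' Anopheles gambiae (Mag the most diverse, then Mdg3, Mdg1, Gypsy, CsRn1).
#'
#' @param n_families Number of families (>= 1).
#' @param ltr_len_range Length range (bp) for the LTR, inclusive.
#' @param total_len_range Length range (bp) for the full consensus, inclusive.
#' @param gc GC fraction of the generated consensi.
#' @param seed Integer seed; the library is deterministic given the seed.
#' @return An object of class \code{ltr_library}: a named list of
#'   \code{ltr_family} objects with fields \code{name}, \code{lineage},
#'   \code{ltr5}, \code{internal}, \code{ltr3}.
#' @export
build_family_library <- function(n_families,
                                 ltr_len_range = c(150L, 400L),
                                 total_len_range = c(5000L, 8000L),
                                 gc = 0.45,
                                 seed = 1L) {
  if (n_families < 1) stop("n_families must be >= 1")
  if (any(ltr_len_range <= 0) || any(total_len_range <= 0) ||
      ltr_len_range[1] > ltr_len_range[2] ||
      total_len_range[1] > total_len_range[2])
    stop("invalid length ranges")
  if (ltr_len_range[1] < 100) stop("LTR length must be >= 100 bp")
  if (gc <= 0 || gc >= 1) stop("gc must be in (0, 1)")
  if (2 * ltr_len_range[2] >= total_len_range[1])
    stop("LTRs would not leave room for an internal region")

  lineage_freq <- c(Mag = 0.41, Mdg3 = 0.22, Mdg1 = 0.15, Gypsy = 0.12, CsRn1 = 0.10)
  with_seed(seed, {
    fams <- lapply(seq_len(n_families), function(i) {
      lin <- sample(names(lineage_freq), 1, prob = lineage_freq)
      ltr_len <- rint(ltr_len_range[1], ltr_len_range[2])
      total <- rint(total_len_range[1], total_len_range[2])
      ltr5 <- random_sequence(ltr_len, gc)
      internal <- random_sequence(total - 2 * ltr_len, gc)
      structure(list(name = sprintf("%s-F%02d", lin, i),
                     lineage = lin,
                     ltr5 = ltr5, internal = internal, ltr3 = ltr5),
                class = "ltr_family")
    })
    names(fams) <- vapply(fams, `[[`, character(1), "name")
    structure(fams, class = "ltr_library")
  })
}

#' Full consensus sequence of a family model
#' @param family An \code{ltr_family}.
#' @return Character string \code{ltr5 + internal + ltr3}.
#' @export
family_consensus <- function(family) {
  paste0(family$ltr5, family$internal, family$ltr3)
}

#' Consensus segmentation of a family model
#' @param family An \code{ltr_family}.
#' @return data.frame with columns segment ("LTR5", "internal", "LTR3"),
#'   start, end (1-based inclusive consensus coordinates).
#' @export
family_segments <- function(family) {
  l5 <- nchar(family$ltr5); li <- nchar(family$internal); l3 <- nchar(family$ltr3)
  data.frame(segment = c("LTR5", "internal", "LTR3"),
             start = c(1L, l5 + 1L, l5 + li + 1L),
             end = c(l5, l5 + li, l5 + li + l3),
             stringsAsFactors = FALSE)
}

validate_indel_spec <- function(indel_spec, cons_len) {
  if (length(indel_spec) == 0) return(invisible(TRUE))
  for (ev in indel_spec) {
    if (!is.list(ev) || !all(c("type", "size", "offset") %in% names(ev)))
      stop("each indel must be a list(type, size, offset)")
    if (!ev$type %in% c("del", "ins")) stop("indel type must be 'del' or 'ins'")
    if (ev$size < 1) stop("indel size must be >= 1")
    if (ev$offset < 1 || ev$offset > cons_len) stop("indel offset outside consensus")
    if (ev$type == "del" && ev$offset + ev$size - 1 > cons_len)
      stop("deletion extends past the consensus end")
  }
  dels <- Filter(function(e) e$type == "del", indel_spec)
  if (length(dels) > 1) {
    iv <- t(vapply(dels, function(e) c(e$offset, e$offset + e$size - 1), numeric(2)))
    iv <- iv[order(iv[, 1]), , drop = FALSE]
    if (any(iv[-1, 1] <= iv[-nrow(iv), 2]))
      stop("overlapping indel_spec entries")
  }
  ins <- Filter(function(e) e$type == "ins", indel_spec)
  if (length(ins) > 1 && anyDuplicated(vapply(ins, `[[`, numeric(1), "offset")))
    stop("overlapping indel_spec entries (duplicate insertion offsets)")
  for (i in ins) {
    for (d in Filter(function(e) e$type == "del", indel_spec)) {
      if (i$offset >= d$offset && i$offset <= d$offset + d$size - 1)
        stop("overlapping indel_spec entries (insertion inside deletion)")
    }
  }
  invisible(TRUE)
}

#' Mutate a consensus into a diverged genomic copy
#'
#' Substitutions are placed uniformly over positions not removed by a planned
#' deletion; the realized substitution count is \code{round(divergence *
#' consensus length)} and each hit site changes to one of the three other
#' bases. Indels from \code{indel_spec} are applied afterwards at their
#' stated consensus offsets (insertions receive random sequence).
#'
#' @param consensus Consensus sequence (character string).
#' @param target_divergence Fraction in [0, 0.5].
#' @param indel_spec List of \code{list(type, size, offset)}; types "del"
#'   and "ins"; offsets are 1-based consensus positions (insertion after the
#'   offset position). Entries must not overlap.
#' @param seed Integer seed.
#' @return List with \code{seq} (mutated sequence), \code{sv} (data.frame of
#'   realized events: type, size, offset), \code{n_sub} (realized
#'   substitution count).
#' @export
mutate_copy <- function(consensus, target_divergence, indel_spec = list(), seed = 1L) {
  if (target_divergence < 0 || target_divergence > 0.5)
    stop("target_divergence must be in [0, 0.5]")
  L <- nchar(consensus)
  validate_indel_spec(indel_spec, L)

  with_seed(seed, {
    chars <- aln_chars(consensus)
    del_pos <- integer(0)
    for (ev in indel_spec) if (ev$type == "del")
      del_pos <- c(del_pos, seq(ev$offset, ev$offset + ev$size - 1))
    candidates <- setdiff(seq_len(L), del_pos)
    n_sub <- round(target_divergence * L)
    n_sub <- min(n_sub, length(candidates))
    if (n_sub > 0) {
      hit <- sample(candidates, n_sub)
      bases <- c("A", "C", "G", "T")
      for (p in hit) {
        alt <- setdiff(bases, chars[p])
        chars[p] <- sample(alt, 1)
      }
    }
    # apply indels right-to-left so earlier offsets stay valid
    if (length(indel_spec) > 0) {
      ord <- order(vapply(indel_spec, `[[`, numeric(1), "offset"), decreasing = TRUE)
      for (ev in indel_spec[ord]) {
        if (ev$type == "del") {
          chars <- chars[-seq(ev$offset, ev$offset + ev$size - 1)]
        } else {
          insert <- aln_chars(random_sequence(ev$size, 0.5))
          chars <- append(chars, insert, after = ev$offset)
        }
      }
    }
    sv <- if (length(indel_spec) > 0) {
      data.frame(type = vapply(indel_spec, `[[`, character(1), "type"),
                 size = vapply(indel_spec, function(e) as.integer(e$size), integer(1)),
                 offset = vapply(indel_spec, function(e) as.integer(e$offset), integer(1)),
                 stringsAsFactors = FALSE)
    } else {
      data.frame(type = character(0), size = integer(0), offset = integer(0))
    }
    list(seq = paste(chars, collapse = ""), sv = sv, n_sub = n_sub)
  })
}

#' Construct a solo-LTR fragment with target-site duplications
#'
#' A solo-LTR is the single LTR left behind when recombination between the
#' two LTRs of one element deletes the internal region; at the insertion
#' locus it remains flanked by the original target-site duplication.
#'
#' @param family An \code{ltr_family}.
#' @param target_divergence Divergence of the surviving LTR from consensus.
#' @param tsd Target-site duplication (4-6 bp, copied verbatim both sides).
#' @param seed Integer seed.
#' @return List with \code{seq} (tsd + mutated LTR + tsd), \code{core}
#'   (the LTR alone), \code{tsd}, \code{n_sub}.
#' @export
make_solo_ltr <- function(family, target_divergence, tsd, seed = 1L) {
  if (nchar(tsd) < 4 || nchar(tsd) > 6) stop("tsd length must be in [4, 6]")
  m <- mutate_copy(family$ltr5, target_divergence, list(), seed)
  list(seq = paste0(tsd, m$seq, tsd), core = m$seq, tsd = tsd, n_sub = m$n_sub)
}
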