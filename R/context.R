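#' Normalize a compartment map
#'
#' @param compartments data.frame(arm, start, end, label); labels among PH,
#'   DIH, CIH, EU (or PE/NPE after derivation, UNK for unassigned zones).
#' @return The validated map (class \code{compartment_map}).
#' @export
compartment_map <- function(compartments) {
  stopifnot(all(c("arm", "start", "end", "label") %in% names(compartments)))
  comp <- compartments[order(compartments$arm, compartments$start), , drop = FALSE]
  for (a in unique(comp$arm)) {
    d <- comp[comp$arm == a, ]
    if (nrow(d) > 1 && any(d$start[-1] <= d$end[-nrow(d)]))
      stop("overlapping compartment intervals on arm ", a)
  }
  rownames(comp) <- NULL
  structure(comp, class = c("compartment_map", "data.frame"))
}

#' Derive the pericentromeric euchromatin (PE)
#'
#' The PE of each arm is the stretch of euchromatin proximal to the
#' pericentric heterochromatin (PH): euchromatic base pairs are accumulated
#' walking from the PH boundary toward the telomere, skipping intercalary
#' heterochromatin, until \code{pe_size} bp are collected. The remaining
#' euchromatin becomes NPE. An explicit coordinate list can override the
#' derivation per arm.
#'
#' @param map \code{\link{compartment_map}} with EU/PH labels.
#' @param pe_size PE size in bp per arm (default 3 Mb).
#' @param pe_override Optional named list (by arm) of data.frame(start, end)
#'   giving PE intervals directly.
#' @return Updated \code{compartment_map} in which EU is split into PE/NPE.
#' @export
derive_pericentromeric_euchromatin <- function(map, pe_size = 3e6,
                                               pe_override = NULL) {
  out <- list()
  for (a in unique(map$arm)) {
    d <- map[map$arm == a, , drop = FALSE]
    d <- d[order(d$start), , drop = FALSE]
    if (!is.null(pe_override) && a %in% names(pe_override)) {
      ov <- pe_override[[a]]
      pieces <- list()
      for (i in seq_len(nrow(d))) {
        row <- d[i, ]
        if (row$label != "EU") { pieces[[length(pieces) + 1]] <- row; next }
        cuts <- ov[ov$start <= row$end & ov$end >= row$start, , drop = FALSE]
        if (nrow(cuts) == 0) {
          row$label <- "NPE"; pieces[[length(pieces) + 1]] <- row; next
        }
        pos <- row$start
        for (j in order(cuts$start)) {
          cs <- max(cuts$start[j], row$start); ce <- min(cuts$end[j], row$end)
          if (cs > pos) pieces[[length(pieces) + 1]] <-
              data.frame(arm = a, start = pos, end = cs - 1, label = "NPE")
          pieces[[length(pieces) + 1]] <-
            data.frame(arm = a, start = cs, end = ce, label = "PE")
          pos <- ce + 1
        }
        if (pos <= row$end) pieces[[length(pieces) + 1]] <-
            data.frame(arm = a, start = pos, end = row$end, label = "NPE")
      }
      out[[a]] <- do.call(rbind, pieces)
      next
    }

    ph <- d[d$label == "PH", , drop = FALSE]
    if (nrow(ph) == 0) {
      warning("arm ", a, ": no PH anchor; all euchromatin assigned to NPE")
      d$label[d$label == "EU"] <- "NPE"
      out[[a]] <- d
      next
    }
    arm_len <- max(d$end)
    # centromere side: the arm end nearest the PH block
    dist_left <- min(ph$start) - 1
    dist_right <- arm_len - max(ph$end)
    walk_right <- dist_left <= dist_right  # PH proximal at left -> walk right
    boundary <- if (walk_right) max(ph$end) else min(ph$start)

    idx <- order(d$start, decreasing = !walk_right)
    acc <- 0
    pieces <- list()
    for (i in idx) {
      row <- d[i, ]
      beyond <- if (walk_right) row$end > boundary else row$start < boundary
      if (row$label != "EU" || !beyond || acc >= pe_size) {
        if (row$label == "EU") row$label <- "NPE"
        pieces[[length(pieces) + 1]] <- row
        next
      }
      len <- row$end - row$start + 1
      take <- min(len, pe_size - acc)
      acc <- acc + take
      if (take == len) {
        row$label <- "PE"
        pieces[[length(pieces) + 1]] <- row
      } else if (walk_right) {
        pieces[[length(pieces) + 1]] <-
          data.frame(arm = a, start = row$start, end = row$start + take - 1,
                     label = "PE")
        pieces[[length(pieces) + 1]] <-
          data.frame(arm = a, start = row$start + take, end = row$end,
                     label = "NPE")
      } else {
        pieces[[length(pieces) + 1]] <-
          data.frame(arm = a, start = row$end - take + 1, end = row$end,
                     label = "PE")
        pieces[[length(pieces) + 1]] <-
          data.frame(arm = a, start = row$start, end = row$end - take,
                     label = "NPE")
      }
    }
    if (acc < pe_size)
      warning("arm ", a, ": euchromatin short of ", pe_size,
              " bp; PE covers all ", acc, " bp of euchromatin")
    res <- do.call(rbind, pieces)
    out[[a]] <- res[order(res$start), , drop = FALSE]
  }
  compartment_map(do.call(rbind, out))
}

#' Assign each copy to a chromatin compartment
#'
#' The label of the interval containing the copy midpoint; copies straddling
#' a boundary take the midpoint's side; copies in unlabeled zones get "UNK".
#'
#' @param copies data.frame with arm, start, end.
#' @param map \code{\link{compartment_map}}.
#' @return \code{copies} with a \code{compartment} column (NA for copies on
#'   unmapped arms).
#' @export
assign_compartment <- function(copies, map) {
  lab <- rep(NA_character_, nrow(copies))
  mid <- floor((copies$start + copies$end) / 2)
  for (a in unique(copies$arm)) {
    sel <- copies$arm == a
    d <- map[map$arm == a, , drop = FALSE]
    if (nrow(d) == 0) next
    hit <- vapply(mid[sel], function(m) {
      k <- which(d$start <= m & d$end >= m)
      if (length(k) == 0) "UNK" else d$label[k[1]]
    }, character(1))
    lab[sel] <- hit
  }
  copies$compartment <- lab
  copies
}

#' Single-linkage clustering of insertions at a distance threshold
#'
#' Two copies are linked when their edge-to-edge gap is at most
#' \code{distance} bp (inclusive); clusters are the connected components.
#' The alternative "start" method measures start-to-start distance.
#'
#' @param copies data.frame with arm, start, end (any order).
#' @param distance Linking distance in bp (default 10 kb).
#' @param method "edge" (edge-to-edge gap, default) or "start".
#' @return \code{copies} with \code{cluster} (id per arm) and
#'   \code{cluster_size} columns; attribute \code{n_in_clusters} counts
#'   copies in clusters of size >= 2.
#' @export
cluster_insertions <- function(copies, distance = 10000,
                               method = c("edge", "start")) {
  method <- match.arg(method)
  copies$cluster <- NA_character_
  copies$cluster_size <- NA_integer_
  for (a in unique(copies$arm)) {
    sel <- which(copies$arm == a)
    ord <- sel[order(copies$start[sel], copies$end[sel])]
    cl <- integer(length(ord))
    cur <- 1; cl[1] <- 1
    if (method == "edge") {
      run_max_end <- copies$end[ord[1]]
      for (i in seq_along(ord)[-1]) {
        gap <- copies$start[ord[i]] - run_max_end - 1
        if (gap > distance) cur <- cur + 1
        cl[i] <- cur
        run_max_end <- max(run_max_end, copies$end[ord[i]])
        if (gap > distance) run_max_end <- copies$end[ord[i]]
      }
    } else {
      for (i in seq_along(ord)[-1]) {
        gap <- copies$start[ord[i]] - copies$start[ord[i - 1]]
        if (gap > distance) cur <- cur + 1
        cl[i] <- cur
      }
    }
    copies$cluster[ord] <- paste0(a, "_c", cl)
    sizes <- table(cl)
    copies$cluster_size[ord] <- as.integer(sizes[as.character(cl)])
  }
  attr(copies, "n_in_clusters") <- sum(copies$cluster_size >= 2, na.rm = TRUE)
  copies
}

#' Gene associations of insertions
#'
#' An association is a copy located within the transcription borders of a
#' gene (region: exon if it overlaps any exon, else intron; proximity 0) or
#' within \code{flank} bp of a border (region: 5' on the transcription-start
#' side, 3' on the end side, strand-aware; proximity = edge distance). A
#' copy may associate with several genes.
#'
#' @param copies data.frame with id, arm, start, end.
#' @param genes data.frame with arm, gene_id, start, end, strand.
#' @param exons data.frame with gene_id, start, end (genes without exon rows
#'   are treated as single-exon, with a warning).
#' @param flank Flank size in bp (default 1000).
#' @return data.frame(copy_id, gene_id, proximity, region).
#' @export
associate_genes <- function(copies, genes, exons = NULL, flank = 1000) {
  res <- list()
  if (is.null(exons))
    exons <- data.frame(gene_id = character(0), start = integer(0), end = integer(0))
  warned <- FALSE
  for (a in unique(copies$arm)) {
    cp <- copies[copies$arm == a, , drop = FALSE]
    gn <- genes[genes$arm == a, , drop = FALSE]
    if (nrow(gn) == 0 || nrow(cp) == 0) next
    for (i in seq_len(nrow(cp))) {
      near <- gn[gn$start - flank <= cp$end[i] & gn$end + flank >= cp$start[i], ,
                 drop = FALSE]
      for (j in seq_len(nrow(near))) {
        gstart <- near$start[j]; gend <- near$end[j]
        inside <- cp$start[i] <= gend && cp$end[i] >= gstart
        if (inside) {
          ex <- exons[exons$gene_id == near$gene_id[j], , drop = FALSE]
          if (nrow(ex) == 0) {
            if (!warned) {
              warning("gene without exon rows treated as single-exon")
              warned <- TRUE
            }
            ex <- data.frame(start = gstart, end = gend)
          }
          hit_exon <- any(ex$start <= cp$end[i] & ex$end >= cp$start[i])
          region <- if (hit_exon) "exon" else "intron"
          prox <- 0L
        } else {
          left_of_gene <- cp$end[i] < gstart
          prox <- if (left_of_gene) gstart - cp$end[i] else cp$start[i] - gend
          if (prox > flank) next
          upstream <- (left_of_gene && near$strand[j] == "+") ||
                      (!left_of_gene && near$strand[j] == "-")
          region <- if (upstream) "5′" else "3′"
        }
        res[[length(res) + 1]] <- data.frame(
          copy_id = cp$id[i], gene_id = near$gene_id[j],
          proximity = as.integer(prox), region = region,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(res) == 0)
    return(data.frame(copy_id = character(0), gene_id = character(0),
                      proximity = integer(0), region = character(0),
                      stringsAsFactors = FALSE))
  do.call(rbind, res)
}

#' Density and composition statistics for a set of regions
#'
#' Copies are counted by midpoint membership; base-pair tallies truncate
#' copies at the region border. Divergence summaries use determined values
#' only.
#'
#' @param copies data.frame with arm, start, end, and optionally condition,
#'   divergence, fragmentation, cluster_size.
#' @param regions data.frame(arm, start, end, label); rows sharing a label
#'   are pooled into one region.
#' @param genes Optional data.frame(arm, start, end) of gene models for
#'   gene density.
#' @return data.frame, one row per region label: size Mb, LTRr bp, percent
#'   of region, insertion count, insertions per Mb, proviral and solo-LTR
#'   counts, percent of provirals fragmented, mean and sd divergence,
#'   insertions in clusters, genes per Mb.
#' @export
region_density <- function(copies, regions, genes = NULL) {
  if (any(regions$end < regions$start)) stop("zero or negative-size region")
  mids <- floor((copies$start + copies$end) / 2)
  gmids <- if (!is.null(genes)) floor((genes$start + genes$end) / 2) else NULL
  out <- list()
  for (lab in unique(regions$label)) {
    rg <- regions[regions$label == lab, , drop = FALSE]
    size_bp <- sum(rg$end - rg$start + 1)
    if (size_bp <= 0) stop("zero-size region: ", lab)
    inreg <- rep(FALSE, nrow(copies))
    ltr_bp <- 0
    n_genes <- 0
    for (k in seq_len(nrow(rg))) {
      sel <- copies$arm == rg$arm[k] & mids >= rg$start[k] & mids <= rg$end[k]
      inreg <- inreg | sel
      ov <- pmin(copies$end, rg$end[k]) - pmax(copies$start, rg$start[k]) + 1
      ltr_bp <- ltr_bp + sum(pmax(0, ov[copies$arm == rg$arm[k]]))
      if (!is.null(genes))
        n_genes <- n_genes + sum(genes$arm == rg$arm[k] &
                                 gmids >= rg$start[k] & gmids <= rg$end[k])
    }
    cp <- copies[inreg, , drop = FALSE]
    n <- nrow(cp)
    size_mb <- size_bp / 1e6
    has_cond <- "condition" %in% names(cp)
    prov <- if (has_cond) sum(cp$condition == "proviral") else NA_integer_
    solo <- if (has_cond) sum(cp$condition == "solo-LTR") else NA_integer_
    frag_pct <- if (has_cond && "fragmentation" %in% names(cp) && prov > 0) {
      100 * sum(cp$condition == "proviral" & !is.na(cp$fragmentation) &
                cp$fragmentation %in% c("moderately-fragmented", "highly-fragmented")) / prov
    } else NA_real_
    divs <- if ("divergence" %in% names(cp)) cp$divergence[!is.na(cp$divergence)] else numeric(0)
    clustered <- if ("cluster_size" %in% names(cp))
      sum(cp$cluster_size >= 2, na.rm = TRUE) else NA_integer_
    out[[length(out) + 1]] <- data.frame(
      region = lab, size_mb = size_mb,
      ltr_bp = ltr_bp, pct_of_region = 100 * ltr_bp / size_bp,
      n_insertions = n, per_mb = n / size_mb,
      n_proviral = prov, n_solo = solo,
      pct_proviral_fragmented = frag_pct,
      mean_divergence = if (length(divs)) mean(divs) * 100 else NA_real_,
      sd_divergence = if (length(divs) > 1) sd(divs) * 100 else NA_real_,
      in_clusters = clustered,
      genes_per_mb = if (!is.null(genes)) n_genes / size_mb else NA_real_,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Windowed insertion counts and TE base-pair density along an arm
#'
#' Non-overlapping windows tiled from position 1; insertion counts use the
#' midpoint rule, base-pair density splits straddling copies between
#' windows; the final short window is normalized by its true length.
#'
#' @param copies data.frame with start, end (one arm), or NULL.
#' @param arm_length Arm length in bp.
#' @param window Window size in bp.
#' @param te_intervals Optional data.frame(start, end) of TE-masked
#'   intervals for the bp density (defaults to \code{copies}).
#' @return data.frame(start, end, count, te_bp, density_pct).
#' @export
windowed_density <- function(copies, arm_length, window,
                             te_intervals = NULL) {
  stopifnot(window > 0)
  if (is.null(te_intervals)) te_intervals <- copies
  starts <- seq(1, arm_length, by = window)
  ends <- pmin(starts + window - 1, arm_length)
  count <- integer(length(starts))
  te_bp <- numeric(length(starts))
  if (!is.null(copies) && nrow(copies) > 0) {
    mids <- floor((copies$start + copies$end) / 2)
    wi <- findInterval(mids, starts)
    tab <- table(wi)
    count[as.integer(names(tab))] <- as.integer(tab)
  }
  if (!is.null(te_intervals) && nrow(te_intervals) > 0) {
    for (k in seq_along(starts)) {
      ov <- pmin(te_intervals$end, ends[k]) - pmax(te_intervals$start, starts[k]) + 1
      te_bp[k] <- sum(pmax(0, ov))
    }
  }
  data.frame(start = starts, end = ends, count = count, te_bp = te_bp,
             density_pct = 100 * te_bp / (ends - starts + 1))
}

#' TE density around inversion breakpoints
#'
#' Base-pair TE densities for the rearranged interval, the proximal and
#' distal remainder of the given bounds, the 50-kb windows on each side of
#' each breakpoint, and a region centered on the proximal breakpoint.
#'
#' @param te_intervals data.frame(start, end) of TE intervals on the arm.
#' @param arm_length Arm length in bp.
#' @param breakpoints Numeric pair (proximal, distal), proximal < distal.
#' @param flank Breakpoint flank size (default 50 kb).
#' @param centered Size of the window centered on the proximal breakpoint
#'   (default 1 Mb).
#' @param bounds Pair delimiting the analyzed region (default whole arm).
#' @return data.frame(region, start, end, te_bp, density_pct).
#' @export
breakpoint_neighborhood_density <- function(te_intervals, arm_length,
                                            breakpoints, flank = 50000,
                                            centered = 1e6,
                                            bounds = c(1, arm_length)) {
  p1 <- breakpoints[1]; p2 <- breakpoints[2]
  stopifnot(p1 < p2, p1 >= 1, p2 <= arm_length)
  regions <- list(
    proximal = c(bounds[1], p1 - 1),
    inside = c(p1, p2),
    distal = c(p2 + 1, bounds[2]),
    prox_bp_left = c(p1 - flank, p1 - 1),
    prox_bp_right = c(p1, p1 + flank - 1),
    dist_bp_left = c(p2 - flank + 1, p2),
    dist_bp_right = c(p2 + 1, p2 + flank),
    centered_prox = c(p1 - centered / 2, p1 + centered / 2 - 1))
  out <- list()
  for (nm in names(regions)) {
    r <- regions[[nm]]
    if (r[1] < 1 || r[2] > arm_length) {
      warning("region ", nm, " truncated at the arm edge")
      r[1] <- max(1, r[1]); r[2] <- min(arm_length, r[2])
    }
    len <- r[2] - r[1] + 1
    bp <- 0
    if (nrow(te_intervals) > 0) {
      ov <- pmin(te_intervals$end, r[2]) - pmax(te_intervals$start, r[1]) + 1
      bp <- sum(pmax(0, ov))
    }
    out[[length(out) + 1]] <- data.frame(
      region = nm, start = r[1], end = r[2], te_bp = bp,
      density_pct = 100 * bp / len, stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}
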