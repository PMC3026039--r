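#' Chromosome blueprint for the synthetic genome
#'
#' @param arm Arm label (e.g. "2L").
#' @param length Arm length in bp (background, before insertions).
#' @param compartments data.frame(start, end, label) tiling [1, length]
#'   without overlap; labels among PH, DIH, CIH, EU.
#' @param genes Optional data.frame(gene_id, start, end, strand).
#' @param exons Optional data.frame(gene_id, start, end) of exon
#'   sub-intervals (each within its gene).
#' @param multipliers Named positive multipliers of the per-bp insertion
#'   rate for each compartment label.
#' @return Object of class \code{chrom_blueprint}.
#' @export
chromosome_blueprint <- function(arm, length, compartments,
                                 genes = NULL, exons = NULL,
                                 multipliers = c(PH = 8, DIH = 5, CIH = 5, EU = 1)) {
  stopifnot(length >= 1)
  comp <- compartments[order(compartments$start), , drop = FALSE]
  if (comp$start[1] != 1 || comp$end[nrow(comp)] != length ||
      (nrow(comp) > 1 && any(comp$start[-1] != comp$end[-nrow(comp)] + 1)))
    stop("compartment segments must tile [1, length] without overlap")
  if (!all(comp$label %in% c("PH", "DIH", "CIH", "EU")))
    stop("compartment labels must be PH, DIH, CIH or EU")
  if (any(multipliers <= 0)) stop("insertion-rate multipliers must be > 0")
  if (!is.null(genes)) {
    if (any(genes$start < 1 | genes$end > length)) stop("genes must lie within the arm")
    if (is.null(exons)) {
      exons <- data.frame(gene_id = genes$gene_id, start = genes$start,
                          end = genes$end, stringsAsFactors = FALSE)
    }
  } else {
    genes <- data.frame(gene_id = character(0), start = integer(0),
                        end = integer(0), strand = character(0))
    exons <- data.frame(gene_id = character(0), start = integer(0), end = integer(0))
  }
  structure(list(arm = arm, length = as.integer(length), compartments = comp,
                 genes = genes, exons = exons, multipliers = multipliers),
            class = "chrom_blueprint")
}

#' Default blueprints emulating the chromatin organisation of a mosquito arm
#'
#' Each arm carries a pericentric heterochromatin (PH) block at its proximal
#' end (~15% of the arm), a small diffuse intercalary (DIH) island mid-arm,
#' and euchromatin elsewhere. Genes are placed at ~55 per Mb in euchromatin
#' and ~14 per Mb in heterochromatin, mirroring the gene densities of the
#' published compartment tables.
#'
#' @param n_arms Number of arms.
#' @param arm_length Background length of each arm (bp).
#' @param seed Integer seed for gene placement.
#' @param multipliers Insertion-rate multipliers per compartment.
#' @return List of \code{chrom_blueprint}.
#' @export
default_blueprints <- function(n_arms = 2, arm_length = 1500000,
                               seed = 1L,
                               multipliers = c(PH = 8, DIH = 5, CIH = 5, EU = 1)) {
  arms <- c("2L", "2R", "3L", "3R", "X")[seq_len(n_arms)]
  lapply(seq_along(arms), function(i) {
    ph_len <- round(0.15 * arm_length)
    dih_start <- round(0.55 * arm_length)
    dih_len <- round(0.03 * arm_length)
    comp <- data.frame(
      start = c(1, ph_len + 1, dih_start, dih_start + dih_len),
      end = c(ph_len, dih_start - 1, dih_start + dih_len - 1, arm_length),
      label = c("PH", "EU", "DIH", "EU"),
      stringsAsFactors = FALSE)
    genes <- with_seed(derive_seed(seed, 500 + i), {
      place_genes(comp, arm_length, eu_per_mb = 55, het_per_mb = 14)
    })
    chromosome_blueprint(arms[i], arm_length, comp,
                         genes = genes$genes, exons = genes$exons,
                         multipliers = multipliers)
  })
}

# Sample non-overlapping gene models with 1-4 exons. Runs under the caller's
# RNG state.
place_genes <- function(comp, arm_length, eu_per_mb = 55, het_per_mb = 14) {
  genes <- list(); exons <- list(); gid <- 0
  for (k in seq_len(nrow(comp))) {
    seg_len <- comp$end[k] - comp$start[k] + 1
    dens <- if (comp$label[k] == "EU") eu_per_mb else het_per_mb
    n <- round(dens * seg_len / 1e6)
    if (n < 1) next
    # lay genes left to right with random gaps
    pos <- comp$start[k]
    for (j in seq_len(n)) {
      glen <- rint(2000L, 8000L)
      gap <- rint(200L, 3000L)
      start <- pos + gap
      end <- start + glen - 1
      if (end > comp$end[k]) break
      gid <- gid + 1
      id <- sprintf("GENE%04d", gid)
      strand <- sample(c("+", "-"), 1)
      genes[[length(genes) + 1]] <- data.frame(
        gene_id = id, start = start, end = end, strand = strand,
        stringsAsFactors = FALSE)
      n_ex <- rint(1L, 4L)
      cuts <- sort(sample(seq(start + 50, end - 50), 2 * (n_ex - 1)))
      bounds <- matrix(c(start, cuts, end), ncol = 2, byrow = TRUE)
      exons[[length(exons) + 1]] <- data.frame(
        gene_id = id, start = bounds[, 1], end = bounds[, 2],
        stringsAsFactors = FALSE)
      pos <- end
    }
  }
  list(genes = do.call(rbind, c(genes, list(data.frame(gene_id = character(0),
                                                       start = integer(0), end = integer(0),
                                                       strand = character(0))))),
       exons = do.call(rbind, c(exons, list(data.frame(gene_id = character(0),
                                                       start = integer(0), end = integer(0))))))
}

#' Default parameters for sampling insertion plans
#'
#' The defaults encode the study conditions the generator emulates:
#' deletion:insertion event ratio 2:1; deletion sizes drawn from the
#' 10-100 / 100-1000 / >1000 bp classes with weights 47/30/23 (38/37/25 for
#' insertions), log-uniform within class; target-site duplications of
#' 4-6 bp; divergence from consensus in [0, 10%] with half of the copies
#' young (<= 1%); solo-LTR, complete-proviral and fragmented-proviral
#' conditions at 40/35/25%.
#'
#' @param ... Overrides of the defaults.
#' @return Named list of parameters.
#' @export
plan_params <- function(...) {
  p <- list(
    condition_probs = c("proviral-complete" = 0.35,
                        "proviral-fragmented" = 0.25,
                        "solo-LTR" = 0.40),
    divergence_max = 0.10,
    young_frac = 0.5,
    young_max = 0.01,
    del_prob = 2 / 3,                      # del:ins = 2:1
    del_class_weights = c(47, 30, 23),
    ins_class_weights = c(38, 37, 25),
    indel_class_bounds = c(10, 100, 1000, 3000),
    n_indels_probs = c(0.35, 0.25, 0.25, 0.15), # 1..4 events
    tsd_range = c(4L, 6L),
    n_gap_prob = 0.05,
    n_gap_len = c(100, 1000),
    minus_strand_prob = 0.5,
    min_site_gap = 50)
  ov <- list(...)
  p[names(ov)] <- ov
  p
}

sample_indel_size <- function(weights, bounds) {
  cls <- sample(seq_along(weights), 1, prob = weights)
  lo <- bounds[cls]; hi <- bounds[cls + 1]
  max(10L, as.integer(round(exp(runif(1, log(lo), log(hi))))))
}

#' Sample insertion plans over a set of blueprints
#'
#' Sites are drawn per compartment with probability proportional to
#' multiplier x compartment length, then uniformly within the compartment;
#' sites closer than \code{min_site_gap} bp on the same arm are rejected and
#' resampled so planted copies never overlap.
#'
#' @param blueprints List of \code{chrom_blueprint}.
#' @param library \code{ltr_library}.
#' @param n Number of insertions to plan.
#' @param params See \code{\link{plan_params}}.
#' @param seed Integer seed.
#' @return data.frame of plans (one row per insertion) with list-columns
#'   \code{indel_spec} and \code{n_gap_spec}.
#' @export
sample_insertion_plans <- function(blueprints, library, n,
                                   params = plan_params(), seed = 1L) {
  stopifnot(n >= 1)
  comp_all <- do.call(rbind, lapply(blueprints, function(b) {
    d <- b$compartments
    d$arm <- b$arm
    d$mult <- b$multipliers[d$label]
    d
  }))
  comp_all$len <- comp_all$end - comp_all$start + 1
  w <- comp_all$mult * comp_all$len

  with_seed(seed, {
    sites <- vector("list", n)
    used <- lapply(blueprints, function(b) integer(0))
    names(used) <- vapply(blueprints, `[[`, character(1), "arm")
    for (i in seq_len(n)) {
      repeat {
        k <- sample(nrow(comp_all), 1, prob = w)
        s <- rint(comp_all$start[k], comp_all$end[k])
        arm <- comp_all$arm[k]
        if (all(abs(used[[arm]] - s) >= params$min_site_gap)) {
          used[[arm]] <- c(used[[arm]], s)
          sites[[i]] <- list(arm = arm, site = s, compartment = comp_all$label[k])
          break
        }
      }
    }
    fam_names <- names(library)
    plans <- lapply(seq_len(n), function(i) {
      cond <- sample(names(params$condition_probs), 1, prob = params$condition_probs)
      div <- if (runif(1) < params$young_frac) runif(1, 0, params$young_max)
             else runif(1, 0, params$divergence_max)
      fam <- sample(fam_names, 1)
      cons_len <- nchar(family_consensus(library[[fam]]))
      seg <- family_segments(library[[fam]])
      indels <- list()
      if (cond == "proviral-fragmented") {
        k_ev <- sample(seq_along(params$n_indels_probs), 1, prob = params$n_indels_probs)
        for (ev in seq_len(k_ev)) {
          # type and size are fixed per event; only the offset is resampled
          # on placement failure, so the del:ins ratio is not biased by the
          # tighter placement constraints of large deletions
          is_del <- runif(1) < params$del_prob
          size <- sample_indel_size(
            if (is_del) params$del_class_weights else params$ins_class_weights,
            params$indel_class_bounds)
          lo <- seg$start[2] + 20
          hi <- seg$end[2] - 20 - if (is_del) size else 0
          if (hi <= lo) next
          for (try in 1:50) {
            off <- rint(lo, hi)
            cand <- c(indels, list(list(type = if (is_del) "del" else "ins",
                                        size = size, offset = off)))
            ok <- tryCatch({ validate_indel_spec(cand, cons_len); TRUE },
                           error = function(e) FALSE)
            if (ok) { indels <- cand; break }
          }
        }
      }
      tsd_len <- rint(params$tsd_range[1], params$tsd_range[2])
      tsd <- random_sequence(tsd_len, 0.4)
      ngap <- list()
      if (runif(1) < params$n_gap_prob) {
        glen <- rint(params$n_gap_len[1], params$n_gap_len[2])
        ngap <- list(list(offset = rint(100L, 2000L), len = glen))
      }
      data.frame(id = sprintf("INS%04d", i),
                 family = fam,
                 arm = sites[[i]]$arm,
                 site = sites[[i]]$site,
                 strand = if (runif(1) < params$minus_strand_prob) "-" else "+",
                 target_divergence = div,
                 planted_condition = cond,
                 tsd = tsd,
                 compartment = sites[[i]]$compartment,
                 indel_spec = I(list(indels)),
                 n_gap_spec = I(list(ngap)),
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, plans)
  })
}

# Apply N-gap tracks in place (replacement, not insertion, so length is
# conserved).
apply_n_gaps <- function(seq, ngap_spec) {
  if (length(ngap_spec) == 0) return(seq)
  chars <- aln_chars(seq)
  for (g in ngap_spec) {
    off <- min(max(1, g$offset), length(chars))
    end <- min(off + g$len - 1, length(chars))
    chars[off:end] <- "N"
  }
  paste(chars, collapse = "")
}

#' Synthesize a genome with planted LTR-retrotransposon copies
#'
#' Background sequence is generated per arm at the stated GC; each plan's
#' fragment (target-site duplication + oriented copy + target-site
#' duplication) is spliced in at its site. Compartment and gene coordinates
#' are remapped through the insertions so they address the emitted genome
#' exactly, as do all ground-truth records.
#'
#' @param blueprints List of \code{chrom_blueprint}.
#' @param library \code{ltr_library}.
#' @param plans data.frame from \code{\link{sample_insertion_plans}} (or
#'   constructed by hand with the same columns).
#' @param seed Integer seed (drives background sequence and per-copy
#'   mutations through derived sub-seeds).
#' @param gc Background GC fraction.
#' @return Object of class \code{ltr_sim}: list with \code{genome} (named
#'   character vector), \code{compartments}, \code{genes}, \code{exons},
#'   \code{truth} (the ground-truth manifest), \code{library}, \code{seed}.
#' @export
synthesize_genome <- function(blueprints, library, plans, seed = 1L, gc = 0.45) {
  arm_names <- vapply(blueprints, `[[`, character(1), "arm")
  if (nrow(plans) > 0) {
    if (!all(plans$arm %in% arm_names)) stop("plan arm not among blueprints")
    # collision check: sites closer than 10 bp on the same arm
    bad <- list()
    for (a in unique(plans$arm)) {
      s <- sort(plans$site[plans$arm == a])
      d <- diff(s)
      if (any(d < 10)) bad[[a]] <- s[which(d < 10)]
    }
    if (length(bad) > 0)
      stop("overlapping insertion plans at: ",
           paste(vapply(names(bad), function(a)
             paste0(a, ":", paste(bad[[a]], collapse = ",")), character(1)),
             collapse = "; "))
  }

  genome <- character(0)
  comp_out <- list(); gene_out <- list(); exon_out <- list(); truth <- list()

  for (bi in seq_along(blueprints)) {
    bp <- blueprints[[bi]]
    bg <- with_seed(derive_seed(seed, bi), random_sequence(bp$length, gc))
    p <- plans[plans$arm == bp$arm, , drop = FALSE]
    p <- p[order(p$site), , drop = FALSE]

    frags <- character(nrow(p)); flens <- integer(nrow(p))
    meta <- vector("list", nrow(p))
    for (j in seq_len(nrow(p))) {
      plan <- p[j, ]
      fam <- library[[plan$family]]
      pseed <- derive_seed(seed, 10000 + match(plan$id, plans$id))
      if (plan$planted_condition == "solo-LTR") {
        m <- mutate_copy(fam$ltr5, plan$target_divergence, list(), pseed)
        core <- m$seq
        true_div <- m$n_sub / nchar(fam$ltr5)
        sv <- m$sv
      } else {
        m <- mutate_copy(family_consensus(fam), plan$target_divergence,
                         plan$indel_spec[[1]], pseed)
        core <- m$seq
        true_div <- m$n_sub / nchar(family_consensus(fam))
        sv <- m$sv
      }
      if (plan$strand == "-") core <- rev_comp(core)
      core <- apply_n_gaps(core, plan$n_gap_spec[[1]])
      frags[j] <- paste0(plan$tsd, core, plan$tsd)
      flens[j] <- nchar(frags[j])
      meta[[j]] <- list(core_len = nchar(core), sv = sv, true_div = true_div,
                        n_sub = m$n_sub)
    }

    sites <- p$site
    cum <- c(0, cumsum(flens))
    # assemble: background split at sites
    pieces <- character(2 * nrow(p) + 1)
    prev <- 1
    for (j in seq_len(nrow(p))) {
      pieces[2 * j - 1] <- substr(bg, prev, sites[j] - 1)
      pieces[2 * j] <- frags[j]
      prev <- sites[j]
    }
    pieces[2 * nrow(p) + 1] <- substr(bg, prev, bp$length)
    arm_seq <- paste(pieces, collapse = "")
    genome[bp$arm] <- arm_seq

    map_start <- function(x) x + vapply(x, function(q) sum(flens[sites < q]), numeric(1))
    map_end <- function(x) x + vapply(x, function(q) sum(flens[sites <= q]), numeric(1))

    cmp <- bp$compartments
    comp_out[[bi]] <- data.frame(arm = bp$arm,
                                 start = as.integer(map_start(cmp$start)),
                                 end = as.integer(map_end(cmp$end)),
                                 label = cmp$label, stringsAsFactors = FALSE)
    if (nrow(bp$genes) > 0) {
      g <- bp$genes
      gene_out[[bi]] <- data.frame(arm = bp$arm, gene_id = g$gene_id,
                                   start = as.integer(map_start(g$start)),
                                   end = as.integer(map_end(g$end)),
                                   strand = g$strand, stringsAsFactors = FALSE)
      e <- bp$exons
      exon_out[[bi]] <- data.frame(arm = bp$arm, gene_id = e$gene_id,
                                   start = as.integer(map_start(e$start)),
                                   end = as.integer(map_end(e$end)),
                                   stringsAsFactors = FALSE)
    }

    if (nrow(p) > 0) {
      tsd_lens <- nchar(p$tsd)
      starts <- sites + cum[seq_len(nrow(p))] + tsd_lens
      ends <- starts + vapply(meta, function(m) m$core_len, numeric(1)) - 1
      truth[[bi]] <- data.frame(
        id = p$id, family = p$family,
        lineage = vapply(p$family, function(f) library[[f]]$lineage, character(1)),
        arm = bp$arm,
        start = as.integer(starts), end = as.integer(ends),
        strand = p$strand,
        planted_condition = p$planted_condition,
        target_divergence = p$target_divergence,
        true_divergence = vapply(meta, function(m) m$true_div, numeric(1)),
        n_indels = vapply(meta, function(m) nrow(m$sv), integer(1)),
        sv = vapply(meta, function(m) sv_string(m$sv), character(1)),
        sv_detail = vapply(meta, function(m) sv_detail_string(m$sv), character(1)),
        tsd = p$tsd,
        has_n_gap = vapply(p$n_gap_spec, function(g) length(g) > 0, logical(1)),
        compartment = p$compartment,
        stringsAsFactors = FALSE)
    }
  }

  structure(list(genome = genome,
                 compartments = do.call(rbind, comp_out),
                 genes = if (length(gene_out)) do.call(rbind, gene_out) else NULL,
                 exons = if (length(exon_out)) do.call(rbind, exon_out) else NULL,
                 truth = if (length(truth)) do.call(rbind, truth) else
                   data.frame(),
                 library = library, seed = seed),
            class = "ltr_sim")
}

# Compact loss-free event serialization ("type:size:offset", comma-joined)
# used by the truth manifest and the annotated-copies table.
sv_detail_string <- function(sv) {
  if (is.null(sv) || nrow(sv) == 0) return("")
  paste(sprintf("%s:%d:%d", sv$type, sv$size, sv$offset), collapse = ",")
}

#' Parse the compact event serialization
#' @param s "type:size:offset" comma-joined string ("" for none).
#' @return data.frame(type, size, offset).
#' @export
parse_sv_detail <- function(s) {
  if (is.na(s) || s == "") return(data.frame(type = character(0),
                                             size = integer(0),
                                             offset = integer(0)))
  parts <- strsplit(strsplit(s, ",", fixed = TRUE)[[1]], ":", fixed = TRUE)
  data.frame(type = vapply(parts, `[[`, "", 1),
             size = as.integer(vapply(parts, `[[`, "", 2)),
             offset = as.integer(vapply(parts, `[[`, "", 3)),
             stringsAsFactors = FALSE)
}
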