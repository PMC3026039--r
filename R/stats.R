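#' Goodness-of-fit chi-square for regional enrichment
#'
#' Tests whether a focal region's insertion count exceeds the expectation
#' proportional to its size in bp: expected = total x size / (size_focal +
#' size_rest); Pearson chi-square, df 1, no continuity correction.
#'
#' @param count_focal,count_rest Observed insertion counts.
#' @param size_focal,size_rest Region sizes (any common unit).
#' @return list(observed, expected, statistic, df, p.value), class
#'   \code{ltr_gof}.
#' @export
chisq_gof_region <- function(count_focal, count_rest, size_focal, size_rest) {
  stopifnot(count_focal >= 0, count_rest >= 0, size_focal > 0, size_rest > 0)
  p <- c(size_focal, size_rest) / (size_focal + size_rest)
  obs <- c(count_focal, count_rest)
  if (any(sum(obs) * p == 0)) stop("zero expected cell")
  ct <- suppressWarnings(chisq.test(obs, p = p, correct = FALSE))
  structure(list(observed = obs, expected = as.numeric(ct$expected),
                 statistic = unname(ct$statistic), df = 1L,
                 p.value = unname(ct$p.value)),
            class = "ltr_gof")
}

#' 2x2 contingency chi-square without continuity correction
#'
#' @param a,b First row counts; \code{c_},\code{d} second row counts.
#' @return list(table, statistic, df, p.value), class \code{ltr_chisq2x2}.
#' @export
chisq_2x2 <- function(a, b, c_, d) {
  m <- matrix(c(a, b, c_, d), nrow = 2, byrow = TRUE)
  if (any(m < 0)) stop("counts must be >= 0")
  if (any(rowSums(m) == 0) || any(colSums(m) == 0)) stop("zero marginal")
  ct <- suppressWarnings(chisq.test(m, correct = FALSE))
  structure(list(table = m, statistic = unname(ct$statistic), df = 1L,
                 p.value = unname(ct$p.value)),
            class = "ltr_chisq2x2")
}

#' Two-sample t test on divergence values
#'
#' Pooled-variance Student test by default (the convention used for the
#' heterochromatin-versus-NPE comparison); Welch variant available.
#'
#' @param group_a,group_b Numeric vectors (n >= 2 each).
#' @param variant "pooled" or "welch".
#' @return list(t, df, p.value, mean_a, mean_b).
#' @export
ttest_divergence <- function(group_a, group_b, variant = c("pooled", "welch")) {
  variant <- match.arg(variant)
  stopifnot(length(group_a) >= 2, length(group_b) >= 2)
  if (sd(group_a) == 0 && sd(group_b) == 0) {
    if (isTRUE(all.equal(mean(group_a), mean(group_b))))
      return(list(t = 0, df = length(group_a) + length(group_b) - 2,
                  p.value = 1, mean_a = mean(group_a), mean_b = mean(group_b)))
    return(list(t = Inf, df = length(group_a) + length(group_b) - 2,
                p.value = 0, mean_a = mean(group_a), mean_b = mean(group_b)))
  }
  tt <- t.test(group_a, group_b, var.equal = (variant == "pooled"))
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p.value = tt$p.value, mean_a = mean(group_a), mean_b = mean(group_b))
}

#' Divergence histogram by condition class
#'
#' Counts per divergence bin (default 0.5-percentage-point bins over
#' 0-10%) per condition, plus the headline shares: fraction of each
#' condition at <= 1% divergence (>= 99% identity) and at >= 5%.
#'
#' @param copies data.frame with condition and divergence (fractions;
#'   NA = undetermined, excluded).
#' @param bin_width Bin width as a divergence fraction (default 0.005).
#' @param max_div Histogram upper bound (default 0.10).
#' @return list(breaks, counts (bin x condition matrix), headline).
#' @export
divergence_histogram <- function(copies, bin_width = 0.005, max_div = 0.10) {
  stopifnot(bin_width > 0)
  d <- copies[!is.na(copies$divergence), , drop = FALSE]
  breaks <- seq(0, max_div, by = bin_width)
  if (breaks[length(breaks)] < max_div) breaks <- c(breaks, max_div)
  conds <- c("proviral", "solo-LTR", "unknown")
  counts <- matrix(0L, nrow = length(breaks) - 1, ncol = length(conds),
                   dimnames = list(NULL, conds))
  for (cn in conds) {
    v <- pmin(d$divergence[d$condition == cn], max_div)
    if (length(v) == 0) next
    # bin i is [breaks[i], breaks[i+1]); the upper bound joins the last bin
    idx <- pmin(findInterval(v, breaks), length(breaks) - 1)
    counts[, cn] <- tabulate(idx, nbins = length(breaks) - 1)
  }
  share <- function(cond, fun) {
    v <- d$divergence[d$condition == cond]
    if (length(v) == 0) return(NA_real_)
    mean(fun(v))
  }
  headline <- list(
    proviral_recent = share("proviral", function(v) v <= 0.01),
    solo_recent = share("solo-LTR", function(v) v <= 0.01),
    proviral_old = share("proviral", function(v) v >= 0.05),
    solo_old = share("solo-LTR", function(v) v >= 0.05))
  list(breaks = breaks, counts = counts, headline = headline)
}

#' Condition ratio by age class
#'
#' 2x2 chi-square of condition (proviral vs solo-LTR) against age class
#' (divergence < young cutoff vs > old cutoff).
#'
#' @param copies data.frame with condition and divergence.
#' @param young Young cutoff (default 0.02).
#' @param old Old cutoff (default 0.05).
#' @return list(table, statistic, df, p.value) from \code{\link{chisq_2x2}}.
#' @export
condition_ratio_by_age <- function(copies, young = 0.02, old = 0.05) {
  d <- copies[!is.na(copies$divergence) &
              copies$condition %in% c("proviral", "solo-LTR"), , drop = FALSE]
  yg <- d[d$divergence < young, ]
  od <- d[d$divergence > old, ]
  counts <- c(sum(yg$condition == "proviral"), sum(yg$condition == "solo-LTR"),
              sum(od$condition == "proviral"), sum(od$condition == "solo-LTR"))
  if (any(c(nrow(yg), nrow(od)) == 0)) stop("empty age class")
  chisq_2x2(counts[1], counts[2], counts[3], counts[4])
}

#' Summary tables by arm and chromatin compartment
#'
#' Reproduces the layout of the per-arm, heterochromatin and euchromatin
#' overview tables: one row per arm, per heterochromatin type (H total, PH,
#' DIH, CIH) and per euchromatin type (E total, PE, NPE), with size, LTRr
#' bp, counts, densities, condition tallies, fragmentation and divergence
#' summaries, clustered-insertion counts and gene densities.
#'
#' @param copies Annotated copies with compartment and cluster columns
#'   (\code{\link{assign_compartment}}, \code{\link{cluster_insertions}}).
#' @param map \code{\link{compartment_map}} with PH/DIH/CIH/PE/NPE labels.
#' @param genes Optional gene models (arm, start, end).
#' @return list(arms, heterochromatin, euchromatin) of data.frames.
#' @export
summarize_tables <- function(copies, map, genes = NULL) {
  arms <- unique(map$arm)
  arm_regions <- do.call(rbind, lapply(arms, function(a) {
    d <- map[map$arm == a, ]
    data.frame(arm = a, start = min(d$start), end = max(d$end), label = a)
  }))
  het <- c("PH", "DIH", "CIH")
  eu <- c("PE", "NPE")
  mk <- function(labels, prefix_arm = TRUE) {
    rg <- map[map$label %in% labels, , drop = FALSE]
    if (nrow(rg) == 0) return(NULL)
    per_arm <- rg
    per_arm$label <- paste0(per_arm$arm, "_", per_arm$label)
    total <- rg
    total$label <- paste0("Total_", total$label)
    rbind(per_arm, total)
  }
  het_regions <- mk(het)
  eu_regions <- mk(eu)
  # combined H and E rows
  if (!is.null(het_regions)) {
    h_all <- map[map$label %in% het, , drop = FALSE]
    if (nrow(h_all) > 0) {
      per_arm_h <- h_all; per_arm_h$label <- paste0(per_arm_h$arm, "_H")
      tot_h <- h_all; tot_h$label <- "Total_H"
      het_regions <- rbind(het_regions, per_arm_h, tot_h)
    }
  }
  if (!is.null(eu_regions)) {
    e_all <- map[map$label %in% eu, , drop = FALSE]
    if (nrow(e_all) > 0) {
      per_arm_e <- e_all; per_arm_e$label <- paste0(per_arm_e$arm, "_E")
      tot_e <- e_all; tot_e$label <- "Total_E"
      eu_regions <- rbind(eu_regions, per_arm_e, tot_e)
    }
  }
  list(
    arms = region_density(copies, arm_regions, genes),
    heterochromatin = if (!is.null(het_regions))
      region_density(copies, het_regions, genes) else NULL,
    euchromatin = if (!is.null(eu_regions))
      region_density(copies, eu_regions, genes) else NULL)
}

#' Published compartment tables shipped with the package
#'
#' The per-arm, heterochromatin and euchromatin overview tables of the
#' Anopheles gambiae Ty3/gypsy census (counts, sizes in Mb, condition
#' tallies, divergences), plus assembly-level constants, as plain-text
#' inputs for re-deriving the census statistics.
#'
#' @return list(arms, heterochromatin, euchromatin, constants) of
#'   data.frames.
#' @export
published_tables <- function() {
  dir <- system.file("extdata", "published_tables", package = "ltrscape")
  read1 <- function(f) read.delim(file.path(dir, f), comment.char = "#",
                                  check.names = FALSE,
                                  stringsAsFactors = FALSE)
  list(arms = read1("arm_overview.tsv"),
       heterochromatin = read1("heterochromatin.tsv"),
       euchromatin = read1("euchromatin.tsv"),
       constants = read1("assembly_constants.tsv"))
}
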