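#!/usr/bin/env Rscript
# Stage 4: the statistical layer.
#
# Re-derives the census's enrichment statistics from the published overview
# tables shipped with the package (chi-square goodness of fit against
# size-proportional expectations, 2x2 condition contrasts, the pooled t on
# per-arm divergences), then computes the same statistics on the simulated
# complement from stages 1-3. Writes results/stats.json.

library(ltrscape)

pt <- published_tables()
arms <- pt$arms; het <- pt$heterochromatin; eu <- pt$euchromatin
tot <- arms[arms$region == "Total", ]
x <- arms[arms$region == "X", ]

g_x <- chisq_gof_region(x$n_insertions, tot$n_insertions - x$n_insertions,
                        x$size_mb, tot$size_mb - x$size_mb)
cat(sprintf("X overrepresentation: chi2 = %.2f (p = %.3g)\n",
            g_x$statistic, g_x$p.value))

pe <- eu[eu$region == "Total_PE", ]; npe <- eu[eu$region == "Total_NPE", ]
g_pe <- chisq_gof_region(pe$n_insertions, npe$n_insertions,
                         pe$size_mb, npe$size_mb)
cat(sprintf("PE enrichment:        chi2 = %.2f (p = %.3g)\n",
            g_pe$statistic, g_pe$p.value))

ph <- het[het$region == "Total_PH", ]
g_c <- chisq_2x2(ph$n_proviral, ph$n_solo, npe$n_proviral, npe$n_solo)
cat(sprintf("proviral/solo PHxNPE: chi2 = %.2f (p = %.3g)\n",
            g_c$statistic, g_c$p.value))

tt <- ttest_divergence(
  het$mean_divergence[het$region %in% c("2L_H", "2R_PH", "3L_H", "3R_H", "X_PH")],
  eu$mean_divergence[eu$region %in% paste0(c("2L", "2R", "3L", "3R", "X"), "_NPE")],
  "pooled")
cat(sprintf("het vs NPE divergence: t = %.2f (p = %.2g)\n", tt$t, tt$p.value))

## the same statistics on the simulated complement
copies <- read_tsv("results/copies_context.tsv")
copies$divergence <- suppressWarnings(as.numeric(copies$divergence_pct)) / 100
map <- derive_pericentromeric_euchromatin(
  compartment_map(read_compartments_bed("results/sim/compartments.bed")),
  pe_size = 3e5)

het_n <- sum(copies$compartment %in% c("PH", "DIH", "CIH"))
eu_n <- sum(copies$compartment %in% c("PE", "NPE"))
len_of <- function(labels) {
  d <- map[map$label %in% labels, ]
  sum(d$end - d$start + 1) / 1e6
}
g_sim <- chisq_gof_region(het_n, eu_n,
                          len_of(c("PH", "DIH", "CIH")), len_of(c("PE", "NPE")))
cat(sprintf("simulated het enrichment: %d het vs %d eu copies, chi2 = %.1f (p = %.2g)\n",
            het_n, eu_n, g_sim$statistic, g_sim$p.value))

h <- divergence_histogram(copies)
cat(sprintf("simulated recent share: %.0f%% of provirals, %.0f%% of solo-LTRs at <= 1%%\n",
            100 * h$headline$proviral_recent, 100 * h$headline$solo_recent))

stats <- list(
  published = list(
    chi2_x = g_x$statistic, chi2_pe = g_pe$statistic,
    chi2_proviral_solo = g_c$statistic, t_het_npe = tt$t),
  simulated = list(
    chi2_het_enrichment = g_sim$statistic,
    het_copies = het_n, eu_copies = eu_n,
    divergence_headline = h$headline))
jsonlite::write_json(stats, "results/stats.json", auto_unbox = TRUE,
                     digits = NA, pretty = TRUE)
cat("wrote results/stats.json\n")
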