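#!/usr/bin/env Rscript
# Stage 3: genomic context of the annotated copies.
#
# Pericentromeric-euchromatin derivation (the PE of each simulated arm is
# the 300-kb euchromatic stretch proximal to the PH block, scaling the
# census's 3-Mb definition to the 1.5-Mb arms), compartment assignment by
# the midpoint rule, 10-kb single-linkage clustering, gene associations of
# the NPE copies (1-kb flanks, exon/intron resolution), 50-kb windowed
# densities, and TE density around a mock rearrangement's breakpoints.
# Writes the overview tables, cluster and association lists under results/.

library(ltrscape)

copies <- read_tsv("results/copies.tsv")
copies$divergence <- suppressWarnings(as.numeric(copies$divergence_pct)) / 100
comp <- read_compartments_bed("results/sim/compartments.bed")
gg <- read_genes_gff3("results/sim/genes.gff3")

map <- derive_pericentromeric_euchromatin(compartment_map(comp),
                                          pe_size = 3e5)
copies <- assign_compartment(copies, map)
copies <- cluster_insertions(copies, 10000)
cat("insertions in clusters (<= 10 kb apart):", attr(copies, "n_in_clusters"),
    "of", nrow(copies), "\n")
print(table(copies$compartment))

npe <- copies[copies$compartment == "NPE", ]
assoc <- associate_genes(npe, gg$genes, gg$exons)
cat("gene associations in the NPE:", nrow(assoc),
    "| copies associated:", length(unique(assoc$copy_id)),
    sprintf("(%.0f%% of NPE copies)",
            100 * length(unique(assoc$copy_id)) / max(1, nrow(npe))), "\n")
print(table(assoc$region))

tabs <- summarize_tables(copies, map, gg$genes)
dir.create("results", showWarnings = FALSE)
for (nm in names(tabs))
  if (!is.null(tabs[[nm]]))
    write_tsv(tabs[[nm]], file.path("results", paste0("table_", nm, ".tsv")))
write_tsv(assoc, "results/gene_associations.tsv")
write_tsv(copies, "results/copies_context.tsv")

# windowed density profile of the first arm + mock breakpoint neighborhood
arm <- copies$arm[1]
arm_len <- max(map$end[map$arm == arm])
w <- windowed_density(copies[copies$arm == arm, ], arm_len, 50000)
write_tsv(w, "results/windowed_density.tsv")
bp <- round(c(0.45, 0.85) * arm_len)
bn <- suppressWarnings(breakpoint_neighborhood_density(
  copies[copies$arm == arm, c("start", "end")], arm_len, bp))
write_tsv(bn, "results/breakpoint_density.tsv")
cat("density profile:", arm, "in", nrow(w), "windows of 50 kb;",
    "breakpoint regions at", paste(bp, collapse = "/"), "\n")
cat("wrote overview tables under results/\n")
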