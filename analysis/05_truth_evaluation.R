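#!/usr/bin/env Rscript
# Stage 5: evaluation against the planted ground truth.
#
# Matches annotated copies to the manifest (same family, >= 90% interval
# overlap) and reports detection recall/precision, condition and
# fragmentation accuracy, structural-event recovery and divergence bias.
# Writes results/evaluation.tsv.

library(ltrscape)

truth <- read_tsv("results/sim/truth.tsv")
copies <- read_tsv("results/copies_context.tsv")
copies$divergence <- suppressWarnings(as.numeric(copies$divergence_pct)) / 100

m <- rep(NA_integer_, nrow(truth))
for (i in seq_len(nrow(truth))) {
  tr <- truth[i, ]
  same <- which(copies$arm == tr$arm & copies$family == tr$family)
  if (!length(same)) next
  ov <- pmin(copies$end[same], tr$end) - pmax(copies$start[same], tr$start) + 1
  best <- which.max(ov)
  if (ov[best] >= 0.9 * (tr$end - tr$start + 1)) m[i] <- same[best]
}

qual <- truth$end - truth$start + 1 >= 500 & truth$target_divergence <= 0.05
idx <- which(!is.na(m) & truth$target_divergence <= 0.05)
pred <- copies$condition[m[idx]]
tru <- ifelse(truth$planted_condition[idx] == "solo-LTR", "solo-LTR", "proviral")
pidx <- idx[truth$planted_condition[idx] != "solo-LTR"]
tfrag <- ifelse(truth$n_indels[pidx] >= 3, "highly-fragmented",
         ifelse(truth$n_indels[pidx] >= 1, "moderately-fragmented",
         ifelse(truth$has_n_gap[pidx], "unknown", "complete")))
sel <- which(!is.na(m) & truth$n_indels == 0 & !truth$has_n_gap &
             truth$end - truth$start + 1 >= 1000)
bias <- copies$divergence[m[sel]] - truth$true_divergence[sel]

ev <- data.frame(
  metric = c("recall_500bp_5pct", "precision", "condition_accuracy",
             "fragmentation_accuracy", "divergence_bias_pp"),
  value = c(mean(!is.na(m[qual])),
            length(unique(m[!is.na(m)])) / nrow(copies),
            mean(pred == tru),
            mean(copies$fragmentation[m[pidx]] == tfrag),
            100 * mean(bias, na.rm = TRUE)),
  n = c(sum(qual), nrow(copies), length(idx), length(pidx), length(sel)))
print(ev, digits = 4)
write_tsv(ev, "results/evaluation.tsv")
cat("wrote results/evaluation.tsv\n")
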