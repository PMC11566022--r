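#!/usr/bin/env Rscript
# Steady-state derepression: NB Wald contrast of knockout vs control
# RNA-seq, the nested derepression classes, and the KS comparison of
# target vs control fold-change distributions.

source("analysis/00_config.R")

report <- run_all(study_config())
ct <- report$contrast
cls <- report$derepression_classes

targets <- report$hc_transcripts
message(sprintf(
  "of %d high-confidence targets: %d increased, %d significant (FDR < 0.01), %d >= 1.5-fold",
  length(targets),
  sum(targets %in% cls$increased),
  sum(targets %in% cls$significant),
  sum(targets %in% cls$strong)))
message(sprintf("target vs control KS: D = %.3f, p = %.3g",
                report$ks_derepression$statistic,
                report$ks_derepression$p_value))

out <- results_dir("expression")
write_tsv(ct, file.path(out, "contrast.tsv"))
write_tsv(data.frame(
  gene = targets,
  log2fc = ct$log2fc[match(targets, ct$gene)],
  q = ct$q[match(targets, ct$gene)],
  significant = targets %in% cls$significant,
  strong = targets %in% cls$strong),
  file.path(out, "target_derepression.tsv"))
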