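#!/usr/bin/env Rscript
# Downstream models: does losing the focal piRNAs change translational
# efficiency of their targets (it should not), and how does RNA polymerase
# II density differ between target classes.

source("analysis/00_config.R")

report <- run_all(study_config())

message(sprintf(
  "delta-TE (knockout/control), %d genes: median %.3f; target-vs-control KS p = %.3g",
  length(report$delta_te), median(report$delta_te), report$ks_te$p_value))

out <- results_dir("downstream")
write_tsv(data.frame(gene = names(report$delta_te),
                     delta_te = report$delta_te),
          file.path(out, "delta_te.tsv"))
write_tsv(data.frame(gene = names(report$density),
                     ppm_per_kb = report$density),
          file.path(out, "polII_density.tsv"))

if (!is.null(report$gro_foldchange))
  message(sprintf(
    "polII density, targets <= 1.25-fold vs >= 1.25-fold derepressed: medians %.0f vs %.0f ppm/kb (MW p = %.3g)",
    report$gro_foldchange$median_a, report$gro_foldchange$median_b,
    report$gro_foldchange$test$p_value))
if (!is.null(report$gro_target))
  message(sprintf(
    "polII density, targets vs non-targets (> 5 copies/cell): medians %.0f vs %.0f ppm/kb (MW p = %.3g)",
    report$gro_target$median_a, report$gro_target$median_b,
    report$gro_target$test$p_value))
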