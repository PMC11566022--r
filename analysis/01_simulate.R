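#!/usr/bin/env Rscript
# Generate the synthetic study: two genotypes (control and a knockout of
# the two focal piRNA loci) x four replicates, with planted cleavage
# targets, and write every assay table plus the ground truth.

source("analysis/00_config.R")

world <- generate_world(study_config())
print(world)

out <- results_dir("simulated")
for (assay in c("transcripts", "rnaseq", "degradome", "ribo", "groseq",
                "truth"))
  emit_reads(world, assay, out)
emit_reads(world, "smallrna", out, depth = 200000L)
write_sim_config(world$config, file.path(out, "sim_config.yaml"))
write_tsv(world$pirnas, file.path(out, "pirnas.tsv"))
write_tsv(world$rates, file.path(out, "rates.tsv"))

tt <- world$truth_targets
message(sprintf(
  "planted %d targets (%d driven by focal-locus piRNAs); tier mix: %s",
  nrow(tt), sum(tt$focal_guide),
  paste(names(table(tt$tier)), table(tt$tier), sep = "=", collapse = " ")))
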