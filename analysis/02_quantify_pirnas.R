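#!/usr/bin/env Rscript
# Absolute piRNA quantification from the UMI-tagged small-RNA reads:
# deduplicate, calibrate against the nine equimolar spike-ins, group by
# 5' 25-nt prefix, apply the 1-ppm detection filter, and convert to
# molecules per cell and pM.

source("analysis/00_config.R")

world <- generate_world(study_config())
fastq <- file.path("results", "simulated", "smallrna_control.fastq")
if (!file.exists(fastq))
  fastq <- emit_reads(world, "smallrna", results_dir("simulated"),
                      depth = 200000L)

reads <- Biostrings::readDNAStringSet(fastq, format = "fastq")
counts <- deduplicate(as.character(reads))
message(length(reads), " reads -> ", sum(counts), " deduplicated molecules (",
        attr(counts, "skipped"), " too short)")

cal <- calibrate(counts, world$config$spike_in)
message(sprintf("spike calibration: %.3f molecules per read", cal$scale))

groups <- group_by_prefix(cal$table[!cal$table$is_spike,
                                    c("sequence", "count", "ppm")])
groups$molecules_per_cell <- ppm_to_molecules(
  groups$ppm, world$config$total_pirnas_per_cell)
groups$pM <- molecules_to_pM(groups$molecules_per_cell,
                             world$config$cell_volume_um3)
groups$detectability <- detectability_probability(groups$molecules_per_cell)

# replicate-level detection uses the count tables (the FASTQ is one library)
sr_ppm <- sweep(world$counts$smallrna, 2, colSums(world$counts$smallrna),
                "/") * 1e6
rep_tab <- data.frame(prefix = substr(world$pirnas$sequence, 1, 25), sr_ppm)
rep_groups <- apply_detection_filter(
  rep_tab, paste0("control_", 1:world$config$n_replicates))
message(nrow(rep_groups), " of ", nrow(rep_tab),
        " piRNA prefix groups detected at >= 1 ppm in every control replicate")

write_tsv(groups, file.path(results_dir("smallrna"), "prefix_groups.tsv"))
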