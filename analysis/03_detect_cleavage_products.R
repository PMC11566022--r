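#!/usr/bin/env Rscript
# Degradome processing: 5'-monophosphorylated RNA species per genotype and
# replicate, the 0.1-ppm detection threshold, and genotype dependence of
# each putative 3' cleavage product.

source("analysis/00_config.R")

world <- generate_world(study_config())
n_rep <- world$config$n_replicates
ctrl <- paste0("control_", seq_len(n_rep))
mut <- paste0("mutant_", seq_len(n_rep))

deg <- world$counts$degradome
ppm <- sweep(as.matrix(deg[, c(ctrl, mut)]), 2,
             colSums(deg[, c(ctrl, mut)]), "/") * 1e6
species <- cbind(deg[, c("transcript_id", "position", "unambiguous")], ppm)
message(nrow(species), " 5'-end species (",
        sum(!species$unambiguous), " ambiguous, excluded)")
species <- species[species$unambiguous, ]

detected <- rowSums(species[, ctrl] >= 0.1) > 0
message(sum(detected), " species detected at >= 0.1 ppm in a control replicate")
products <- species[detected, ]

products$dependence <- vapply(seq_len(nrow(products)), function(i)
  genotype_dependence(as.numeric(products[i, ctrl]),
                      as.numeric(products[i, mut]), mode = "absent"),
  character(1))
products$dependence_fold8 <- vapply(seq_len(nrow(products)), function(i)
  genotype_dependence(as.numeric(products[i, ctrl]),
                      as.numeric(products[i, mut]), mode = "fold8"),
  character(1))
print(table(products$dependence))

out <- results_dir("degradome")
write_tsv(products, file.path(out, "cleavage_products.tsv"))
cp <- products
class(cp) <- c("cleavage_products", "data.frame")
cp$ppm <- rowMeans(cp[, ctrl])
write_cleavage_bed(cp, file.path(out, "cleavage_sites.bed"))
message("wrote ", file.path(out, "cleavage_sites.bed"))
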