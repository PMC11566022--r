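# Shared settings for the analysis scripts. Every script regenerates the
# synthetic world from this configuration (generation is deterministic and
# takes well under a second), so the scripts can be run independently or in
# order.

library(pisliceR)

STUDY_SEED <- 1L
study_config <- function() sim_config(seed = STUDY_SEED)

results_dir <- function(...) {
  d <- file.path("results", ...)
  if (!dir.exists(d)) dir.create(d, recursive = TRUE)
  d
}

write_tsv <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  message("wrote ", path)
}
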