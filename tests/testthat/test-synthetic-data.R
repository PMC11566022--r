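# Synthetic world: determinism, steady-state arithmetic, planted-site
# geometry, tier mix, knockout structure, and file round trips.

test_that("identical configurations generate identical worlds", {
  w1 <- generate_world(sim_config(seed = 123, n_transcripts = 40L,
                                  n_loci = 4L, n_pirnas_per_locus = 10L))
  w2 <- generate_world(sim_config(seed = 123, n_transcripts = 40L,
                                  n_loci = 4L, n_pirnas_per_locus = 10L))
  expect_identical(w1$transcripts, w2$transcripts)
  expect_identical(w1$truth_targets, w2$truth_targets)
  expect_identical(w1$counts, w2$counts)
})

test_that("steady-state fold change follows (k_dec + k_slice) / k_dec", {
  # k_slice forced equal to k_dec: expected knockout/control fold change 2
  cfg <- sim_config(seed = 5, n_transcripts = 60L,
                    k_dec_range = c(0.5, 0.5), k_slice_range = c(0.5, 0.5))
  w <- generate_world(cfg)
  lost <- w$truth_targets$transcript_id[w$truth_targets$lost_in_mutant]
  expect_gt(length(lost), 0)
  idx <- match(lost, w$rates$transcript_id)
  expect_equal(w$rates$expected_log2fc[idx], rep(1, length(lost)))
  # planted targets kept in the mutant (non-focal guides) do not change
  kept <- setdiff(w$truth_targets$transcript_id, lost)
  expect_true(all(w$rates$expected_log2fc[
    match(kept, w$rates$transcript_id)] == 0))

  # no planted targets: no fold changes, degradome is background only
  w0 <- generate_world(sim_config(seed = 5, frac_planted_targets = 0))
  expect_true(all(w0$rates$expected_log2fc == 0))
  expect_true(all(w0$counts$degradome$type == "background"))
})

test_that("planted tier counts match the tier mix within multinomial error", {
  w <- default_world()   # seed 1, 200 transcripts, equal tier mix
  counts <- table(factor(w$truth_targets$tier, levels = c("R1", "R2", "R3", "R4")))
  expect_equal(sum(counts), 60)
  gof <- suppressWarnings(chisq.test(counts, p = rep(0.25, 4)))
  expect_gt(gof$p.value, 1e-3)
})

test_that("planted sites satisfy exactly the requested geometry when re-scanned", {
  set.seed(99)
  tx <- paste(sample(c("A", "C", "G", "T"), 400, replace = TRUE), collapse = "")
  guide <- paste(sample(c("A", "C", "G", "T"), 26, replace = TRUE), collapse = "")

  planted <- plant_target_site(guide, tx, "R2")
  pr <- align_guide_at_site(guide, planted$transcript, planted$position)
  expect_true(is_contiguous(pr, 3, 15))
  expect_false(pr$match[2]); expect_false(pr$match[16])

  # R1 minimal example: exactly 20 paired within g2-g25, no contiguous core
  planted1 <- plant_target_site(guide, tx, "R1")
  pr1 <- align_guide_at_site(guide, planted1$transcript, planted1$position)
  expect_equal(paired_in(pr1, 2, 25), 20)
  expect_false(is_contiguous(pr1, 3, 15))
  v <- satisfies_tier(pr1, 100)
  expect_identical(v$satisfied_rules, "R1")

  # determinism of the planted coordinate
  set.seed(7); a <- plant_target_site(guide, tx, "R4")
  set.seed(7); b <- plant_target_site(guide, tx, "R4")
  expect_identical(a$position, b$position)

  expect_error(plant_target_site(guide, "ACGT", "R1"), "too short")
})

test_that("every planted site passes its tier against its own guide (closure)", {
  w <- default_world()
  tt <- w$truth_targets
  for (i in seq_len(nrow(tt))) {
    guide <- w$pirnas$sequence[w$pirnas$guide_id == tt$guide_id[i]]
    ppm <- w$pirnas$ppm_true[w$pirnas$guide_id == tt$guide_id[i]]
    pr <- align_guide_at_site(guide, w$transcripts[[tt$transcript_id[i]]],
                              tt$position[i])
    expect_true(tt$tier[i] %in% satisfies_tier(pr, ppm)$satisfied_rules)
  }
})

test_that("knocked-out loci have zero small-RNA reads in the mutant", {
  w <- default_world()
  focal_rows <- w$pirnas$locus %in% w$focal_loci
  mut <- w$counts$smallrna[, paste0("mutant_", 1:4)]
  expect_true(all(mut[focal_rows, ] == 0))
  expect_gt(sum(w$counts$smallrna[focal_rows, "control_1"]), 0)
})

test_that("count tables have the configured depth and round-trip through files", {
  w <- default_world()
  cs <- colSums(w$counts$degradome[, paste0(rep(c("control", "mutant"), each = 4),
                                            "_", 1:4)])
  expect_true(all(abs(cs - 1e6) < 5 * sqrt(1e6) * sqrt(1 + 0.05 * 1e4)))
  dir <- withr::local_tempdir()
  emit_reads(w, "rnaseq", dir)
  back <- read_count_table(file.path(dir, "rnaseq_counts.tsv"))
  expect_equal(back, w$counts$rnaseq)
  emit_reads(w, "transcripts", dir)
  fa <- Biostrings::readDNAStringSet(file.path(dir, "transcripts.fasta"))
  expect_equal(as.character(fa), w$transcripts)
  expect_error(emit_reads(w, "nonsense", dir), "unknown assay")
})

test_that("configuration validation and YAML round trip", {
  expect_error(sim_config(depth = 0), "depth")
  expect_error(sim_config(tier_mix = c(R1 = 0.5, R2 = 0.2)), "tier_mix")
  expect_error(sim_config(k_dec_range = c(0, 1)), "rates")
  expect_error(sim_config(n_replicates = 0), "replicate")

  cfg <- sim_config(seed = 9, n_transcripts = 33L, nb_dispersion = 0.02)
  path <- withr::local_tempfile(fileext = ".yaml")
  write_sim_config(cfg, path)
  cfg2 <- read_sim_config(path)
  expect_equal(cfg2$n_transcripts, 33L)
  expect_equal(cfg2$nb_dispersion, 0.02)
  expect_equal(cfg2$spike_in$sequence, cfg$spike_in$sequence)
  expect_identical(generate_world(cfg)$truth_targets,
                   generate_world(cfg2)$truth_targets)
})

test_that("estimated fold changes are calibrated against the planted truth", {
  w <- default_world()
  rn <- w$counts$rnaseq
  genes <- !(rownames(rn) %in% w$spike_rna$name)
  ct <- nb_contrast(rn[genes, ], paste0("control_", 1:4), paste0("mutant_", 1:4))
  tt <- w$truth_targets[w$truth_targets$lost_in_mutant, ]
  truth <- setNames(w$rates$expected_log2fc, w$rates$transcript_id)
  err <- ct$log2fc[match(tt$transcript_id, ct$gene)] - truth[tt$transcript_id]
  # NB noise floor: SE of a log2 ratio of n-replicate means at dispersion
  # phi and mean depth mu is sqrt(2 * (phi + 1/mu) / n) / ln 2
  mu <- ct$mean_a[match(tt$transcript_id, ct$gene)]
  se <- sqrt(2 * (w$config$nb_dispersion + 1 / mu) / w$config$n_replicates) /
    log(2)
  expect_gt(mean(abs(err) < 2 * se), 0.9)
})
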