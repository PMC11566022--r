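# UMI deduplication, spike-in calibration, prefix grouping, detection
# thresholds, and unit conversions.

test_that("deduplication counts unique insert/UMI-pair combinations", {
  u1 <- strrep("A", 9); u2 <- strrep("C", 9)
  insert <- "GGGTTTCCCAAAGGGTTTCCCAAAGGGTTT"
  # identical inserts with the identical UMI pair collapse to one
  r <- deduplicate(c(paste0(u1, insert, u2), paste0(u1, insert, u2)))
  expect_equal(unname(r[insert]), 1L)
  # different UMIs count separately
  r2 <- deduplicate(c(paste0(u1, insert, u2), paste0(u2, insert, u1)))
  expect_equal(unname(r2[insert]), 2L)
  # too-short reads are skipped and tallied
  r3 <- deduplicate(c(paste0(u1, insert, u2), "ACGTACGT"))
  expect_equal(attr(r3, "skipped"), 1L)
})

test_that("PCR amplification of known molecules is collapsed to the molecules sampled", {
  set.seed(31)
  n_mol <- 100L
  mol_insert <- rep(paste(sample(c("A", "C", "G", "T"), 30, replace = TRUE),
                          collapse = ""), n_mol)
  mol_umi5 <- rand_dna_fixture(n_mol, 9)
  mol_umi3 <- rand_dna_fixture(n_mol, 9)
  picked <- sample.int(n_mol, 1000L, replace = TRUE)   # PCR resampling
  reads <- paste0(mol_umi5[picked], mol_insert[picked], mol_umi3[picked])
  r <- deduplicate(reads)
  # in the 4^18 UMI space collisions are vanishingly rare: the deduplicated
  # count equals the number of distinct molecules sampled
  expect_equal(sum(r), length(unique(picked)))
  expect_lte(sum(r), n_mol)
})

test_that("spike-in calibration yields molecules per read and leaves ppm scale-invariant", {
  spikes <- spike_in_set(paste0("s", 1:9), vapply(1:9, function(i)
    strrep(c("ACGT", "TGCA", "GATC")[i %% 3 + 1], 8), character(1)),
    rep(100, 9))
  counts <- setNames(c(rep(100L, 9), 500L, 300L),
                     c(spikes$sequence, "AAACCCGGGTTTAAACCCGGGTTTAAA",
                       "TTTGGGCCCAAATTTGGGCCCAAATTT"))
  cal <- calibrate(counts, spikes)
  expect_equal(cal$scale, 1.0)   # 900 reads for 900 molecules
  expect_equal(cal$table$ppm[!cal$table$is_spike],
               c(500, 300) / 800 * 1e6)
  # doubling all counts: scale halves, ppm unchanged
  cal2 <- calibrate(counts * 2L, spikes)
  expect_equal(cal2$table$ppm, cal$table$ppm)
  expect_equal(cal2$scale, 0.5)
  # no spike reads -> calibration error
  expect_error(calibrate(counts[10:11], spikes), "calibration")
})

test_that("prefix grouping sums abundance and picks the right representative", {
  prefix <- strrep("ACGTA", 5)
  tab <- data.frame(
    sequence = c(paste0(prefix, "AAA"), paste0(prefix, "G"), prefix,
                 paste0("T", substr(prefix, 1, 27))),
    count = c(50L, 30L, 20L, 10L),
    ppm = c(5, 3, 2, 1),
    stringsAsFactors = FALSE
  )
  g <- group_by_prefix(tab)
  expect_equal(nrow(g), 2L)
  i <- which(g$prefix == prefix)
  expect_equal(g$ppm[i], 10)
  expect_equal(g$representative[i], paste0(prefix, "AAA"))
  expect_equal(g$n_members[i], 3L)

  # tie on count: lexicographically smaller member wins, independent of
  # input order
  tie <- data.frame(sequence = c(paste0(prefix, "T"), paste0(prefix, "C")),
                    count = c(4L, 4L), ppm = c(4, 4), stringsAsFactors = FALSE)
  for (ord in list(1:2, 2:1)) {
    gt <- group_by_prefix(tie[ord, ])
    expect_equal(gt$representative, paste0(prefix, "C"))
  }

  # short inserts are discarded and tallied
  short <- data.frame(sequence = "ACGT", count = 5L, ppm = 5,
                      stringsAsFactors = FALSE)
  gs <- group_by_prefix(short)
  expect_equal(nrow(gs), 0L)
  expect_equal(attr(gs, "discarded"), 1L)
})

test_that("detection thresholds are inclusive", {
  g <- data.frame(prefix = c("a", "b"), c1 = c(1.0, 0.9), c2 = c(1.2, 5),
                  c3 = c(3.0, 5))
  kept <- apply_detection_filter(g, c("c1", "c2", "c3"))
  expect_equal(kept$prefix, "a")
  expect_equal(nrow(apply_detection_filter(g[0, ], c("c1", "c2", "c3"))), 0L)

  expect_true(is_undetectable_in_mutant(c(0.05, 0.05)))
  expect_true(is_undetectable_in_mutant(c(0.1, 0.1)))     # inclusive
  expect_false(is_undetectable_in_mutant(c(0.2, 0.2)))
})

test_that("unit conversions reproduce the per-cell arithmetic", {
  expect_equal(ppm_to_molecules(1, 1e7), 10)
  expect_equal(ppm_to_molecules(50, 1e7), 500)
  pm1 <- molecules_to_pM(1, 1800)
  expect_equal(pm1, 1 / (1.8e-12 * 6.02214076e23) * 1e12, tolerance = 1e-12)
  expect_equal(round(pm1), 1)    # ~1 pM per molecule
  # round trip to machine precision
  x <- c(0.3, 1, 47.2)
  expect_equal(pM_to_molecules(molecules_to_pM(x)), x, tolerance = 1e-12)
  expect_error(ppm_to_molecules(1, 0))
  expect_error(molecules_to_pM(1, -5))
})

test_that("detectability follows the Poisson and NB closed forms", {
  expect_equal(detectability_probability(10), 1 - exp(-10), tolerance = 1e-12)
  expect_gte(detectability_probability(10), 0.9999)
  expect_equal(detectability_probability(0), 0)
  expect_equal(detectability_probability(log(2)), 0.5, tolerance = 1e-12)
  # overdispersion can only lower detectability at the same mean
  expect_lt(detectability_probability(3, "nb", dispersion = 0.5),
            detectability_probability(3))
  expect_error(detectability_probability(-1))
})

test_that("simulated reads round-trip to piRNA abundances", {
  w <- default_world()
  dir <- withr::local_tempdir()
  small <- emit_reads(w, "smallrna", file.path(dir, "a"), depth = 10000L)
  reads10k <- Biostrings::readDNAStringSet(small, format = "fastq")
  expect_equal(length(reads10k), 10000L)
  inserts_len <- Biostrings::width(reads10k) - 18L
  expect_true(all(inserts_len >= 14 & inserts_len <= 54))

  path <- emit_reads(w, "smallrna", file.path(dir, "b"), depth = 200000L)
  reads <- Biostrings::readDNAStringSet(path, format = "fastq")
  counts <- deduplicate(as.character(reads))
  cal <- calibrate(counts, w$config$spike_in)
  groups <- group_by_prefix(cal$table[!cal$table$is_spike,
                                      c("sequence", "count", "ppm")])
  # recovered ppm vs generator truth for well-expressed guides
  truth_prefix <- substr(w$pirnas$sequence, 1, 25)
  truth_ppm <- tapply(w$pirnas$ppm_true, truth_prefix, sum)
  common <- intersect(names(truth_ppm)[truth_ppm >= 200], groups$prefix)
  expect_gt(length(common), 20)
  rel_err <- abs(groups$ppm[match(common, groups$prefix)] -
                   truth_ppm[common]) / truth_ppm[common]
  expect_lt(median(rel_err), 0.15)
})

test_that("count-table quantification recovers generator pM within tolerance", {
  w <- default_world()
  ppm <- sweep(w$counts$smallrna, 2, colSums(w$counts$smallrna), "/") * 1e6
  est_ppm <- rowMeans(ppm[, paste0("control_", 1:4)])
  truth <- w$pirnas$ppm_true
  sel <- truth >= 10
  est_pm <- molecules_to_pM(ppm_to_molecules(est_ppm[sel]))
  truth_pm <- molecules_to_pM(ppm_to_molecules(truth[sel]))
  rel_err <- abs(est_pm - truth_pm) / truth_pm
  expect_lt(median(rel_err), 0.15)
  expect_gt(cor(est_pm, truth_pm, method = "spearman"), 0.95)
  # retained ppm cannot exceed the library total
  expect_true(all(colSums(ppm) <= 1e6 + 1e-6))
})
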