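# Target calling: brute-force oracle equivalence, exclusivity and
# confidence filters, control targets, permutation summaries.

test_that("the vectorized scan matches a brute-force scorer over all windows", {
  set.seed(4)
  transcripts <- setNames(rand_dna_fixture(3, 500), c("ta", "tb", "tc"))
  guides <- rand_dna_fixture(18, 28)
  ppm <- c(rep(c(0.5, 2, 7, 20, 100), 3), 100, 100, 100)
  # plant sites so that true calls exist across all tiers
  for (i in 1:6) {
    id <- c("ta", "tb", "tc")[(i - 1) %% 3 + 1]
    pl <- plant_target_site(guides[13 + (i - 1) %% 5], transcripts[[id]],
                            c("R1", "R2", "R3", "R4")[(i - 1) %% 4 + 1])
    transcripts[[id]] <- pl$transcript
  }
  groups <- data.frame(guide_id = paste0("g", 1:18),
                       locus = rep(c("locusA", "locusB"), 9),
                       sequence = guides, ppm = ppm, stringsAsFactors = FALSE)
  products <- do.call(rbind, lapply(names(transcripts), function(id)
    data.frame(transcript_id = id, position = 0:499)))
  got <- scan_transcriptome(groups, products, transcripts)
  want <- brute_force_calls(groups, products, transcripts)
  key <- function(d) sort(paste(d$guide_id, d$transcript_id, d$position, d$rules))
  expect_gt(nrow(want), 0)
  expect_identical(key(got), key(want))
})

test_that("scan recovers every planted target in the default world", {
  rep <- default_report()
  w <- default_world()
  tt <- w$truth_targets
  called <- paste(rep$calls$guide_id, rep$calls$transcript_id,
                  rep$calls$position)
  planted <- paste(tt$guide_id, tt$transcript_id, tt$position)
  expect_true(all(planted %in% called))
  # no guides or no products: empty result
  expect_equal(nrow(scan_transcriptome(
    rep$groups[0, c("guide_id", "locus", "sequence", "ppm")],
    rep$products, w$transcripts)), 0L)
  expect_error(scan_transcriptome(
    data.frame(guide_id = "g", locus = "l", sequence = "ACGT", ppm = 10),
    data.frame(transcript_id = "nope", position = 5L),
    w$transcripts), "not found")
})

test_that("exclusivity requires that no non-focal guide explains the site", {
  calls <- data.frame(
    guide_id = c("f1", "f2", "n1"),
    locus = c("locusA", "locusA", "locusB"),
    ppm = c(10, 10, 10),
    transcript_id = c("t1", "t2", "t2"),
    position = c(100L, 50L, 50L),
    rules = "R3",
    stringsAsFactors = FALSE
  )
  out <- exclusivity_filter(calls, "locusA")
  expect_equal(out$exclusive, c(TRUE, FALSE))

  # a non-focal guide with matching geometry but insufficient abundance is
  # never callable, so the focal call stays exclusive
  s <- make_perfect_site()
  groups <- data.frame(
    guide_id = c("focal", "weak_nonfocal"),
    locus = c("locusA", "locusB"),
    sequence = s$guide, ppm = c(20, 0.5),
    stringsAsFactors = FALSE
  )
  calls2 <- scan_transcriptome(groups,
                               data.frame(transcript_id = "t",
                                          position = s$p),
                               c(t = s$transcript))
  out2 <- exclusivity_filter(calls2, "locusA")
  expect_equal(nrow(out2), 1L)
  expect_true(out2$exclusive)
})

test_that("high confidence needs exclusivity and genotype dependence together", {
  cand <- data.frame(
    guide_id = "g", locus = "locusA", ppm = 10,
    transcript_id = c("t1", "t2", "t3", "t4"),
    position = c(1L, 2L, 3L, 4L), rules = "R2",
    exclusive = c(TRUE, TRUE, FALSE, FALSE),
    stringsAsFactors = FALSE
  )
  dep <- data.frame(
    transcript_id = c("t1", "t2", "t3"),
    position = 1:3,
    dependence = c("dependent", "independent", "dependent"),
    stringsAsFactors = FALSE
  )
  out <- call_high_confidence(cand, dep)
  expect_equal(out$confidence, c("high", "candidate", "candidate", "candidate"))
  # a product missing from the dependence table is treated as undetermined
  expect_false(out$genotype_dependent[4])
})

test_that("control targets are non-focal, biogenesis-independent, present in both genotypes", {
  calls <- data.frame(
    guide_id = c("f", "c", "d", "c2"),
    locus = c("locusA", "locusB", "locusC", "locusB"),
    ppm = 10,
    transcript_id = c("t1", "t2", "t3", "t4"),
    position = 1:4, rules = "R2",
    stringsAsFactors = FALSE
  )
  dep <- data.frame(
    transcript_id = c("t1", "t2", "t3", "t4"), position = 1:4,
    dependence = c("independent", "independent", "independent", "dependent"),
    stringsAsFactors = FALSE
  )
  out <- call_control_targets(calls, dep, focal_loci = "locusA",
                              dependent_loci = "locusC")
  expect_equal(out$guide_id, "c")   # focal, dependent-locus, and lost products excluded
})

test_that("permutation summary enumerates all replicate pairings", {
  # identical replicates: constant count, zero IQR
  perm <- permutation_summary(1:4, 1:4, function(ci, mi) 7)
  expect_equal(length(perm$counts), 16L)
  expect_equal(perm$median, 7)
  expect_equal(perm$iqr, 0)
  # 2 x 2 toy: exactly 4 pairings
  perm2 <- permutation_summary(c("a", "b"), c("x", "y"),
                               function(ci, mi) nchar(paste0(ci, mi)))
  expect_equal(length(perm2$counts), 4L)
})

test_that("planted focal targets are recovered with high precision and recall", {
  rep <- default_report()
  w <- default_world()
  truth_focal <- unique(
    w$truth_targets$transcript_id[w$truth_targets$focal_guide])
  recall <- mean(truth_focal %in% rep$hc_transcripts)
  precision <- mean(rep$hc_transcripts %in% truth_focal)
  expect_gte(recall, 0.9)
  expect_gte(precision, 0.95)
  # permutation median within 10% of the planted focal count
  expect_lte(abs(rep$permutation$median - length(truth_focal)),
             0.1 * length(truth_focal))
  # fraction of guides with a planted target tracks the planted fraction
  n_guides_with_target <- length(unique(w$truth_targets$guide_id))
  called_guides <- length(unique(
    rep$calls$guide_id[paste(rep$calls$guide_id, rep$calls$transcript_id,
                             rep$calls$position) %in%
                         paste(w$truth_targets$guide_id,
                               w$truth_targets$transcript_id,
                               w$truth_targets$position)]))
  expect_equal(called_guides, n_guides_with_target)
})
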