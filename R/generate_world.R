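# Synthetic study generator. Produces a complete two-genotype experiment
# (control vs knockout of the focal piRNA loci) with planted cleavage
# targets, so that every downstream stage -- quantification, degradome
# thresholding, tiered target calling, expression/translation/transcription
# contrasts -- can be tested against known ground truth.
#
# The abundance model is a first-order steady state: transcript abundance is
# k_tx / (k_dec + k_slice) in the control and k_tx / k_dec once the slicing
# guide is lost, so the expected derepression of a planted target is
# 1 + k_slice / k_dec. Degradome abundance of a planted 3' cleavage product
# is proportional to the slicing flux k_slice * steady-state abundance.
# GRO-seq signal is proportional to k_tx per kb with Poisson noise; all
# other count tables draw negative-binomial noise around expected library
# proportions.

rand_dna <- function(n, len) {
  vapply(len, function(l)
    paste(sample(c("A", "C", "G", "T"), l, replace = TRUE), collapse = ""),
    character(1))
}

# paired / forced-mismatch guide positions per tier rule. Mismatches are
# placed so the planted site satisfies exactly the requested geometry and
# violates the stricter contiguous windows (R3 necessarily also satisfies
# the R2 window, which it contains).
tier_geometry <- function(tier) {
  switch(tier,
    R1 = list(paired = c(2:11, 16:25), mismatch = c(1L, 12:15, 26:30)),
    R2 = list(paired = 3:15, mismatch = c(1:2, 16:30)),
    R3 = list(paired = 3:16, mismatch = c(1:2, 17:30)),
    R4 = list(paired = 4:17, mismatch = c(1:3, 18:30)),
    stop("unknown tier: ", tier)
  )
}

#' Plant a cleavage site for a guide into a transcript
#'
#' Overwrites a 30-nt window of the transcript so that the guide pairs to it
#' with exactly the geometry of the requested tier rule: the rule's window
#' positions are set to the Watson-Crick complement of the guide and the
#' flanking positions are forced to mismatch (the target base is set equal
#' to the guide base, which can never pair, wobble included). The cleavage
#' register places the 5' end of the 3' product opposite guide position g10.
#'
#' @param guide guide sequence (26-30 nt).
#' @param transcript transcript sequence (character).
#' @param tier one of `"R1"`, `"R2"`, `"R3"`, `"R4"`.
#' @param position 0-based cleavage coordinate; sampled uniformly from the
#'   positions where the full site window fits when `NULL`.
#' @return list with `transcript` (modified sequence) and `position`
#'   (0-based coordinate of the 3'-product 5' end).
#' @export
plant_target_site <- function(guide, transcript, tier, position = NULL) {
  g <- seq_chars(guide)
  tx <- seq_chars(transcript)
  L <- length(tx)
  if (L < 31L) stop("transcript too short for a 30-nt site")
  # guide k pairs coordinate position + 10 - k; k in 1..30 needs
  # position - 20 >= 0 and position + 9 <= L - 1
  if (is.null(position)) {
    lo <- 20L
    hi <- L - 10L
    position <- if (hi > lo) sample(lo:hi, 1L) else lo
  }
  if (position < 20L || position > L - 10L)
    stop("site window does not fit the transcript at this position")
  geom <- tier_geometry(tier)
  for (k in geom$paired) {
    if (k > length(g)) stop("guide too short for tier geometry")
    tx[position + 11L - k] <- unname(DNA_COMPLEMENT[g[k]])
  }
  for (k in geom$mismatch) {
    if (k > length(g)) next
    idx <- position + 11L - k
    if (idx >= 1L && idx <= L) tx[idx] <- g[k]
  }
  list(transcript = paste(tx, collapse = ""), position = position)
}

nb_counts <- function(mu, n_rep, dispersion, colnames_prefix) {
  m <- vapply(seq_len(n_rep), function(i)
    rnbinom(length(mu), mu = mu, size = 1 / dispersion), numeric(length(mu)))
  colnames(m) <- paste0(colnames_prefix, "_", seq_len(n_rep))
  m
}

#' Generate a synthetic study with planted piRNA targets
#'
#' See the package vignette for the full model. Identical configurations
#' (including the seed) produce identical worlds.
#'
#' @param config a [sim_config()].
#' @return object of class `synthetic_world`: a list with `config`,
#'   `transcripts` (named character vector), `regions` (0-based half-open
#'   5'UTR/CDS/3'UTR intervals), `pirnas`, `truth_targets`, `rates`,
#'   `spike_rna` (RNA-seq spike truth), and `counts` (matrices/data frames
#'   for `rnaseq`, `smallrna`, `smallrna_spikes`, `degradome`, `ribo`,
#'   `groseq`).
#' @export
generate_world <- function(config) {
  validate_sim_config(config)
  set.seed(config$seed)
  n_rep <- config$n_replicates
  phi <- config$nb_dispersion

  ## transcripts and region annotation
  tx_ids <- sprintf("tx%04d", seq_len(config$n_transcripts))
  tx_len <- sample(900:3000, config$n_transcripts, replace = TRUE)
  transcripts <- setNames(rand_dna(config$n_transcripts, tx_len), tx_ids)
  utr5_end <- pmax(50L, round(0.1 * tx_len))
  cds_end <- round(0.7 * tx_len)
  regions <- data.frame(
    transcript_id = rep(tx_ids, each = 3L),
    region = rep(c("5UTR", "CDS", "3UTR"), config$n_transcripts),
    start = as.integer(rbind(0L, utr5_end, cds_end)),
    end = as.integer(rbind(utr5_end, cds_end, tx_len)),
    stringsAsFactors = FALSE
  )

  ## piRNA population
  loci <- sprintf("locus%02d", seq_len(config$n_loci))
  focal_loci <- loci[seq_len(config$n_focal_loci)]
  dependent_loci <- if (config$n_loci > config$n_focal_loci + 1L)
    loci[config$n_loci] else character(0)
  n_guides <- config$n_loci * config$n_pirnas_per_locus
  guide_ids <- sprintf("piR%04d", seq_len(n_guides))
  guide_locus <- rep(loci, each = config$n_pirnas_per_locus)
  guide_len <- sample(26:30, n_guides, replace = TRUE)
  guide_seq <- rand_dna(n_guides, guide_len)
  rel <- rlnorm(n_guides, config$pirna_abundance[["meanlog"]],
                config$pirna_abundance[["sdlog"]])
  ppm_true <- rel / sum(rel) * 1e6
  lost <- guide_locus %in% c(focal_loci, dependent_loci)
  pirnas <- data.frame(
    guide_id = guide_ids, locus = guide_locus, sequence = guide_seq,
    ppm_true = ppm_true,
    repeat_derived = runif(n_guides) < config$frac_repeat_derived,
    focal = guide_locus %in% focal_loci,
    biogenesis_dependent = guide_locus %in% dependent_loci,
    lost_in_mutant = lost,
    stringsAsFactors = FALSE
  )

  ## plant true target sites
  n_planted <- round(config$frac_planted_targets * config$n_transcripts)
  planted_tx <- sample(tx_ids, n_planted)
  tiers <- sample(names(config$tier_mix), n_planted, replace = TRUE,
                  prob = config$tier_mix)
  rules <- tier_rules()
  min_ppm <- setNames(rules$min_ppm, rules$rule)
  truth <- vector("list", n_planted)
  for (i in seq_len(n_planted)) {
    eligible <- which(ppm_true >= min_ppm[[tiers[i]]])
    gi <- if (length(eligible) == 1L) eligible else sample(eligible, 1L)
    planted <- plant_target_site(guide_seq[gi], transcripts[[planted_tx[i]]],
                                 tiers[i])
    transcripts[[planted_tx[i]]] <- planted$transcript
    truth[[i]] <- data.frame(
      guide_id = guide_ids[gi], locus = guide_locus[gi],
      transcript_id = planted_tx[i], position = planted$position,
      tier = tiers[i], focal_guide = guide_locus[gi] %in% focal_loci,
      lost_in_mutant = lost[gi], stringsAsFactors = FALSE
    )
  }
  truth_targets <- if (n_planted > 0L) do.call(rbind, truth) else
    data.frame(guide_id = character(0), locus = character(0),
               transcript_id = character(0), position = integer(0),
               tier = character(0), focal_guide = logical(0),
               lost_in_mutant = logical(0), stringsAsFactors = FALSE)

  ## kinetic rates and steady states
  k_tx <- runif(config$n_transcripts, config$k_tx_range[1], config$k_tx_range[2])
  k_dec <- runif(config$n_transcripts, config$k_dec_range[1], config$k_dec_range[2])
  k_slice <- numeric(config$n_transcripts)
  pl_idx <- match(truth_targets$transcript_id, tx_ids)
  k_slice[pl_idx] <- runif(n_planted, config$k_slice_range[1],
                           config$k_slice_range[2])
  truth_targets$k_slice <- k_slice[pl_idx]
  ss_control <- k_tx / (k_dec + k_slice)
  sliced_in_mutant <- logical(config$n_transcripts)
  sliced_in_mutant[pl_idx] <- !truth_targets$lost_in_mutant
  ss_mutant <- ifelse(k_slice > 0 & !sliced_in_mutant, k_tx / k_dec, ss_control)
  copies_scale <- 100 / median(ss_control)
  rates <- data.frame(
    transcript_id = tx_ids, length = tx_len, k_tx = k_tx, k_dec = k_dec,
    k_slice = k_slice, ss_control = ss_control, ss_mutant = ss_mutant,
    copies_control = ss_control * copies_scale,
    copies_mutant = ss_mutant * copies_scale,
    expected_log2fc = log2(ss_mutant / ss_control),
    stringsAsFactors = FALSE
  )

  ## RNA-seq counts with ERCC-style spike rows (2-fold dilution series)
  spike_rna_ids <- sprintf("spike_rna_%02d", 1:9)
  spike_copies <- 2^(0:8)
  spike_copies <- spike_copies * 0.03 * sum(rates$copies_control) /
    sum(spike_copies)
  spike_rna <- data.frame(name = spike_rna_ids, copies = spike_copies,
                          stringsAsFactors = FALSE)
  w_ctrl <- c(rates$copies_control, spike_copies)
  w_mut <- c(rates$copies_mutant, spike_copies)
  rnaseq <- cbind(
    nb_counts(w_ctrl / sum(w_ctrl) * config$depth, n_rep, phi, "control"),
    nb_counts(w_mut / sum(w_mut) * config$depth, n_rep, phi, "mutant")
  )
  rownames(rnaseq) <- c(tx_ids, spike_rna_ids)

  ## small-RNA counts per guide, plus spike-in reads
  g_ctrl <- ppm_true
  g_mut <- ifelse(lost, 0, ppm_true)
  g_mut <- if (sum(g_mut) > 0) g_mut / sum(g_mut) * 1e6 else g_mut
  sr_depth <- config$depth * (1 - config$spike_read_frac)
  smallrna <- cbind(
    nb_counts(g_ctrl / 1e6 * sr_depth, n_rep, phi, "control"),
    nb_counts(g_mut / 1e6 * sr_depth, n_rep, phi, "mutant")
  )
  rownames(smallrna) <- guide_ids
  spike_mu <- rep(config$depth * config$spike_read_frac / nrow(config$spike_in),
                  nrow(config$spike_in))
  smallrna_spikes <- cbind(
    nb_counts(spike_mu, n_rep, phi, "control"),
    nb_counts(spike_mu, n_rep, phi, "mutant")
  )
  rownames(smallrna_spikes) <- config$spike_in$name

  ## degradome species: planted 3' cleavage products + background 5' ends
  bg_n <- config$n_background_species
  bg_tx <- sample(tx_ids, bg_n, replace = TRUE)
  bg_pos <- vapply(bg_tx, function(id)
    sample.int(nchar(transcripts[[id]]), 1L) - 1L, integer(1))
  bg_key <- paste(bg_tx, bg_pos)
  planted_key <- paste(truth_targets$transcript_id, truth_targets$position)
  keep_bg <- !(bg_key %in% planted_key) & !duplicated(bg_key)
  bg_tx <- bg_tx[keep_bg]; bg_pos <- bg_pos[keep_bg]
  bg_w <- rlnorm(length(bg_tx), 0, 1)
  planted_w_ctrl <- truth_targets$k_slice *
    rates$ss_control[match(truth_targets$transcript_id, tx_ids)]
  planted_w_mut <- ifelse(truth_targets$lost_in_mutant, 0, planted_w_ctrl)
  bgf <- config$background_degradome_frac
  bg_w <- if (sum(planted_w_ctrl) > 0)
    bg_w / sum(bg_w) * bgf / (1 - bgf) * sum(planted_w_ctrl)
  else bg_w / sum(bg_w)
  w_ctrl_deg <- c(planted_w_ctrl, bg_w)
  w_mut_deg <- c(planted_w_mut, bg_w)
  n_ambig <- min(10L, length(bg_tx))
  ambiguous <- c(rep(FALSE, n_planted),
                 seq_along(bg_tx) %in% seq_len(n_ambig))
  degradome <- data.frame(
    transcript_id = c(truth_targets$transcript_id, bg_tx),
    position = c(truth_targets$position, bg_pos),
    type = c(rep("planted", n_planted), rep("background", length(bg_tx))),
    unambiguous = !ambiguous,
    stringsAsFactors = FALSE
  )
  degradome <- cbind(
    degradome,
    nb_counts(w_ctrl_deg / sum(w_ctrl_deg) * config$depth, n_rep, phi, "control"),
    nb_counts(w_mut_deg / sum(w_mut_deg) * config$depth, n_rep, phi, "mutant")
  )

  ## ribosome footprints: occupancy proportional to mRNA (TE = 1 throughout)
  ribo <- cbind(
    nb_counts(rates$copies_control / sum(rates$copies_control) * config$depth,
              n_rep, phi, "control"),
    nb_counts(rates$copies_mutant / sum(rates$copies_mutant) * config$depth,
              n_rep, phi, "mutant")
  )
  rownames(ribo) <- tx_ids

  ## GRO-seq: polymerase density proportional to k_tx per kb, Poisson noise,
  ## first 500 bp of each gene excluded from the counted interval
  gro_w <- k_tx * pmax(tx_len - 500L, 0L) / 1000
  gro_mu <- gro_w / sum(gro_w) * config$depth
  groseq <- vapply(seq_len(n_rep), function(i) rpois(length(gro_mu), gro_mu),
                   numeric(length(gro_mu)))
  colnames(groseq) <- paste0("control_", seq_len(n_rep))
  rownames(groseq) <- tx_ids

  structure(
    list(
      config = config, transcripts = transcripts, regions = regions,
      pirnas = pirnas, truth_targets = truth_targets, rates = rates,
      spike_rna = spike_rna, focal_loci = focal_loci,
      dependent_loci = dependent_loci,
      counts = list(rnaseq = rnaseq, smallrna = smallrna,
                    smallrna_spikes = smallrna_spikes, degradome = degradome,
                    ribo = ribo, groseq = groseq)
    ),
    class = "synthetic_world"
  )
}

#' @export
print.synthetic_world <- function(x, ...) {
  cat("synthetic_world:", length(x$transcripts), "transcripts,",
      nrow(x$pirnas), "piRNAs from", x$config$n_loci, "loci,",
      nrow(x$truth_targets), "planted targets",
      sprintf("(%d focal)", sum(x$truth_targets$focal_guide)), "\n")
  invisible(x)
}

#' Write one assay of a synthetic world to disk
#'
#' `assay = "smallrna"` writes a FASTQ of UMI-flanked reads (9-nt UMIs at
#' both ends) sampled from the piRNA and spike-in abundances;
#' `"transcripts"` writes a FASTA plus a BED of region annotation; the
#' count-table assays (`"rnaseq"`, `"degradome"`, `"ribo"`, `"groseq"`)
#' write TSV tables; `"truth"` writes the planted-target table.
#'
#' @param world a `synthetic_world`.
#' @param assay one of `"smallrna"`, `"transcripts"`, `"rnaseq"`,
#'   `"degradome"`, `"ribo"`, `"groseq"`, `"truth"`.
#' @param dir output directory (created if missing).
#' @param depth number of FASTQ reads for `assay = "smallrna"`
#'   (default 10,000).
#' @return invisibly, the path(s) written.
#' @export
emit_reads <- function(world, assay, dir, depth = 10000L) {
  stopifnot(inherits(world, "synthetic_world"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  cfg <- world$config
  switch(assay,
    smallrna = {
      path <- file.path(dir, "smallrna_control.fastq")
      inserts <- c(world$pirnas$sequence, cfg$spike_in$sequence)
      w <- c(world$pirnas$ppm_true / 1e6 * (1 - cfg$spike_read_frac),
             rep(cfg$spike_read_frac / nrow(cfg$spike_in), nrow(cfg$spike_in)))
      idx <- sample.int(length(inserts), depth, replace = TRUE, prob = w)
      umi_block <- function() {
        m <- matrix(sample(c("A", "C", "G", "T"), 9L * depth, replace = TRUE),
                    nrow = depth)
        do.call(paste0, as.data.frame(m, stringsAsFactors = FALSE))
      }
      reads <- paste0(umi_block(), inserts[idx], umi_block())
      rs <- Biostrings::DNAStringSet(reads)
      names(rs) <- sprintf("read%06d", seq_len(depth))
      qs <- Biostrings::PhredQuality(
        vapply(nchar(reads), function(n) strrep("I", n), character(1)))
      Biostrings::writeQualityScaledXStringSet(
        Biostrings::QualityScaledDNAStringSet(rs, qs), path)
      invisible(path)
    },
    transcripts = {
      fa <- file.path(dir, "transcripts.fasta")
      Biostrings::writeXStringSet(
        Biostrings::DNAStringSet(world$transcripts), fa)
      bed <- file.path(dir, "regions.bed")
      write.table(
        data.frame(world$regions$transcript_id, world$regions$start,
                   world$regions$end, world$regions$region),
        bed, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
      invisible(c(fa, bed))
    },
    truth = {
      path <- file.path(dir, "truth_targets.tsv")
      write.table(world$truth_targets, path, sep = "\t", quote = FALSE,
                  row.names = FALSE)
      invisible(path)
    },
    rnaseq = ,
    degradome = ,
    ribo = ,
    groseq = {
      path <- file.path(dir, paste0(assay, "_counts.tsv"))
      tab <- world$counts[[assay]]
      if (is.matrix(tab))
        tab <- data.frame(id = rownames(tab), tab, check.names = FALSE)
      write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
      invisible(path)
    },
    stop("unknown assay: ", assay)
  )
}

#' Read a count table written by [emit_reads()]
#'
#' @param path TSV path; the first column is taken as row names when named
#'   `id`.
#' @return matrix or data frame.
#' @export
read_count_table <- function(path) {
  tab <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                    stringsAsFactors = FALSE)
  if (names(tab)[1] == "id") {
    m <- as.matrix(tab[, -1, drop = FALSE])
    rownames(m) <- tab$id
    return(m)
  }
  tab
}
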