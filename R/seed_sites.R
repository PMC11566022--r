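# miRNA-style and translation-model site scanning. These site classes are
# used to test alternative regulatory models: high-affinity seed sites
# (g2-g8 with target adenosine at t1), seed plus >= 7 additional paired
# nucleotides in g9-g30 (miRNA-like destabilization model), and seed plus
# >= 12 in g9-g30 near an ELAVL1 motif (translational activation model).
#
# Register: t1 is the target nucleotide opposite guide position g1 and lies
# at the 3' end of the site; guide position k pairs target coordinate
# t1 - (k - 1) (0-based), consistent with the cleavage register used by the
# pairing engine (t1 = cleavage position + 9).

revcomp_dna <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(
    normalize_seq(x))))
}

#' Find seed-match sites for a guide in one transcript
#'
#' Modes: `"sevenmer_A1"` requires an exact match to the reverse complement
#' of guide g2-g8 with an A immediately 3' on the target (the t1 position);
#' `"seed_plus7"` / `"seed_plus12"` require the g2-g8 seed match (t1
#' unconstrained) plus at least 7 / 12 paired positions, not necessarily
#' contiguous, within g9-g30 at the same register.
#'
#' @param guide guide sequence.
#' @param transcript_id transcript identifier (used for region lookup).
#' @param transcript transcript sequence.
#' @param regions region annotation: data frame with `transcript_id`,
#'   `region` (5UTR/CDS/3UTR), `start`, `end` (0-based half-open).
#' @param mode site class (see above).
#' @param region_set regions to scan (default both UTRs); a site is kept
#'   only if its seed interval lies entirely within one of these regions.
#' @return data frame of class sites: `transcript_id`, `region`, `t1`
#'   (0-based coordinate of the target t1 position), `mode`,
#'   `n_paired_g9_g30`.
#' @export
find_sites <- function(guide, transcript_id, transcript, regions,
                       mode = c("sevenmer_A1", "seed_plus7", "seed_plus12"),
                       region_set = c("5UTR", "3UTR")) {
  mode <- match.arg(mode)
  reg <- regions[regions$transcript_id == transcript_id, , drop = FALSE]
  if (nrow(reg) == 0L) stop("missing region annotation for ", transcript_id)
  g <- normalize_seq(guide)
  if (nchar(g) < 8L) stop("guide shorter than the g2-g8 seed")
  seed_rc <- revcomp_dna(substr(g, 2L, 8L))
  pattern <- if (mode == "sevenmer_A1") paste0(seed_rc, "A") else seed_rc
  tx <- normalize_seq(as.character(transcript))
  hits <- Biostrings::matchPattern(pattern, Biostrings::DNAString(tx))
  if (length(hits) == 0L) return(empty_sites())
  start0 <- Biostrings::start(hits) - 1L          # 0-based start of match
  # t1 sits one base 3' of the seed match for seed-only patterns, and is
  # the final A of the 8-mer pattern for sevenmer_A1
  t1 <- if (mode == "sevenmer_A1") start0 + 7L else start0 + 7L
  site_start <- start0
  site_end <- if (mode == "sevenmer_A1") t1 + 1L else start0 + 7L
  keep_region <- rep(NA_character_, length(hits))
  for (i in seq_len(nrow(reg))) {
    inside <- site_start >= reg$start[i] & site_end <= reg$end[i]
    keep_region[inside] <- reg$region[i]
  }
  ok <- !is.na(keep_region) & keep_region %in% region_set
  t1 <- t1[ok]; keep_region <- keep_region[ok]
  if (length(t1) == 0L) return(empty_sites())
  # paired positions within g9-g30 at this register (guide k pairs target
  # coordinate t1 - (k - 1)); counted directly so sites near the transcript
  # 5' end are clipped rather than rejected
  gch <- seq_chars(g)
  txch <- seq_chars(tx)
  n_paired <- vapply(t1, function(c1) {
    k <- 9:30
    k <- k[k <= length(gch)]
    idx <- c1 - (k - 1L) + 1L
    ok <- idx >= 1L & idx <= length(txch)
    sum(DNA_COMPLEMENT[gch[k[ok]]] == txch[idx[ok]])
  }, numeric(1))
  min_add <- switch(mode, sevenmer_A1 = 0L, seed_plus7 = 7L, seed_plus12 = 12L)
  ok2 <- n_paired >= min_add
  out <- data.frame(
    transcript_id = rep(transcript_id, sum(ok2)),
    region = keep_region[ok2], t1 = as.integer(t1[ok2]),
    mode = rep(mode, sum(ok2)), n_paired_g9_g30 = as.integer(n_paired[ok2]),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

empty_sites <- function() {
  data.frame(transcript_id = character(0), region = character(0),
             t1 = integer(0), mode = character(0),
             n_paired_g9_g30 = integer(0), stringsAsFactors = FALSE)
}

#' Count sites for one guide across a transcriptome
#'
#' @param guide guide sequence.
#' @param transcripts named character vector of transcript sequences.
#' @param regions region annotation (see [find_sites()]).
#' @inheritParams find_sites
#' @return total site count across the stated regions.
#' @export
count_sites_per_guide <- function(guide, transcripts, regions,
                                  mode = "sevenmer_A1",
                                  region_set = c("5UTR", "3UTR")) {
  if (length(transcripts) == 0L) return(0L)
  sum(vapply(names(transcripts), function(id)
    nrow(find_sites(guide, id, transcripts[[id]], regions, mode, region_set)),
    numeric(1)))
}

#' Median and IQR of per-guide site counts
#'
#' @param counts numeric vector of site counts (one per guide).
#' @return list with `median`, `q25`, `q75`.
#' @export
summarize_site_counts <- function(counts) {
  qs <- quantile(counts, c(0.25, 0.75), names = FALSE)
  list(median = median(counts), q25 = qs[1], q75 = qs[2])
}

#' Annotate sites with ELAVL1-motif co-occurrence
#'
#' Flags each site whose transcript carries a match to the (configurable)
#' U-rich ELAVL1-binding motif within the stated scope -- by default
#' anywhere in the same 3'UTR.
#'
#' @param sites site table from [find_sites()].
#' @param transcripts named character vector of transcript sequences.
#' @param regions region annotation.
#' @param motif motif pattern (DNA alphabet; default a U-rich pentamer).
#' @param scope region searched for the motif (default `"3UTR"`).
#' @return `sites` with a logical `has_elavl1_motif` column.
#' @export
elavl1_annotate <- function(sites, transcripts, regions, motif = "TTTTT",
                            scope = "3UTR") {
  if (nrow(sites) == 0L) {
    sites$has_elavl1_motif <- logical(0)
    return(sites)
  }
  motif <- normalize_seq(motif)
  has_motif <- vapply(unique(sites$transcript_id), function(id) {
    reg <- regions[regions$transcript_id == id & regions$region == scope, ,
                   drop = FALSE]
    if (nrow(reg) == 0L) return(FALSE)
    tx <- normalize_seq(as.character(transcripts[[id]]))
    any(vapply(seq_len(nrow(reg)), function(i) {
      sub <- substr(tx, reg$start[i] + 1L, reg$end[i])
      length(Biostrings::matchPattern(motif, Biostrings::DNAString(sub))) > 0L
    }, logical(1)))
  }, logical(1))
  sites$has_elavl1_motif <- unname(has_motif[sites$transcript_id])
  sites
}
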