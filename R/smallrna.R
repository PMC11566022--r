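# Small-RNA quantification: UMI deduplication, spike-in calibration to
# absolute molecule counts, 25-nt prefix grouping, and the detection
# thresholds used to decide which piRNA families enter target calling.

#' Construct a spike-in set
#'
#' @param name,sequence,molecules_added parallel vectors describing the
#'   synthetic spike-in oligonucleotides and the number of molecules of each
#'   added per library.
#' @return data frame of class `spike_in_set`.
#' @export
spike_in_set <- function(name, sequence, molecules_added) {
  if (length(name) < 1L) stop("a spike-in set needs >= 1 entry")
  if (any(molecules_added <= 0)) stop("molecules_added must be positive")
  out <- data.frame(
    name = as.character(name),
    sequence = vapply(sequence, normalize_seq, character(1), USE.NAMES = FALSE),
    molecules_added = as.numeric(molecules_added),
    stringsAsFactors = FALSE
  )
  class(out) <- c("spike_in_set", "data.frame")
  out
}

#' Collapse PCR duplicates of UMI-tagged small-RNA reads
#'
#' Each read is expected to carry a 9-nt UMI at either end flanking the
#' insert (adapters already trimmed). Identical (insert, 5' UMI, 3' UMI)
#' combinations are counted once. Reads shorter than `2 * umi_length + 1`
#' nt are skipped and tallied.
#'
#' @param reads character vector of reads.
#' @param umi_length UMI length at each end (default 9).
#' @return named integer vector of deduplicated counts per insert, with
#'   attribute `skipped` giving the number of too-short reads.
#' @export
deduplicate <- function(reads, umi_length = 9L) {
  reads <- normalize_seq(reads)
  min_len <- 2L * umi_length + 1L
  short <- nchar(reads) < min_len
  reads <- reads[!short]
  if (length(reads) == 0L) {
    out <- integer(0)
    attr(out, "skipped") <- sum(short)
    return(out)
  }
  n <- nchar(reads)
  insert <- substr(reads, umi_length + 1L, n - umi_length)
  umi <- paste0(substr(reads, 1L, umi_length),
                substr(reads, n - umi_length + 1L, n))
  uniq <- !duplicated(paste(insert, umi, sep = "\r"))
  counts <- table(insert[uniq])
  out <- setNames(as.integer(counts), names(counts))
  attr(out, "skipped") <- sum(short)
  out
}

#' Calibrate a library against its spike-ins
#'
#' Spike-in reads are assigned by exact sequence match (no mismatches). The
#' per-library scale is total spike molecules added divided by total spike
#' reads (molecules per deduplicated read). ppm is computed over non-spike
#' reads only.
#'
#' @param counts named integer vector of deduplicated insert counts (as from
#'   [deduplicate()]).
#' @param spikes a [spike_in_set()].
#' @return list with `scale` (molecules/read), and `table`: data frame with
#'   `sequence`, `count`, `is_spike`, `ppm` (NA for spikes), `molecules`.
#' @export
calibrate <- function(counts, spikes) {
  stopifnot(inherits(spikes, "spike_in_set"))
  seqs <- names(counts)
  is_spike <- seqs %in% spikes$sequence
  spike_reads <- sum(counts[is_spike])
  if (spike_reads == 0L) stop("calibration error: no spike-in reads detected")
  scale <- sum(spikes$molecules_added) / spike_reads
  nonspike_total <- sum(counts[!is_spike])
  ppm <- ifelse(is_spike, NA_real_,
                as.numeric(counts) / nonspike_total * 1e6)
  list(
    scale = scale,
    table = data.frame(
      sequence = seqs,
      count = as.integer(counts),
      is_spike = is_spike,
      ppm = ppm,
      molecules = as.numeric(counts) * scale,
      stringsAsFactors = FALSE
    )
  )
}

#' Group small-RNA species by their 5' 25-nt prefix
#'
#' 3' trimming leaves piRNA 3' ends heterogeneous, so reads are grouped by
#' their 5' 25-nt prefix and a group is treated as one piRNA species family.
#' Group abundance is the sum over members; the representative full-length
#' sequence is the highest-count member, ties broken by lexicographic order.
#' Inserts shorter than the prefix length are routed to a discard bin.
#'
#' @param table data frame with a `sequence` column, a `count` column, and
#'   one or more abundance columns named in `abundance_cols` (default:
#'   `"ppm"`).
#' @param prefix_length prefix length (default 25).
#' @param abundance_cols names of per-replicate abundance columns to sum
#'   over group members.
#' @return data frame with `prefix`, `representative`, `n_members`, `count`
#'   and the summed abundance columns; attribute `discarded` holds the
#'   number of too-short inserts.
#' @export
group_by_prefix <- function(table, prefix_length = 25L,
                            abundance_cols = "ppm") {
  stopifnot(is.data.frame(table), "sequence" %in% names(table),
            "count" %in% names(table),
            all(abundance_cols %in% names(table)))
  short <- nchar(table$sequence) < prefix_length
  discarded <- sum(short)
  table <- table[!short, , drop = FALSE]
  if (nrow(table) == 0L) {
    out <- data.frame(prefix = character(0), representative = character(0),
                      n_members = integer(0), count = integer(0))
    for (col in abundance_cols) out[[col]] <- numeric(0)
    attr(out, "discarded") <- discarded
    return(out)
  }
  prefix <- substr(table$sequence, 1L, prefix_length)
  # representative: order by count desc, then sequence asc, take first per group
  ord <- order(prefix, -table$count, table$sequence)
  table <- table[ord, , drop = FALSE]
  prefix <- prefix[ord]
  first <- !duplicated(prefix)
  out <- data.frame(
    prefix = prefix[first],
    representative = table$sequence[first],
    n_members = as.integer(tapply(rep(1L, nrow(table)), prefix, sum)),
    count = as.integer(round(tapply(table$count, prefix, sum))),
    stringsAsFactors = FALSE
  )
  for (col in abundance_cols)
    out[[col]] <- as.numeric(tapply(table[[col]], prefix, sum))
  rownames(out) <- NULL
  attr(out, "discarded") <- discarded
  out
}

#' Keep prefix groups detected in every control replicate
#'
#' A prefix group is retained when its abundance is at least `min_ppm`
#' (inclusive) in every control replicate.
#'
#' @param groups data frame of prefix groups.
#' @param control_cols names of the control-replicate ppm columns.
#' @param min_ppm detection threshold (default 1 ppm).
#' @return the retained rows of `groups`.
#' @export
apply_detection_filter <- function(groups, control_cols, min_ppm = 1) {
  if (length(control_cols) < 1L) stop("need >= 1 control replicate")
  if (nrow(groups) == 0L) return(groups)
  m <- as.matrix(groups[, control_cols, drop = FALSE])
  keep <- rowSums(m >= min_ppm) == ncol(m)
  groups[keep, , drop = FALSE]
}

#' Is a prefix group undetectable in mutant libraries?
#'
#' `TRUE` iff the mean abundance across mutant replicates is at most
#' `max_ppm` (inclusive; default 0.1 ppm).
#'
#' @param mutant_ppm numeric vector of per-replicate ppm values.
#' @param max_ppm undetectability threshold.
#' @return logical.
#' @export
is_undetectable_in_mutant <- function(mutant_ppm, max_ppm = 0.1) {
  if (length(mutant_ppm) < 1L) stop("need >= 1 mutant replicate")
  mean(mutant_ppm) <= max_ppm
}
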