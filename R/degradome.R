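# Degradome (5'-monophosphorylated long RNA) processing: collapse reads into
# 5'-end species, detection thresholds, and genotype dependence of putative
# 3' cleavage products.

#' Collapse degradome reads into 5'-monophosphorylated RNA species
#'
#' Reads sharing a transcript and 5'-end coordinate are merged into one
#' species. A species is flagged unambiguous only if none of its reads
#' multi-mapped; only unambiguous species should enter target calling.
#' ppm is computed over all reads in the library (ambiguous included).
#'
#' @param alignments data frame with columns `transcript_id`, `position`
#'   (0-based 5'-end coordinate) and optionally `multi` (logical,
#'   multi-mapping read) and `count` (reads per row, default 1).
#' @param transcript_lengths optional named vector; rows whose position
#'   falls outside `[0, length)` are rejected and tallied in attribute
#'   `rejected`.
#' @return data frame of class `cleavage_products` with `transcript_id`,
#'   `position`, `count`, `ppm`, `unambiguous`.
#' @export
collapse_species <- function(alignments, transcript_lengths = NULL) {
  stopifnot(is.data.frame(alignments),
            all(c("transcript_id", "position") %in% names(alignments)))
  if (is.null(alignments$multi)) alignments$multi <- rep(FALSE, nrow(alignments))
  if (is.null(alignments$count)) alignments$count <- rep(1L, nrow(alignments))
  rejected <- 0L
  if (!is.null(transcript_lengths)) {
    len <- transcript_lengths[alignments$transcript_id]
    bad <- is.na(len) | alignments$position < 0 | alignments$position >= len
    rejected <- sum(alignments$count[bad])
    if (rejected > 0L)
      message(rejected, " degradome reads outside transcript bounds rejected")
    alignments <- alignments[!bad, , drop = FALSE]
  }
  if (nrow(alignments) == 0L) {
    out <- data.frame(transcript_id = character(0), position = integer(0),
                      count = integer(0), ppm = numeric(0),
                      unambiguous = logical(0))
    attr(out, "rejected") <- rejected
    class(out) <- c("cleavage_products", "data.frame")
    return(out)
  }
  key <- paste(alignments$transcript_id, alignments$position, sep = "\r")
  total <- sum(alignments$count)
  agg_count <- tapply(alignments$count, key, sum)
  agg_multi <- tapply(alignments$multi, key, any)
  ids <- names(agg_count)
  split_key <- strsplit(ids, "\r", fixed = TRUE)
  out <- data.frame(
    transcript_id = vapply(split_key, `[`, character(1), 1L),
    position = as.integer(vapply(split_key, `[`, character(1), 2L)),
    count = as.integer(agg_count),
    ppm = as.numeric(agg_count) / total * 1e6,
    unambiguous = !as.logical(agg_multi),
    stringsAsFactors = FALSE
  )
  out <- out[order(out$transcript_id, out$position), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "rejected") <- rejected
  class(out) <- c("cleavage_products", "data.frame")
  out
}

#' Does a cleavage product pass the detection threshold?
#'
#' @param ppm product abundance in ppm in one replicate.
#' @param min_ppm threshold, inclusive (default 0.1 ppm).
#' @return logical.
#' @export
passes_product_threshold <- function(ppm, min_ppm = 0.1) {
  ppm >= min_ppm
}

#' Genotype dependence of a putative 3' cleavage product
#'
#' Classifies a product as `dependent` (present in control, lost in the
#' piRNA-knockout mutant), `independent` (detected in both genotypes -- the
#' control-target criterion), or `undetermined` (not detected in control).
#' Presence uses any-replicate detection at `detect_ppm`; the `fold8`
#' magnitude criterion compares means across replicates, with the mutant
#' mean floored at `pseudocount` so the ratio is always defined.
#'
#' @param control_ppm,mutant_ppm per-replicate ppm vectors.
#' @param mode `"absent"`: dependent iff the product is undetected in the
#'   mutant; `"fold8"`: dependent iff mean(control) / mean(mutant) >=
#'   `min_fold`.
#' @param detect_ppm detection threshold (default 0.1 ppm).
#' @param min_fold fold-change requirement for `mode = "fold8"` (default 8).
#' @param pseudocount floor for the mutant mean in fold computation
#'   (default 0.01 ppm).
#' @param strict_zero for `mode = "absent"`, require zero mutant reads
#'   rather than < `detect_ppm`.
#' @return one of `"dependent"`, `"independent"`, `"undetermined"`.
#' @export
genotype_dependence <- function(control_ppm, mutant_ppm,
                                mode = c("absent", "fold8"),
                                detect_ppm = 0.1, min_fold = 8,
                                pseudocount = 0.01, strict_zero = FALSE) {
  mode <- match.arg(mode)
  if (length(control_ppm) < 1L || length(mutant_ppm) < 1L)
    stop("need >= 1 replicate per genotype")
  detected_control <- any(control_ppm >= detect_ppm)
  if (!detected_control) return("undetermined")
  detected_mutant <- if (strict_zero) any(mutant_ppm > 0) else
    any(mutant_ppm >= detect_ppm)
  if (mode == "absent") {
    if (!detected_mutant) "dependent" else "independent"
  } else {
    fold <- mean(control_ppm) / max(mean(mutant_ppm), pseudocount)
    if (fold >= min_fold) "dependent"
    else if (detected_mutant) "independent"
    else "undetermined"
  }
}

#' Export cleavage sites as BED intervals
#'
#' Writes single-nucleotide, 0-based half-open intervals (one per species).
#'
#' @param products a `cleavage_products` data frame.
#' @param path output path.
#' @export
write_cleavage_bed <- function(products, path) {
  bed <- data.frame(
    chrom = products$transcript_id,
    start = products$position,
    end = products$position + 1L,
    name = sprintf("%s:%d", products$transcript_id, products$position),
    score = round(products$ppm, 4),
    strand = "+"
  )
  write.table(bed, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
}
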