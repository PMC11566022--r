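# Translational efficiency: ribosome occupancy normalized to mRNA
# abundance, with the occupancy detection filter applied before any
# summary, and the distribution-level test of the translational-activation
# model.

#' Compute translational efficiency
#'
#' TE = ribosome occupancy TPM / mRNA TPM. Genes with zero mRNA TPM are
#' undefined and excluded (with a message); genes below the occupancy
#' filter are kept in the table but flagged, and should be excluded from
#' downstream summaries.
#'
#' @param mrna_tpm,occupancy_tpm named numeric vectors over the same genes.
#' @param min_occupancy_tpm occupancy filter threshold, inclusive
#'   (default 10 TPM).
#' @return data frame: `gene`, `mrna_tpm`, `occupancy_tpm`, `te`,
#'   `passes_filter`.
#' @export
compute_te <- function(mrna_tpm, occupancy_tpm, min_occupancy_tpm = 10) {
  stopifnot(length(mrna_tpm) == length(occupancy_tpm))
  genes <- names(mrna_tpm)
  if (is.null(genes)) genes <- as.character(seq_along(mrna_tpm))
  undef <- mrna_tpm == 0
  if (any(undef))
    message(sum(undef), " genes with zero mRNA TPM excluded (TE undefined)")
  out <- data.frame(
    gene = genes[!undef],
    mrna_tpm = mrna_tpm[!undef],
    occupancy_tpm = occupancy_tpm[!undef],
    te = occupancy_tpm[!undef] / mrna_tpm[!undef],
    passes_filter = occupancy_tpm[!undef] >= min_occupancy_tpm,
    row.names = NULL, stringsAsFactors = FALSE
  )
  out
}

#' Classify translational-efficiency changes between stages
#'
#' @param te_b,te_a named TE vectors for the later and earlier stage.
#' @param up_fold threshold for the increased class (ratio >= 2 by default,
#'   inclusive).
#' @param down_fold threshold for the decreased class (ratio <= 1/1.5 by
#'   default, inclusive).
#' @return list of gene-id vectors `up` and `down`.
#' @export
stage_te_change <- function(te_b, te_a, up_fold = 2, down_fold = 1.5) {
  genes <- intersect(names(te_b), names(te_a))
  ratio <- te_b[genes] / te_a[genes]
  list(up = genes[ratio >= up_fold], down = genes[ratio <= 1 / down_fold])
}

#' Test the translational-activation model
#'
#' Two-sample KS test comparing the change in translational efficiency
#' (mutant / control TE) between the putative activation targets (genes
#' with a 3'UTR ELAVL1 motif plus a seed + >= 12 nt site) and control
#' genes.
#'
#' @param delta_te named numeric vector of TE changes.
#' @param target_ids,control_ids gene-id vectors (non-empty).
#' @return a `pislice_test`.
#' @export
test_activation_model <- function(delta_te, target_ids, control_ids) {
  x <- delta_te[names(delta_te) %in% target_ids]
  y <- delta_te[names(delta_te) %in% control_ids]
  if (length(x) == 0L || length(y) == 0L)
    stop("both target and control sets must be non-empty")
  ks_2samp(x, y)
}
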