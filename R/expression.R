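# Transcript quantification and two-genotype differential abundance.
#
# The differential test is a deliberately simple negative-binomial Wald
# contrast -- median-of-ratios size factors, method-of-moments dispersion
# with a floor, log2 fold change of normalized group means with a
# pseudocount, Benjamini-Hochberg correction -- fully specified here so the
# analysis is reproducible from this package alone.

#' Median-of-ratios size factors
#'
#' DESeq-style: each library's size factor is the median across genes of
#' the ratio of its count to the gene's geometric mean, computed over genes
#' with a positive count in every library.
#'
#' @param mat genes x libraries count matrix (spike rows excluded).
#' @return numeric vector of size factors, one per column.
#' @export
estimate_size_factors <- function(mat) {
  log_gm <- rowMeans(log(mat))
  use <- is.finite(log_gm)
  if (!any(use)) stop("no gene has positive counts in every library")
  apply(mat[use, , drop = FALSE], 2, function(cnt)
    exp(median(log(cnt) - log_gm[use])))
}

#' Normalize an expression matrix
#'
#' Computes TPM over non-spike rows (counts are transcript-level,
#' UMI-deduplicated molecule counts, so TPM is count share x 1e6),
#' median-of-ratios normalized counts, and absolute molecules per cell from
#' a through-origin regression of known spike molecules on spike counts.
#'
#' @param mat genes x libraries count matrix including spike rows.
#' @param spike_rows row names (or indices) of the spike rows.
#' @param spike_molecules known molecules per cell of each spike row (same
#'   order as `spike_rows`); required for molecule estimates.
#' @return list with `tpm`, `norm_counts`, `size_factors` (all over
#'   non-spike rows) and `molecules_per_cell` (NULL without spike
#'   molecules).
#' @export
normalize_expression <- function(mat, spike_rows = NULL,
                                 spike_molecules = NULL) {
  stopifnot(is.matrix(mat), all(mat >= 0))
  is_spike <- if (is.null(spike_rows)) rep(FALSE, nrow(mat)) else
    rownames(mat) %in% spike_rows | seq_len(nrow(mat)) %in% spike_rows
  genes <- mat[!is_spike, , drop = FALSE]
  tpm <- sweep(genes, 2, colSums(genes), "/") * 1e6
  sf <- estimate_size_factors(genes)
  molecules <- NULL
  if (!is.null(spike_molecules) && any(is_spike)) {
    spikes <- mat[is_spike, , drop = FALSE]
    m <- spike_molecules[match(rownames(spikes), spike_rows)]
    # through-origin regression: molecules = b * counts per library
    b <- vapply(seq_len(ncol(spikes)), function(j)
      sum(m * spikes[, j]) / sum(spikes[, j]^2), numeric(1))
    molecules <- sweep(genes, 2, b, "*")
  }
  list(tpm = tpm, norm_counts = sweep(genes, 2, sf, "/"),
       size_factors = sf, molecules_per_cell = molecules)
}

#' Negative-binomial Wald contrast between two genotypes
#'
#' Per transcript: size-factor-normalized group means, log2 fold change
#' (group B vs group A) with pseudocount, method-of-moments NB dispersion
#' (floored), Wald test of the log ratio via the delta method, and BH
#' adjustment.
#'
#' @param mat genes x libraries count matrix (no spike rows).
#' @param group_a,group_b column names (or indices) of the two groups
#'   (>= 2 each); fold changes are B over A (e.g. mutant over control).
#' @param pseudocount added to normalized means for the fold change
#'   (default 0.5).
#' @param dispersion_floor lower bound on the dispersion estimate
#'   (default 0.01).
#' @return data frame: `gene`, `mean_a`, `mean_b`, `log2fc`, `p`, `q`.
#' @export
nb_contrast <- function(mat, group_a, group_b, pseudocount = 0.5,
                        dispersion_floor = 0.01) {
  a <- mat[, group_a, drop = FALSE]
  b <- mat[, group_b, drop = FALSE]
  if (ncol(a) < 2L || ncol(b) < 2L)
    stop("need >= 2 replicates per group")
  sf <- estimate_size_factors(cbind(a, b))
  na <- ncol(a); nb <- ncol(b)
  an <- sweep(a, 2, sf[seq_len(na)], "/")
  bn <- sweep(b, 2, sf[na + seq_len(nb)], "/")
  mu_a <- rowMeans(an); mu_b <- rowMeans(bn)
  # method-of-moments dispersion from within-group mean/variance, averaged
  # across groups, floored
  mom <- function(m, v) ifelse(m > 0, (v - m) / m^2, NA_real_)
  phi <- rowMeans(cbind(mom(mu_a, apply(an, 1, var)),
                        mom(mu_b, apply(bn, 1, var))), na.rm = TRUE)
  phi <- pmax(ifelse(is.finite(phi), phi, dispersion_floor), dispersion_floor)
  log_fc <- log((mu_b + pseudocount) / (mu_a + pseudocount))
  se <- sqrt((1 / (mu_a + pseudocount) + phi) / na +
               (1 / (mu_b + pseudocount) + phi) / nb)
  z <- log_fc / se
  p <- 2 * pnorm(-abs(z))
  data.frame(
    gene = rownames(mat), mean_a = mu_a, mean_b = mu_b,
    log2fc = log_fc / log(2), p = p, q = bh_adjust(p),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Nested derepression classes
#'
#' Splits a contrast result into the nested sets used for reporting:
#' transcripts whose abundance increased at all, those whose increase is
#' significant at the FDR threshold, and the significant increases of at
#' least `min_fold`.
#'
#' @param result a [nb_contrast()] result.
#' @param fdr FDR threshold (default 0.01).
#' @param min_fold fold-change threshold (default 1.5).
#' @return list of gene-id vectors: `increased`, `significant`, `strong`
#'   (each a subset of the previous).
#' @export
classify_derepression <- function(result, fdr = 0.01, min_fold = 1.5) {
  up <- result$log2fc > 0
  sig <- up & !is.na(result$q) & result$q < fdr
  strong <- sig & result$log2fc >= log2(min_fold)
  list(increased = result$gene[up],
       significant = result$gene[sig],
       strong = result$gene[strong])
}

#' Compare fold-change distributions of targets vs controls
#'
#' Two-sample, two-tailed Kolmogorov-Smirnov test on the log2 fold changes
#' of a target set against a control set.
#'
#' @param result a [nb_contrast()] result.
#' @param target_ids,control_ids gene-id vectors (non-empty).
#' @return a `pislice_test`.
#' @export
compare_target_vs_control_foldchange <- function(result, target_ids,
                                                 control_ids) {
  x <- result$log2fc[result$gene %in% target_ids]
  y <- result$log2fc[result$gene %in% control_ids]
  if (length(x) == 0L || length(y) == 0L)
    stop("both target and control sets must be non-empty")
  ks_2samp(x, y)
}
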