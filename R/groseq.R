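# GRO-seq: RNA polymerase II density per gene body as a transcription-rate
# proxy, excluding the first 500 bp of each gene to minimize the
# contribution of paused polymerase.

#' RNA polymerase II density in ppm per kb
#'
#' density = (reads overlapping [start + exclude_bp, end) / depth * 1e6) /
#' ((length - exclude_bp) / 1000). Genes no longer than `exclude_bp` are
#' excluded (NA, with a message).
#'
#' @param reads reads overlapping the counted gene-body interval (vector).
#' @param gene_length gene length in bp (vector).
#' @param depth library sequencing depth.
#' @param exclude_bp length of the excluded 5' interval (default 500).
#' @return numeric vector of densities (ppm/kb), NA for excluded genes.
#' @export
polII_density <- function(reads, gene_length, depth, exclude_bp = 500) {
  stopifnot(length(reads) == length(gene_length), depth > 0)
  short <- gene_length <= exclude_bp
  if (any(short))
    message(sum(short), " genes <= ", exclude_bp, " bp excluded")
  dens <- rep(NA_real_, length(reads))
  kb <- (gene_length[!short] - exclude_bp) / 1000
  dens[!short] <- (reads[!short] / depth * 1e6) / kb
  dens
}

#' Compare polymerase density between two gene classes
#'
#' Reports class medians with IQRs and a two-tailed, unpaired Mann-Whitney
#' test.
#'
#' @param density named density vector (from [polII_density()]).
#' @param class_a,class_b gene-id vectors (non-empty after NA removal).
#' @return list with `median_a`, `iqr_a`, `median_b`, `iqr_b`, `test`
#'   (a `pislice_test`).
#' @export
compare_classes <- function(density, class_a, class_b) {
  x <- density[names(density) %in% class_a]
  y <- density[names(density) %in% class_b]
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) == 0L || length(y) == 0L)
    stop("both classes must be non-empty")
  qa <- quantile(x, c(0.25, 0.75), names = FALSE)
  qb <- quantile(y, c(0.25, 0.75), names = FALSE)
  list(median_a = median(x), iqr_a = qa, median_b = median(y), iqr_b = qb,
       test = mann_whitney(x, y))
}

#' Split genes by derepression fold change at a boundary
#'
#' The classes overlap at the boundary, which belongs to both (a gene at
#' exactly the boundary fold change is counted in the `low` class and the
#' `high` class).
#'
#' @param log2fc named log2 fold-change vector.
#' @param boundary_fold fold-change boundary (default 1.25).
#' @return list of gene-id vectors `low` (<= boundary) and `high`
#'   (>= boundary).
#' @export
split_by_foldchange <- function(log2fc, boundary_fold = 1.25) {
  b <- log2(boundary_fold)
  list(low = names(log2fc)[log2fc <= b], high = names(log2fc)[log2fc >= b])
}
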