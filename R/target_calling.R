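# The analytical core: decide for each (piRNA, cleavage product) pair
# whether the guide could have directed the cleavage, then apply the
# locus-exclusivity and genotype-dependence filters that define
# high-confidence targets, and summarize over replicate permutations.

# Precompute a guides-by-30 character matrix of guide bases (NA beyond the
# guide's length) so that a whole guide set can be evaluated against one
# site window with a single vectorized comparison.
guide_matrix <- function(sequences) {
  n <- length(sequences)
  m <- matrix(NA_character_, n, 30L)
  for (i in seq_len(n)) {
    g <- seq_chars(sequences[i])
    k <- seq_len(min(30L, length(g)))
    m[i, k] <- g[k]
  }
  m
}

# For one cleavage site, the guide base that WOULD pair each position:
# complement of the transcript base at coordinate position + 10 - k
# (NA where the window hangs off the transcript).
site_window <- function(tx_chars, position) {
  k <- seq_len(30L)
  idx <- position + 11L - k
  w <- rep(NA_character_, 30L)
  ok <- idx >= 1L & idx <= length(tx_chars)
  w[ok] <- unname(DNA_COMPLEMENT[tx_chars[idx[ok]]])
  w
}

#' Scan all (prefix group, cleavage product) pairs for callable targets
#'
#' For every cleavage product, every guide is aligned at the product's
#' cleavage register and the abundance-tiered pairing rules are evaluated;
#' callable pairs are returned. Guides are represented by their full-length
#' representative sequence. Products are expected to have passed the
#' detection threshold already.
#'
#' @param groups data frame with columns `guide_id`, `locus`, `sequence`,
#'   `ppm` (abundance used for the tier preconditions).
#' @param products data frame with columns `transcript_id`, `position`.
#' @param transcripts named character vector (or `DNAStringSet`) of
#'   transcript sequences.
#' @param rules tier rule table, defaults to [tier_rules()].
#' @return data frame of candidate calls: `guide_id`, `locus`, `ppm`,
#'   `transcript_id`, `position`, `rules` (comma-separated satisfied rules).
#' @export
scan_transcriptome <- function(groups, products, transcripts,
                               rules = tier_rules()) {
  stopifnot(all(c("guide_id", "locus", "sequence", "ppm") %in% names(groups)),
            all(c("transcript_id", "position") %in% names(products)))
  empty <- data.frame(guide_id = character(0), locus = character(0),
                      ppm = numeric(0), transcript_id = character(0),
                      position = integer(0), rules = character(0),
                      stringsAsFactors = FALSE)
  if (nrow(groups) == 0L || nrow(products) == 0L) return(empty)
  transcripts <- setNames(as.character(transcripts), names(transcripts))
  missing <- setdiff(unique(products$transcript_id), names(transcripts))
  if (length(missing) > 0L)
    stop("transcript id(s) not found: ", paste(missing, collapse = ", "))
  gm <- guide_matrix(groups$sequence)
  abund <- groups$ppm
  contig <- rules$type == "contiguous"
  tx_chars <- lapply(transcripts[unique(products$transcript_id)], seq_chars)
  out <- vector("list", nrow(products))
  for (p in seq_len(nrow(products))) {
    w <- site_window(tx_chars[[products$transcript_id[p]]],
                     products$position[p])
    M <- gm == matrix(w, nrow(gm), 30L, byrow = TRUE)
    M[is.na(M)] <- FALSE
    sat <- matrix(FALSE, nrow(gm), nrow(rules))
    for (r in seq_len(nrow(rules))) {
      n_paired <- rowSums(M[, rules$ga[r]:rules$gb[r], drop = FALSE])
      geom_ok <- if (contig[r])
        n_paired == (rules$gb[r] - rules$ga[r] + 1L)
      else n_paired >= rules$min_paired[r]
      sat[, r] <- geom_ok & abund >= rules$min_ppm[r]
    }
    hit <- which(rowSums(sat) > 0L)
    if (length(hit) > 0L) {
      out[[p]] <- data.frame(
        guide_id = groups$guide_id[hit], locus = groups$locus[hit],
        ppm = abund[hit],
        transcript_id = products$transcript_id[p],
        position = products$position[p],
        rules = vapply(hit, function(i)
          paste(rules$rule[sat[i, ]], collapse = ","), character(1)),
        stringsAsFactors = FALSE
      )
    }
  }
  out <- out[!vapply(out, is.null, logical(1))]
  if (length(out) == 0L) return(empty)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Locus-exclusivity filter
#'
#' A candidate call by a focal-locus guide is exclusive iff no guide from a
#' non-focal locus is callable at the same cleavage site.
#'
#' @param calls candidate calls from [scan_transcriptome()] (all loci).
#' @param focal_loci character vector of focal locus ids.
#' @return the focal-guide subset of `calls` with a logical `exclusive`
#'   column added.
#' @export
exclusivity_filter <- function(calls, focal_loci) {
  site <- paste(calls$transcript_id, calls$position)
  nonfocal_sites <- unique(site[!(calls$locus %in% focal_loci)])
  out <- calls[calls$locus %in% focal_loci, , drop = FALSE]
  out$exclusive <- !(paste(out$transcript_id, out$position) %in% nonfocal_sites)
  rownames(out) <- NULL
  out
}

#' High-confidence target calls
#'
#' Confidence is `"high"` iff the call is exclusive and its 3' cleavage
#' product is genotype-dependent (lost in the knockout); otherwise
#' `"candidate"`.
#'
#' @param candidates focal candidate calls carrying an `exclusive` column
#'   (from [exclusivity_filter()]).
#' @param dependence data frame with `transcript_id`, `position`,
#'   `dependence` (`"dependent"` / `"independent"` / `"undetermined"`,
#'   from [genotype_dependence()] per product).
#' @return `candidates` with `genotype_dependent` and `confidence` columns.
#' @export
call_high_confidence <- function(candidates, dependence) {
  key <- paste(candidates$transcript_id, candidates$position)
  dep_key <- paste(dependence$transcript_id, dependence$position)
  dep <- dependence$dependence[match(key, dep_key)]
  dep[is.na(dep)] <- "undetermined"
  candidates$genotype_dependent <- dep == "dependent"
  candidates$confidence <- ifelse(
    candidates$exclusive & candidates$genotype_dependent, "high", "candidate")
  candidates
}

#' Control-target calls
#'
#' Control targets are cleavage sites explained by guides that (1) come from
#' a non-focal locus, (2) whose biogenesis does not depend on the focal
#' loci, and (3) whose 3' cleavage product is detected in both genotypes
#' (genotype-independent).
#'
#' @param calls candidate calls from [scan_transcriptome()] (all loci).
#' @param dependence per-product genotype dependence table (see
#'   [call_high_confidence()]).
#' @param focal_loci focal locus ids.
#' @param dependent_loci loci whose piRNA biogenesis depends on the focal
#'   loci (excluded from the control set).
#' @return the control-target subset of `calls`.
#' @export
call_control_targets <- function(calls, dependence, focal_loci,
                                 dependent_loci = character(0)) {
  keep <- !(calls$locus %in% focal_loci) & !(calls$locus %in% dependent_loci)
  out <- calls[keep, , drop = FALSE]
  key <- paste(out$transcript_id, out$position)
  dep_key <- paste(dependence$transcript_id, dependence$position)
  dep <- dependence$dependence[match(key, dep_key)]
  out <- out[!is.na(dep) & dep == "independent", , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Summarize a caller over all control x mutant replicate pairings
#'
#' Runs `caller(control_replicate, mutant_replicate)` for every pairing of
#' the given replicate indices (e.g. 4 x 4 = 16 permutations) and reports
#' the per-pairing counts with their median and inter-quartile range.
#'
#' @param control_reps,mutant_reps vectors of replicate identifiers.
#' @param caller function of (control replicate, mutant replicate)
#'   returning a count.
#' @return list with `counts` (named vector over pairings), `median`, `q25`,
#'   `q75`, `iqr`.
#' @export
permutation_summary <- function(control_reps, mutant_reps, caller) {
  grid <- expand.grid(control = control_reps, mutant = mutant_reps,
                      stringsAsFactors = FALSE)
  counts <- vapply(seq_len(nrow(grid)), function(i)
    caller(grid$control[i], grid$mutant[i]), numeric(1))
  names(counts) <- paste(grid$control, grid$mutant, sep = "|")
  qs <- quantile(counts, c(0.25, 0.75), names = FALSE, type = 7)
  list(counts = counts, median = median(counts),
       q25 = qs[1], q75 = qs[2], iqr = qs[2] - qs[1])
}
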