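# End-to-end orchestration: simulate (or accept) a study, quantify piRNAs,
# detect cleavage products, call high-confidence and control targets,
# summarize over replicate permutations, and run the downstream
# derepression / translation / transcription contrasts.

#' Default analysis thresholds
#'
#' All defaults are the thresholds used throughout the analysis: piRNA
#' prefix-group detection at 1 ppm in every control replicate,
#' undetectability in mutants at mean <= 0.1 ppm, cleavage-product
#' detection at 0.1 ppm, the 8-fold product-reduction alternative,
#' FDR 0.01, the 1.5-fold derepression class, the 1.25-fold
#' polymerase-density split, the 10 TPM ribosome-occupancy filter, and the
#' 500 bp gene-body exclusion.
#'
#' @return named list of thresholds.
#' @export
run_thresholds <- function() {
  list(group_detect_ppm = 1, mutant_undetect_ppm = 0.1,
       product_detect_ppm = 0.1, product_min_fold = 8,
       fdr = 0.01, derepression_fold = 1.5, density_boundary_fold = 1.25,
       occupancy_min_tpm = 10, groseq_exclude_bp = 500)
}

ppm_matrix <- function(counts) {
  sweep(counts, 2, colSums(counts), "/") * 1e6
}

#' Extrapolate the transcriptome-wide target count
#'
#' Scales the number of targets found for the focal loci by the fraction of
#' all piRNAs the focal loci produce. 112 targets at a 13.5% focal fraction
#' extrapolates to ~830 transcriptome-wide targets.
#'
#' @param count focal target count.
#' @param focal_fraction fraction of piRNAs from the focal loci (0-1).
#' @param round_to rounding granularity of the reported estimate
#'   (default 10; use NULL for the raw value).
#' @return extrapolated target count.
#' @export
extrapolate_targets <- function(count, focal_fraction, round_to = 10) {
  if (focal_fraction <= 0 || focal_fraction > 1)
    stop("focal_fraction must lie in (0, 1]")
  x <- count / focal_fraction
  if (is.null(round_to)) x else round(x / round_to) * round_to
}

#' Run the full analysis on a synthetic study
#'
#' Generates a world from `config`, quantifies piRNA abundance from the
#' small-RNA counts, detects cleavage products, scans for callable
#' guide:product pairs, applies the exclusivity and genotype-dependence
#' filters, summarizes high-confidence target counts over all control x
#' mutant replicate pairings, and runs the derepression, translational
#' efficiency and polymerase-density contrasts. Identical seeds give
#' identical reports.
#'
#' @param config a [sim_config()] (or an already generated
#'   `synthetic_world`).
#' @param thresholds threshold list, defaults to [run_thresholds()].
#' @param dependence_mode `"absent"` (product lost in mutant) or `"fold8"`
#'   (product reduced >= 8-fold).
#' @return object of class `pislice_report`; see the vignette for the
#'   component tables.
#' @export
run_all <- function(config = sim_config(), thresholds = run_thresholds(),
                    dependence_mode = c("absent", "fold8")) {
  dependence_mode <- match.arg(dependence_mode)
  world <- if (inherits(config, "synthetic_world")) config else
    generate_world(config)
  cfg <- world$config
  n_rep <- cfg$n_replicates
  ctrl_cols <- paste0("control_", seq_len(n_rep))
  mut_cols <- paste0("mutant_", seq_len(n_rep))

  ## piRNA quantification: ppm per library, detection filter on controls
  sr_ppm <- ppm_matrix(world$counts$smallrna)
  groups <- data.frame(
    guide_id = world$pirnas$guide_id, locus = world$pirnas$locus,
    sequence = world$pirnas$sequence,
    ppm = rowMeans(sr_ppm[, ctrl_cols, drop = FALSE]),
    stringsAsFactors = FALSE
  )
  groups <- cbind(groups, sr_ppm)
  groups <- apply_detection_filter(groups, ctrl_cols,
                                   thresholds$group_detect_ppm)
  groups$undetectable_in_mutant <- apply(
    groups[, mut_cols, drop = FALSE], 1, is_undetectable_in_mutant,
    max_ppm = thresholds$mutant_undetect_ppm)

  ## degradome: unambiguous species, ppm per library
  deg <- world$counts$degradome
  lib_cols <- c(ctrl_cols, mut_cols)
  deg_ppm <- ppm_matrix(as.matrix(deg[, lib_cols, drop = FALSE]))
  species <- cbind(deg[, c("transcript_id", "position", "unambiguous")],
                   deg_ppm)
  species <- species[species$unambiguous, , drop = FALSE]
  detected_any_ctrl <- rowSums(
    species[, ctrl_cols, drop = FALSE] >= thresholds$product_detect_ppm) > 0L
  products <- species[detected_any_ctrl, , drop = FALSE]

  ## candidate calls and per-product genotype dependence (all replicates)
  calls <- scan_transcriptome(groups, products, world$transcripts)
  dependence <- data.frame(
    transcript_id = products$transcript_id, position = products$position,
    dependence = vapply(seq_len(nrow(products)), function(i)
      genotype_dependence(
        as.numeric(products[i, ctrl_cols]), as.numeric(products[i, mut_cols]),
        mode = dependence_mode, detect_ppm = thresholds$product_detect_ppm,
        min_fold = thresholds$product_min_fold), character(1)),
    stringsAsFactors = FALSE
  )
  focal_calls <- call_high_confidence(
    exclusivity_filter(calls, world$focal_loci), dependence)
  hc_transcripts <- unique(
    focal_calls$transcript_id[focal_calls$confidence == "high"])
  control_calls <- call_control_targets(calls, dependence, world$focal_loci,
                                        world$dependent_loci)
  control_transcripts <- unique(control_calls$transcript_id)

  ## permutation summary over all control x mutant replicate pairings
  focal_excl <- focal_calls[focal_calls$exclusive, , drop = FALSE]
  site_idx <- match(paste(focal_excl$transcript_id, focal_excl$position),
                    paste(products$transcript_id, products$position))
  perm <- permutation_summary(ctrl_cols, mut_cols, function(ci, mi) {
    c_ppm <- products[site_idx, ci]
    m_ppm <- products[site_idx, mi]
    dep <- c_ppm >= thresholds$product_detect_ppm &
      (if (dependence_mode == "absent") m_ppm < thresholds$product_detect_ppm
       else c_ppm / pmax(m_ppm, 0.01) >= thresholds$product_min_fold)
    length(unique(focal_excl$transcript_id[dep]))
  })

  ## extrapolation from the focal piRNA species fraction
  focal_fraction <- mean(groups$locus %in% world$focal_loci)
  extrapolated <- extrapolate_targets(perm$median, focal_fraction)

  ## steady-state derepression contrast
  rnaseq <- world$counts$rnaseq
  gene_rows <- !(rownames(rnaseq) %in% world$spike_rna$name)
  contrast <- nb_contrast(rnaseq[gene_rows, , drop = FALSE],
                          ctrl_cols, mut_cols)
  classes <- classify_derepression(contrast, thresholds$fdr,
                                   thresholds$derepression_fold)
  ks_derepression <- if (length(hc_transcripts) > 0L &&
                         length(control_transcripts) > 0L)
    compare_target_vs_control_foldchange(contrast, hc_transcripts,
                                         control_transcripts)
  else NULL

  ## translational efficiency (mutant vs control change)
  tpm_mrna <- ppm_matrix(rnaseq[gene_rows, , drop = FALSE])
  tpm_ribo <- ppm_matrix(world$counts$ribo)
  te_ctrl <- compute_te(rowMeans(tpm_mrna[, ctrl_cols]),
                        rowMeans(tpm_ribo[, ctrl_cols]),
                        thresholds$occupancy_min_tpm)
  te_mut <- compute_te(rowMeans(tpm_mrna[, mut_cols]),
                       rowMeans(tpm_ribo[, mut_cols]),
                       thresholds$occupancy_min_tpm)
  common <- intersect(te_ctrl$gene[te_ctrl$passes_filter], te_mut$gene)
  delta_te <- setNames(
    te_mut$te[match(common, te_mut$gene)] /
      te_ctrl$te[match(common, te_ctrl$gene)], common)
  ks_te <- if (length(intersect(common, hc_transcripts)) > 0L &&
               length(intersect(common, control_transcripts)) > 0L)
    test_activation_model(delta_te, hc_transcripts, control_transcripts)
  else NULL

  ## polymerase density and the transcription-rate contrasts
  gro <- world$counts$groseq
  gene_len <- setNames(world$rates$length, world$rates$transcript_id)
  dens_rep <- vapply(seq_len(ncol(gro)), function(j)
    polII_density(gro[, j], gene_len[rownames(gro)], sum(gro[, j]),
                  thresholds$groseq_exclude_bp), numeric(nrow(gro)))
  density <- setNames(rowMeans(dens_rep), rownames(gro))
  universe <- world$rates$transcript_id[world$rates$copies_control > 5]
  lfc <- setNames(contrast$log2fc, contrast$gene)
  fc_split <- split_by_foldchange(
    lfc[intersect(hc_transcripts, names(lfc))],
    thresholds$density_boundary_fold)
  gro_fc <- if (length(fc_split$low) > 0L && length(fc_split$high) > 0L)
    compare_classes(density, fc_split$low, fc_split$high) else NULL
  target_any <- unique(calls$transcript_id)
  nontargets <- setdiff(universe, target_any)
  gro_target <- if (length(intersect(universe, target_any)) > 0L &&
                    length(nontargets) > 0L)
    compare_classes(density, intersect(universe, target_any), nontargets)
  else NULL

  structure(
    list(
      world = world, thresholds = thresholds,
      dependence_mode = dependence_mode,
      groups = groups, products = products, calls = calls,
      dependence = dependence, focal_calls = focal_calls,
      hc_transcripts = hc_transcripts,
      control_transcripts = control_transcripts,
      permutation = perm, focal_fraction = focal_fraction,
      extrapolated_targets = extrapolated,
      contrast = contrast, derepression_classes = classes,
      ks_derepression = ks_derepression,
      delta_te = delta_te, ks_te = ks_te,
      density = density, gro_foldchange = gro_fc, gro_target = gro_target
    ),
    class = "pislice_report"
  )
}

#' @export
print.pislice_report <- function(x, ...) {
  cat("pislice_report\n")
  cat("  retained piRNA groups:", nrow(x$groups),
      sprintf("(focal fraction %.3f)", x$focal_fraction), "\n")
  cat("  detected cleavage products:", nrow(x$products), "\n")
  cat("  high-confidence targets:", length(x$hc_transcripts),
      sprintf("(permutation median %g, IQR %g-%g)",
              x$permutation$median, x$permutation$q25, x$permutation$q75),
      "\n")
  cat("  control targets:", length(x$control_transcripts), "\n")
  cat("  extrapolated transcriptome-wide targets:",
      x$extrapolated_targets, "\n")
  if (!is.null(x$ks_derepression))
    cat(sprintf("  derepression KS: D = %.3f, p = %.3g\n",
                x$ks_derepression$statistic, x$ks_derepression$p_value))
  if (!is.null(x$ks_te))
    cat(sprintf("  delta-TE KS: D = %.3f, p = %.3g\n",
                x$ks_te$statistic, x$ks_te$p_value))
  invisible(x)
}
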