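# Configuration of the synthetic study. The defaults define the simulated
# study conditions: two genotypes (control and a double-knockout of the
# focal piRNA loci) with four replicates each, sequencing depth 1e6,
# negative-binomial dispersion 0.05, and a piRNA population whose abundances
# span roughly 0.01-10 nM after scaling, mirroring the concentration range
# observed in primary spermatocytes.

#' Default spike-in set: nine equimolar synthetic oligonucleotides
#'
#' @param molecules_each molecules of each oligo added per library.
#' @return a [spike_in_set()].
#' @export
default_spike_ins <- function(molecules_each = 1e4) {
  # fixed arbitrary 30-mers, chosen once; content is irrelevant beyond
  # being distinct from simulated piRNAs with overwhelming probability
  seqs <- c(
    "ACGTACGTTAGCCTAGGATCCATGCAAGTC",
    "TTGACCATGGCGTATACCGGTTAACGTAGC",
    "GGCATTACGATCGTACGGATCCTTAGCAAC",
    "CCATGGTTAACGGCATACGTAGGCTAATCG",
    "ATCGGATATGCCTTGACGCGTATAGCCTGA",
    "TGCAATCCGGTATGCGATACCTTGGAACGT",
    "GATCCGTAACGGTTACGCATGGCTATACGA",
    "CAGTTAGCGGCATCCGATATACGGTTGACC",
    "TACGGACCTTAGCGTTAGCATCCGGATAAC"
  )
  spike_in_set(sprintf("spike_%02d", seq_along(seqs)), seqs,
               rep(molecules_each, length(seqs)))
}

#' Configure a synthetic study
#'
#' @param seed integer RNG seed; a fixed seed makes the generated world
#'   byte-identical.
#' @param n_transcripts number of transcripts.
#' @param n_loci number of piRNA-producing loci; the first `n_focal_loci`
#'   are the focal (knocked-out) loci and, when `n_loci` permits, the last
#'   locus is flagged as biogenesis-dependent on the focal loci.
#' @param n_pirnas_per_locus guides per locus.
#' @param pirna_abundance log-normal parameters (`meanlog`, `sdlog`) for
#'   relative piRNA abundance; draws are rescaled to sum to 1e6 ppm, so only
#'   `sdlog` shapes the distribution.
#' @param frac_planted_targets fraction of transcripts given one true
#'   cleavage site.
#' @param tier_mix named proportions (summing to 1) of planted sites per
#'   pairing rule R1-R4.
#' @param k_tx_range transcription rate range (arbitrary units/h).
#' @param k_dec_range decay rate range (1/h).
#' @param k_slice_range slicing rate range for planted targets (1/h).
#' @param nb_dispersion negative-binomial dispersion of replicate counts.
#' @param depth reads per library.
#' @param n_replicates replicates per genotype.
#' @param spike_in a [spike_in_set()] for the small-RNA libraries.
#' @param cell_volume_um3 cell volume used for pM conversions (default 1800).
#' @param total_pirnas_per_cell piRNA molecules per cell (default 1e7).
#' @param n_focal_loci number of knocked-out loci (default 2).
#' @param frac_repeat_derived fraction of guides flagged repeat-derived.
#' @param background_degradome_frac fraction of degradome reads assigned to
#'   background (non-planted) 5'-end species.
#' @param n_background_species number of background degradome species.
#' @param spike_read_frac fraction of small-RNA reads from spike-ins.
#' @return a validated `sim_config` list.
#' @export
sim_config <- function(seed = 1L,
                       n_transcripts = 200L,
                       n_loci = 10L,
                       n_pirnas_per_locus = 30L,
                       pirna_abundance = c(meanlog = 0, sdlog = 2.5),
                       frac_planted_targets = 0.3,
                       tier_mix = c(R1 = 0.25, R2 = 0.25, R3 = 0.25, R4 = 0.25),
                       k_tx_range = c(1, 100),
                       k_dec_range = c(0.1, 1),
                       k_slice_range = c(0.05, 0.6),
                       nb_dispersion = 0.05,
                       depth = 1e6,
                       n_replicates = 4L,
                       spike_in = default_spike_ins(),
                       cell_volume_um3 = 1800,
                       total_pirnas_per_cell = 1e7,
                       n_focal_loci = 2L,
                       frac_repeat_derived = 0.17,
                       background_degradome_frac = 0.05,
                       n_background_species = 300L,
                       spike_read_frac = 0.02) {
  cfg <- list(
    seed = as.integer(seed), n_transcripts = as.integer(n_transcripts),
    n_loci = as.integer(n_loci),
    n_pirnas_per_locus = as.integer(n_pirnas_per_locus),
    pirna_abundance = pirna_abundance,
    frac_planted_targets = frac_planted_targets, tier_mix = tier_mix,
    k_tx_range = k_tx_range, k_dec_range = k_dec_range,
    k_slice_range = k_slice_range, nb_dispersion = nb_dispersion,
    depth = depth, n_replicates = as.integer(n_replicates),
    spike_in = spike_in, cell_volume_um3 = cell_volume_um3,
    total_pirnas_per_cell = total_pirnas_per_cell,
    n_focal_loci = as.integer(n_focal_loci),
    frac_repeat_derived = frac_repeat_derived,
    background_degradome_frac = background_degradome_frac,
    n_background_species = as.integer(n_background_species),
    spike_read_frac = spike_read_frac
  )
  validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

validate_sim_config <- function(cfg) {
  if (cfg$depth <= 0) stop("configuration error: depth must be positive")
  rates <- c(cfg$k_tx_range, cfg$k_dec_range, cfg$k_slice_range)
  if (any(rates <= 0)) stop("configuration error: all rates must be positive")
  if (abs(sum(cfg$tier_mix) - 1) > 1e-8)
    stop("configuration error: tier_mix must sum to 1")
  if (!all(names(cfg$tier_mix) %in% tier_rules()$rule))
    stop("configuration error: tier_mix names must be rules R1-R4")
  if (cfg$nb_dispersion <= 0)
    stop("configuration error: nb_dispersion must be positive")
  if (cfg$n_replicates < 1L) stop("configuration error: need >= 1 replicate")
  if (cfg$frac_planted_targets < 0 || cfg$frac_planted_targets > 1)
    stop("configuration error: frac_planted_targets must lie in [0, 1]")
  if (cfg$n_focal_loci < 1L || cfg$n_focal_loci >= cfg$n_loci)
    stop("configuration error: need 1 <= n_focal_loci < n_loci")
  invisible(cfg)
}

#' Read / write a simulation configuration as YAML
#'
#' The spike-in set is serialized with its entries; all other fields map
#' directly.
#'
#' @param path YAML file path.
#' @rdname sim_config_yaml
#' @export
read_sim_config <- function(path) {
  y <- yaml::read_yaml(path)
  spikes <- if (!is.null(y$spike_in)) {
    spike_in_set(
      vapply(y$spike_in, `[[`, character(1), "name"),
      vapply(y$spike_in, `[[`, character(1), "sequence"),
      vapply(y$spike_in, function(e) as.numeric(e$molecules_added), numeric(1))
    )
  } else default_spike_ins()
  y$spike_in <- NULL
  args <- y
  for (nm in c("pirna_abundance", "tier_mix"))
    if (!is.null(args[[nm]])) args[[nm]] <- unlist(args[[nm]])
  do.call(sim_config, c(args, list(spike_in = spikes)))
}

#' @param config a `sim_config`.
#' @rdname sim_config_yaml
#' @export
write_sim_config <- function(config, path) {
  y <- unclass(config)
  y$pirna_abundance <- as.list(y$pirna_abundance)
  y$tier_mix <- as.list(y$tier_mix)
  y$spike_in <- lapply(seq_len(nrow(config$spike_in)), function(i)
    list(name = config$spike_in$name[i],
         sequence = config$spike_in$sequence[i],
         molecules_added = config$spike_in$molecules_added[i]))
  yaml::write_yaml(y, path)
  invisible(path)
}
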