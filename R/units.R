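# Absolute-abundance unit conversions. A primary spermatocyte holds on the
# order of 1e7 piRNAs in a median volume of 1800 um^3, so 1 ppm of the
# small-RNA library corresponds to ~10 molecules per cell and 1 molecule per
# cell to ~1 pM.

AVOGADRO <- 6.02214076e23

#' Convert library ppm to molecules per cell
#'
#' @param ppm abundance in parts per million of the (non-spike) library.
#' @param total_per_cell total number of molecules of the small-RNA class per
#'   cell; default 1e7 piRNAs per primary spermatocyte.
#' @return molecules per cell.
#' @examples
#' ppm_to_molecules(1)   # 10 molecules / cell
#' ppm_to_molecules(50)  # 500
#' @export
ppm_to_molecules <- function(ppm, total_per_cell = 1e7) {
  if (total_per_cell <= 0) stop("total_per_cell must be positive")
  if (any(ppm < 0)) stop("ppm must be non-negative")
  ppm * total_per_cell * 1e-6
}

#' Convert molecules per cell to intracellular concentration (pM)
#'
#' @param n molecules per cell.
#' @param cell_volume_um3 cell volume in cubic micrometers; default 1800,
#'   the median volume of a primary spermatocyte.
#' @return concentration in pM. One molecule in 1800 um^3 is ~0.92 pM.
#' @export
molecules_to_pM <- function(n, cell_volume_um3 = 1800) {
  if (cell_volume_um3 <= 0) stop("cell volume must be positive")
  if (any(n < 0)) stop("molecule counts must be non-negative")
  volume_l <- cell_volume_um3 * 1e-15
  n / (volume_l * AVOGADRO) * 1e12
}

#' Convert intracellular concentration (pM) to molecules per cell
#'
#' Inverse of [molecules_to_pM()].
#' @param pM concentration in pM.
#' @param cell_volume_um3 cell volume in cubic micrometers.
#' @return molecules per cell.
#' @export
pM_to_molecules <- function(pM, cell_volume_um3 = 1800) {
  if (cell_volume_um3 <= 0) stop("cell volume must be positive")
  if (any(pM < 0)) stop("concentrations must be non-negative")
  pM * 1e-12 * cell_volume_um3 * 1e-15 * AVOGADRO
}

#' Fraction of cells containing at least one molecule
#'
#' Given a mean number of molecules per cell, the probability that a cell
#' contains >= 1 molecule under a Poisson model (1 - exp(-mean)) or a
#' negative-binomial model with the given dispersion.
#'
#' @param mean_molecules mean molecules per cell (>= 0).
#' @param model `"poisson"` (default) or `"nb"`.
#' @param dispersion negative-binomial dispersion (var = mu + mu^2 * disp);
#'   only used for `model = "nb"`.
#' @return probability in `[0, 1]`.
#' @examples
#' detectability_probability(10)  # 0.9999546...
#' @export
detectability_probability <- function(mean_molecules,
                                      model = c("poisson", "nb"),
                                      dispersion = 0.1) {
  model <- match.arg(model)
  if (any(mean_molecules < 0)) stop("mean must be non-negative")
  if (model == "poisson") {
    1 - exp(-mean_molecules)
  } else {
    if (dispersion <= 0) stop("dispersion must be positive")
    size <- 1 / dispersion
    1 - (size / (size + mean_molecules))^size
  }
}
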