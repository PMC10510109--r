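#' Simulate paired NMR peak tables for CSP and PRE analysis
#'
#' Emulates the inputs of chemical-shift-perturbation and paramagnetic
#' relaxation enhancement analysis: a two-state peak list (reference vs
#' alternate ligand state) and a tagged/untagged intensity table. Reference
#' shifts are drawn in realistic amide windows (1H 7-10 ppm, 15N 105-130
#' ppm). Perturbed residues receive the stated 1H/15N shift offsets
#' exactly; their tagged intensities are attenuated by `pre_effect`
#' (I_tagged = I_untagged * (1 - pre_effect)). Multiplicative Gaussian
#' noise of fractional SD `noise_sd` is applied to intensities.
#'
#' @param n_residues Number of residues (rows).
#' @param perturbed Integer indices (subset of `1:n_residues`) of residues
#'   that respond to the perturbation.
#' @param csp_effect List with components `dH` and `dN` (ppm offsets applied
#'   to perturbed residues; recycled across them).
#' @param pre_effect Fractional intensity reduction in [0, 1) for perturbed
#'   residues (recycled).
#' @param noise_sd Fractional multiplicative noise SD on intensities
#'   (0 = noise-free).
#' @param seed Integer seed.
#' @return List of class `"nmr_sim"`: `peaks` (data frame `residue`,
#'   `H_ref_ppm`, `N_ref_ppm`, `H_alt_ppm`, `N_alt_ppm`), `intensities`
#'   (data frame `residue`, `I_tagged`, `I_untagged`) and `truth` (the
#'   perturbed set with applied effects).
#' @export
gen_nmr_tables <- function(n_residues, perturbed = integer(0),
                           csp_effect = list(dH = 0.1, dN = 0.5),
                           pre_effect = 0.5, noise_sd = 0, seed = 1L) {
  if (n_residues < 1) stopf("`n_residues` must be >= 1")
  perturbed <- as.integer(perturbed)
  if (length(perturbed) && (min(perturbed) < 1 || max(perturbed) > n_residues)) {
    stopf("`perturbed` must be a subset of 1..%d", n_residues)
  }
  if (any(pre_effect < 0 | pre_effect >= 1)) {
    stopf("`pre_effect` must lie in [0, 1)")
  }
  with_seed(seed, {
    res <- seq_len(n_residues)
    H_ref <- stats::runif(n_residues, 7, 10)
    N_ref <- stats::runif(n_residues, 105, 130)
    dH <- rep(0, n_residues); dN <- rep(0, n_residues)
    drop <- rep(0, n_residues)
    if (length(perturbed)) {
      dH[perturbed] <- rep_len(csp_effect$dH, length(perturbed))
      dN[perturbed] <- rep_len(csp_effect$dN, length(perturbed))
      drop[perturbed] <- rep_len(pre_effect, length(perturbed))
    }
    I_untagged <- stats::runif(n_residues, 0.5, 1.5)
    I_tagged <- I_untagged * (1 - drop)
    if (noise_sd > 0) {
      I_untagged <- I_untagged * (1 + stats::rnorm(n_residues, 0, noise_sd))
      I_tagged <- I_tagged * (1 + stats::rnorm(n_residues, 0, noise_sd))
      I_untagged <- pmax(I_untagged, .Machine$double.eps)
      I_tagged <- pmax(I_tagged, 0)
    }
    structure(list(
      peaks = data.frame(residue = res, H_ref_ppm = H_ref, N_ref_ppm = N_ref,
                         H_alt_ppm = H_ref + dH, N_alt_ppm = N_ref + dN),
      intensities = data.frame(residue = res, I_tagged = I_tagged,
                               I_untagged = I_untagged),
      truth = data.frame(residue = res, dH = dH, dN = dN, pre_effect = drop)
    ), class = "nmr_sim")
  })
}

#' @export
print.nmr_sim <- function(x, ...) {
  cat(sprintf("synthetic NMR tables: %d residues, %d perturbed\n",
              nrow(x$peaks), sum(x$truth$pre_effect > 0 | x$truth$dH != 0 | x$truth$dN != 0)))
  invisible(x)
}
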