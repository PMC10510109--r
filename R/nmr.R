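#' Combined 1H/15N chemical shift perturbation
#'
#' Per-residue CSP between two ligand states,
#' `CSP (ppm) = sqrt((dN^2/25 + dH^2)/2)`, the conventional combined shift
#' difference with the 15N axis down-weighted by its larger ppm range.
#' Residues with a missing state are skipped with a log entry. The value
#' depends only on the absolute shift differences, so swapping which state
#' is called "reference" leaves it unchanged.
#'
#' @param pairs Data frame with columns `residue`, `H_ref_ppm`,
#'   `N_ref_ppm`, `H_alt_ppm`, `N_alt_ppm` (see [gen_nmr_tables()]).
#' @return Data frame `residue`, `csp_ppm`.
#' @examples
#' pk <- data.frame(residue = 1, H_ref_ppm = 8, N_ref_ppm = 120,
#'                  H_alt_ppm = 8.1, N_alt_ppm = 120.5)
#' compute_csp(pk)$csp_ppm  # 0.1
#' @export
compute_csp <- function(pairs) {
  need <- c("residue", "H_ref_ppm", "N_ref_ppm", "H_alt_ppm", "N_alt_ppm")
  miss <- setdiff(need, names(pairs))
  if (length(miss)) stopf("peak table missing column(s): %s", paste(miss, collapse = ", "))
  ok <- stats::complete.cases(pairs[, need])
  if (any(!ok)) {
    mn_log(sprintf("compute_csp: %d residue(s) skipped (missing state)", sum(!ok)))
  }
  p <- pairs[ok, ]
  dH <- p$H_alt_ppm - p$H_ref_ppm
  dN <- p$N_alt_ppm - p$N_ref_ppm
  data.frame(residue = p$residue, csp_ppm = sqrt((dN^2 / 25 + dH^2) / 2))
}

#' Normalised paramagnetic relaxation enhancement ratios
#'
#' Per-residue tagged/untagged intensity ratios, normalised so the
#' least-attenuated residue is exactly 1. Residues close to the
#' paramagnetic tag (here, the membrane surface) are broadened and show
#' small ratios. By default the raw ratios are divided by their maximum
#' (`method = "max"`); alternatively a user-named set of unaffected
#' residues can serve as the reference (`method = "reference"`, divide by
#' their mean raw ratio). Output is scale-invariant: rescaling all
#' intensities of either spectrum leaves it unchanged.
#'
#' @param pairs Data frame with columns `residue`, `I_tagged`,
#'   `I_untagged`.
#' @param method `"max"` (default) or `"reference"`.
#' @param reference_residues Residue indices used when
#'   `method = "reference"`.
#' @return Data frame `residue`, `raw_ratio`, `pre_ratio`. Residues with
#'   zero untagged intensity are excluded with a log entry.
#' @export
compute_pre_ratios <- function(pairs, method = c("max", "reference"),
                               reference_residues = NULL) {
  method <- match.arg(method)
  need <- c("residue", "I_tagged", "I_untagged")
  miss <- setdiff(need, names(pairs))
  if (length(miss)) stopf("intensity table missing column(s): %s", paste(miss, collapse = ", "))
  if (any(pairs$I_tagged < 0 | pairs$I_untagged < 0, na.rm = TRUE)) {
    stopf("intensities must be non-negative")
  }
  ok <- is.finite(pairs$I_untagged) & pairs$I_untagged > 0 & is.finite(pairs$I_tagged)
  if (any(!ok)) {
    mn_log(sprintf("compute_pre_ratios: %d residue(s) excluded (zero/missing untagged intensity)", sum(!ok)))
  }
  p <- pairs[ok, ]
  if (!nrow(p)) stopf("no residues with positive untagged intensity")
  raw <- p$I_tagged / p$I_untagged
  denom <- switch(method,
    max = max(raw),
    reference = {
      if (is.null(reference_residues)) stopf("`reference_residues` required for method = 'reference'")
      sel <- p$residue %in% reference_residues
      if (!any(sel)) stopf("none of the reference residues are present")
      mean(raw[sel])
    })
  if (denom <= 0) stopf("normalisation denominator is not positive")
  data.frame(residue = p$residue, raw_ratio = raw, pre_ratio = raw / denom)
}

# --- TRACT ------------------------------------------------------------------

# Physical constants for the 15N CSA / 1H-15N dipole cross-correlation.
.tract_const <- list(
  mu0 = 4e-7 * pi,        # vacuum permeability (T m / A)
  hbar = 1.054571817e-34, # reduced Planck constant (J s)
  gammaH = 2.6752218744e8,# 1H gyromagnetic ratio (rad/s/T)
  gammaN = 2.7116e7,      # |15N| gyromagnetic ratio (rad/s/T)
  rNH = 1.02e-10,         # N-H bond length (m)
  csaN = 160e-6,          # 15N CSA (ppm)
  theta = 17 * pi / 180   # angle between CSA axis and NH bond
)

#' TRACT alpha/beta rate difference for a given correlation time
#'
#' Forward rigid-rotor relation between the rotational correlation time
#' and the TROSY/anti-TROSY relaxation-rate difference
#' `delta_R = 2 * eta_xy`, where `eta_xy` is the transverse 15N CSA /
#' 1H-15N dipole cross-correlated relaxation rate,
#' `eta_xy = p * dN * (3 cos^2(theta) - 1) * (4 J(0) + 3 J(wN))` with the
#' rigid isotropic spectral density `J(w) = (2/5) tau_c / (1 + (w tau_c)^2)`.
#' This relation is strictly increasing in `tau_c`, which is what lets
#' [fit_tract()] invert it numerically.
#'
#' @param tau_c_ns Rotational correlation time(s) in ns.
#' @param field_MHz Spectrometer 1H frequency in MHz (default 900).
#' @return `delta_R` in 1/s (vectorised over `tau_c_ns`).
#' @export
tract_delta_r <- function(tau_c_ns, field_MHz = 900) {
  cst <- .tract_const
  tau <- tau_c_ns * 1e-9
  B0 <- 2 * pi * field_MHz * 1e6 / cst$gammaH
  wN <- cst$gammaN * B0
  p <- cst$mu0 * cst$hbar * cst$gammaH * cst$gammaN /
    (8 * pi * sqrt(2) * cst$rNH^3)
  dN <- cst$gammaN * B0 * cst$csaN / (3 * sqrt(2))
  J <- function(w) 0.4 * tau / (1 + (w * tau)^2)
  eta <- p * dN * (3 * cos(cst$theta)^2 - 1) * (4 * J(0) + 3 * J(wN))
  2 * eta
}

#' Fit TRACT decays and estimate the rotational correlation time
#'
#' Fits the TROSY (alpha, slow) and anti-TROSY (beta, fast) 1D decay
#' series each to `I(t) = I0 * exp(-R * t)` by nonlinear least squares
#' (initialised from a log-linear fit; an additive offset can be enabled),
#' forms `delta_R = R_beta - R_alpha`, and numerically inverts
#' [tract_delta_r()] to obtain the rotational correlation time `tau_c` at
#' the stated field. Larger tau_c (slower tumbling, e.g. a protein held
#' at a membrane surface) gives a larger rate difference.
#'
#' @param decay_alpha,decay_beta [curve_trace()] objects (delays in s,
#'   intensities positive at delay 0); at least 5 points each.
#' @param field_MHz Spectrometer 1H frequency in MHz (default 900).
#' @param offset Fit an additive baseline offset (default FALSE).
#' @return Object of class `"tract_result"`: `R_alpha`, `R_beta`,
#'   `delta_R` (1/s), `tau_c_ns`, `field_MHz`, and the two fits.
#' @export
fit_tract <- function(decay_alpha, decay_beta, field_MHz = 900, offset = FALSE) {
  Ra <- fit_exp_rate(decay_alpha, offset, "alpha")
  Rb <- fit_exp_rate(decay_beta, offset, "beta")
  dR <- Rb$R - Ra$R
  if (dR < 0) {
    warning("R_beta < R_alpha: unphysical state assignment; tau_c not defined", call. = FALSE)
    tau <- NA_real_
  } else if (dR == 0) {
    tau <- 0
  } else {
    upper <- 1000
    if (tract_delta_r(upper, field_MHz) < dR) {
      stopf("delta_R = %.3g 1/s exceeds the rigid-rotor relation at tau_c = %g ns", dR, upper)
    }
    tau <- stats::uniroot(function(t) tract_delta_r(t, field_MHz) - dR,
                          lower = 1e-4, upper = upper, tol = 1e-10)$root
  }
  structure(list(R_alpha = Ra$R, R_beta = Rb$R, delta_R = dR,
                 tau_c_ns = tau, field_MHz = field_MHz,
                 fit_alpha = Ra$fit, fit_beta = Rb$fit),
            class = "tract_result")
}

# Mono-exponential rate fit with log-linear initialisation.
fit_exp_rate <- function(trace, offset, label) {
  stopifnot(inherits(trace, "curve_trace"))
  t <- trace$x; y <- trace$y
  if (length(t) < 5) stopf("%s decay needs at least 5 points", label)
  if (y[which.min(t)] <= 0) stopf("%s decay must have positive intensity at the first delay", label)
  pos <- y > 0
  if (sum(pos) < 3) stopf("%s decay has too few positive intensities for initialisation", label)
  ll <- stats::lm(log(y[pos]) ~ t[pos])
  R0 <- max(-unname(stats::coef(ll)[2]), 1e-3)
  I00 <- exp(unname(stats::coef(ll)[1]))
  df <- data.frame(t = t, y = y)
  fit <- if (offset) {
    minpack.lm::nlsLM(y ~ I0 * exp(-R * t) + C, data = df,
                      start = list(I0 = I00, R = R0, C = 0),
                      control = minpack.lm::nls.lm.control(maxiter = 200))
  } else {
    minpack.lm::nlsLM(y ~ I0 * exp(-R * t), data = df,
                      start = list(I0 = I00, R = R0),
                      control = minpack.lm::nls.lm.control(maxiter = 200))
  }
  if (!fit$convInfo$isConv) {
    stopf("%s decay fit did not converge (RSS = %.3g)", label,
          sum(stats::residuals(fit)^2))
  }
  list(R = unname(stats::coef(fit)["R"]), fit = fit)
}

#' @export
print.tract_result <- function(x, ...) {
  cat(sprintf("TRACT at %g MHz: R_alpha = %.2f, R_beta = %.2f, delta_R = %.2f 1/s\n",
              x$field_MHz, x$R_alpha, x$R_beta, x$delta_R))
  cat(sprintf("  rotational correlation time tau_c = %.2f ns\n", x$tau_c_ns))
  invisible(x)
}
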