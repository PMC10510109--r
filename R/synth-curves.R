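#' Default TRACT relaxation-delay schedules
#'
#' The delay grids used to sample TROSY (alpha) and anti-TROSY (beta)
#' relaxation decays, in seconds. The beta state relaxes faster so its
#' schedule is denser and shorter.
#'
#' @return List with components `alpha` and `beta` (delays in seconds).
#' @export
tract_delays <- function() {
  list(
    alpha = c(0, 5, 10, 16, 22, 30, 40, 50, 64, 80, 100, 130, 170, 240) / 1000,
    beta  = c(0, 1, 2, 4, 7, 11, 15, 20, 26, 32, 39, 47, 56, 70) / 1000
  )
}

#' Default DSF temperature grid: 25-95 degC in 0.5 degC steps
#' @return Numeric vector of temperatures (degC).
#' @export
dsf_grid <- function() seq(25, 95, by = 0.5)

#' Simulate an assay curve
#'
#' Generates the four curve families the package fits, with known ground
#' truth and multiplicative Gaussian noise proportional to the signal:
#'
#' * `tract`: mono-exponential decay `I0 * exp(-R * t)`; `params` needs
#'   `I0`, `R` (1/s); grid in seconds.
#' * `melt`: thermal-unfolding sigmoid
#'   `base + amplitude / (1 + exp(-(T - Tm)/width))`, optionally with a
#'   linear post-transition decline `post_slope * pmax(T - Tm, 0)`;
#'   `params` needs `Tm` (degC), `width` (degC), optional `base`,
#'   `amplitude`, `post_slope`; grid in degC.
#' * `dls`: continuous two-segment line in log10(concentration):
#'   slope `slope_below` up to the breakpoint `log10(cac)`, then
#'   `slope_above`; `params` needs `cac` (nM), `slope_below`,
#'   `slope_above`, optional `intercept`; grid in log10(nM). The default
#'   `cac = 80` nM mirrors the aggregation onset reported for
#'   long-lipid-tail inhibitor conjugates.
#' * `flim`: fluorescence decay `I0 * exp(-t / tau) + offset`; `params`
#'   needs `I0`, `tau` (ns), optional `offset`; grid in ns.
#'
#' @param kind One of `"tract"`, `"melt"`, `"dls"`, `"flim"`.
#' @param params Named list of kind-specific parameters (see Details).
#' @param grid Strictly increasing abscissa; defaults per kind
#'   ([tract_delays()] alpha grid, [dsf_grid()], `seq(0.5, 4, by = 0.1)`
#'   log10 nM, `seq(0, 25, by = 0.1)` ns).
#' @param noise_sd Fractional Gaussian noise SD (proportional to signal).
#' @param seed Integer seed.
#' @return A [curve_trace()] with a `truth` attribute holding `params`.
#' @export
gen_curve <- function(kind = c("tract", "melt", "dls", "flim"),
                      params = list(), grid = NULL, noise_sd = 0, seed = 1L) {
  kind <- match.arg(kind)
  p <- params
  default <- function(name, val) if (is.null(p[[name]])) val else p[[name]]
  out <- switch(kind,
    tract = {
      if (is.null(grid)) grid <- tract_delays()$alpha
      I0 <- default("I0", 1); R <- default("R", 20)
      list(y = I0 * exp(-R * grid), xu = "s")
    },
    melt = {
      if (is.null(grid)) grid <- dsf_grid()
      Tm <- default("Tm", 55); w <- default("width", 2)
      base <- default("base", 0.05); amp <- default("amplitude", 1)
      post <- default("post_slope", 0)
      y <- base + amp / (1 + exp(-(grid - Tm) / w)) - post * pmax(grid - Tm, 0)
      list(y = y, xu = "degC")
    },
    dls = {
      cac <- default("cac", 80)
      # default grid samples the onset itself (a titration would bracket it)
      if (is.null(grid)) grid <- sort(unique(c(seq(0.5, 4, by = 0.1), log10(cac))))
      sb <- default("slope_below", 0.2); sa <- default("slope_above", 5)
      b0 <- default("intercept", 1)
      bp <- log10(cac)
      y <- b0 + sb * grid + (sa - sb) * pmax(grid - bp, 0)
      list(y = y, xu = "log10_nM")
    },
    flim = {
      if (is.null(grid)) grid <- seq(0, 25, by = 0.1)
      I0 <- default("I0", 1e4); tau <- default("tau", 2.6)
      off <- default("offset", 0)
      list(y = I0 * exp(-grid / tau) + off, xu = "ns")
    }
  )
  y <- out$y
  if (noise_sd > 0) {
    y <- with_seed(seed, y * (1 + stats::rnorm(length(y), 0, noise_sd)))
  }
  tr <- curve_trace(grid, y, kind = kind, x_unit = out$xu)
  attr(tr, "truth") <- p
  tr
}
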