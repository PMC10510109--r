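#' Isotropic edge-correction weight
#'
#' For a circle centred at a point inside a rectangular region, computes the
#' inverse of the proportion of its circumference that lies inside the
#' region. This is the classical isotropic correction for Ripley's
#' K-function: pairs whose circle is cut by the sheet boundary are
#' up-weighted to compensate for neighbours that fall outside the observed
#' area. The proportion is computed analytically from arc geometry
#' (exterior arcs for each edge closer than the radius, with
#' inclusion-exclusion at the corners), never by sampling.
#'
#' @param center Numeric `c(x, y)`, inside the region.
#' @param distance Circle radius (> 0), same unit as the region.
#' @param region A [region()].
#' @return Weight `1/p >= 1`. Errors if the circle lies entirely outside
#'   the region (p = 0).
#' @examples
#' r <- region(1000, 1000)
#' edge_weight(c(500, 500), 100, r)  # fully interior: 1
#' edge_weight(c(0, 500), 100, r)    # on an edge: 2
#' edge_weight(c(0, 0), 100, r)      # on a corner: 4
#' @export
edge_weight <- function(center, distance, region) {
  stopifnot(inherits(region, "region"), length(center) == 2)
  if (any(distance <= 0)) stopf("`distance` must be > 0")
  if (center[1] < 0 || center[1] > region$width ||
      center[2] < 0 || center[2] > region$height) {
    stopf("`center` must lie inside the region")
  }
  w <- edge_weights(rep(center[1], length(distance)),
                    rep(center[2], length(distance)), distance, region)
  if (any(!is.finite(w))) {
    stopf("circle of radius %g about (%g, %g) lies entirely outside the region",
          distance[!is.finite(w)][1], center[1], center[2])
  }
  w
}

# Vectorised workhorse: weights for circles centred at (x, y) with radii d.
# Returns Inf where the inside proportion is <= 0.
edge_weights <- function(x, y, d, region) {
  # exterior arc per edge: 2*acos(dist/r), zero once the edge is beyond r
  # (acos is clipped at 1); corner overlap acos(dx/r)+acos(dy/r)-pi/2 is
  # positive exactly when the corner lies inside the circle, so pmax(.,0)
  # applies the inclusion-exclusion without branching
  a1 <- acos(pmin(x / d, 1))
  a2 <- acos(pmin((region$width - x) / d, 1))
  a3 <- acos(pmin(y / d, 1))
  a4 <- acos(pmin((region$height - y) / d, 1))
  halfpi <- pi / 2
  ext <- 2 * (a1 + a2 + a3 + a4) -
    pmax(a1 + a3 - halfpi, 0) - pmax(a1 + a4 - halfpi, 0) -
    pmax(a2 + a3 - halfpi, 0) - pmax(a2 + a4 - halfpi, 0)
  p <- 1 - ext / (2 * pi)
  w <- 1 / p
  w[p <= 1e-12] <- Inf
  w
}

# Validate a radius grid against a region.
check_radii <- function(radii, region = NULL) {
  radii <- as.numeric(radii)
  if (length(radii) == 0) stopf("the radius grid is empty")
  if (any(!is.finite(radii)) || min(radii) <= 0) stopf("radii must be positive")
  if (any(diff(radii) <= 0)) stopf("radii must be strictly increasing")
  if (!is.null(region) && max(radii) > min(region$width, region$height) / 2) {
    warning(sprintf(
      "max radius %g exceeds half the shorter region side (%g); edge weights become unstable",
      max(radii), min(region$width, region$height) / 2), call. = FALSE)
  }
  radii
}

#' Default radius grid for nanocluster analysis
#'
#' 1-240 nm in 1 nm steps: covers the length scales of membrane
#' nanoclusters on a 1 um^2 sheet while keeping edge weights well defined.
#'
#' @param rmax Largest radius (nm). @param by Step (nm).
#' @return Numeric radius vector.
#' @export
radius_grid <- function(rmax = 240, by = 1) seq(by, rmax, by = by)

#' Edge-corrected Ripley's K-function
#'
#' Estimates the univariate K-function of a point pattern on a rectangular
#' sheet with the standard unbiased isotropic-corrected estimator:
#' \deqn{\hat K(r) = \frac{A}{n(n-1)} \sum_i \sum_{j \ne i}
#'   w_{ij}\, 1(\lVert x_i - x_j \rVert \le r)}
#' where `A` is the sheet area, `n` the point count and `w_ij` the
#' isotropic edge-correction weight ([edge_weight()]) for the circle
#' centred at `x_i` through `x_j`. The `n(n-1)` pair normalisation makes
#' the estimator exactly unbiased under complete spatial randomness,
#' where `K(r) = pi r^2`; values above that indicate clustering at
#' scale r.
#'
#' @param pattern A [point_pattern()] with at least 2 points.
#' @param radii Strictly increasing positive radii (same unit as the
#'   region); default [radius_grid()].
#' @param correction `"isotropic"` (default) or `"none"` (all weights 1;
#'   negatively biased near the boundary, provided for comparison).
#' @return Object of class `"k_estimate"`: `radii`, `k` (area units),
#'   `n`, `area`, `correction`.
#' @export
ripley_k <- function(pattern, radii = radius_grid(),
                     correction = c("isotropic", "none")) {
  stopifnot(inherits(pattern, "point_pattern"))
  correction <- match.arg(correction)
  radii <- check_radii(radii, pattern$region)
  n <- pattern$n
  if (n < 2) stopf("Ripley's K needs at least 2 points (pattern has %d)", n)
  d <- as.vector(stats::dist(cbind(pattern$x, pattern$y)))
  # pair indices matching dist() order: (1,2), (1,3), ..., (n-1,n)
  i_idx <- rep.int(seq_len(n - 1L), (n - 1L):1L)
  j_idx <- sequence((n - 1L):1L) + i_idx
  rmax <- max(radii)
  keep <- d <= rmax
  d <- d[keep]; i_idx <- i_idx[keep]; j_idx <- j_idx[keep]
  if (length(d)) {
    if (correction == "isotropic") {
      pos <- d > 0
      wsum <- rep(2, length(d))  # coincident pairs: circle of radius 0, w = 1 each
      if (any(pos)) {
        wi <- edge_weights(pattern$x[i_idx[pos]], pattern$y[i_idx[pos]], d[pos], pattern$region)
        wj <- edge_weights(pattern$x[j_idx[pos]], pattern$y[j_idx[pos]], d[pos], pattern$region)
        if (any(!is.finite(wi)) || any(!is.finite(wj))) {
          stopf("an edge-correction circle lies entirely outside the region; reduce the radius grid")
        }
        wsum[pos] <- wi + wj
      }
    } else {
      wsum <- rep(2, length(d))
    }
    ord <- order(d)
    cw <- cumsum(wsum[ord])
    counts <- findInterval(radii, d[ord])
    k <- pattern$region$area / (n * (n - 1)) * ifelse(counts > 0, cw[pmax(counts, 1L)], 0)
  } else {
    k <- rep(0, length(radii))
  }
  structure(list(radii = radii, k = k, n = n, area = pattern$region$area,
                 correction = correction),
            class = "k_estimate")
}

#' @export
print.k_estimate <- function(x, ...) {
  cat(sprintf("Ripley's K estimate (%s correction): n = %d, %d radii in [%g, %g]\n",
              x$correction, x$n, length(x$radii), min(x$radii), max(x$radii)))
  invisible(x)
}

#' L(r) - r transform of a K estimate
#'
#' The variance-stabilised linearisation `L(r) = sqrt(K(r)/pi)`, reported as
#' `L(r) - r`: zero under complete spatial randomness, positive where the
#' pattern is clustered at scale r.
#'
#' @param k A [ripley_k()] result.
#' @return Object of class `"l_curve"`: `radii`, `l_minus_r`, `n`.
#' @export
l_curve <- function(k) {
  stopifnot(inherits(k, "k_estimate"))
  structure(list(radii = k$radii, l_minus_r = sqrt(k$k / pi) - k$radii, n = k$n),
            class = "l_curve")
}

#' @export
print.l_curve <- function(x, ...) {
  cat(sprintf("L(r) - r curve: n = %d, max %.3g at r = %g\n",
              x$n, max(x$l_minus_r), x$radii[which.max(x$l_minus_r)]))
  invisible(x)
}

#' @export
plot.l_curve <- function(x, ...) {
  plot(x$radii, x$l_minus_r, type = "l", xlab = "r", ylab = "L(r) - r", ...)
  graphics::abline(h = 0, lty = 2, col = "grey50")
  invisible(x)
}

#' Monte-Carlo CSR envelope for L(r) - r
#'
#' Simulates `n_sims` CSR patterns with the same number of points on the
#' same region and returns the pointwise `percentile`-th percentile of
#' their L(r) - r values at each radius. Dividing an observed curve by
#' this envelope puts the CSR confidence limit at 1, so normalized values
#' above 1 indicate statistically meaningful clustering at that scale.
#'
#' @param n Point count the envelope is conditioned on (>= 2).
#' @param region A [region()].
#' @param radii Radius grid.
#' @param n_sims Number of CSR simulations (>= 100; default 1000).
#' @param percentile Pointwise percentile (default 99).
#' @param seed Integer seed; sub-seeds for individual simulations are
#'   derived deterministically.
#' @return Object of class `"csr_envelope"`: `radii`, `values`,
#'   `percentile`, `n_sims`, `n`, `region`.
#' @export
csr_envelope <- function(n, region, radii = radius_grid(), n_sims = 1000,
                         percentile = 99, seed = 1L) {
  stopifnot(inherits(region, "region"))
  if (n < 2) stopf("`n` must be >= 2")
  if (n_sims < 100) stopf("`n_sims` must be >= 100 for a stable percentile")
  radii <- check_radii(radii, region)
  lmat <- matrix(NA_real_, n_sims, length(radii))
  for (s in seq_len(n_sims)) {
    p <- gen_csr_pattern(n, region, derive_seed(seed, s))
    lmat[s, ] <- l_curve(ripley_k(p, radii))$l_minus_r
  }
  vals <- apply(lmat, 2, stats::quantile, probs = percentile / 100,
                names = FALSE, type = 7)
  structure(list(radii = radii, values = vals, percentile = percentile,
                 n_sims = n_sims, n = as.integer(n), region = region),
            class = "csr_envelope")
}

#' @export
print.csr_envelope <- function(x, ...) {
  cat(sprintf("CSR %g%% envelope: n = %d, %d sims, %d radii\n",
              x$percentile, x$n, x$n_sims, length(x$radii)))
  invisible(x)
}

#' Normalise an L(r) - r curve by a CSR envelope and extract L_max
#'
#' Divides the observed L(r) - r values by the pointwise CSR envelope so
#' that the confidence limit sits at 1. Radii where the envelope is not
#' positive are excluded from the curve and from the L_max search (a
#' non-positive "confidence interval" cannot meaningfully scale the
#' statistic). `L_max`, the maximum of the normalised curve, summarises
#' the extent of nanoclustering; ties are broken by the smallest radius.
#'
#' @param l An [l_curve()].
#' @param env A [csr_envelope()] on the same radius grid (and ideally the
#'   same n; a mismatch triggers a warning).
#' @return Object of class `"normalized_l_curve"`: `radii`, `values`,
#'   `l_max`, `r_at_max`, `n_excluded`.
#' @export
normalize_and_lmax <- function(l, env) {
  stopifnot(inherits(l, "l_curve"), inherits(env, "csr_envelope"))
  if (length(l$radii) != length(env$radii) ||
      any(abs(l$radii - env$radii) > 1e-9)) {
    stopf("the curve and the envelope use different radius grids")
  }
  if (!is.na(l$n) && l$n != env$n) {
    warning(sprintf("envelope computed at n = %d but curve has n = %d", env$n, l$n),
            call. = FALSE)
  }
  pos <- env$values > 0
  if (!any(pos)) stopf("the envelope is non-positive at every radius; cannot normalise")
  if (any(!pos)) {
    mn_log(sprintf("normalize_and_lmax: %d radii with non-positive envelope excluded", sum(!pos)))
  }
  vals <- l$l_minus_r[pos] / env$values[pos]
  idx <- which.max(vals)  # which.max returns the first maximum: smallest radius on ties
  structure(list(radii = l$radii[pos], values = vals,
                 l_max = vals[idx], r_at_max = l$radii[pos][idx],
                 n_excluded = sum(!pos)),
            class = "normalized_l_curve")
}

#' @export
print.normalized_l_curve <- function(x, ...) {
  cat(sprintf("normalised L(r) - r: L_max = %.3f at r = %g (1 = CSR %s)\n",
              x$l_max, x$r_at_max, "confidence limit"))
  invisible(x)
}

#' @export
plot.normalized_l_curve <- function(x, ...) {
  plot(x$radii, x$values, type = "l", xlab = "r",
       ylab = "normalised L(r) - r", ...)
  graphics::abline(h = 1, lty = 2, col = "grey50")
  invisible(x)
}

#' Full nanoclustering analysis of one sheet
#'
#' Convenience wrapper: K-function, L(r) - r, and normalisation by a CSR
#' envelope (built to match the pattern's n if not supplied).
#'
#' @param pattern A [point_pattern()].
#' @param envelope Optional precomputed [csr_envelope()]; built with the
#'   given `n_sims`/`percentile`/`seed` otherwise.
#' @param radii Radius grid.
#' @inheritParams csr_envelope
#' @return A [normalize_and_lmax()] result.
#' @export
analyze_sheet <- function(pattern, envelope = NULL, radii = radius_grid(),
                          n_sims = 1000, percentile = 99, seed = 1L) {
  stopifnot(inherits(pattern, "point_pattern"))
  if (is.null(envelope)) {
    envelope <- csr_envelope(pattern$n, pattern$region, radii,
                             n_sims = n_sims, percentile = percentile, seed = seed)
  }
  normalize_and_lmax(l_curve(ripley_k(pattern, envelope$radii)), envelope)
}

#' Bootstrap comparison of per-sheet L_max between two conditions
#'
#' Tests whether mean L_max differs between two groups of sheets. The
#' observed statistic is the difference of group means; the null is built
#' by pooling both groups and resampling two groups of the original sizes
#' with replacement `n_boot` times. The two-sided p-value is
#' `(1 + #{|boot| >= |obs|}) / (n_boot + 1)`, so it can never be smaller
#' than `1/(n_boot + 1)`.
#'
#' @param group_a,group_b Numeric vectors of per-sheet L_max values
#'   (typically >= 15 sheets per condition).
#' @param n_boot Number of bootstrap resamples (>= 1000).
#' @param seed Integer seed.
#' @return Object of class `"bootstrap_result"`: `observed_difference`,
#'   `p_value`, `n_boot`, `group_sizes`.
#' @export
bootstrap_lmax <- function(group_a, group_b, n_boot = 1000, seed = 1L) {
  group_a <- as.numeric(group_a); group_b <- as.numeric(group_b)
  if (length(group_a) == 0 || length(group_b) == 0) stopf("both groups must be non-empty")
  if (length(group_a) < 2 || length(group_b) < 2) {
    warning("groups with fewer than 2 sheets give a degenerate bootstrap", call. = FALSE)
  }
  if (n_boot < 1000) stopf("`n_boot` must be >= 1000")
  na <- length(group_a); nb <- length(group_b)
  obs <- mean(group_a) - mean(group_b)
  pooled <- c(group_a, group_b)
  boot <- with_seed(seed, {
    ma <- matrix(sample(pooled, na * n_boot, replace = TRUE), nrow = na)
    mb <- matrix(sample(pooled, nb * n_boot, replace = TRUE), nrow = nb)
    .colMeans(ma, na, n_boot) - .colMeans(mb, nb, n_boot)
  })
  p <- (1 + sum(abs(boot) >= abs(obs))) / (n_boot + 1)
  structure(list(observed_difference = obs, p_value = p,
                 n_boot = as.integer(n_boot), group_sizes = c(na, nb)),
            class = "bootstrap_result")
}

#' @export
print.bootstrap_result <- function(x, ...) {
  cat(sprintf("bootstrap test (%d vs %d sheets, %d resamples)\n",
              x$group_sizes[1], x$group_sizes[2], x$n_boot))
  cat(sprintf("  mean difference = %.4f, two-sided p = %.4g\n",
              x$observed_difference, x$p_value))
  invisible(x)
}

#' Gold labelling density with one-way ANOVA across conditions
#'
#' Computes per-sheet labelling density (points per um^2) and compares
#' group means with a standard one-way ANOVA. When all densities are
#' identical the F statistic is reported as 0 with p = 1.
#'
#' @param patterns List of [point_pattern()] objects (one per sheet).
#' @param groups Factor or character vector of condition labels, one per
#'   sheet; at least 2 groups with at least 2 sheets each.
#' @return Object of class `"density_anova"`: `densities` (data frame
#'   `sheet_id`, `n`, `area_um2`, `density_um2`, `group`), `F`, `p` and
#'   the underlying `anova` table.
#' @export
labeling_density <- function(patterns, groups) {
  if (!length(patterns) || !all(vapply(patterns, inherits, TRUE, "point_pattern"))) {
    stopf("`patterns` must be a non-empty list of point_pattern objects")
  }
  groups <- factor(groups)
  if (length(groups) != length(patterns)) stopf("one group label per pattern required")
  if (nlevels(groups) < 2) stopf("at least 2 groups are required")
  if (any(table(groups) < 2)) stopf("every group needs at least 2 sheets")
  to_um2 <- function(reg) {
    switch(reg$unit, nm = reg$area / 1e6, um = reg$area,
           stopf("unsupported region unit '%s' for density", reg$unit))
  }
  area <- vapply(patterns, function(p) to_um2(p$region), numeric(1))
  if (any(area <= 0)) stopf("a sheet has zero area")
  dens <- data.frame(
    sheet_id = vapply(patterns, function(p) as.character(p$sheet_id), character(1)),
    n = vapply(patterns, function(p) p$n, numeric(1)),
    area_um2 = area,
    density_um2 = vapply(patterns, function(p) p$n, numeric(1)) / area,
    group = groups
  )
  ss_between <- sum(tapply(dens$density_um2, groups, function(v) {
    length(v) * (mean(v) - mean(dens$density_um2))^2
  }))
  if (ss_between < .Machine$double.eps * max(1, mean(dens$density_um2))^2) {
    an <- NULL; Fv <- 0; pv <- 1
  } else {
    an <- suppressWarnings(stats::anova(stats::lm(density_um2 ~ group, data = dens)))
    Fv <- an[["F value"]][1]; pv <- an[["Pr(>F)"]][1]
    if (!is.finite(Fv)) { Fv <- Inf; pv <- 0 }  # zero within-group variance
  }
  structure(list(densities = dens, F = Fv, p = pv, anova = an),
            class = "density_anova")
}

#' @export
print.density_anova <- function(x, ...) {
  cat(sprintf("labelling density: %d sheets, %d groups; one-way ANOVA F = %.3g, p = %.4g\n",
              nrow(x$densities), nlevels(x$densities$group), x$F, x$p))
  invisible(x)
}
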