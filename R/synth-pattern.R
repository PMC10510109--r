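#' Simulate complete spatial randomness (CSR)
#'
#' Draws `n` points independently and uniformly over a rectangular region:
#' the homogeneous Poisson null (conditioned on n) against which
#' nanoclustering is judged. CSR patterns are the Monte-Carlo simulations
#' behind the 99% confidence envelope of the L(r) - r statistic.
#'
#' @param n Number of points (>= 0).
#' @param region A [region()].
#' @param seed Integer seed; identical seeds give identical patterns.
#' @return A [point_pattern()].
#' @examples
#' p <- gen_csr_pattern(300, region(1000, 1000), seed = 1)
#' @export
gen_csr_pattern <- function(n, region, seed) {
  stopifnot(inherits(region, "region"))
  if (!is.numeric(n) || length(n) != 1L || is.na(n) || n < 0 || n != round(n)) {
    stopf("`n` must be a single non-negative integer (got %s)", format(n)[1])
  }
  n <- as.integer(n)
  with_seed(seed, {
    point_pattern(stats::runif(n, 0, region$width),
                  stats::runif(n, 0, region$height),
                  region, sheet_id = sprintf("csr_seed%d", as.integer(seed)))
  })
}

#' Clustered point process model
#'
#' Parameters of a Thomas-type cluster process used to emulate immunogold
#' patterns of membrane nanoclusters: uniformly placed parent centres, each
#' emitting a discrete-uniform number of offspring (default 4-6, the
#' reported occupancy of K-Ras nanoclusters) displaced by an isotropic
#' Gaussian. The cluster radius is not reported for these nanoclusters;
#' `cluster_sd = 20` nm is a package default chosen to keep clusters well
#' below the ~200 nm length scales probed by the K-function.
#'
#' @param n_clusters Number of parent centres (>= 0).
#' @param points_per_cluster Integer range `c(lower, upper)` for offspring
#'   counts, drawn uniformly; default `c(4, 6)`.
#' @param cluster_sd Isotropic Gaussian dispersion of offspring about the
#'   parent, in region units (> 0).
#' @param region A [region()].
#' @return Object of class `"cluster_model"`.
#' @export
cluster_model <- function(n_clusters, points_per_cluster = c(4, 6),
                          cluster_sd = 20, region = memnano::region(1000, 1000)) {
  stopifnot(inherits(region, "region"))
  if (n_clusters < 0 || n_clusters != round(n_clusters)) {
    stopf("`n_clusters` must be a non-negative integer")
  }
  ppc <- as.integer(points_per_cluster)
  if (length(ppc) != 2L || ppc[1] < 1L || ppc[1] > ppc[2]) {
    stopf("`points_per_cluster` must be c(lower, upper) with 1 <= lower <= upper")
  }
  if (!is.numeric(cluster_sd) || cluster_sd <= 0) stopf("`cluster_sd` must be > 0")
  structure(list(n_clusters = as.integer(n_clusters), points_per_cluster = ppc,
                 cluster_sd = as.numeric(cluster_sd), region = region),
            class = "cluster_model")
}

#' Simulate a clustered (Thomas-type) gold-particle pattern
#'
#' Parent centres are uniform on the region; each parent emits a
#' discrete-uniform count of offspring displaced by an isotropic Gaussian.
#' Offspring falling outside the region are re-drawn until inside, which
#' preserves the total point count and keeps the density edge-consistent
#' with how PM sheets are cropped. Ground-truth parent assignments are
#' returned alongside the observable pattern.
#'
#' @param model A [cluster_model()].
#' @param seed Integer seed.
#' @return A list of class `"cluster_sim"`: `pattern` (a [point_pattern()]),
#'   `parents` (data frame `parent_id`, `x`, `y`) and `assignment` (integer
#'   parent id per point).
#' @export
gen_cluster_pattern <- function(model, seed) {
  stopifnot(inherits(model, "cluster_model"))
  reg <- model$region
  with_seed(seed, {
    k <- model$n_clusters
    px <- stats::runif(k, 0, reg$width)
    py <- stats::runif(k, 0, reg$height)
    occupancy <- seq(model$points_per_cluster[1], model$points_per_cluster[2])
    counts <- if (k > 0) {
      occupancy[sample.int(length(occupancy), k, replace = TRUE)]
    } else integer(0)
    xs <- numeric(0); ys <- numeric(0); who <- integer(0)
    for (i in seq_len(k)) {
      m <- counts[i]
      ox <- oy <- numeric(m)
      todo <- seq_len(m)
      while (length(todo)) {
        cx <- stats::rnorm(length(todo), px[i], model$cluster_sd)
        cy <- stats::rnorm(length(todo), py[i], model$cluster_sd)
        ok <- cx >= 0 & cx <= reg$width & cy >= 0 & cy <= reg$height
        ox[todo[ok]] <- cx[ok]; oy[todo[ok]] <- cy[ok]
        todo <- todo[!ok]
      }
      xs <- c(xs, ox); ys <- c(ys, oy); who <- c(who, rep.int(i, m))
    }
    structure(list(
      pattern = point_pattern(xs, ys, reg,
                              sheet_id = sprintf("thomas_seed%d", as.integer(seed))),
      parents = data.frame(parent_id = seq_len(k), x = px, y = py),
      assignment = who
    ), class = "cluster_sim")
  })
}

#' @export
print.cluster_sim <- function(x, ...) {
  cat(sprintf("clustered pattern: %d points from %d parents\n",
              x$pattern$n, nrow(x$parents)))
  invisible(x)
}
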