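# Shared fixtures: everything is generated in code, nothing read from disk.

sheet_1um <- function() region(1000, 1000)

# Naive O(n^2 * |r|) double-loop K-function oracle, independent of the
# cumulative-sum implementation path in ripley_k().
oracle_ripley_k <- function(pattern, radii, correction = "isotropic") {
  n <- pattern$n
  A <- pattern$region$area
  K <- numeric(length(radii))
  for (ri in seq_along(radii)) {
    s <- 0
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (i == j) next
      d <- sqrt((pattern$x[i] - pattern$x[j])^2 + (pattern$y[i] - pattern$y[j])^2)
      if (d <= radii[ri]) {
        w <- if (correction == "isotropic" && d > 0) {
          edge_weight(c(pattern$x[i], pattern$y[i]), d, pattern$region)
        } else 1
        s <- s + w
      }
    }
    K[ri] <- A / (n * (n - 1)) * s
  }
  K
}

# Brute-force enumeration of admissible MSD observation pairs.
oracle_msd_pairs <- function(track_set, max_lag) {
  tb <- track_set$tracks
  total <- 0L
  for (tr in split(tb, tb$track_id)) {
    m <- nrow(tr)
    if (m < 2) next
    for (a in seq_len(m - 1)) for (b in (a + 1):m) {
      if (tr$frame[b] - tr$frame[a] <= max_lag) total <- total + 1L
    }
  }
  total
}

# Exhaustive two-segment breakpoint search, written independently of
# fit_cac(): fits each side separately under the continuity constraint via
# the hinge design matrix.
oracle_cac_breakpoint <- function(x, y) {
  n <- length(x)
  best_bp <- NA_real_; best_rss <- Inf
  for (bp in x[3:(n - 2)]) {
    X <- cbind(1, x, pmax(x - bp, 0))
    rss <- sum(lm.fit(X, y)$residuals^2)
    if (rss < best_rss) { best_rss <- rss; best_bp <- bp }
  }
  best_bp
}
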