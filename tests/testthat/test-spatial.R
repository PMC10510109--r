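test_that("edge weights follow the analytic arc geometry", {
  reg <- sheet_1um()
  expect_equal(edge_weight(c(500, 500), 100, reg), 1)
  expect_equal(edge_weight(c(0, 500), 123.4, reg), 2)   # half circumference inside
  expect_equal(edge_weight(c(0, 0), 50, reg), 4)        # quarter circumference
  expect_gte(edge_weight(c(10, 500), 100, reg), 1)
  expect_error(edge_weight(c(1, 1), 1e7, reg), "outside the region")
  expect_error(edge_weight(c(-5, 0), 10, reg), "inside the region")
})

test_that("ripley_k matches hand values and rejects degenerate input", {
  reg <- sheet_1um()
  p <- point_pattern(c(400, 600), c(500, 500), reg)
  k <- ripley_k(p, c(100, 199.9, 200, 250))
  expect_equal(k$k, c(0, 0, 1e6, 1e6))                  # A*2/(n(n-1)) once r >= d
  expect_error(ripley_k(point_pattern(500, 500, reg), c(10)), "at least 2")
  expect_error(ripley_k(p, numeric(0)), "empty")
  expect_error(ripley_k(p, c(10, 10)), "strictly increasing")

  # K is zero below the minimum pairwise distance
  pp <- gen_csr_pattern(40, reg, seed = 2)
  dmin <- min(dist(cbind(pp$x, pp$y)))
  expect_equal(ripley_k(pp, c(dmin * 0.99, 240))$k[1], 0)
})

test_that("ripley_k equals the brute-force double-loop oracle", {
  reg <- sheet_1um()
  for (s in 1:5) {
    pp <- gen_csr_pattern(sample(c(20, 60, 120), 1), reg, seed = 100 + s)
    radii <- sort(runif(6, 10, 400))
    expect_equal(ripley_k(pp, radii)$k, oracle_ripley_k(pp, radii),
                 tolerance = 1e-12)
  }
})

test_that("K estimate is permutation invariant and scales as s^2 under dilation", {
  reg <- sheet_1um()
  pp <- gen_csr_pattern(80, reg, seed = 31)
  radii <- c(40, 100, 200)
  k0 <- ripley_k(pp, radii)$k

  perm <- sample(pp$n)
  pp_perm <- point_pattern(pp$x[perm], pp$y[perm], reg)
  expect_equal(ripley_k(pp_perm, radii)$k, k0)

  s <- 3
  pp_scaled <- point_pattern(pp$x * s, pp$y * s, region(1000 * s, 1000 * s))
  expect_equal(ripley_k(pp_scaled, radii * s)$k, s^2 * k0, tolerance = 1e-10)
})

test_that("edge-corrected K is unbiased under CSR; the uncorrected one is not", {
  reg <- sheet_1um()
  radii <- c(60, 140, 240)
  km <- matrix(NA_real_, 150, length(radii))
  ku <- matrix(NA_real_, 150, length(radii))
  for (s in seq_len(150)) {
    p <- gen_csr_pattern(300, reg, seed = 4000 + s)
    km[s, ] <- ripley_k(p, radii)$k
    ku[s, ] <- ripley_k(p, radii, correction = "none")$k
  }
  se <- apply(km, 2, sd) / sqrt(nrow(km))
  expect_true(all(abs(colMeans(km) - pi * radii^2) < 3 * se))
  # without correction, boundary losses bias K down at large r
  expect_lt(mean(ku[, 3]), pi * 240^2 - 3 * se[3])
})

test_that("l_curve is the algebraic transform of K", {
  reg <- sheet_1um()
  radii <- c(10, 50, 100)
  mk <- function(kv) structure(list(radii = radii, k = kv, n = 100,
                                    area = reg$area, correction = "isotropic"),
                               class = "k_estimate")
  expect_equal(l_curve(mk(pi * radii^2))$l_minus_r, rep(0, 3))      # CSR
  expect_equal(l_curve(mk(4 * pi * radii^2))$l_minus_r, radii)      # sqrt(4 r^2) - r
  expect_equal(l_curve(mk(rep(0, 3)))$l_minus_r, -radii)
})

test_that("CSR envelopes are deterministic and tighten with n", {
  reg <- sheet_1um()
  radii <- c(50, 100, 150)
  e1 <- csr_envelope(100, reg, radii, n_sims = 120, seed = 5)
  e2 <- csr_envelope(100, reg, radii, n_sims = 120, seed = 5)
  expect_identical(e1$values, e2$values)
  e_small <- csr_envelope(50, reg, radii, n_sims = 200, seed = 6)
  e_big <- csr_envelope(1000, reg, radii, n_sims = 200, seed = 6)
  expect_true(all(e_big$values < e_small$values))
})

test_that("normalisation puts the envelope at 1 and handles degenerate radii", {
  radii <- c(50, 100, 150)
  env <- structure(list(radii = radii, values = c(2, 4, 8), percentile = 99,
                        n_sims = 1000, n = 100, region = sheet_1um()),
                   class = "csr_envelope")
  lc <- structure(list(radii = radii, l_minus_r = c(2, 4, 8), n = 100), class = "l_curve")
  nl <- normalize_and_lmax(lc, env)
  expect_equal(nl$values, rep(1, 3))
  expect_equal(nl$l_max, 1)
  expect_equal(nl$r_at_max, 50)                          # first radius on ties

  zero <- structure(list(radii = radii, l_minus_r = rep(0, 3), n = 100), class = "l_curve")
  expect_equal(normalize_and_lmax(zero, env)$l_max, 0)

  env_neg <- env; env_neg$values <- c(-1, 4, 8)
  nl2 <- normalize_and_lmax(lc, env_neg)
  expect_equal(nl2$n_excluded, 1)
  expect_equal(nl2$radii, c(100, 150))

  env_bad <- env; env_bad$values <- c(-1, -2, 0)
  expect_error(normalize_and_lmax(lc, env_bad), "non-positive")
  env_grid <- env; env_grid$radii <- radii + 1
  expect_error(normalize_and_lmax(lc, env_grid), "different radius grids")
})

test_that("clustered patterns exceed the CSR envelope and L_max grows as clusters tighten", {
  reg <- sheet_1um()
  radii <- seq(10, 240, by = 10)
  # fixed occupancy 5 so one envelope (n = 250) serves every replicate
  env <- csr_envelope(250, reg, radii, n_sims = 199, seed = 77)
  lmax_at <- function(sd_nm, s) {
    sim <- gen_cluster_pattern(cluster_model(50, c(5, 5), sd_nm, reg), seed = s)
    normalize_and_lmax(l_curve(ripley_k(sim$pattern, radii)), env)$l_max
  }
  lm20 <- vapply(1:25, function(s) lmax_at(20, 500 + s), numeric(1))
  lm40 <- vapply(1:25, function(s) lmax_at(40, 600 + s), numeric(1))
  lm80 <- vapply(1:25, function(s) lmax_at(80, 700 + s), numeric(1))
  expect_true(all(lm20 > 1))
  expect_gt(median(lm40), median(lm80))
  expect_gt(median(lm20), median(lm40))
})

test_that("bootstrap on L_max: null, determinism and power behave as designed", {
  a <- c(1.2, 1.4, 1.3, 1.5)
  b1 <- bootstrap_lmax(a, a, n_boot = 1000, seed = 1)
  expect_equal(b1$observed_difference, 0)
  expect_equal(b1$p_value, 1)
  expect_gte(b1$p_value, 1 / 1001)
  expect_identical(bootstrap_lmax(a, rev(a) + 0.1, 1000, seed = 2)$p_value,
                   bootstrap_lmax(a, rev(a) + 0.1, 1000, seed = 2)$p_value)
  expect_error(bootstrap_lmax(numeric(0), a), "non-empty")

  # clear separation on 15-vs-15 sheets rejects at alpha = 0.05
  set.seed(42)
  ga <- rnorm(15, 2.0, 0.2); gb <- rnorm(15, 3.0, 0.2)
  expect_lt(bootstrap_lmax(ga, gb, n_boot = 2000, seed = 3)$p_value, 0.05)
})

test_that("labelling density ANOVA matches hand computation and edge cases", {
  reg <- sheet_1um()
  mk <- function(n, id) gen_csr_pattern(n, reg, seed = id)
  same <- lapply(c(100, 100, 100, 100), mk, id = 1)
  res0 <- labeling_density(same, c("a", "a", "b", "b"))
  expect_equal(res0$F, 0)
  expect_equal(res0$p, 1)

  # densities exactly {1,1,1} vs {2,2,2} per um^2: zero within-group variance
  g1 <- lapply(1:3, function(i) mk(1, i))
  g2 <- lapply(4:6, function(i) mk(2, i))
  res <- labeling_density(c(g1, g2), rep(c("ctrl", "drug"), each = 3))
  expect_equal(res$densities$density_um2, rep(c(1, 2), each = 3))
  expect_lt(res$p, 0.01)

  # general case agrees with stats::oneway.test (equal variances)
  pats <- Map(mk, c(80, 95, 110, 60, 70, 85), 1:6)
  grp <- rep(c("a", "b"), each = 3)
  res2 <- labeling_density(pats, grp)
  ref <- stats::oneway.test(res2$densities$density_um2 ~ grp, var.equal = TRUE)
  expect_equal(res2$F, unname(ref$statistic))
  expect_equal(res2$p, unname(ref$p.value))

  expect_error(labeling_density(pats, rep("a", 6)), "2 groups")
  expect_error(labeling_density(pats[1:3], c("a", "a", "b")), "at least 2 sheets")
})
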