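test_that("CSR generator is deterministic, contained and uniform in its moments", {
  reg <- sheet_1um()
  expect_equal(gen_csr_pattern(0, reg, seed = 1)$n, 0)
  expect_error(gen_csr_pattern(-1, reg, seed = 1), "non-negative")

  p1 <- gen_csr_pattern(300, reg, seed = 7)
  p2 <- gen_csr_pattern(300, reg, seed = 7)
  expect_identical(p1$x, p2$x)
  expect_identical(p1$y, p2$y)
  expect_true(all(p1$x >= 0 & p1$x <= 1000 & p1$y >= 0 & p1$y <= 1000))

  big <- gen_csr_pattern(1e4, reg, seed = 11)
  se <- 1000 / sqrt(12) / sqrt(1e4)            # SE of the mean of U(0, 1000)
  expect_lt(abs(mean(big$x) - 500), 3 * se)
  expect_lt(abs(mean(big$y) - 500), 3 * se)
})

test_that("clustered patterns respect occupancy, region and ground truth", {
  reg <- sheet_1um()
  expect_equal(gen_cluster_pattern(cluster_model(0, region = reg), seed = 1)$pattern$n, 0)

  sim <- gen_cluster_pattern(cluster_model(50, c(4, 6), 20, reg), seed = 3)
  expect_gte(sim$pattern$n, 200)
  expect_lte(sim$pattern$n, 300)
  expect_length(sim$assignment, sim$pattern$n)
  expect_true(all(sim$assignment %in% sim$parents$parent_id))

  # mean occupancy over 1000 clusters: discrete uniform on {4,5,6},
  # mean 5, sd sqrt(2/3)
  big <- gen_cluster_pattern(cluster_model(1000, c(4, 6), 20, reg), seed = 5)
  occ <- tabulate(big$assignment, nbins = 1000)
  expect_lt(abs(mean(occ) - 5), 3 * sqrt(2 / 3) / sqrt(1000))

  # degenerate dispersion: offspring collapse onto their parents
  tight <- gen_cluster_pattern(cluster_model(20, c(4, 6), 1e-9, reg), seed = 4)
  px <- tight$parents$x[tight$assignment]
  py <- tight$parents$y[tight$assignment]
  expect_lt(max(abs(tight$pattern$x - px)), 1e-6)
  expect_lt(max(abs(tight$pattern$y - py)), 1e-6)
})

test_that("Brownian increments have variance 2 D dt and blinking is single-frame", {
  frozen <- gen_brownian_tracks(diffusion_model(0, n_frames = 50), 5, seed = 2)
  for (tr in split(frozen$observed$tracks, frozen$observed$tracks$track_id)) {
    expect_equal(diff(range(tr$x)), 0)
    expect_equal(diff(range(tr$y)), 0)
  }

  m <- diffusion_model(0.5, frame_interval = 0.010, n_frames = 1001)
  sim <- gen_brownian_tracks(m, 100, seed = 8)          # 1e5 steps
  steps <- do.call(c, lapply(split(sim$truth$tracks, sim$truth$tracks$track_id),
                             function(tr) diff(tr$x)))
  v <- stats::var(steps)
  se_var <- v * sqrt(2 / (length(steps) - 1))
  expect_lt(abs(v - 2 * 0.5 * 0.010), 3 * se_var)

  full <- gen_brownian_tracks(diffusion_model(0.1, n_frames = 40), 10, seed = 6)
  expect_equal(nrow(full$observed$tracks), 10 * 40)     # blink_probability = 0

  blink <- gen_brownian_tracks(
    diffusion_model(0.1, n_frames = 200, blink_probability = 0.3), 20, seed = 9)
  for (tr in split(blink$observed$tracks, blink$observed$tracks$track_id)) {
    expect_true(all(diff(tr$frame) <= 2))               # at most one missing frame
  }
  expect_lt(nrow(blink$observed$tracks), 20 * 200)      # some frames dropped
})

test_that("frame rendering: background level, centroid accuracy, photon linearity", {
  empty <- track_set(data.frame(track_id = integer(0), frame = integer(0),
                                x = numeric(0), y = numeric(0)))
  st <- render_frames(empty, background = 10, n_frames = 3, seed = 1)
  expect_equal(dim(st$frames), c(100, 100, 3))
  expect_lt(abs(mean(st$frames) - 10), 4 * sqrt(10 / length(st$frames)))

  # noiseless emitter: intensity-weighted centroid hits the true position
  one <- track_set(data.frame(track_id = 1, frame = 0, x = 30.3 * 0.16, y = 40.7 * 0.16))
  img <- render_frames(one, photons = 5000, background = 0, poisson_noise = FALSE)$frames[, , 1]
  xs <- col(img) - 1; ys <- row(img) - 1
  expect_lt(abs(sum(img * xs) / sum(img) - 30.3), 0.01)
  expect_lt(abs(sum(img * ys) / sum(img) - 40.7), 0.01)

  s1 <- sum(render_frames(one, photons = 2000, background = 5, seed = 3)$frames[, , 1]) - 5 * 1e4
  s2 <- sum(render_frames(one, photons = 4000, background = 5, seed = 4)$frames[, , 1]) - 5 * 1e4
  # Var(s2 - 2 s1) = (4000 + bg) + 4 (2000 + bg) with bg = 5e4 background counts
  expect_lt(abs(s2 - 2 * s1), 4 * sqrt((4000 + 5e4) + 4 * (2000 + 5e4)))
})

test_that("NMR table generator: null case, ordering by construction, validation", {
  quiet <- gen_nmr_tables(30, perturbed = integer(0), noise_sd = 0, seed = 1)
  expect_equal(compute_csp(quiet$peaks)$csp_ppm, rep(0, 30))
  expect_equal(compute_pre_ratios(quiet$intensities)$pre_ratio, rep(1, 30))

  hit <- gen_nmr_tables(80, perturbed = 62:66, pre_effect = 0.5, noise_sd = 0, seed = 2)
  pr <- compute_pre_ratios(hit$intensities)
  expect_setequal(pr$residue[order(pr$pre_ratio)][1:5], 62:66)

  expect_error(gen_nmr_tables(10, perturbed = 1, pre_effect = 1.2), "\\[0, 1\\)")
  expect_error(gen_nmr_tables(10, perturbed = 11), "subset")
})

test_that("gen_curve produces the documented functional forms", {
  tr <- gen_curve("tract", list(I0 = 3, R = 20))
  expect_equal(tr$y[tr$x == 0], 3)                       # exp(-R*0) = 1
  expect_equal(tr$y, 3 * exp(-20 * tr$x))

  melt <- gen_curve("melt", list(Tm = 55, width = 2))
  dy <- diff(melt$y) / diff(melt$x)
  xm <- (melt$x[-1] + melt$x[-length(melt$x)]) / 2
  expect_lt(abs(xm[which.max(dy)] - 55), 0.5)            # derivative peaks at Tm

  dls <- gen_curve("dls", list(cac = 80, slope_below = 0.2, slope_above = 5))
  bp <- log10(80)
  slopes <- diff(dls$y) / diff(dls$x)
  expect_true(all(abs(slopes[xm_below <- dls$x[-1] <= bp] - 0.2) < 1e-9))
  expect_true(all(abs(slopes[dls$x[-length(dls$x)] >= bp] - 5) < 1e-9))

  expect_error(gen_curve("unknown-kind"), "arg")
})
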