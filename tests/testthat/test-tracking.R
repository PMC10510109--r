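static_track <- function(x_px, y_px, frames, id = 1, pixel_size = 0.16) {
  data.frame(track_id = id, frame = frames, x = x_px * pixel_size, y = y_px * pixel_size)
}

test_that("spot detection finds emitters accurately and rejects bad frames", {
  one <- track_set(static_track(30.3, 40.7, 0))
  noisy <- render_frames(one, photons = 5000, background = 20, seed = 3)$frames[, , 1]
  d <- detect_spots(noisy)
  expect_equal(nrow(d), 1)
  expect_lt(abs(d$x - 30.3), 0.15)
  expect_lt(abs(d$y - 40.7), 0.15)

  two <- track_set(rbind(static_track(40, 50, 0, id = 1),
                         static_track(50, 50, 0, id = 2)))   # 10 px apart
  d2 <- detect_spots(render_frames(two, photons = 5000, background = 20, seed = 4)$frames[, , 1])
  expect_equal(nrow(d2), 2)

  bad <- noisy; bad[3, 7] <- NaN
  expect_error(detect_spots(bad), "row 3, column 7")
  sat <- noisy; sat[10, 10] <- 70000
  expect_error(detect_spots(sat), "saturated")
})

test_that("pure-background frames yield no detections", {
  set.seed(99)
  fp <- vapply(1:20, function(i) {
    nrow(detect_spots(matrix(rpois(1e4, 20), 100, 100)))
  }, numeric(1))
  expect_lte(sum(fp > 0), 1)   # >= 99% of frames empty under the null
})

test_that("sub-pixel position bias stays below 0.05 px at high SNR", {
  set.seed(7)
  errs <- t(vapply(1:20, function(i) {
    x0 <- 45 + runif(1); y0 <- 55 + runif(1)
    st <- render_frames(track_set(static_track(x0, y0, 0)),
                        photons = 8000, background = 10, seed = 1000 + i)
    d <- detect_spots(st$frames[, , 1])
    c(d$x - x0, d$y - y0)
  }, numeric(2)))
  expect_lt(abs(mean(errs[, 1])), 0.05)
  expect_lt(abs(mean(errs[, 2])), 0.05)
})

test_that("linking follows the jump/gap/length rules and ground-truth identity", {
  # one static particle over 20 frames -> one track of length 20
  locs <- data.frame(frame = 0:19, x = 10, y = 10)
  lt <- link_tracks(locs)
  expect_equal(length(unique(lt$tracks$track_id)), 1)
  expect_equal(nrow(lt$tracks), 20)

  # observed for 5 frames only: below the >= 6 frame persistence rule
  expect_equal(nrow(link_tracks(data.frame(frame = 0:4, x = 1, y = 1))$tracks), 0)

  # two particles always farther apart than max_jump keep their identities
  sim <- gen_brownian_tracks(diffusion_model(0.01, n_frames = 30), 2, seed = 12)
  tb <- sim$truth$tracks
  tb$x <- tb$x - ave(tb$x, tb$track_id, FUN = function(v) v[1]) + ifelse(tb$track_id == 1, 2, 14)
  tb$y <- tb$y - ave(tb$y, tb$track_id, FUN = function(v) v[1]) + 8
  lt2 <- link_tracks(tb[, c("frame", "x", "y")], max_jump = 5 * 0.16, unit = "um")
  expect_equal(length(unique(lt2$tracks$track_id)), 2)
  got <- split(lt2$tracks, lt2$tracks$track_id)
  for (g in got) {
    expect_equal(nrow(g), 30)
    expect_lt(diff(range(g$x)), 2)   # each track stays near one start: no identity swaps
  }

  # blinking: a single missing frame is bridged, two are not
  gap1 <- data.frame(frame = c(0, 1, 3, 4, 5, 6), x = 1, y = 1)
  expect_equal(length(unique(link_tracks(gap1)$tracks$track_id)), 1)
  gap2 <- data.frame(frame = c(0, 1, 4, 5, 6, 7, 8, 9, 10, 11, 12), x = 1, y = 1)
  lt3 <- link_tracks(gap2, min_length = 6)
  expect_equal(length(unique(lt3$tracks$track_id)), 1)   # only the post-gap run survives
  expect_equal(min(lt3$tracks$frame), 4)
})

test_that("linking is invariant to the input row order", {
  sim <- gen_brownian_tracks(diffusion_model(0.05, n_frames = 25), 6, seed = 3)
  locs <- sim$observed$tracks[, c("frame", "x", "y")]
  lt_a <- link_tracks(locs, max_jump = 0.8, unit = "um")
  set.seed(5)
  lt_b <- link_tracks(locs[sample(nrow(locs)), ], max_jump = 0.8, unit = "um")
  key <- function(ts) {
    sp <- split(ts$tracks[, c("frame", "x", "y")], ts$tracks$track_id)
    sort(vapply(sp, function(d) paste(round(d$frame), round(d$x, 9), round(d$y, 9), collapse = ";"),
                character(1)))
  }
  expect_identical(unname(key(lt_a)), unname(key(lt_b)))
})

test_that("MSD: static, deterministic drift, and pair bookkeeping", {
  still <- track_set(data.frame(track_id = 1, frame = 0:19, x = 2, y = 3))
  expect_equal(compute_msd(still, max_lag = 5)$table$msd, rep(0, 5))

  v <- 1.5; dt <- 0.010
  drift <- track_set(data.frame(track_id = 1, frame = 0:49, x = v * (0:49) * dt, y = 0),
                     frame_interval = dt)
  msd <- compute_msd(drift, max_lag = 6)
  expect_equal(msd$table$msd, (v * msd$table$lag_s)^2)

  blink <- gen_brownian_tracks(
    diffusion_model(0.3, n_frames = 40, blink_probability = 0.2), 8, seed = 21)
  m <- compute_msd(blink$observed, max_lag = 5)
  expect_equal(sum(m$table$n_obs), oracle_msd_pairs(blink$observed, 5))
})

test_that("diffusion fit recovers slope, intercept and flags negative D", {
  line <- structure(list(table = data.frame(lag_frames = 1:6, lag_s = (1:6) * 0.01,
                                            msd = 4 * 0.2 * (1:6) * 0.01, n_obs = 100),
                         frame_interval = 0.01, unit = "um"), class = "msd_curve")
  fit <- fit_diffusion(line, n_lags = 4)
  expect_equal(fit$D, 0.2)
  expect_equal(fit$intercept, 0)

  sim <- gen_brownian_tracks(diffusion_model(0.5, n_frames = 100), 200, seed = 14)
  f2 <- fit_diffusion(compute_msd(sim$observed, max_lag = 6), n_lags = 4)
  expect_lt(abs(f2$D - 0.5) / 0.5, 0.05)

  down <- line; down$table$msd <- rev(line$table$msd)
  expect_warning(f3 <- fit_diffusion(down), "negative")
  expect_true(f3$negative_D)
})

test_that("render -> detect -> link -> MSD -> fit recovers D end to end", {
  # moderate D keeps displacements within the 5 px jump bound at 10 ms frames
  sim <- gen_brownian_tracks(
    diffusion_model(0.3, n_frames = 60,
                    region = region(10, 10, unit = "um")), 12, seed = 31)
  shifted <- sim$truth$tracks
  shifted$x <- shifted$x + 3; shifted$y <- shifted$y + 3  # keep inside the frame
  st <- render_frames(track_set(shifted), photons = 8000, background = 10,
                      dims = c(100, 100), seed = 8)
  locs <- detect_movie(st)
  lt <- link_tracks(locs[, c("frame", "x", "y")], max_jump = 5, min_length = 6)
  px <- lt$tracks; px$x <- px$x * st$pixel_size; px$y <- px$y * st$pixel_size
  msd <- compute_msd(track_set(px, frame_interval = 0.010), max_lag = 4)
  fit <- fit_diffusion(msd, n_lags = 4)
  expect_lt(abs(fit$D - 0.3) / 0.3, 0.10)
})
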