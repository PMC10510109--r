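#' Brownian-diffusion simulation model
#'
#' Parameters for simulating membrane-anchored single-particle trajectories
#' as 2D Brownian motion observed through a localisation microscope:
#' per-frame displacement components are Gaussian with variance 2*D*dt per
#' axis, reported positions carry independent Gaussian localisation noise,
#' and observations can blink off for single frames. Defaults mirror the
#' TIRF acquisition the pipeline targets: 10 ms frames in a 16 x 16 um
#' field of view.
#'
#' @param diffusion_coefficient D in um^2/s (>= 0).
#' @param frame_interval Frame time in seconds (default 0.010).
#' @param n_frames Number of frames in the movie.
#' @param localization_sd Localisation noise SD in um (default 0).
#' @param blink_probability Probability that a frame's observation is
#'   dropped; consecutive drops are forbidden so single-frame gap closing
#'   can in principle recover every track. Must be in [0, 1).
#' @param region A [region()] in um (default 16 x 16 um).
#' @return Object of class `"diffusion_model"`.
#' @export
diffusion_model <- function(diffusion_coefficient, frame_interval = 0.010,
                            n_frames = 100, localization_sd = 0,
                            blink_probability = 0,
                            region = memnano::region(16, 16, unit = "um")) {
  stopifnot(inherits(region, "region"))
  if (diffusion_coefficient < 0) stopf("`diffusion_coefficient` must be >= 0")
  if (frame_interval <= 0) stopf("`frame_interval` must be > 0")
  if (n_frames < 1) stopf("`n_frames` must be >= 1")
  if (localization_sd < 0) stopf("`localization_sd` must be >= 0")
  if (blink_probability < 0 || blink_probability >= 1) {
    stopf("`blink_probability` must be in [0, 1)")
  }
  structure(list(diffusion_coefficient = diffusion_coefficient,
                 frame_interval = frame_interval, n_frames = as.integer(n_frames),
                 localization_sd = localization_sd,
                 blink_probability = blink_probability, region = region),
            class = "diffusion_model")
}

#' Simulate Brownian single-particle tracks
#'
#' Each track starts uniform in the region and performs a 2D random walk
#' with per-axis step variance 2*D*dt. True positions are unconstrained by
#' the region boundary after the start (free diffusion); observed positions
#' add Gaussian localisation noise and may blink off for at most one
#' consecutive frame. Both the true and the observed trajectories are
#' returned so recovery can be tested without re-simulation.
#'
#' @param model A [diffusion_model()].
#' @param n_tracks Number of tracks (>= 0).
#' @param seed Integer seed.
#' @return List of class `"track_sim"`: `observed` and `truth`, both
#'   [track_set()] objects sharing track ids; blinked frames are absent
#'   from `observed` but present in `truth`.
#' @export
gen_brownian_tracks <- function(model, n_tracks, seed) {
  stopifnot(inherits(model, "diffusion_model"))
  if (n_tracks < 0 || n_tracks != round(n_tracks)) stopf("`n_tracks` must be >= 0")
  n_tracks <- as.integer(n_tracks)
  reg <- model$region
  step_sd <- sqrt(2 * model$diffusion_coefficient * model$frame_interval)
  nf <- model$n_frames
  with_seed(seed, {
    true_list <- vector("list", n_tracks)
    obs_list <- vector("list", n_tracks)
    for (i in seq_len(n_tracks)) {
      x <- cumsum(c(stats::runif(1, 0, reg$width),  stats::rnorm(nf - 1, 0, step_sd)))
      y <- cumsum(c(stats::runif(1, 0, reg$height), stats::rnorm(nf - 1, 0, step_sd)))
      frames <- seq_len(nf) - 1L
      true_list[[i]] <- data.frame(track_id = i, frame = frames, x = x, y = y)
      ox <- x + stats::rnorm(nf, 0, model$localization_sd)
      oy <- y + stats::rnorm(nf, 0, model$localization_sd)
      keep <- rep(TRUE, nf)
      if (model$blink_probability > 0) {
        u <- stats::runif(nf)
        for (f in seq_len(nf)) {
          # a frame can only blink off if the previous one was observed
          if (u[f] < model$blink_probability && (f == 1L || keep[f - 1L])) {
            keep[f] <- FALSE
          }
        }
      }
      obs_list[[i]] <- data.frame(track_id = i, frame = frames[keep],
                                  x = ox[keep], y = oy[keep])
    }
    empty <- data.frame(track_id = integer(0), frame = integer(0),
                        x = numeric(0), y = numeric(0))
    truth <- if (n_tracks) do.call(rbind, true_list) else empty
    obs <- if (n_tracks) do.call(rbind, obs_list) else empty
    structure(list(
      observed = track_set(obs, model$frame_interval, unit = reg$unit),
      truth = track_set(truth, model$frame_interval, unit = reg$unit)
    ), class = "track_sim")
  })
}

#' @export
print.track_sim <- function(x, ...) {
  cat("Brownian track simulation\n")
  cat("  observed: "); print(x$observed)
  cat("  truth:    "); print(x$truth)
  invisible(x)
}
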