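#' Pipeline run configuration
#'
#' Collects every tunable parameter of the spatial pipeline with its
#' documented default; unknown keys are rejected so typos cannot silently
#' fall back to defaults.
#'
#' @param ... Overrides for the defaults listed below.
#' @return Object of class `"run_config"` (a named list). Defaults:
#'   `seed = 1`, `out_dir = tempdir()`, `region_width = 1000` and
#'   `region_height = 1000` nm (`region_unit = "nm"`), `rmax = 240`,
#'   `r_by = 1` nm, `n_sims = 1000`, `percentile = 99`, `n_sheets = 1`,
#'   `n_clusters = 50`, `points_per_cluster = c(4, 6)`, `cluster_sd = 20`
#'   nm, `max_jump = 5` px, `max_gap = 1`, `min_length = 6`,
#'   `pixel_size = 0.16` um/px, `dt = 0.01` s, `n_lags = 4`,
#'   `field_MHz = 900`.
#' @export
run_config <- function(...) {
  defaults <- list(
    seed = 1L, out_dir = tempdir(),
    region_width = 1000, region_height = 1000, region_unit = "nm",
    rmax = 240, r_by = 1, n_sims = 1000, percentile = 99,
    n_sheets = 1L, n_clusters = 50L, points_per_cluster = c(4L, 6L),
    cluster_sd = 20,
    max_jump = 5, max_gap = 1L, min_length = 6L,
    pixel_size = 0.16, dt = 0.01, n_lags = 4L, field_MHz = 900
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(defaults))
  if (length(unknown)) {
    stopf("unknown config key(s): %s (valid: %s)",
          paste(unknown, collapse = ", "), paste(names(defaults), collapse = ", "))
  }
  defaults[names(over)] <- over
  structure(defaults, class = "run_config")
}

#' @export
print.run_config <- function(x, ...) {
  cat("memnano run configuration\n")
  for (k in names(x)) cat(sprintf("  %-18s %s\n", k, paste(format(x[[k]]), collapse = " ")))
  invisible(x)
}

#' Run the spatial analysis pipeline
#'
#' Executes the named stages in order, persisting every intermediate as
#' CSV in `config$out_dir` and recording a reproducibility manifest
#' (config, seed, package version, md5 checksums of all outputs) as
#' `manifest.json`. Available stages:
#'
#' * `simulate` — clustered gold patterns (`points.csv`, `truth.csv`);
#' * `kfunction` — per-sheet K and L(r) - r curves (`curves.csv`);
#' * `envelope` — CSR envelopes per distinct sheet n (`envelope.csv`);
#' * `lmax` — normalised curves and the per-sheet summary
#'   (`summary.csv`: `sheet_id,n,density_um2,l_max,r_at_max_nm`).
#'
#' A failing stage halts the run with the stage name; outputs of earlier
#' stages remain on disk.
#'
#' @param config A [run_config()].
#' @param stages Character vector of stage names, executed in the given
#'   order (default: all four in order).
#' @return Invisibly, a list with the manifest and the per-sheet summary
#'   (when the `lmax` stage ran).
#' @export
run_pipeline <- function(config = run_config(),
                         stages = c("simulate", "kfunction", "envelope", "lmax")) {
  stopifnot(inherits(config, "run_config"))
  valid <- c("simulate", "kfunction", "envelope", "lmax")
  bad <- setdiff(stages, valid)
  if (length(bad)) {
    stopf("invalid stage name(s): %s (valid stages: %s)",
          paste(bad, collapse = ", "), paste(valid, collapse = ", "))
  }
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  reg <- region(config$region_width, config$region_height, config$region_unit)
  radii <- radius_grid(config$rmax, config$r_by)
  paths <- list(points = file.path(config$out_dir, "points.csv"),
                truth = file.path(config$out_dir, "truth.csv"),
                curves = file.path(config$out_dir, "curves.csv"),
                envelope = file.path(config$out_dir, "envelope.csv"),
                summary = file.path(config$out_dir, "summary.csv"),
                manifest = file.path(config$out_dir, "manifest.json"))
  summary_df <- NULL
  for (stage in stages) {
    res <- tryCatch(switch(stage,
      simulate = {
        pats <- vector("list", config$n_sheets)
        truth <- vector("list", config$n_sheets)
        for (s in seq_len(config$n_sheets)) {
          sim <- gen_cluster_pattern(
            cluster_model(config$n_clusters, config$points_per_cluster,
                          config$cluster_sd, reg),
            seed = derive_seed(config$seed, s))
          sim$pattern$sheet_id <- sprintf("sheet%02d", s)
          pats[[s]] <- sim$pattern
          truth[[s]] <- data.frame(sheet_id = sim$pattern$sheet_id,
                                   parent_id = sim$assignment)
        }
        write_points_csv(pats, paths$points)
        utils::write.csv(do.call(rbind, truth), paths$truth, row.names = FALSE)
      },
      kfunction = {
        pats <- read_points_csv(paths$points, reg)
        rows <- lapply(pats, function(p) {
          l <- l_curve(ripley_k(p, radii))
          data.frame(sheet_id = p$sheet_id, r_nm = l$radii, l_minus_r_nm = l$l_minus_r)
        })
        utils::write.csv(do.call(rbind, rows), paths$curves, row.names = FALSE)
      },
      envelope = {
        pats <- read_points_csv(paths$points, reg)
        ns <- sort(unique(vapply(pats, function(p) p$n, numeric(1))))
        rows <- lapply(ns, function(n) {
          env <- csr_envelope(n, reg, radii, n_sims = config$n_sims,
                              percentile = config$percentile,
                              seed = derive_seed(config$seed, 10000 + n))
          data.frame(n = n, r_nm = env$radii, value_nm = env$values)
        })
        utils::write.csv(do.call(rbind, rows), paths$envelope, row.names = FALSE)
      },
      lmax = {
        pats <- read_points_csv(paths$points, reg)
        envs <- utils::read.csv(paths$envelope)
        summary_df <- do.call(rbind, lapply(pats, function(p) {
          ev <- envs[envs$n == p$n, ]
          env <- structure(list(radii = ev$r_nm, values = ev$value_nm,
                                percentile = config$percentile,
                                n_sims = config$n_sims, n = p$n, region = reg),
                           class = "csr_envelope")
          nl <- normalize_and_lmax(l_curve(ripley_k(p, radii)), env)
          area_um2 <- if (reg$unit == "nm") reg$area / 1e6 else reg$area
          data.frame(sheet_id = p$sheet_id, n = p$n,
                     density_um2 = p$n / area_um2,
                     l_max = nl$l_max, r_at_max_nm = nl$r_at_max)
        }))
        utils::write.csv(summary_df, paths$summary, row.names = FALSE)
      }
    ), error = function(e) {
      stopf("pipeline stage '%s' failed: %s", stage, conditionMessage(e))
    })
  }
  produced <- Filter(file.exists, unlist(paths[names(paths) != "manifest"]))
  manifest <- list(
    config = unclass(config),
    stages = stages,
    package_version = as.character(utils::packageVersion("memnano")),
    outputs = as.list(tools::md5sum(produced))
  )
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE, pretty = TRUE)
  invisible(list(manifest = manifest, summary = summary_df))
}
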