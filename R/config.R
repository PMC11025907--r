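# Run configuration and workflow commands. Every run is driven by a
# YAML-style config validated against a per-command schema; the resolved
# configuration (with defaults filled in) is written as a JSON sidecar next
# to the outputs so each artifact is traceable to its parameters and seed.

command_schemas <- function() {
  proj <- c("d_proj")
  list(
    "generate-geometry" = list(
      required = proj,
      defaults = list(throw_ratio = 1.4, aspect_ratio = 16 / 9,
                      alpha_min_deg = 15, alpha_max_deg = 140,
                      beta_span_deg = 180, n_alpha = 200, n_beta = 90,
                      scale = 1)),
    "build-maps" = list(
      required = proj,
      defaults = list(throw_ratio = 1.4, aspect_ratio = 16 / 9,
                      image_width_px = 1280, image_height_px = 720,
                      texture_rows = 125, texture_cols = 180,
                      az_min_deg = -90, az_max_deg = 90,
                      el_min_deg = -75, el_max_deg = 50,
                      alpha_min_deg = 15, alpha_max_deg = 140,
                      beta_span_deg = 180)),
    "render-stimulus" = list(
      required = c("stimulus"),
      defaults = list(res_deg = 1, frames = 1, rate = 60, yaw = 0,
                      velocity = 0)),
    "estimate-rf" = list(
      required = c("sensor"),
      defaults = list(cell_deg = 5, az_extent_deg = 180,
                      el_extent_deg = 140, rate = 60, duration_s = 60,
                      max_lag = 20, seed = 1)),
    "evaluate-distortion" = list(
      required = c("screen"),
      defaults = list(d_proj = 100, throw_ratio = 1.4,
                      aspect_ratio = 16 / 9, fov_deg = 105,
                      goldberg_m = 3, goldberg_n = 3, shrink = 1)),
    "simulate-closed-loop" = list(
      required = c("texture"),
      defaults = list(duration_s = 60, rate = 60, gain = 100,
                      max_rate = 140, policy_gain = 0.05,
                      policy_noise_sd = 0.5, trials = 1, seed = 1))
  )
}

#' Read and validate a run configuration
#'
#' Reads a YAML configuration, checks it against the schema of the given
#' command (missing required fields are reported by name) and fills in
#' documented defaults.
#'
#' @param path YAML file path, or a named list already in memory.
#' @param command One of the workflow command names (see [run_command()]).
#' @return The resolved configuration as a named list, with attribute
#'   `"command"`.
#' @export
read_run_config <- function(path, command) {
  schemas <- command_schemas()
  if (!command %in% names(schemas)) {
    stop_domain("unknown command `", command, "`; available: ",
                paste(names(schemas), collapse = ", "))
  }
  cfg <- if (is.character(path)) yaml::read_yaml(path) else path
  if (is.null(cfg)) cfg <- list()
  sch <- schemas[[command]]
  missing <- setdiff(sch$required, names(cfg))
  if (length(missing) > 0) {
    stop_domain("config for `", command, "` is missing required field",
                if (length(missing) > 1) "s" else "", ": ",
                paste(missing, collapse = ", "))
  }
  for (nm in names(sch$defaults)) {
    if (is.null(cfg[[nm]])) cfg[[nm]] <- sch$defaults[[nm]]
  }
  attr(cfg, "command") <- command
  cfg
}

write_resolved_config <- function(cfg, out_dir, command, seed) {
  path <- file.path(out_dir, "resolved-config.json")
  jsonlite::write_json(c(list(command = command, seed = seed), cfg), path,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  path
}

#' Run a workflow command
#'
#' Dispatches one of the package workflows from a validated configuration:
#' `generate-geometry` (SVG profile + STL surface), `build-maps` (pixel
#' maps + sidecar), `render-stimulus` (PNG frames), `estimate-rf`
#' (synthetic-rig reverse correlation; kernel + summary CSV),
#' `evaluate-distortion` (per-face CSV report) and `simulate-closed-loop`
#' (trajectory + fixation density CSVs). Every run writes its resolved
#' configuration as `resolved-config.json` next to the outputs.
#'
#' @param command Command name.
#' @param config Path to a YAML config, or a named list.
#' @param out_dir Output directory (created if needed).
#' @param seed Integer master seed for stochastic commands.
#' @return Character vector of the files written, invisibly.
#' @export
run_command <- function(command, config, out_dir, seed = 1) {
  cfg <- read_run_config(config, command)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  written <- switch(command,
    "generate-geometry" = cmd_generate_geometry(cfg, out_dir),
    "build-maps" = cmd_build_maps(cfg, out_dir),
    "render-stimulus" = cmd_render_stimulus(cfg, out_dir),
    "estimate-rf" = cmd_estimate_rf(cfg, out_dir, seed),
    "evaluate-distortion" = cmd_evaluate_distortion(cfg, out_dir),
    "simulate-closed-loop" = cmd_simulate_closed_loop(cfg, out_dir, seed))
  written <- c(written, write_resolved_config(cfg, out_dir, command, seed))
  invisible(written)
}

cfg_model <- function(cfg) {
  projector_model(d_proj = cfg$d_proj, throw_ratio = cfg$throw_ratio,
                  aspect_ratio = cfg$aspect_ratio,
                  image_width_px = cfg$image_width_px %||% 1280,
                  image_height_px = cfg$image_height_px %||% 720)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

cmd_generate_geometry <- function(cfg, out_dir) {
  model <- cfg_model(cfg)
  prof <- screen_profile(model, c(cfg$alpha_min_deg, cfg$alpha_max_deg),
                         cfg$n_alpha)
  surf <- screen_surface(model, c(cfg$alpha_min_deg, cfg$alpha_max_deg),
                         cfg$beta_span_deg, cfg$n_alpha, cfg$n_beta)
  svg <- file.path(out_dir, "profile.svg")
  stl <- file.path(out_dir, "surface.stl")
  write_profile_svg(prof, svg, scale = cfg$scale)
  write_surface_stl(surf, stl, scale = cfg$scale)
  c(svg, stl)
}

cmd_build_maps <- function(cfg, out_dir) {
  model <- cfg_model(cfg)
  maps <- build_pixel_maps(
    model, texture_dims = c(cfg$texture_rows, cfg$texture_cols),
    az_range = c(cfg$az_min_deg, cfg$az_max_deg),
    el_range = c(cfg$el_min_deg, cfg$el_max_deg),
    alpha_range = c(cfg$alpha_min_deg, cfg$alpha_max_deg),
    az_span = cfg$beta_span_deg)
  rds <- file.path(out_dir, "pixel-maps.rds")
  saveRDS(maps, rds, compress = "gzip")
  meta <- file.path(out_dir, "pixel-maps.json")
  jsonlite::write_json(
    list(projector = unclass(model)[c("d_proj", "throw_ratio",
                                      "aspect_ratio", "image_width_px",
                                      "image_height_px")],
         texture_dims = maps$texture_dims, az_range = maps$az_range,
         el_range = maps$el_range, alpha_range = maps$alpha_range,
         az_span = maps$az_span, valid_fraction = mean(maps$valid)),
    meta, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  c(rds, meta)
}

cmd_render_stimulus <- function(cfg, out_dir) {
  make_frame <- function(yaw, t) {
    switch(cfg$stimulus,
      grating = cylinder_grating(period = cfg$period %||% 30,
                                 height = cfg$height %||% 36,
                                 yaw = yaw, res = cfg$res_deg),
      bar = dark_bar(width = cfg$width %||% 15, position = yaw,
                     res = cfg$res_deg),
      cuboid = cuboid_interior(yaw = yaw, res = cfg$res_deg),
      edge = moving_edge(cfg$polarity %||% "bright",
                         velocity = cfg$velocity, t = t,
                         res = cfg$res_deg),
      stop_domain("unknown stimulus type `", cfg$stimulus, "`"))
  }
  paths <- character(0)
  for (f in seq_len(cfg$frames)) {
    t <- (f - 1) / cfg$rate
    tex <- make_frame(cfg$yaw + cfg$velocity * t, t)
    p <- file.path(out_dir, sprintf("frame-%04d.png", f))
    write_texture_png(tex, p)
    paths <- c(paths, p)
  }
  paths
}

cmd_estimate_rf <- function(cfg, out_dir, seed) {
  grid <- noise_grid(cell = cfg$cell_deg, az_extent = cfg$az_extent_deg,
                     el_extent = cfg$el_extent_deg, rate = cfg$rate,
                     seed = seed)
  stim <- binary_noise(grid, cfg$duration_s)
  sensor <- cfg$sensor
  resp <- if (identical(sensor$type, "neuron")) {
    model <- ln_neuron_model(center = c(sensor$az %||% 0, sensor$el %||% -20),
                             fwhm = sensor$fwhm %||% 10,
                             noise_sd = sensor$noise_sd %||% 0.1)
    neuron_respond(stim, model, seed)
  } else {
    model <- photodiode_model(center = c(sensor$az %||% 0,
                                         sensor$el %||% -20),
                              fwhm = sensor$fwhm %||% 20,
                              profile = "gaussian",
                              noise_sd = sensor$noise_sd %||% 0.02)
    photodiode_respond(stim, model, seed)
  }
  k <- reverse_correlate(stim, resp, cfg$max_lag)
  rec <- recenter_rf(k)
  st <- rf_stats(rec)
  rds <- file.path(out_dir, "kernel.rds")
  saveRDS(k, rds, compress = "gzip")
  csv <- file.path(out_dir, "rf-summary.csv")
  utils::write.csv(
    data.frame(center_az = st$center[1], center_el = st$center[2],
               fwhm_az = st$fwhm_az, fwhm_el = st$fwhm_el,
               size_deg2 = st$size_deg2, polarity = st$polarity,
               peak = st$peak_value,
               peak_lag = kernel_peak_lag(k)),
    csv, row.names = FALSE)
  c(rds, csv)
}

cmd_evaluate_distortion <- function(cfg, out_dir) {
  gp <- orient_to_center(equalize_areas(
    goldberg_polyhedron(cfg$goldberg_m, cfg$goldberg_n)))
  screen <- switch(cfg$screen,
    flat = screen_flat(1),
    cylinder = screen_cylinder(1),
    bowl = screen_bowl(cfg_model(cfg)),
    stop_domain("unknown screen kind `", cfg$screen, "`"))
  pr <- project_faces(gp, screen, fov = cfg$fov_deg, shrink = cfg$shrink)
  df <- distortion_metrics(pr)
  csv <- file.path(out_dir, "distortion.csv")
  write_distortion_csv(df, csv)
  csv
}

cmd_simulate_closed_loop <- function(cfg, out_dir, seed) {
  tex <- switch(cfg$texture,
    bar = dark_bar(width = cfg$width %||% 15, res = 2),
    cuboid = cuboid_interior(res = 2),
    stop_domain("unknown texture `", cfg$texture, "`"))
  paths <- character(0)
  dens <- list()
  for (tr in seq_len(cfg$trials)) {
    pol <- dark_seeking_policy(k = cfg$policy_gain,
                               noise_sd = cfg$policy_noise_sd,
                               seed = seed + tr)
    traj <- simulate_fixation(tex, pol, duration_s = cfg$duration_s,
                              rate = cfg$rate, gain = cfg$gain,
                              max_rate = cfg$max_rate, seed = seed + tr)
    p <- file.path(out_dir, sprintf("trajectory-%02d.csv", tr))
    utils::write.csv(traj, p, row.names = FALSE)
    paths <- c(paths, p)
    dens[[tr]] <- fixation_density(traj$yaw, cfg$rate)
  }
  avg <- average_fixation_density(dens)
  p <- file.path(out_dir, "fixation-density.csv")
  utils::write.csv(avg, p, row.names = FALSE)
  c(paths, p)
}
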