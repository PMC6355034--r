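#' Analysis settings for tracking, kinematics and directionality
#'
#' Bundles every user-tunable threshold of the analysis pipeline into a
#' validated list. Defaults correspond to a 60 fps acquisition of a
#' simulated arena at 1 um/px; for real microscope data set `um_per_px`
#' (and usually the cell-size window) to match the optics.
#'
#' @param um_per_px Spatial scale, microns per pixel.
#' @param fps Frame rate of the video (frames per second).
#' @param min_cell_size,max_cell_size Detection size window in square
#'   microns; connected components outside it are discarded.
#' @param min_vcl Minimum curvilinear velocity (um/s) for a track to be
#'   called motile.
#' @param min_track_length Minimum number of points a track must have to be
#'   kept by [filter_tracks()].
#' @param max_displacement Search radius for frame-to-frame linking, in
#'   microns: how far a cell may move between consecutive frames.
#' @param window_size Width `w` (frames) of the rectangular moving average
#'   that defines the average path. Must lie between 2 and the number of
#'   frames minus one.
#' @param str_threshold,vap_threshold Progressive-motility cut-offs: a
#'   motile track is progressive when STR (%) exceeds `str_threshold` and
#'   VAP (um/s) exceeds `vap_threshold`.
#' @param vcl_lower,vcl_upper VCL reporting bands (um/s) used only to
#'   colour-code trajectories in overlay output (slow / moderate / fast).
#' @param angle_delta Frame lag used when computing displacement
#'   directions (directionality angles and MAD).
#' @param gamma Half-amplitude of the gradient cone, degrees in (0, 90]:
#'   displacements with |psi| <= gamma count as oriented up-gradient.
#' @param theta Gradient direction, degrees, in image coordinates
#'   (0 = +x axis; y points down).
#' @param option Counting rule for displacements not pointing up-gradient:
#'   `1` counts every angle outside the cone as N-, `2` counts only the
#'   opposite cone `[180 - gamma, 180 + gamma]`.
#' @param n_resamples Number of bootstrap iterations for the odds-ratio
#'   null distribution.
#' @param invert Logical; `TRUE` for bright-field-like images where cells
#'   are darker than the background (the frame is inverted before Otsu
#'   thresholding).
#'
#' @return A list of class `casa_settings`.
#' @seealso [simulation_params()], [read_config()]
#' @examples
#' s <- analysis_settings(um_per_px = 0.5, fps = 25)
#' s$max_displacement
#' @export
analysis_settings <- function(um_per_px = 1, fps = 60,
                              min_cell_size = 10, max_cell_size = 300,
                              min_vcl = 10, min_track_length = 10,
                              max_displacement = 10, window_size = 5,
                              str_threshold = 80, vap_threshold = 25,
                              vcl_lower = 60, vcl_upper = 200,
                              angle_delta = 1, gamma = 30, theta = 0,
                              option = 1, n_resamples = 10000,
                              invert = FALSE) {
  stop_if_not_number(um_per_px, "um_per_px", 0, strict_min = TRUE)
  stop_if_not_number(fps, "fps", 0, strict_min = TRUE)
  stop_if_not_number(min_cell_size, "min_cell_size", 0)
  stop_if_not_number(max_cell_size, "max_cell_size", min_cell_size)
  stop_if_not_number(min_vcl, "min_vcl", 0)
  stop_if_not_number(min_track_length, "min_track_length", 1)
  stop_if_not_number(max_displacement, "max_displacement", 0,
                     strict_min = TRUE)
  stop_if_not_number(window_size, "window_size", 2)
  stop_if_not_number(str_threshold, "str_threshold", 0, 100)
  stop_if_not_number(vap_threshold, "vap_threshold", 0)
  stop_if_not_number(angle_delta, "angle_delta", 1)
  stop_if_not_number(gamma, "gamma", 0, 90, strict_min = TRUE)
  stop_if_not_number(theta, "theta")
  if (!option %in% c(1, 2)) abort("`option` must be 1 or 2")
  stop_if_not_number(n_resamples, "n_resamples", 1)
  if (!is.logical(invert) || length(invert) != 1L) {
    abort("`invert` must be TRUE or FALSE")
  }
  structure(
    list(um_per_px = um_per_px, fps = fps,
         min_cell_size = min_cell_size, max_cell_size = max_cell_size,
         min_vcl = min_vcl, min_track_length = as.integer(min_track_length),
         max_displacement = max_displacement,
         window_size = as.integer(window_size),
         str_threshold = str_threshold, vap_threshold = vap_threshold,
         vcl_lower = vcl_lower, vcl_upper = vcl_upper,
         angle_delta = as.integer(angle_delta), gamma = gamma,
         theta = theta, option = as.integer(option),
         n_resamples = as.integer(n_resamples), invert = invert),
    class = "casa_settings")
}

#' @export
print.casa_settings <- function(x, ...) {
  cat("<casa_settings>\n")
  for (nm in names(x)) cat(sprintf("  %-17s %s\n", nm, format(x[[nm]])))
  invisible(x)
}

#' Parameters of the persistent random walk simulator
#'
#' Defines a virtual population whose cells swim at constant speed `v0`
#' while their heading diffuses with rotational diffusion coefficient
#' `d_rot` and, for the responsive fraction, relaxes toward the +x axis at
#' rate `beta / tau`. Defaults reproduce the reference validation
#' configuration: 100 cells on an 800 x 800 px arena for 500 frames with
#' `d_rot = 0.1`, `v0 = 3` and no attraction.
#'
#' @param d_rot Rotational diffusion coefficient (rad^2/frame), >= 0.
#' @param v0 Swimming speed (px/frame), >= 0.
#' @param beta Alignment strength toward the +x axis (per frame, signed;
#'   0 = no attraction, negative values align to -x).
#' @param tau Alignment time constant (frames), > 0.
#' @param responsiveness Fraction in \[0, 1\] of cells that feel `beta` —
#'   the capacitated subpopulation; the rest swim with `beta = 0`.
#' @param psi0 Initial heading: `"uniform"` for headings drawn uniformly on
#'   the circle, or a single angle in radians.
#' @param n_cells Number of cells (>= 1).
#' @param n_frames Number of frames per trajectory (>= 2).
#' @param arena_w,arena_h Arena size in pixels.
#' @param cell_axes Ellipse semi-axes (px, `c(major, minor)`) used when
#'   rendering cells to frames; the default draws a 10 x 8 px cell.
#'
#' @return A list of class `casa_sim_params`.
#' @examples
#' p <- simulation_params(beta = 1, responsiveness = 0.5)
#' tracks <- simulate_population(p, seed = 1)
#' @export
simulation_params <- function(d_rot = 0.1, v0 = 3, beta = 0, tau = 1,
                              responsiveness = 0, psi0 = "uniform",
                              n_cells = 100, n_frames = 500,
                              arena_w = 800, arena_h = 800,
                              cell_axes = c(5, 4)) {
  stop_if_not_number(d_rot, "d_rot", 0)
  stop_if_not_number(v0, "v0", 0)
  stop_if_not_number(beta, "beta")
  stop_if_not_number(tau, "tau", 0, strict_min = TRUE)
  stop_if_not_number(responsiveness, "responsiveness", 0, 1)
  if (!(identical(psi0, "uniform") || is_number(psi0))) {
    abort("`psi0` must be \"uniform\" or a single angle in radians")
  }
  stop_if_not_number(n_cells, "n_cells", 1)
  stop_if_not_number(n_frames, "n_frames", 2)
  stop_if_not_number(arena_w, "arena_w", 1)
  stop_if_not_number(arena_h, "arena_h", 1)
  if (!is.numeric(cell_axes) || length(cell_axes) != 2L ||
      any(!is.finite(cell_axes)) || any(cell_axes <= 0)) {
    abort("`cell_axes` must be two positive semi-axes (px)")
  }
  structure(
    list(d_rot = d_rot, v0 = v0, beta = beta, tau = tau,
         responsiveness = responsiveness, psi0 = psi0,
         n_cells = as.integer(n_cells), n_frames = as.integer(n_frames),
         arena_w = as.integer(arena_w), arena_h = as.integer(arena_h),
         cell_axes = as.numeric(cell_axes)),
    class = "casa_sim_params")
}

#' @export
print.casa_sim_params <- function(x, ...) {
  cat("<casa_sim_params>\n")
  for (nm in names(x)) {
    cat(sprintf("  %-15s %s\n", nm, paste(format(x[[nm]]), collapse = " ")))
  }
  invisible(x)
}

#' Read or write a pipeline configuration file
#'
#' A single YAML file with two optional sections, `analysis` and
#' `simulation`, whose keys are the arguments of [analysis_settings()] and
#' [simulation_params()]. Unknown keys are rejected so typos cannot
#' silently fall back to defaults.
#'
#' @param path Path to a YAML file.
#' @return `read_config()`: a list with elements `analysis`
#'   (`casa_settings`) and `simulation` (`casa_sim_params`).
#' @examples
#' cfg <- tempfile(fileext = ".yaml")
#' writeLines("analysis:\n  fps: 25\nsimulation:\n  n_cells: 10", cfg)
#' read_config(cfg)$analysis$fps
#' @export
read_config <- function(path) {
  if (!file.exists(path)) abort(sprintf("config file not found: %s", path))
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  bad <- setdiff(names(raw), c("analysis", "simulation"))
  if (length(bad)) {
    abort(sprintf("unknown config section(s): %s", toString(bad)))
  }
  check_keys <- function(got, fn, section) {
    bad <- setdiff(names(got), names(formals(fn)))
    if (length(bad)) {
      abort(sprintf("unknown key(s) in `%s` section: %s",
                    section, toString(bad)))
    }
    got
  }
  analysis <- do.call(
    analysis_settings,
    check_keys(raw$analysis %||% list(), analysis_settings, "analysis"))
  simulation <- do.call(
    simulation_params,
    check_keys(raw$simulation %||% list(), simulation_params, "simulation"))
  list(analysis = analysis, simulation = simulation)
}

#' @param config A list as returned by [read_config()].
#' @rdname read_config
#' @export
write_config <- function(config, path) {
  strip <- function(x) {
    x <- unclass(x)
    lapply(x, function(v) if (length(v) > 1) as.list(v) else v)
  }
  yaml::write_yaml(list(analysis = strip(config$analysis),
                        simulation = strip(config$simulation)), path)
  invisible(path)
}
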