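#' One Euler step of the persistent random walk
#'
#' Advances one or more cells by a single frame. The heading first receives
#' the alignment and diffusion update,
#' `psi' = wrap(psi - (beta_eff / tau) * sin(psi) + sqrt(2 * d_rot) * z)`
#' with `z` standard normal and `beta_eff = beta` for responsive cells and
#' 0 otherwise; the displacement of the same step then uses the updated
#' heading: `x' = x + v0 * cos(psi')`, `y' = y + v0 * sin(psi')`. The time
#' step is one frame, so all rates are per frame.
#'
#' @param x,y,psi Numeric vectors (recycled to a common length): positions
#'   in px and headings in radians.
#' @param params A [simulation_params()] object.
#' @param responsive Logical vector: which cells feel the alignment term.
#' @param noise Optional standard-normal draws to use instead of fresh
#'   `rnorm()` values (useful for deterministic checks).
#'
#' @return A tibble with columns `x`, `y`, `psi` (psi wrapped to
#'   (-pi, pi]).
#' @examples
#' # noise-free straight swimmer along +x
#' p <- simulation_params(d_rot = 0, v0 = 3)
#' step_cell(0, 0, 0, p)
#' @export
step_cell <- function(x, y, psi, params, responsive = FALSE, noise = NULL) {
  stopifnot(inherits(params, "casa_sim_params"))
  n <- max(length(x), length(y), length(psi), length(responsive))
  x <- rep_len(as.numeric(x), n)
  y <- rep_len(as.numeric(y), n)
  psi <- rep_len(as.numeric(psi), n)
  responsive <- rep_len(as.logical(responsive), n)
  z <- if (is.null(noise)) rnorm(n) else rep_len(as.numeric(noise), n)
  beta_eff <- ifelse(responsive, params$beta, 0)
  psi_new <- wrap_angle(psi - (beta_eff / params$tau) * sin(psi) +
                          sqrt(2 * params$d_rot) * z)
  tibble(x = x + params$v0 * cos(psi_new),
         y = y + params$v0 * sin(psi_new),
         psi = psi_new)
}

#' Simulate a population of persistent-random-walk swimmers
#'
#' Generates `n_cells` trajectories of `n_frames` points each. The first
#' `floor(responsiveness * n_cells)` cells are responsive (the alignment
#' strength `beta` applies); the rest swim with `beta = 0`. Initial
#' positions are uniform over the arena; initial headings follow `psi0`.
#' Cells are free to leave the arena: positions are never reflected and are
#' only clipped at render time.
#'
#' @param params A [simulation_params()] object.
#' @param seed Optional integer seed for reproducibility; the same seed
#'   yields a bit-identical track table.
#' @param init_xy Optional `n_cells` x 2 matrix of initial positions (px),
#'   overriding the uniform placement (handy for collision-free fixtures).
#'
#' @return A tibble with columns `track_id`, `frame` (0-based), `x`, `y`
#'   (px) and `responsive`, ordered by track then frame.
#' @examples
#' tracks <- simulate_population(simulation_params(n_cells = 5,
#'                                                 n_frames = 50), seed = 1)
#' dplyr::count(tracks, track_id)
#' @export
simulate_population <- function(params, seed = NULL, init_xy = NULL) {
  stopifnot(inherits(params, "casa_sim_params"))
  if (!is.null(seed)) set.seed(seed)
  nc <- params$n_cells
  nf <- params$n_frames
  if (is.null(init_xy)) {
    x0 <- runif(nc, 0, params$arena_w)
    y0 <- runif(nc, 0, params$arena_h)
  } else {
    init_xy <- as.matrix(init_xy)
    stopifnot(nrow(init_xy) == nc, ncol(init_xy) == 2)
    x0 <- as.numeric(init_xy[, 1])
    y0 <- as.numeric(init_xy[, 2])
  }
  psi <- if (identical(params$psi0, "uniform")) {
    runif(nc, -pi, pi)
  } else {
    rep(as.numeric(params$psi0), nc)
  }
  responsive <- seq_len(nc) <= floor(params$responsiveness * nc)

  X <- matrix(0, nf, nc)
  Y <- matrix(0, nf, nc)
  X[1, ] <- x0
  Y[1, ] <- y0
  beta_eff <- ifelse(responsive, params$beta, 0)
  rate <- beta_eff / params$tau
  sig <- sqrt(2 * params$d_rot)
  for (t in seq_len(nf - 1L)) {
    psi <- wrap_angle(psi - rate * sin(psi) + sig * rnorm(nc))
    X[t + 1L, ] <- X[t, ] + params$v0 * cos(psi)
    Y[t + 1L, ] <- Y[t, ] + params$v0 * sin(psi)
  }
  tibble(track_id = rep(seq_len(nc), each = nf),
         frame = rep(0:(nf - 1L), times = nc),
         x = as.numeric(X), y = as.numeric(Y),
         responsive = rep(responsive, each = nf))
}

# Headings per point, from forward differences (last point: backward).
track_headings <- function(tracks) {
  tracks |>
    dplyr::arrange(.data$track_id, .data$frame) |>
    dplyr::group_by(.data$track_id) |>
    dplyr::mutate(
      dx = dplyr::lead(.data$x) - .data$x,
      dy = dplyr::lead(.data$y) - .data$y,
      dx = dplyr::coalesce(.data$dx, dplyr::lag(.data$dx)),
      dy = dplyr::coalesce(.data$dy, dplyr::lag(.data$dy)),
      heading = atan2(.data$dy, .data$dx)) |>
    dplyr::ungroup() |>
    dplyr::mutate(heading = ifelse(is.na(.data$heading), 0, .data$heading)) |>
    dplyr::select(-"dx", -"dy")
}

#' Render simulated tracks to synthetic video frames
#'
#' Paints each cell as a filled bright ellipse (intensity 255 on a black
#' background) with the given semi-axes, centred at its position and with
#' the major axis aligned to its current heading (estimated from the
#' displacement to the next frame). Cells outside the arena are clipped.
#'
#' @param tracks A track tibble (`track_id`, `frame`, `x`, `y`).
#' @param params A [simulation_params()] object (arena size, cell axes).
#' @param frames Which frame indices to render; defaults to every frame
#'   present in `tracks`.
#' @return `render_frames()`: a list of integer matrices of dimension
#'   `arena_w` x `arena_h` (first index x, second y, matching the
#'   image convention used throughout the package), one per frame.
#'   `render_frame()`: a single such matrix.
#' @examples
#' p <- simulation_params(n_cells = 3, n_frames = 5, arena_w = 100,
#'                        arena_h = 100)
#' fr <- render_frames(simulate_population(p, seed = 1), p)
#' length(fr)
#' @export
render_frames <- function(tracks, params, frames = NULL) {
  stopifnot(inherits(params, "casa_sim_params"))
  if (2 * max(params$cell_axes) + 1 > min(params$arena_w, params$arena_h)) {
    abort("arena is smaller than one rendered cell")
  }
  if (is.null(frames)) frames <- sort(unique(tracks$frame))
  with_heading <- track_headings(tracks)
  lapply(frames, function(f) render_one(with_heading, f, params))
}

#' @param frame A single frame index to render.
#' @rdname render_frames
#' @export
render_frame <- function(tracks, frame, params) {
  stopifnot(inherits(params, "casa_sim_params"))
  if (2 * max(params$cell_axes) + 1 > min(params$arena_w, params$arena_h)) {
    abort("arena is smaller than one rendered cell")
  }
  render_one(track_headings(tracks), frame, params)
}

render_one <- function(with_heading, frame, params) {
  w <- params$arena_w
  h <- params$arena_h
  a <- params$cell_axes[1]
  b <- params$cell_axes[2]
  img <- matrix(0L, nrow = w, ncol = h)
  pts <- with_heading[with_heading$frame == frame, , drop = FALSE]
  nc <- nrow(pts)
  if (nc == 0) return(img)
  # one shared candidate grid of pixel offsets around each cell centre
  r <- ceiling(max(a, b)) + 1L
  offs <- -r:r
  gx <- rep(offs, times = length(offs))
  gy <- rep(offs, each = length(offs))
  ng <- length(gx)
  X <- rep(floor(pts$x), each = ng) + gx
  Y <- rep(floor(pts$y), each = ng) + gy
  dx <- X - rep(pts$x, each = ng)
  dy <- Y - rep(pts$y, each = ng)
  cs <- rep(cos(pts$heading), each = ng)
  sn <- rep(sin(pts$heading), each = ng)
  u <- dx * cs + dy * sn
  v <- -dx * sn + dy * cs
  inside <- (u / a)^2 + (v / b)^2 <= 1 &
    X >= 1L & X <= w & Y >= 1L & Y <= h
  img[X[inside] + (Y[inside] - 1L) * w] <- 255L
  img
}
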