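as_xy <- function(points) {
  if (is.data.frame(points)) {
    stopifnot(all(c("x", "y") %in% names(points)))
    points <- cbind(points$x, points$y)
  }
  points <- as.matrix(points)
  stopifnot(ncol(points) == 2, is.numeric(points))
  unname(points)
}

#' Average path of a trajectory
#'
#' Smooths a raw trajectory with a rectangular (simple) moving average of
#' window `w`: the t-th average point is the mean of raw points
#' `t .. t + w - 1`, so a trajectory of `N` points yields an average path
#' of exactly `N - w + 1` points, with no padding at the edges.
#'
#' @param points Trajectory points: a 2-column matrix or a data frame with
#'   `x` and `y` columns, in frame order.
#' @param w Window size in frames, `2 <= w <= N - 1`.
#' @return A `(N - w + 1)` x 2 numeric matrix.
#' @examples
#' average_path(cbind(c(0, 1, 2), c(0, 1, 0)), w = 2)
#' @export
average_path <- function(points, w) {
  p <- as_xy(points)
  n <- nrow(p)
  w <- as.integer(w)
  if (w < 2 || w > n - 1) {
    abort(sprintf("window size w=%d out of range [2, N-1] for N=%d", w, n))
  }
  cs <- apply(rbind(0, p), 2, cumsum)
  (cs[(w + 1):(n + 1), , drop = FALSE] -
     cs[1:(n - w + 1), , drop = FALSE]) / w
}

#' Straight-line, curvilinear and average-path velocities
#'
#' VSL is the first-to-last-point distance over the observation time, VCL
#' the summed point-to-point path length over the same time, and VAP the
#' length of the average path over its own time span; all converted to
#' um/s with the frame rate and the um/px scale.
#'
#' @inheritParams average_path
#' @param avg Average path from [average_path()] (its length fixes `w`).
#' @param settings An [analysis_settings()] object (`fps`, `um_per_px`).
#' @return A one-row tibble with `vsl`, `vcl`, `vap` in um/s.
#' @examples
#' p <- cbind(0:9, 0)
#' path_velocities(p, average_path(p, 2), analysis_settings(fps = 1))
#' @export
path_velocities <- function(points, avg, settings) {
  p <- as_xy(points)
  q <- as_xy(avg)
  n <- nrow(p)
  stopifnot(n >= 2)
  w <- n - nrow(q) + 1L
  k <- settings$fps * settings$um_per_px
  seglen <- function(m) sqrt(rowSums((m[-1, , drop = FALSE] -
                                        m[-nrow(m), , drop = FALSE])^2))
  tibble(vsl = sqrt(sum((p[n, ] - p[1, ])^2)) * k / (n - 1),
         vcl = sum(seglen(p)) * k / (n - 1),
         vap = sum(seglen(q)) * k / (n - w))
}

#' Linearity, wobble and straightness ratios
#'
#' LIN = VSL/VCL, WOB = VAP/VCL, STR = VSL/VAP, each as a percentage.
#' Ratios with a zero denominator are reported as `NA`.
#'
#' @param vsl,vcl,vap Velocities in um/s.
#' @return A one-row tibble with `lin`, `wob`, `str` (%).
#' @examples
#' velocity_ratios(5, 10, 8)
#' @export
velocity_ratios <- function(vsl, vcl, vap) {
  tibble(lin = if (isTRUE(vcl > 0)) 100 * vsl / vcl else NA_real_,
         wob = if (isTRUE(vcl > 0) && is.finite(vap)) 100 * vap / vcl
               else NA_real_,
         str = if (isTRUE(vap > 0)) 100 * vsl / vap else NA_real_)
}

# Distance from point pt to the closed segment [a, b].
point_segment_distance <- function(pt, a, b) {
  ab <- b - a
  len2 <- sum(ab^2)
  tt <- if (len2 == 0) 0 else max(0, min(1, sum((pt - a) * ab) / len2))
  sqrt(sum((pt - a + tt * (a - b))^2))
}

#' Amplitude of lateral head displacement (ALH)
#'
#' For each average-path segment midpoint, the distance to the nearest raw
#' segment among those built from the window of raw points that produced
#' it (`p_t .. p_{t+w-1}`) is computed; the series of these deviations is
#' scanned for strict local maxima (greater than both neighbours), read as
#' the peaks of the head's lateral oscillation about the average path.
#' ALH is twice the peak deviation (peak-to-trough convention): the mean
#' of the local maxima and the largest one, in microns. A trajectory whose
#' deviation series has no local maxima (e.g. a perfect straight line)
#' reports 0 for both.
#'
#' @inheritParams path_velocities
#' @return A one-row tibble with `alh_mean` and `alh_max` (um).
#' @export
track_alh <- function(points, avg, settings) {
  p <- as_xy(points)
  q <- as_xy(avg)
  n <- nrow(p)
  w <- n - nrow(q) + 1L
  m <- nrow(q) - 1L           # midpoints qm_t, t = 1..N-w
  if (m < 3) return(tibble(alh_mean = NA_real_, alh_max = NA_real_))
  dser <- numeric(m)
  for (t in seq_len(m)) {
    qm <- (q[t, ] + q[t + 1, ]) / 2
    js <- t:(t + w - 2L)      # raw segments fully inside the window
    dser[t] <- min(vapply(js, function(j) {
      point_segment_distance(qm, p[j, ], p[j + 1, ])
    }, numeric(1)))
  }
  i <- 2:(m - 1)
  peaks <- dser[i][dser[i] > dser[i - 1] & dser[i] > dser[i + 1]]
  if (!length(peaks)) return(tibble(alh_mean = 0, alh_max = 0))
  tibble(alh_mean = 2 * settings$um_per_px * mean(peaks),
         alh_max = 2 * settings$um_per_px * max(peaks))
}

# TRUE where segment pairs (a1->a2, b1->b2) properly cross (strict
# transversal intersection; collinear overlaps and endpoint touches do
# not count). Orientation determinants within a relative epsilon of zero
# are snapped to zero so that nominally collinear geometry (e.g. a
# straight path and its own moving average) does not generate crossings
# out of rounding noise. All arguments are n x 2 matrices.
segments_cross <- function(a1, a2, b1, b2) {
  crs <- function(u1, u2, v1, v2) {
    ux <- u2[, 1] - u1[, 1]
    uy <- u2[, 2] - u1[, 2]
    vx <- v2[, 1] - v1[, 1]
    vy <- v2[, 2] - v1[, 2]
    d <- ux * vy - uy * vx
    d[abs(d) < 1e-9 * sqrt((ux^2 + uy^2) * (vx^2 + vy^2))] <- 0
    d
  }
  d1 <- crs(a1, a2, a1, b1)
  d2 <- crs(a1, a2, a1, b2)
  d3 <- crs(b1, b2, b1, a1)
  d4 <- crs(b1, b2, b1, a2)
  d1 * d2 < 0 & d3 * d4 < 0
}

#' Beat-cross frequency (BCF)
#'
#' Counts proper crossings between any raw-trajectory segment and any
#' average-path segment, and converts the count to Hz with the frame rate
#' over the average-path time span: `BCF = count * fps / (N - w)`.
#' Collinear overlaps and shared-endpoint touches are not crossings.
#'
#' @inheritParams path_velocities
#' @return BCF in Hz (a single number).
#' @export
track_bcf <- function(points, avg, settings) {
  p <- as_xy(points)
  q <- as_xy(avg)
  n <- nrow(p)
  w <- n - nrow(q) + 1L
  nr <- n - 1L
  na_ <- nrow(q) - 1L
  i <- rep(seq_len(nr), times = na_)
  j <- rep(seq_len(na_), each = nr)
  hits <- segments_cross(p[i, , drop = FALSE], p[i + 1L, , drop = FALSE],
                         q[j, , drop = FALSE], q[j + 1L, , drop = FALSE])
  sum(hits) * settings$fps / (n - w)
}

#' Mean angular displacement (MAD)
#'
#' Directions are taken from the displacement vectors `p_t -> p_{t+delta}`.
#' The default `"turning"` mode returns the time average of the absolute
#' wrapped angle between consecutive directions — the mean absolute
#' instantaneous turning angle, in degrees. `"literal"` mode instead
#' averages the raw (wrapped) direction angles themselves, the plain
#' reading of the defining formula; it is provided for comparison.
#' Zero-length displacements contribute no direction and are skipped.
#'
#' @inheritParams average_path
#' @param delta Frame lag for the displacement vectors (>= 1).
#' @param mode `"turning"` (default) or `"literal"`.
#' @return MAD in degrees (a single number), `NA` if fewer than two
#'   directions exist.
#' @examples
#' track_mad(cbind(c(0, 1, 2, 2, 2), c(0, 0, 0, 1, 2)))  # one 90 deg turn
#' @export
track_mad <- function(points, delta = 1, mode = c("turning", "literal")) {
  mode <- match.arg(mode)
  p <- as_xy(points)
  n <- nrow(p)
  delta <- as.integer(delta)
  if (delta < 1 || delta > n - 2) {
    abort(sprintf("delta=%d out of range [1, N-2] for N=%d", delta, n))
  }
  d <- p[(1 + delta):n, , drop = FALSE] - p[1:(n - delta), , drop = FALSE]
  nz <- rowSums(d^2) > 0
  ang <- atan2(d[nz, 2], d[nz, 1])
  if (mode == "literal") {
    if (!length(ang)) return(NA_real_)
    return(mean(wrap_deg(ang * 180 / pi)))
  }
  if (length(ang) < 2) return(NA_real_)
  mean(abs(wrap_angle(diff(ang)))) * 180 / pi
}

#' Katz fractal dimension of a trajectory
#'
#' `FD = log(n) / (log(n) + log(d / L))` with `n` the number of track
#' intervals (points minus one), `d` the planar extent (maximum distance
#' from the first point to any other) and `L` the curvilinear length.
#' A straight line gives exactly 1; irregular, plane-filling walks
#' approach 2. Stationary tracks (`d = 0`) are undefined (`NA`).
#'
#' @inheritParams average_path
#' @return The fractal dimension (a single number >= 1, or `NA`).
#' @examples
#' track_fd(cbind(0:10, 0))
#' @export
track_fd <- function(points) {
  p <- as_xy(points)
  n <- nrow(p) - 1L
  stopifnot(n >= 2)
  d <- sqrt(max(rowSums((p - matrix(p[1, ], nrow(p), 2, byrow = TRUE))^2)))
  L <- sum(sqrt(rowSums((p[-1, , drop = FALSE] -
                           p[-nrow(p), , drop = FALSE])^2)))
  if (d == 0 || L == 0) return(NA_real_)
  log(n) / (log(n) + log(d / L))
}

#' Motile / progressive classification of one track
#'
#' A track is motile when its VCL strictly exceeds the `min_vcl` threshold
#' and its first and last points differ; it is progressive when it is
#' motile and additionally STR > `str_threshold` and VAP >
#' `vap_threshold`.
#'
#' @inheritParams average_path
#' @param vcl,vap,str Computed kinematic values for the track.
#' @param settings An [analysis_settings()] object.
#' @return A one-row tibble with logicals `motile` and `progressive`.
#' @export
classify_motility <- function(points, vcl, vap, str, settings) {
  p <- as_xy(points)
  moved <- any(p[1, ] != p[nrow(p), ])
  motile <- isTRUE(vcl > settings$min_vcl) && moved
  progressive <- motile && isTRUE(str > settings$str_threshold) &&
    isTRUE(vap > settings$vap_threshold)
  tibble(motile = motile, progressive = progressive)
}

kinematics_one <- function(p, settings, mad_mode) {
  n <- nrow(p)
  w <- settings$window_size
  have_avg <- n >= w + 1L
  if (have_avg) {
    q <- average_path(p, w)
    vel <- path_velocities(p, q, settings)
    alh <- track_alh(p, q, settings)
    bcf <- track_bcf(p, q, settings)
  } else {
    q <- NULL
    vel <- path_velocities(p, p, settings)  # vap over full path ...
    vel$vap <- NA_real_                     # ... then marked undefined
    alh <- tibble(alh_mean = NA_real_, alh_max = NA_real_)
    bcf <- NA_real_
  }
  rat <- velocity_ratios(vel$vsl, vel$vcl, vel$vap)
  mad <- if (n >= 3 && settings$angle_delta <= n - 2) {
    track_mad(p, settings$angle_delta, mad_mode)
  } else {
    NA_real_
  }
  fd <- if (n >= 3) track_fd(p) else NA_real_
  cls <- classify_motility(p, vel$vcl, vel$vap, rat$str, settings)
  dplyr::bind_cols(
    tibble(n_points = n), vel, rat, alh,
    tibble(bcf = bcf, mad = mad,
           dnc = if (is.na(alh$alh_mean)) NA_real_
                 else vel$vcl * alh$alh_mean,
           fd = fd),
    cls)
}

#' Kinematic parameters for every track
#'
#' Computes the full kinematic panel per track: VSL, VCL, VAP (um/s), LIN,
#' WOB, STR (%), ALH mean/max (um), BCF (Hz), MAD (degrees), DNC
#' (um^2/s), fractal dimension, and the motile / progressive flags.
#' Undefined quantities (zero denominators, tracks too short for the
#' average-path window) are reported as `NA` and excluded from population
#' means of that parameter only.
#'
#' @param tracks A track tibble (`track_id`, `frame`, `x`, `y`).
#' @param settings An [analysis_settings()] object.
#' @param mad_mode Passed to [track_mad()].
#' @return A tibble with one row per track.
#' @seealso [summarize_kinematics()]
#' @examples
#' tr <- simulate_population(simulation_params(n_cells = 4, n_frames = 60),
#'                           seed = 1)
#' measure_kinematics(tr, analysis_settings())
#' @export
measure_kinematics <- function(tracks, settings,
                               mad_mode = c("turning", "literal")) {
  mad_mode <- match.arg(mad_mode)
  stopifnot(inherits(settings, "casa_settings"))
  tr <- dplyr::arrange(tracks, .data$track_id, .data$frame)
  lens <- dplyr::count(tr, .data$track_id)
  short <- lens$track_id[lens$n < 2]
  if (length(short)) {
    warn(sprintf("dropping %d single-point track(s)", length(short)))
    tr <- tr[!tr$track_id %in% short, ]
  }
  if (nrow(tr) == 0) {
    return(tibble(track_id = integer()))
  }
  tr |>
    dplyr::group_by(.data$track_id) |>
    dplyr::group_modify(function(g, key) {
      kinematics_one(cbind(g$x, g$y), settings, mad_mode)
    }) |>
    dplyr::ungroup()
}

#' Population summary of a kinematics table
#'
#' Means of every kinematic parameter over the motile tracks (tracks with
#' an undefined value are excluded from that parameter's mean only), plus
#' track counts and the percentages of motile and progressive tracks.
#'
#' @param kin Output of [measure_kinematics()].
#' @return A one-row tibble.
#' @export
summarize_kinematics <- function(kin) {
  motile <- dplyr::filter(kin, .data$motile)
  pars <- c("vsl", "vcl", "vap", "lin", "wob", "str", "alh_mean",
            "alh_max", "bcf", "mad", "dnc", "fd")
  means <- lapply(pars, function(pp) {
    if (nrow(motile)) mean(motile[[pp]], na.rm = TRUE) else NA_real_
  })
  dplyr::bind_cols(
    tibble(n_tracks = nrow(kin), n_motile = nrow(motile),
           pct_motile = if (nrow(kin)) 100 * nrow(motile) / nrow(kin)
                        else NA_real_,
           pct_progressive = if (nrow(kin))
             100 * sum(kin$progressive) / nrow(kin) else NA_real_),
    setNames(as_tibble(means, .name_repair = "minimal"), pars))
}
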