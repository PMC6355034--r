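#' Instantaneous directionality angles of a track population
#'
#' For every track and every frame `t`, the signed angle psi between the
#' displacement `p_t -> p_{t+delta}` and the gradient direction `theta`,
#' wrapped to (-180, 180] degrees. Zero-length displacements carry no
#' direction and are skipped. Angles are computed in image coordinates
#' (x right, y down), the same frame in which `theta` is given.
#'
#' @param tracks A track tibble (`track_id`, `frame`, `x`, `y`).
#' @param delta Frame lag of the displacement vectors (>= 1).
#' @param theta Gradient direction in degrees (0 = +x axis).
#' @return A tibble `track_id`, `frame` (start frame of the displacement),
#'   `psi` (degrees).
#' @examples
#' tr <- tibble::tibble(track_id = 1, frame = 0:3, x = 0:3, y = 0)
#' directionality_angles(tr, delta = 1, theta = 0)
#' @export
directionality_angles <- function(tracks, delta = 1, theta = 0) {
  delta <- as.integer(delta)
  stopifnot(delta >= 1)
  tracks |>
    dplyr::arrange(.data$track_id, .data$frame) |>
    dplyr::group_by(.data$track_id) |>
    dplyr::mutate(dx = dplyr::lead(.data$x, delta) - .data$x,
                  dy = dplyr::lead(.data$y, delta) - .data$y) |>
    dplyr::ungroup() |>
    dplyr::filter(!is.na(.data$dx), .data$dx != 0 | .data$dy != 0) |>
    dplyr::mutate(psi = wrap_deg(atan2(.data$dy, .data$dx) * 180 / pi -
                                   theta)) |>
    dplyr::select("track_id", "frame", "psi")
}

#' Count displacements pointing up- and down-gradient
#'
#' `n_plus` counts angles inside the closed cone `[-gamma, +gamma]`.
#' Under option 1 `n_minus` is every other angle; under option 2 only
#' angles in the opposite cone `[180 - gamma, 180 + gamma]` (wrapped)
#' count, and side-pointing displacements are ignored.
#'
#' @param psi Numeric vector of directionality angles in degrees, or a
#'   tibble from [directionality_angles()].
#' @param gamma Cone half-amplitude in degrees, in (0, 90].
#' @param option Counting rule, 1 or 2.
#' @return A one-row tibble with `n_plus` and `n_minus`.
#' @examples
#' count_oriented(c(0, 10, 170, -170), gamma = 30, option = 1)
#' count_oriented(c(0, 10, 170, -170), gamma = 30, option = 2)
#' @export
count_oriented <- function(psi, gamma = 30, option = 1) {
  if (is.data.frame(psi)) psi <- psi$psi
  stop_if_not_number(gamma, "gamma", 0, 90, strict_min = TRUE)
  if (!option %in% c(1, 2)) abort("`option` must be 1 or 2")
  plus <- abs(psi) <= gamma
  minus <- if (option == 1) !plus else abs(wrap_deg(psi - 180)) <= gamma
  tibble(n_plus = sum(plus), n_minus = sum(minus))
}

#' Chemotaxis index
#'
#' The percentage of counted displacements that point up-gradient:
#' `100 * n_plus / (n_plus + n_minus)`. Under a uniform angle
#' distribution with `gamma = 30` and option 1 the expectation is
#' `60/360 * 100 = 16.67` percent.
#'
#' @param n_plus,n_minus Oriented-displacement counts, or a one-row tibble
#'   from [count_oriented()] as the first argument.
#' @return The index in percent (`NA` if no displacement was counted).
#' @examples
#' ch_index(25, 75)
#' @export
ch_index <- function(n_plus, n_minus = NULL) {
  if (is.data.frame(n_plus)) {
    n_minus <- n_plus$n_minus
    n_plus <- n_plus$n_plus
  }
  tot <- n_plus + n_minus
  ifelse(tot > 0, 100 * n_plus / tot, NA_real_)
}

#' Odds and odds-ratio of directional bias
#'
#' The odds value of a sample is `n_plus / n_minus`; the O.R. ratio of a
#' test sample over a control sample is the ratio of their odds and
#' measures the strength of the directional (chemotactic) bias: values
#' near 1 mean the test resembles the control, values above 1 mean
#' attraction toward the gradient.
#'
#' @param test,control One-row tibbles (or lists) with `n_plus` and
#'   `n_minus`, as from [count_oriented()].
#' @return The O.R. ratio (`NA` when any count is zero).
#' @examples
#' or_ratio(list(n_plus = 30, n_minus = 10), list(n_plus = 10, n_minus = 30))
#' @export
or_ratio <- function(test, control) {
  counts <- c(test$n_plus, test$n_minus, control$n_plus, control$n_minus)
  if (length(counts) != 4 || any(counts == 0)) return(NA_real_)
  (test$n_plus / test$n_minus) / (control$n_plus / control$n_minus)
}

# Per-trajectory oriented counts, pooled later by the bootstrap.
per_track_counts <- function(tracks, settings) {
  directionality_angles(tracks, settings$angle_delta, settings$theta) |>
    dplyr::group_by(.data$track_id) |>
    dplyr::summarise(
      n_plus = sum(abs(.data$psi) <= settings$gamma),
      n_minus = if (settings$option == 1) {
        sum(abs(.data$psi) > settings$gamma)
      } else {
        sum(abs(wrap_deg(.data$psi - 180)) <= settings$gamma)
      },
      .groups = "drop")
}

#' Bootstrap null distribution of the odds ratio
#'
#' Builds the no-bias reference distribution of the O.R. statistic from
#' control recordings. Each iteration draws two disjoint subsets of
#' `subset_size` trajectories from the pooled control trajectories
#' (trajectories are returned to the pool between iterations), pools each
#' subset's oriented-displacement counts, and records the ratio of their
#' odds. The decision threshold is the 95th percentile of the resampled
#' ratios, so a test called positive against it carries an approximate 5
#' percent type-I error.
#'
#' `subset_size` defaults to the pool size divided by the number of
#' control recordings — each subset is one recording's worth of
#' trajectories — so the null spread matches the sampling variability of
#' a single recording, which is what an experimental O.R. compares.
#' When `controls` is a single track table (one recording) the default
#' falls back to a half/half split of the pool, which
#' `subset_size = floor(n/2)` also selects explicitly. Iterations in
#' which a subset has a zero count are redrawn.
#'
#' @param controls A track tibble, or a list of track tibbles (one per
#'   control recording).
#' @param settings An [analysis_settings()] object (`angle_delta`,
#'   `theta`, `gamma`, `option`).
#' @param n_resamples Number of bootstrap iterations (default from
#'   `settings`).
#' @param subset_size Trajectories per subset (see above).
#' @param seed Optional integer seed; same seed, same distribution.
#' @return An object of class `casa_or_null` with elements `ratios`,
#'   `threshold` (P95), `subset_size`, `n_recordings`, `n_redraws`.
#' @seealso [is_chemotactic()], [chemotaxis_test()]
#' @export
bootstrap_or_null <- function(controls, settings,
                              n_resamples = settings$n_resamples,
                              subset_size = NULL, seed = NULL) {
  stopifnot(inherits(settings, "casa_settings"))
  if (!is.null(seed)) set.seed(seed)
  if (is.data.frame(controls)) controls <- list(controls)
  n_rec <- length(controls)
  counts <- controls |>
    purrr::imap(function(tr, i) {
      dplyr::mutate(per_track_counts(tr, settings), recording = i)
    }) |>
    dplyr::bind_rows()
  n <- nrow(counts)
  if (n < 4) abort("need at least 4 pooled control trajectories")
  if (is.null(subset_size)) {
    subset_size <- if (n_rec > 1) round(n / n_rec) else floor(n / 2)
  }
  or_null_from_counts(counts$n_plus, counts$n_minus,
                      n_recordings = n_rec, n_resamples = n_resamples,
                      subset_size = subset_size)
}

#' @export
print.casa_or_null <- function(x, ...) {
  cat("<casa_or_null>\n")
  cat(sprintf("  %d resampled O.R. ratios (subsets of %d trajectories, %d recordings)\n",
              length(x$ratios), x$subset_size, x$n_recordings))
  cat(sprintf("  mean %.4f  sd %.4f  P95 threshold %.4f\n",
              mean(x$ratios), sd(x$ratios), x$threshold))
  invisible(x)
}

#' Call directional bias against a bootstrap threshold
#'
#' @param or_value An O.R. ratio from [or_ratio()].
#' @param null A `casa_or_null` object (or a single numeric threshold).
#' @return `TRUE` when `or_value` strictly exceeds the P95 threshold.
#' @export
is_chemotactic <- function(or_value, null) {
  thr <- if (inherits(null, "casa_or_null")) null$threshold else null
  isTRUE(or_value > thr)
}

#' Directional-bias (chemotaxis) test of one population against a control
#'
#' Pools the directionality angles of each population, computes both
#' chemotaxis indices and odds, their O.R. ratio, and compares it with the
#' P95 bootstrap threshold. The null distribution may be supplied
#' pre-computed (recommended when one control panel serves many tests) or
#' is built from the control tracks.
#'
#' @param test,control Track tibbles.
#' @param settings An [analysis_settings()] object.
#' @param null Optional `casa_or_null`; built from `control` when absent.
#' @param ... Passed to [bootstrap_or_null()] when `null` is built here.
#' @return An object of class `casa_chemotaxis`; see [glance.casa_chemotaxis()].
#' @examples
#' s <- analysis_settings(min_track_length = 2)
#' p <- simulation_params(n_cells = 30, n_frames = 80)
#' ctl <- simulate_population(p, seed = 1)
#' tst <- simulate_population(
#'   simulation_params(beta = 1, responsiveness = 1, n_cells = 30,
#'                     n_frames = 80), seed = 2)
#' chemotaxis_test(tst, ctl, s, n_resamples = 200, seed = 3)
#' @export
chemotaxis_test <- function(test, control, settings, null = NULL, ...) {
  stopifnot(inherits(settings, "casa_settings"))
  ang <- function(tr) directionality_angles(tr, settings$angle_delta,
                                            settings$theta)
  cnt <- function(a) count_oriented(a, settings$gamma, settings$option)
  test_counts <- cnt(ang(test))
  control_counts <- cnt(ang(control))
  if (is.null(null)) null <- bootstrap_or_null(control, settings, ...)
  orv <- or_ratio(test_counts, control_counts)
  structure(list(test_counts = test_counts,
                 control_counts = control_counts,
                 ch_index_test = ch_index(test_counts),
                 ch_index_control = ch_index(control_counts),
                 or = orv, null = null,
                 chemotactic = is_chemotactic(orv, null)),
            class = "casa_chemotaxis")
}

#' @export
print.casa_chemotaxis <- function(x, ...) {
  cat("<casa_chemotaxis>\n")
  cat(sprintf("  ch-index: test %.2f%%  control %.2f%%\n",
              x$ch_index_test, x$ch_index_control))
  cat(sprintf("  O.R. %.4f vs P95 threshold %.4f -> %s\n", x$or,
              x$null$threshold,
              if (x$chemotactic) "DIRECTIONAL BIAS" else "no bias detected"))
  invisible(x)
}
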