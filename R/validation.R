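#' Simulation-based validation of the directionality analysis
#'
#' These helpers replicate the package's own validation protocol on
#' unbiased (beta = 0) persistent-random-walk populations: the chemotaxis
#' index of a no-bias population, the bootstrap O.R. null built from many
#' control simulations, and the empirical type-I error of the P95 call.
#' They are used by the test suite and the acceptance script, and are
#' exported so users can rerun the validation under their own settings.
#'
#' `simulate_ch_index()` runs `n_runs` independent simulations and
#' computes each run's pooled ch-index, either directly on the simulated
#' trajectories (`rendered = FALSE`) or through the full
#' render-segment-link pipeline on synthetic frames (`rendered = TRUE`),
#' which adds the detection and track-crossing noise of real analyses.
#'
#' @param n_runs Number of independent simulated populations.
#' @param params A [simulation_params()] object.
#' @param settings An [analysis_settings()] object.
#' @param seed Integer; run `i` uses `seed + i`, so results are
#'   reproducible and runs are independent.
#' @param rendered Pass each population through frames + tracking first?
#' @return A tibble with one row per run: `run`, `ch_index`, `n_plus`,
#'   `n_minus`.
#' @seealso [bootstrap_or_null()], [chemotaxis_test()]
#' @export
simulate_ch_index <- function(n_runs, params, settings, seed,
                              rendered = FALSE) {
  stopifnot(inherits(params, "casa_sim_params"),
            inherits(settings, "casa_settings"))
  purrr::map_dfr(seq_len(n_runs), function(i) {
    tracks <- if (rendered) {
      pipeline_tracks(params, settings, seed + i)
    } else {
      simulate_population(params, seed = seed + i)
    }
    cnt <- count_oriented(
      directionality_angles(tracks, settings$angle_delta, settings$theta),
      settings$gamma, settings$option)
    tibble(run = i, ch_index = ch_index(cnt),
           n_plus = cnt$n_plus, n_minus = cnt$n_minus)
  })
}

# Simulate, render frame by frame, detect and re-link: the full pipeline
# applied to one synthetic video, without materialising the frame stack.
pipeline_tracks <- function(params, settings, seed) {
  tracks <- simulate_population(params, seed = seed)
  wh <- track_headings(tracks)
  det <- lapply(0:(params$n_frames - 1L), function(f) {
    segment_frame(render_one(wh, f, params), settings)
  })
  filter_tracks(link_frames(det, settings), settings)
}

#' @description
#' `simulate_or_null()` simulates `n_controls` unbiased control
#' recordings, pools their trajectories and builds the bootstrap O.R.
#' null distribution ([bootstrap_or_null()] semantics, subsets of one
#' recording's worth of trajectories). It returns the null together with
#' each control recording's pooled counts so the same controls can be
#' reused for type-I-error checks.
#'
#' @param n_controls Number of control recordings to simulate.
#' @param n_resamples Bootstrap iterations.
#' @rdname simulate_ch_index
#' @return For `simulate_or_null()`: a list with `null` (a
#'   `casa_or_null`) and `control_counts` (tibble: `recording`, `n_plus`,
#'   `n_minus`).
#' @export
simulate_or_null <- function(n_controls, params, settings,
                             n_resamples = settings$n_resamples, seed) {
  stopifnot(inherits(params, "casa_sim_params"),
            inherits(settings, "casa_settings"))
  per_track <- purrr::map_dfr(seq_len(n_controls), function(i) {
    tracks <- simulate_population(params, seed = seed + i)
    dplyr::mutate(per_track_counts(tracks, settings), recording = i)
  })
  control_counts <- per_track |>
    dplyr::group_by(.data$recording) |>
    dplyr::summarise(n_plus = sum(.data$n_plus),
                     n_minus = sum(.data$n_minus), .groups = "drop")
  set.seed(seed)
  null <- or_null_from_counts(per_track$n_plus, per_track$n_minus,
                              n_recordings = n_controls,
                              n_resamples = n_resamples,
                              subset_size = round(nrow(per_track) /
                                                    n_controls))
  list(null = null, control_counts = control_counts)
}

# Bootstrap core on precomputed per-trajectory counts; RNG state is the
# caller's.
or_null_from_counts <- function(np, nm, n_recordings, n_resamples,
                                subset_size) {
  n <- length(np)
  if (n < 4) abort("need at least 4 pooled control trajectories")
  subset_size <- as.integer(subset_size)
  if (subset_size < 1 || 2 * subset_size > n) {
    abort("`subset_size` must satisfy 1 <= subset_size <= n/2")
  }
  ratios <- numeric(n_resamples)
  n_redraws <- 0L
  max_attempts <- 100 * n_resamples
  i <- 1L
  while (i <= n_resamples) {
    if (n_redraws + n_resamples > max_attempts) {
      abort("too many degenerate bootstrap iterations (zero counts)")
    }
    idx <- sample.int(n, 2L * subset_size)
    a <- idx[seq_len(subset_size)]
    b <- idx[subset_size + seq_len(subset_size)]
    pa <- sum(np[a]); ma <- sum(nm[a])
    pb <- sum(np[b]); mb <- sum(nm[b])
    if (pa == 0 || ma == 0 || pb == 0 || mb == 0) {
      n_redraws <- n_redraws + 1L
      next
    }
    ratios[i] <- (pa / ma) / (pb / mb)
    i <- i + 1L
  }
  structure(list(ratios = ratios,
                 threshold = unname(quantile(ratios, 0.95)),
                 subset_size = subset_size,
                 n_recordings = as.integer(n_recordings),
                 n_resamples = as.integer(n_resamples),
                 n_redraws = n_redraws),
            class = "casa_or_null")
}

#' @description
#' `simulate_false_positives()` pairs every control recording with a
#' fresh, independent unbiased simulation, computes each pair's O.R.
#' (test over control) and calls it against the null's P95 threshold;
#' with no true bias anywhere, about 5 percent of calls should come out
#' positive.
#'
#' @param control_counts,null Output of `simulate_or_null()`.
#' @rdname simulate_ch_index
#' @return For `simulate_false_positives()`: a tibble with one row per
#'   pair: `pair`, `or`, `positive`.
#' @export
simulate_false_positives <- function(control_counts, null, params,
                                     settings, seed) {
  stopifnot(inherits(null, "casa_or_null"))
  purrr::map_dfr(seq_len(nrow(control_counts)), function(i) {
    tracks <- simulate_population(params, seed = seed + i)
    tst <- count_oriented(
      directionality_angles(tracks, settings$angle_delta, settings$theta),
      settings$gamma, settings$option)
    orv <- or_ratio(tst, control_counts[i, ])
    tibble(pair = i, or = orv, positive = is_chemotactic(orv, null))
  })
}
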