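#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidiers for bootstrap null distributions
#'
#' `tidy()` returns one row per resampled O.R. ratio; `glance()` one row
#' summarising the distribution (mean, sd, P95 threshold, bookkeeping).
#'
#' @param x A `casa_or_null` object from [bootstrap_or_null()].
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.casa_or_null <- function(x, ...) {
  tibble(iteration = seq_along(x$ratios), or = x$ratios)
}

#' @rdname tidy.casa_or_null
#' @export
glance.casa_or_null <- function(x, ...) {
  tibble(mean_or = mean(x$ratios), sd_or = sd(x$ratios),
         p95_threshold = x$threshold, n_resamples = length(x$ratios),
         subset_size = x$subset_size, n_recordings = x$n_recordings,
         n_redraws = x$n_redraws)
}

#' Tidiers for directional-bias tests
#'
#' `glance()` condenses a [chemotaxis_test()] result to one row: counts,
#' chemotaxis indices, O.R., threshold and verdict. `tidy()` returns the
#' per-sample counts in long form.
#'
#' @param x A `casa_chemotaxis` object.
#' @param ... Unused.
#' @return A tibble.
#' @export
glance.casa_chemotaxis <- function(x, ...) {
  tibble(n_plus_test = x$test_counts$n_plus,
         n_minus_test = x$test_counts$n_minus,
         n_plus_control = x$control_counts$n_plus,
         n_minus_control = x$control_counts$n_minus,
         ch_index_test = x$ch_index_test,
         ch_index_control = x$ch_index_control,
         or = x$or, p95_threshold = x$null$threshold,
         chemotactic = x$chemotactic)
}

#' @rdname glance.casa_chemotaxis
#' @export
tidy.casa_chemotaxis <- function(x, ...) {
  dplyr::bind_rows(
    dplyr::mutate(x$test_counts, sample = "test",
                  ch_index = x$ch_index_test),
    dplyr::mutate(x$control_counts, sample = "control",
                  ch_index = x$ch_index_control))
}

#' Tidiers for viability results
#'
#' `tidy()` returns the per-cell table (centroid, area, label);
#' `glance()` the counts and percentages.
#'
#' @param x A `casa_viability` object from [classify_viability()].
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.casa_viability <- function(x, ...) x$cells

#' @rdname tidy.casa_viability
#' @export
glance.casa_viability <- function(x, ...) {
  tibble(n_viable = x$n_viable, n_nonviable = x$n_nonviable,
         pct_viable = x$pct_viable, pct_nonviable = x$pct_nonviable)
}
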