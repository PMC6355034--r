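test_that("directionality angles relative to the gradient", {
  # straight swim along the gradient: all psi = 0
  tr <- straight_track(10)
  expect_true(all(directionality_angles(tr, 1, 0)$psi == 0))

  # swim perpendicular to the gradient: psi = +/- 90
  up <- tibble::tibble(track_id = 1, frame = 0:9, x = 0, y = 0:9)
  expect_true(all(abs(directionality_angles(up, 1, 0)$psi) == 90))

  # rotating the gradient rotates psi
  expect_true(all(directionality_angles(tr, 1, 45)$psi == -45))

  # a path that pauses every other frame, delta = 2: half the angles,
  # none from zero-length displacements
  pause <- tibble::tibble(track_id = 1, frame = 0:5,
                          x = c(0, 0, 1, 1, 2, 2), y = 0)
  a2 <- directionality_angles(pause, 2, 0)
  expect_equal(nrow(a2), 4)          # the four t with nonzero p_t -> p_t+2
  a1 <- directionality_angles(pause, 1, 0)
  expect_equal(nrow(a1), 2)          # zero-length steps skipped
})

test_that("oriented counting honours gamma, closed bounds and options", {
  psi <- c(0, 10, 170, -170)
  expect_equal(count_oriented(psi, 30, 1),
               tibble::tibble(n_plus = 2L, n_minus = 2L))
  expect_equal(count_oriented(psi, 30, 2),
               tibble::tibble(n_plus = 2L, n_minus = 2L))
  # side angles are ignored under option 2
  expect_equal(count_oriented(c(50, -60), 30, 2),
               tibble::tibble(n_plus = 0L, n_minus = 0L))
  # the cone is closed: psi exactly +/- gamma counts as N+
  expect_equal(count_oriented(c(30, -30), 30, 1)$n_plus, 2L)
  # under option 1, N+ + N- equals the number of angles
  set.seed(11)
  psi <- runif(500, -180, 180)
  cnt <- count_oriented(psi, 30, 1)
  expect_equal(cnt$n_plus + cnt$n_minus, 500L)
})

test_that("ch-index arithmetic and undefined case", {
  expect_equal(ch_index(25, 75), 25)
  expect_equal(ch_index(7, 0), 100)
  expect_true(is.na(ch_index(0, 0)))
  expect_equal(ch_index(count_oriented(c(0, 50, 100), 30, 1)), 100 / 3)
})

test_that("ch-index is invariant to trajectory order and splitting", {
  p <- simulation_params(n_cells = 20, n_frames = 80)
  tr <- simulate_population(p, seed = 12)
  s <- analysis_settings()
  chi <- function(t) ch_index(count_oriented(directionality_angles(t),
                                             s$gamma, s$option))
  shuffled <- dplyr::arrange(tr, dplyr::desc(track_id), frame)
  expect_equal(chi(tr), chi(shuffled))
  half1 <- dplyr::filter(tr, track_id <= 10)
  half2 <- dplyr::filter(tr, track_id > 10)
  c1 <- count_oriented(directionality_angles(half1), s$gamma, s$option)
  c2 <- count_oriented(directionality_angles(half2), s$gamma, s$option)
  expect_equal(chi(tr), ch_index(c1$n_plus + c2$n_plus,
                                 c1$n_minus + c2$n_minus))
})

test_that("odds ratio arithmetic and reciprocity", {
  a <- list(n_plus = 30, n_minus = 10)
  b <- list(n_plus = 10, n_minus = 30)
  expect_equal(or_ratio(a, a), 1)
  expect_equal(or_ratio(a, b), 9)
  expect_equal(or_ratio(a, b) * or_ratio(b, a), 1)
  expect_true(is.na(or_ratio(a, list(n_plus = 0, n_minus = 5))))
})

test_that("bootstrap null: degenerate pool, determinism, structure", {
  s <- analysis_settings(n_resamples = 50)
  # a pool of identical trajectories: every ratio is exactly 1
  one <- tibble::tibble(track_id = 1L, frame = 0:19,
                        x = cumsum(rep(c(1, 0), 10)),
                        y = cumsum(rep(c(0, 1), 10)))
  pool <- dplyr::bind_rows(
    lapply(1:4, function(i) dplyr::mutate(one, track_id = i)))
  null <- bootstrap_or_null(pool, s, subset_size = 2, seed = 13)
  expect_true(all(null$ratios == 1))
  expect_equal(null$threshold, 1)

  # same seed, same distribution; different seed, different draws
  p <- simulation_params(n_cells = 30, n_frames = 60)
  ctl <- simulate_population(p, seed = 14)
  n1 <- bootstrap_or_null(ctl, s, n_resamples = 30, subset_size = 10,
                          seed = 15)
  n2 <- bootstrap_or_null(ctl, s, n_resamples = 30, subset_size = 10,
                          seed = 15)
  expect_identical(n1$ratios, n2$ratios)
  expect_equal(length(n1$ratios), 30)
  expect_equal(n1$threshold, unname(quantile(n1$ratios, 0.95)))

  # default subset size: one recording's worth when a list is given
  nl <- bootstrap_or_null(list(ctl, simulate_population(p, seed = 16)),
                          s, n_resamples = 10, seed = 17)
  expect_equal(nl$subset_size, 30)
  expect_equal(nl$n_recordings, 2)
})

test_that("the chemotaxis call is strict at the threshold", {
  null <- structure(list(ratios = rep(1, 10), threshold = 1.2),
                    class = "casa_or_null")
  expect_false(is_chemotactic(1.2, null))
  expect_true(is_chemotactic(1.2000001, null))
})

test_that("attracted populations are detected, unbiased ones mostly not", {
  s <- analysis_settings()
  p0 <- simulation_params(n_cells = 60, n_frames = 150)
  ctl <- simulate_population(p0, seed = 18)
  null <- bootstrap_or_null(ctl, s, n_resamples = 400, subset_size = 30,
                            seed = 19)
  p1 <- simulation_params(beta = 1, responsiveness = 0.5, n_cells = 60,
                          n_frames = 150)
  tst <- simulate_population(p1, seed = 20)
  res <- chemotaxis_test(tst, ctl, s, null = null)
  expect_true(res$chemotactic)
  expect_gt(res$or, 2)
  # the attracted sample's ch-index sits well above the 16.67% baseline
  expect_gt(res$ch_index_test, 30)
  g <- glance(res)
  expect_true(g$chemotactic)
  expect_equal(g$or, res$or)
})

test_that("tidiers expose the null distribution and test verdicts", {
  p <- simulation_params(n_cells = 20, n_frames = 60)
  ctl <- simulate_population(p, seed = 21)
  null <- bootstrap_or_null(ctl, analysis_settings(), n_resamples = 25,
                            subset_size = 10, seed = 22)
  td <- tidy(null)
  expect_equal(nrow(td), 25)
  gl <- glance(null)
  expect_equal(gl$p95_threshold, null$threshold)
  expect_equal(gl$mean_or, mean(null$ratios))
})
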