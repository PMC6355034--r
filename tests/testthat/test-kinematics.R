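s1 <- analysis_settings(fps = 1, um_per_px = 1, min_vcl = 0.1,
                        window_size = 2, min_track_length = 1)

test_that("average path is an exact rectangular moving average", {
  q <- average_path(cbind(c(0, 1, 2), c(0, 1, 0)), w = 2)
  expect_equal(q, rbind(c(0.5, 0.5), c(1.5, 0.5)))

  pts <- cbind(rep(3, 10), rep(-2, 10))
  expect_equal(average_path(pts, 4), cbind(rep(3, 7), rep(-2, 7)))

  expect_error(average_path(pts, 1), "out of range")
  expect_error(average_path(pts, 10), "out of range")

  # smoothing a fast sinusoid shrinks its amplitude
  t <- 0:99
  wave <- cbind(t, 5 * sin(2 * pi * t / 4))
  q2 <- average_path(wave, 8) # window spans two periods
  expect_lt(max(abs(q2[, 2])), 0.5)
})

test_that("velocities match closed forms", {
  p <- cbind(0:9, 0)
  v <- path_velocities(p, average_path(p, 2), s1)
  expect_equal(c(v$vsl, v$vcl, v$vap), c(1, 1, 1))

  # square zig-zag: VCL exceeds VSL (triangle inequality)
  zz <- cbind(0:9, rep(c(0, 1), 5))
  vz <- path_velocities(zz, average_path(zz, 2), s1)
  expect_gt(vz$vcl, vz$vsl)

  # simulated straight swimmer: v0 = 3 px/frame at 60 fps, 0.5 um/px
  sim <- simulate_population(
    simulation_params(d_rot = 0, v0 = 3, n_cells = 1, n_frames = 50),
    seed = 1)
  s60 <- analysis_settings(fps = 60, um_per_px = 0.5, window_size = 5)
  pm <- cbind(sim$x, sim$y)
  v3 <- path_velocities(pm, average_path(pm, 5), s60)
  expect_equal(v3$vcl, 3 * 60 * 0.5, tolerance = 1e-10)
  expect_equal(v3$vsl, 90, tolerance = 1e-10)
})

test_that("ratio indices and their algebraic identity", {
  r <- velocity_ratios(5, 10, 8)
  expect_equal(c(r$lin, r$wob, r$str), c(50, 80, 62.5))
  expect_equal(velocity_ratios(3, 3, 3),
               tibble::tibble(lin = 100, wob = 100, str = 100))
  expect_true(is.na(velocity_ratios(5, 10, 0)$str))

  set.seed(4)
  for (i in 1:20) {
    v <- sort(runif(3, 1, 100)) # vsl <= vap <= vcl
    r <- velocity_ratios(v[1], v[3], v[2])
    expect_equal(r$lin, r$wob * r$str / 100)
  }
})

test_that("ALH is zero on a line and recovers zig-zag amplitude", {
  p <- cbind(0:19, 0)
  a <- track_alh(p, average_path(p, 4), s1)
  expect_equal(c(a$alh_mean, a$alh_max), c(0, 0))

  # triangle wave of half-amplitude a, window spanning one period; the
  # oracle recomputes the deviation series with dense-sampling distances
  # and its own peak scan
  alh_vs_oracle <- function(amp) {
    tri <- cbind(0:39, amp * rep(c(0, 1, 0, -1), 10))
    w <- 4
    q <- average_path(tri, w)
    a2 <- track_alh(tri, q, s1)
    dser <- vapply(seq_len(nrow(q) - 1), function(t) {
      qm <- (q[t, ] + q[t + 1, ]) / 2
      min(vapply(t:(t + w - 2), function(j) {
        point_seg_dist_sampled(qm, tri[j, ], tri[j + 1, ])
      }, numeric(1)))
    }, numeric(1))
    i <- 2:(length(dser) - 1)
    peaks <- dser[i][dser[i] > dser[i - 1] & dser[i] > dser[i + 1]]
    expect_equal(a2$alh_max, 2 * max(peaks), tolerance = 1e-3)
    expect_equal(a2$alh_mean, 2 * mean(peaks), tolerance = 1e-3)
    expect_gte(a2$alh_max, a2$alh_mean)
    a2
  }
  res <- vapply(c(1, 2, 4), function(a) alh_vs_oracle(a)$alh_max,
                numeric(1))
  # a wider beat envelope yields a larger ALH
  expect_true(all(diff(res) > 0))
})

test_that("BCF equals the brute-force segment-intersection oracle", {
  # straight path coincident with its average path: collinear, 0 crossings
  p <- cbind(0:19, 0)
  expect_equal(track_bcf(p, average_path(p, 4), s1), 0)

  # zig-zag crossing its mean axis between vertices (w = 3 keeps the
  # crossings interior to both segment families)
  zz <- cbind(0:19, rep(c(0.5, -0.5), 10))
  q <- average_path(zz, 3)
  k <- bcf_crossings_bruteforce(zz, q)
  expect_gt(k, 0)
  expect_equal(track_bcf(zz, q, s1), k * 1 / (20 - 3))

  # artificially disjoint paths never cross
  expect_equal(track_bcf(zz, q + 100, s1), 0)

  # with w = 2 every average-path vertex is the midpoint of a raw
  # segment, i.e. an exact touch: the convention counts none of them
  q2 <- average_path(zz, 2)
  expect_equal(track_bcf(zz, q2, s1), 0)
  expect_equal(bcf_crossings_bruteforce(zz, q2), 0)

  # oracle equivalence on noisy random walks (w > 2 keeps the geometry
  # generic: no structural touches, so both formulations must agree)
  set.seed(5)
  for (i in 1:8) {
    n <- sample(30:120, 1)
    rw <- apply(matrix(rnorm(2 * n), ncol = 2), 2, cumsum)
    w <- sample(3:8, 1)
    q <- average_path(rw, w)
    expect_equal(track_bcf(rw, q, s1) * (n - w) / 1,
                 bcf_crossings_bruteforce(rw, q))
  }
})

test_that("MAD measures turning: line, single turn, polygon", {
  expect_equal(track_mad(cbind(0:9, 0)), 0)

  # 4-point path with one 90 degree turn: turning angles {0, 90}
  p <- cbind(c(0, 1, 2, 2), c(0, 0, 0, 1))
  expect_equal(track_mad(p, 1), mean(c(0, 90)))

  # regular polygon: every exterior angle equals 360/k
  for (k in c(5, 8, 12)) {
    th <- 2 * pi * (0:(k + 1)) / k
    poly <- cbind(cos(th), sin(th))
    expect_equal(track_mad(poly, 1), 360 / k, tolerance = 1e-9)
  }

  # literal mode averages the raw direction angles
  east <- cbind(0:5, 0)
  expect_equal(track_mad(east, 1, mode = "literal"), 0)
  north_east <- cbind(0:5, 0:5)
  expect_equal(track_mad(north_east, 1, mode = "literal"), 45)
})

test_that("fractal dimension: straight lines give 1, crumpled walks more", {
  expect_equal(track_fd(cbind(0:10, 0)), 1)
  expect_equal(track_fd(cbind(0:10, 2 * (0:10))), 1)

  set.seed(6)
  for (i in 1:10) {
    n <- sample(20:200, 1)
    rw <- apply(matrix(rnorm(2 * n), ncol = 2), 2, cumsum)
    expect_gte(track_fd(rw), 1)
  }

  # dense diffusion-dominated walk stays near the origin: FD well above 1
  p <- simulation_params(d_rot = 3, v0 = 2, n_cells = 1, n_frames = 2000)
  tr <- simulate_population(p, seed = 7)
  expect_gt(track_fd(cbind(tr$x, tr$y)), 1.5)
})

test_that("DNC is the VCL x ALH product", {
  tr <- simulate_population(
    simulation_params(d_rot = 0.5, n_cells = 3, n_frames = 80), seed = 8)
  kin <- measure_kinematics(tr, analysis_settings(min_track_length = 1))
  expect_equal(kin$dnc, kin$vcl * kin$alh_mean)
})

test_that("motility classification uses strict thresholds and net motion", {
  s <- analysis_settings(min_vcl = 10, str_threshold = 80,
                         vap_threshold = 20)
  # stationary cell: not motile regardless of VCL
  loop <- cbind(c(0, 5, 5, 0, 0), c(0, 0, 5, 5, 0))
  expect_false(classify_motility(loop, vcl = 50, vap = 40, str = 90,
                                 s)$motile)
  cl <- classify_motility(cbind(0:4, 0), vcl = 50, vap = 40, str = 90, s)
  expect_true(cl$motile && cl$progressive)
  # VCL exactly at the threshold is not motile (strict inequality)
  expect_false(classify_motility(cbind(0:4, 0), vcl = 10, vap = 40,
                                 str = 90, s)$motile)
  # progressive needs both STR and VAP above their cut-offs
  expect_false(classify_motility(cbind(0:4, 0), vcl = 50, vap = 15,
                                 str = 90, s)$progressive)
})

test_that("whole-table kinematics: invariants over random walks", {
  set.seed(9)
  n_tracks <- 40
  tracks <- purrr::map_dfr(seq_len(n_tracks), function(id) {
    n <- sample(20:60, 1)
    tibble::tibble(track_id = id, frame = 0:(n - 1),
                   x = cumsum(rnorm(n)), y = cumsum(rnorm(n)))
  })
  s <- analysis_settings(min_track_length = 1, window_size = 5)
  kin <- measure_kinematics(tracks, s)
  expect_equal(nrow(kin), n_tracks)
  expect_true(all(kin$vsl <= kin$vcl + 1e-9))
  expect_true(all(kin$vap <= kin$vcl + 1e-9, na.rm = TRUE))
  ok <- !is.na(kin$lin) & !is.na(kin$wob) & !is.na(kin$str)
  expect_true(all(abs(kin$lin - kin$wob * kin$str / 100)[ok] < 1e-9))
  expect_true(all(kin$fd >= 1, na.rm = TRUE))
  expect_true(all(kin$alh_max >= kin$alh_mean, na.rm = TRUE))
})

test_that("straight-line swimmer hits every closed form at once", {
  tr <- straight_track(50, step = 2, angle = pi / 7)
  s <- analysis_settings(fps = 10, um_per_px = 0.5, window_size = 5,
                         min_track_length = 1, min_vcl = 1)
  kin <- measure_kinematics(tr, s)
  expect_equal(kin$lin, 100)
  expect_equal(kin$wob, 100)
  expect_equal(kin$str, 100)
  expect_equal(kin$alh_mean, 0)
  expect_equal(kin$alh_max, 0)
  expect_equal(kin$bcf, 0)
  expect_equal(kin$mad, 0)
  expect_equal(kin$fd, 1)
  expect_equal(kin$vcl, 2 * 10 * 0.5)
  expect_true(kin$motile)
})

test_that("scaling px size and um/px together leaves um outputs fixed", {
  set.seed(10)
  n <- 60
  base <- tibble::tibble(track_id = 1L, frame = 0:(n - 1),
                         x = cumsum(rnorm(n, 1)), y = cumsum(rnorm(n)))
  c_ <- 3.7
  scaled <- dplyr::mutate(base, x = x * c_, y = y * c_)
  k1 <- measure_kinematics(base, analysis_settings(um_per_px = 1,
                                                   min_track_length = 1))
  k2 <- measure_kinematics(scaled, analysis_settings(um_per_px = 1 / c_,
                                                     min_track_length = 1))
  for (col in c("vsl", "vcl", "vap", "lin", "wob", "str", "alh_mean",
                "alh_max", "bcf", "mad", "dnc", "fd")) {
    expect_equal(k1[[col]], k2[[col]], tolerance = 1e-9, label = col)
  }
})

test_that("population summary averages motile tracks only", {
  tr <- dplyr::bind_rows(
    straight_track(30, step = 3, id = 1L),          # fast, motile
    straight_track(30, step = 0.01, id = 2L))       # too slow: non-motile
  s <- analysis_settings(fps = 10, min_vcl = 5, min_track_length = 1)
  kin <- measure_kinematics(tr, s)
  sm <- summarize_kinematics(kin)
  expect_equal(sm$n_tracks, 2)
  expect_equal(sm$n_motile, 1)
  expect_equal(sm$pct_motile, 50)
  expect_equal(sm$vcl, kin$vcl[kin$motile])
})
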