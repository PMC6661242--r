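test_that("an unambiguous mover forms one track with the right speed", {
  ev <- data.frame(frame = 1:10, x_um = 132 * (1:10), y_um = 500,
                   kind = "single")
  tr <- link_tracks(ev, frame_rate_hz = 10, max_link_distance_um = 500)
  expect_equal(length(unique(tr$tracks$track_id)), 1)
  expect_equal(nrow(tr$tracks), 10)
  expect_equal(unique(na.omit(tr$tracks$speed_um_s)), 1320)
})

test_that("two parallel movers never cross over", {
  ev <- rbind(
    data.frame(frame = rep(1:8, each = 1), x_um = 132 * (1:8), y_um = 1000),
    data.frame(frame = rep(1:8, each = 1), x_um = 132 * (1:8), y_um = 1000 + 5 * 132))
  ev$kind <- "single"
  tr <- link_tracks(ev, 10, max_link_distance_um = 400)
  expect_equal(length(unique(tr$tracks$track_id)), 2)
  for (id in unique(tr$tracks$track_id)) {
    p <- tr$tracks[tr$tracks$track_id == id, ]
    expect_equal(length(unique(p$y_um)), 1) # stays in its own lane
    expect_equal(nrow(p), 8)
  }
  # agrees with per-frame-pair exhaustive optimal assignment
  for (fr in 1:7) {
    a <- ev[ev$frame == fr, ]; b <- ev[ev$frame == fr + 1, ]
    opt <- optimal_assignment_oracle(a, b, 400)
    expect_equal(opt$n_pairs, 2)
  }
})

test_that("no link ever exceeds the gate; fast movers fragment", {
  ev <- data.frame(frame = 1:6, x_um = 2000 * (1:6), y_um = 300, kind = "single")
  tr <- link_tracks(ev, 10, max_link_distance_um = 1000)
  expect_equal(length(unique(tr$tracks$track_id)), 6) # all births
  expect_true(all(is.na(tr$tracks$speed_um_s)))
})

test_that("track count equals birth count and events keep one identity", {
  set.seed(41)
  ev <- data.frame(frame = rep(1:6, each = 5),
                   x_um = runif(30, 0, 20000), y_um = runif(30, 0, 10000),
                   kind = "single")
  tr <- link_tracks(ev, 10)
  expect_equal(nrow(tr$tracks), nrow(ev))
  expect_true(all(tr$tracks$frame[!is.na(tr$tracks$speed_um_s)] > 1 |
                  duplicated(tr$tracks$track_id)))
  # frames strictly increasing within each track
  for (id in unique(tr$tracks$track_id)) {
    p <- tr$tracks[tr$tracks$track_id == id, ]
    if (nrow(p) > 1) expect_true(all(diff(p$frame) == 1))
  }
})

test_that("density maps count distinct tracks once per subpixel", {
  ev <- data.frame(frame = 1:6, x_um = seq(200, 2200, length.out = 6),
                   y_um = 570, kind = "single")
  tr <- link_tracks(ev, 10)
  dm <- render_density_map(tr, c(20, 20), 132, 3)
  touched <- which(dm$values > 0, arr.ind = TRUE)
  expect_equal(length(unique(touched[, 1])), 1) # one-subpixel-wide line
  expect_true(all(dm$values[touched] == 1))
  # two coincident tracks double the count on the same line
  two <- rbind(transform(tr$tracks, track_id = 1L),
               transform(tr$tracks, track_id = 2L))
  dm2 <- render_density_map(two, c(20, 20), 132, 3)
  expect_true(all(dm2$values[touched] == 2))
  expect_equal(sum(dm2$values), 2 * sum(dm$values))
  # density mass conservation against an independent fine rasterization
  cell <- 44
  mass_oracle <- sum(vapply(split(seq_len(nrow(tr$tracks)), tr$tracks$track_id),
    function(ii) {
      p <- tr$tracks[ii, ]
      if (nrow(p) < 2) return(0)
      cells <- unique(paste(
        pmin(pmax(ceiling(approx(seq_len(nrow(p)), p$x_um, n = 4000)$y / cell), 1), 60),
        pmin(pmax(ceiling(approx(seq_len(nrow(p)), p$y_um, n = 4000)$y / cell), 1), 60)))
      length(cells)
    }, numeric(1)))
  expect_equal(sum(dm$values), mass_oracle)
})

test_that("velocity maps average track speeds per subpixel", {
  mk <- function(speed_um_frame, y) {
    data.frame(frame = 1:6, x_um = 200 + speed_um_frame * (0:5), y_um = y,
               kind = "single")
  }
  ev <- mk(100, 570) # 1 mm/s at 10 Hz
  tr <- link_tracks(ev, 10)
  vm <- render_velocity_map(tr, c(20, 20), 132, 3)
  expect_equal(unique(vm$values[vm$values > 0]), 1000)
  # coincident 1 and 3 mm/s tracks average to 2 mm/s
  two <- rbind(
    data.frame(track_id = 1L, frame = 1:6, x_um = 200 + 100 * (0:5), y_um = 570,
               speed_um_s = c(NA, rep(1000, 5))),
    data.frame(track_id = 2L, frame = 1:6, x_um = 200 + 100 * (0:5), y_um = 570,
               speed_um_s = c(NA, rep(3000, 5))))
  vm2 <- render_velocity_map(two, c(20, 20), 132, 3)
  dm2 <- render_density_map(two, c(20, 20), 132, 3)
  both <- dm2$values == 2
  expect_gt(sum(both), 0)
  expect_equal(unique(vm2$values[both]), 2000)
  # velocity defined exactly on the density support
  expect_identical(vm2$values > 0, dm2$values > 0)
})

test_that("rendered track speeds reflect the simulator's Poiseuille speeds", {
  dp <- 20; mu <- 3.5e-3; r <- 60; len <- 2000
  net <- solve_flow(straight_tube_network(r, len), dp, mu)
  v_true <- r^2 * dp / (8 * mu * len)
  gt <- advect_particles(net, 1, 3, 10, seed = 44)
  ev <- data.frame(frame = gt$frame, x_um = gt$x_um, y_um = gt$y_um,
                   kind = "single")
  tr <- link_tracks(ev, 10, max_link_distance_um = 1.5 * v_true / 10)
  vm <- render_velocity_map(tr, c(6, ceiling(len / 132)), 132, 3)
  mid <- vm$values[, 10:30]
  expect_lt(abs(mean(mid[mid > 0]) - v_true) / v_true, 0.15)
})

test_that("merged events record split and merge annotations", {
  ev <- rbind(
    data.frame(frame = 1, x_um = c(1000, 1400), y_um = 500, kind = "single"),
    data.frame(frame = 2, x_um = 1200, y_um = 500, kind = "merged"),
    data.frame(frame = 3, x_um = c(1000, 1400), y_um = 500, kind = "single"))
  tr <- link_tracks(ev, 10, max_link_distance_um = 300)
  expect_gte(nrow(tr$links), 2)
  expect_true("merge" %in% tr$links$type)
  expect_true("split" %in% tr$links$type)
})

test_that("FWHM measurements match the ridge geometry", {
  # ideal one-subpixel line
  v <- matrix(0, 60, 60); v[30, ] <- 1
  m <- structure(list(values = v, pixel_pitch_um = 44, kind = "density",
                      subdivision = 3), class = "sr_map")
  w <- measure_fwhm(m, c(30 * 44, 27.5 * 44), c(30 * 44, 31.5 * 44))
  expect_equal(w, 44, tolerance = 0.1)
  # Gaussian ridge of known sigma
  sig <- 5.5
  g <- matrix(0, 90, 90)
  for (i in 1:90) g[i, ] <- exp(-((i - 45)^2) / (2 * sig^2))
  mg <- structure(list(values = g, pixel_pitch_um = 44, kind = "density",
                       subdivision = 3), class = "sr_map")
  wg <- measure_fwhm(mg, c(45 * 44, 10 * 44), c(45 * 44, 80 * 44))
  expect_equal(wg, 2.355 * sig * 44, tolerance = 0.05 * 2.355 * sig * 44)
  # fully zero profile errors out
  expect_error(measure_fwhm(m, c(10 * 44, 1 * 44), c(12 * 44, 1 * 44)),
               "measurement error")
})
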