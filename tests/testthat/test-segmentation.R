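seg_fixture <- function(area_px = 12, peak = 0.6, noise = 0, seed = 1) {
  app <- fixed_appearance(area_px, peak = peak)
  pos <- data.frame(x_um = 20.3 * 132, y_um = 14.6 * 132)
  f <- render_frame(pos, app, shape = c(30, 40), noise_sigma = noise, seed = seed)
  ppi <- particle_probability_image(f, haar_feature_image(f), 0.1)
  sd <- detect_seeds(f, ppi)
  list(frame = f, seeds = sd$seeds, regions = sd$regions,
       smoothed = sd$smoothed, pos = pos)
}

test_that("the inverted-Gaussian watershed recovers the above-floor area", {
  fx <- seg_fixture(12)
  lab <- watershed_segment(fx$frame, fx$seeds, fx$regions, "inverted_gaussian",
                           smoothed = fx$smoothed, floor = 0.1)
  expect_lte(abs(sum(lab == 1) - 12), 2.0001)
})

test_that("the gradient relief shrinks the segmented region", {
  for (area in c(10, 16, 24)) {
    fx <- seg_fixture(area)
    ig <- watershed_segment(fx$frame, fx$seeds, fx$regions, "inverted_gaussian",
                            smoothed = fx$smoothed, floor = 0.1)
    gr <- watershed_segment(fx$frame, fx$seeds, fx$regions, "gradient",
                            smoothed = fx$smoothed, floor = 0.1)
    expect_lt(sum(gr == 1), sum(ig == 1))
  }
})

test_that("two seeds partition a merged blob without overlap", {
  app <- rbind(fixed_appearance(12, peak = 0.8), fixed_appearance(12, peak = 0.7))
  pos <- data.frame(x_um = c(2000, 2450), y_um = c(1980, 1980))
  f <- render_frame(pos, app, shape = c(30, 40), noise_sigma = 0)
  ppi <- particle_probability_image(f, haar_feature_image(f), 0.1)
  sd <- detect_seeds(f, ppi, detection_params(gaussian_sigma = 0.8))
  expect_equal(nrow(sd$seeds), 2)
  lab <- watershed_segment(f, sd$seeds, sd$regions, "inverted_gaussian",
                           smoothed = sd$smoothed, floor = 0.1)
  # disjoint by construction of a label image; each seed keeps its own label
  expect_equal(lab[sd$seeds$row[1], sd$seeds$col[1]], 1L)
  expect_equal(lab[sd$seeds$row[2], sd$seeds$col[2]], 2L)
  expect_gt(sum(lab == 1), 0)
  expect_gt(sum(lab == 2), 0)
})

test_that("seeds outside the frame violate the contract", {
  fx <- seg_fixture()
  bad <- data.frame(row = -1, col = 5)
  expect_error(watershed_segment(fx$frame, bad, fx$regions), "contract violation")
})

test_that("size and intensity filters follow the stated semantics", {
  labels <- matrix(0L, 20, 30)
  labels[2:3, 2:3] <- 1L          # 4 px: below minimum
  labels[8:11, 5:7] <- 2L         # 12 px: single
  labels[14:18, 12:19] <- 3L      # 40 px: merged-size
  frame <- matrix(0, 20, 30)
  frame[labels > 0] <- 0.5
  p_single <- detection_params(mean_echo_intensity = 0.1, max_echo_area = 20)
  ev_s <- filter_regions(labels, frame, p_single)
  expect_equal(sort(ev_s$region), 2L)
  expect_equal(ev_s$kind, "single")
  p_merged <- detection_params(mean_echo_intensity = 0.1)
  ev_m <- filter_regions(labels, frame, p_merged)
  expect_equal(sort(ev_m$region), c(2L, 3L))
  expect_equal(ev_m$kind[ev_m$region == 3L], "merged")
  # dim region removed by the mean-intensity classifier
  frame[labels == 2L] <- 0.05
  ev_d <- filter_regions(labels, frame, p_merged)
  expect_false(2L %in% ev_d$region)
})

test_that("the centroid of a symmetric echo at a pixel center is exact", {
  app <- fixed_appearance(12, ratio = 1)
  pos <- data.frame(x_um = px_center_x(20, 132), y_um = px_center_y(15, 132))
  f <- render_frame(pos, app, shape = c(30, 40), noise_sigma = 0)
  idx <- which(f > 1e-6)
  px <- data.frame(row = (idx - 1) %% 30 + 1, col = (idx - 1) %/% 30 + 1)
  cen <- localize(px, f[idx])
  expect_equal(unname(cen[1]), pos$x_um, tolerance = 1e-9)
  expect_equal(unname(cen[2]), pos$y_um, tolerance = 1e-9)
})

test_that("a two-pixel weighted centroid lands at the hand-computed point", {
  px <- data.frame(row = c(5, 5), col = c(10, 11))
  cen <- localize(px, c(1, 3), 132)
  expect_equal(unname(cen[1]), px_center_x(10, 132) + 0.75 * 132)
  expect_equal(unname(cen[2]), px_center_y(5, 132))
  expect_error(localize(px, c(0, 0)), "degenerate")
})

test_that("localization is translation-equivariant under integer shifts", {
  app <- fixed_appearance(14, peak = 0.7)
  base <- data.frame(x_um = 12.37 * 132, y_um = 9.81 * 132)
  ev0 <- detect_events(render_frame(base, app, c(40, 50), noise_sigma = 0),
                       noise_sigma = 0.1)
  shifted <- data.frame(x_um = base$x_um + 7 * 132, y_um = base$y_um + 11 * 132)
  ev1 <- detect_events(render_frame(shifted, app, c(40, 50), noise_sigma = 0),
                       noise_sigma = 0.1)
  expect_equal(ev1$x_um - ev0$x_um, 7 * 132, tolerance = 1e-9)
  expect_equal(ev1$y_um - ev0$y_um, 11 * 132, tolerance = 1e-9)
})

test_that("noiseless sub-pixel localization error is below a fifth of a pixel", {
  app <- sample_echo_appearance(200, seed = 31)
  set.seed(32)
  devs <- vapply(seq_len(nrow(app)), function(i) {
    pos <- data.frame(x_um = (12 + runif(1, -0.5, 0.5)) * 132,
                      y_um = (12 + runif(1, -0.5, 0.5)) * 132)
    f <- render_frame(pos, app[i, ], shape = c(24, 24), noise_sigma = 0)
    ev <- detect_events(f, noise_sigma = 0.1)
    if (nrow(ev) == 0) return(NA_real_) # the faintest, smallest echoes can
    sqrt((ev$x_um[1] - pos$x_um)^2 + (ev$y_um[1] - pos$y_um)^2) # fall under
  }, numeric(1))                                # the 5 px size classifier
  expect_gte(mean(!is.na(devs)), 0.95)
  expect_lt(compute_rmse(devs[!is.na(devs)]), 132 / 5)
})

test_that("a merged 59 um pair localizes onto the tube axis", {
  app <- rbind(fixed_appearance(10, peak = 0.7, ratio = 1),
               fixed_appearance(10, peak = 0.7, ratio = 1))
  axis_y <- 14.5 * 132
  pos <- data.frame(x_um = c(2000, 2000), y_um = axis_y + c(-29.5, 29.5))
  f <- render_frame(pos, app, shape = c(30, 40), noise_sigma = 0)
  ev <- detect_events(f, noise_sigma = 0.1)
  expect_equal(nrow(ev), 1)
  expect_lt(abs(ev$y_um - axis_y), 40)
})
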