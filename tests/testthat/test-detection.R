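test_that("a flat frame yields an identically zero feature image", {
  f <- matrix(0.4, 50, 60)
  feat <- haar_feature_image(f)
  expect_true(all(feat == 0))
})

test_that("the feature maximum of a noiseless echo sits on its peak", {
  set.seed(4)
  for (rep in 1:6) {
    app <- sample_echo_appearance(1)
    pos <- data.frame(x_um = runif(1, 18, 22) * 132, y_um = runif(1, 13, 17) * 132)
    f <- render_frame(pos, app, shape = c(30, 40), noise_sigma = 0)
    feat <- haar_feature_image(f)
    pk_f <- arrayInd(which.max(feat), dim(f))
    pk_i <- arrayInd(which.max(f), dim(f))
    expect_lte(max(abs(pk_f - pk_i)), 1)
  }
})

test_that("the selected kernel scale grows with the echo footprint", {
  peak_scale <- function(area) {
    app <- fixed_appearance(area, peak = 0.8)
    pos <- data.frame(x_um = 25 * 132, y_um = 20 * 132)
    f <- render_frame(pos, app, shape = c(40, 50), noise_sigma = 0)
    resp <- vapply(c(1, 2, 3), function(h) {
      fi <- haar_feature_image(f, h)
      fi[20, 25] * attr(fi, "max_response")
    }, numeric(1))
    which.max(resp)
  }
  s <- vapply(c(8, 20, 45, 80), peak_scale, numeric(1))
  expect_true(all(diff(s) >= 0)) # monotone scale selection
  expect_gt(s[4], s[1])          # large echoes pick a larger kernel
})

test_that("kernel scales larger than the frame are rejected", {
  expect_error(haar_feature_image(matrix(0, 10, 10), haar_scales = 5),
               "configuration error")
})

test_that("pure-noise significance rate stays within the calibrated bound", {
  set.seed(16)
  sigma <- 0.1
  hits <- 0; total <- 0
  for (i in 1:25) {
    f <- matrix(rnorm(150 * 200, 0, sigma), 150, 200)
    feat <- haar_feature_image(f)
    ppi <- particle_probability_image(f, feat, sigma)
    sig <- attr(ppi, "components") > 0
    interior <- sig[13:138, 13:188]
    hits <- hits + sum(interior); total <- total + length(interior)
  }
  nominal <- ulm2d:::haar_nominal_tail(sigma, sigma, attr(feat, "kernel_l2"))
  expect_lte(hits / total, 1.5 * nominal)
  expect_gte(hits / total, nominal / 20)
})

test_that("the nonlocal-means pre-filter denoises without erasing echoes", {
  app <- fixed_appearance(14, peak = 0.9)
  pos <- data.frame(x_um = 20 * 132, y_um = 15 * 132)
  set.seed(71)
  clean <- render_frame(pos, app, shape = c(30, 40), noise_sigma = 0)
  noisy <- render_frame(pos, app, shape = c(30, 40), noise_sigma = 0.1, seed = 72)
  den <- nlm_filter(noisy, 0.1)
  bg <- clean < 1e-3
  expect_lt(stats::sd(den[bg]), 0.5 * stats::sd(noisy[bg])) # noise suppressed
  expect_gt(den[15, 20], 0.9 * noisy[15, 20])               # echo preserved
  expect_identical(nlm_filter(noisy, 0.1), den)             # deterministic
  ev <- detect_events(noisy, noise_sigma = 0.1, nlm = TRUE)
  expect_equal(nrow(ev), 1)
  expect_lt(abs(ev$x_um - pos$x_um), 66)
})

test_that("a bright compact echo has high interior particle probability", {
  app <- fixed_appearance(12, peak = 0.9)
  pos <- data.frame(x_um = 20 * 132, y_um = 15 * 132)
  f <- render_frame(pos, app, shape = c(30, 40), noise_sigma = 0)
  feat <- haar_feature_image(f)
  ppi <- particle_probability_image(f, feat, 0.1)
  expect_gte(ppi[15, 20], 0.5)
  expect_true(all(ppi >= 0 & ppi <= 1))
  expect_true(all(ppi[attr(ppi, "components") == 0] == 0))
})

test_that("well-separated echoes seed one point each; near pairs merge", {
  app2 <- rbind(fixed_appearance(10, peak = 0.8), fixed_appearance(10, peak = 0.7))
  # two isolated echoes -> exactly 2 seeds
  pos <- data.frame(x_um = c(10, 30) * 132, y_um = c(15, 15) * 132)
  f <- render_frame(pos, app2, shape = c(30, 40), noise_sigma = 0)
  sd <- detect_seeds(f, particle_probability_image(f, haar_feature_image(f), 0.1))
  expect_equal(nrow(sd$seeds), 2)
  # a 59 um pair is a single merged event at any width
  pos59 <- data.frame(x_um = c(2000, 2059), y_um = c(1980, 1980))
  f59 <- render_frame(pos59, app2, shape = c(30, 40), noise_sigma = 0)
  sd59 <- detect_seeds(f59, particle_probability_image(f59, haar_feature_image(f59), 0.1))
  expect_equal(nrow(sd59$seeds), 1)
  # a ~420 um pair: small widths attempt the split, large widths keep one
  pos420 <- data.frame(x_um = c(2000, 2420), y_um = c(1980, 1980))
  f420 <- render_frame(pos420, app2, shape = c(30, 40), noise_sigma = 0)
  ppi420 <- particle_probability_image(f420, haar_feature_image(f420), 0.1)
  small <- detect_seeds(f420, ppi420,
                        detection_params(gaussian_sigma = 0.8, local_maxima_width = 3))
  large <- detect_seeds(f420, ppi420,
                        detection_params(gaussian_sigma = 2.5, local_maxima_width = 9))
  expect_equal(nrow(small$seeds), 2)
  expect_equal(nrow(large$seeds), 1)
})

test_that("raising the noise threshold never increases the seed count", {
  set.seed(19)
  app <- sample_echo_appearance(12)
  tf <- tile_frame(4, 3, 25, app, noise_sigma = 0.1, seed = 20)
  feat <- haar_feature_image(tf$frame)
  prev <- Inf
  for (thr in c(0.05, 0.1, 0.2, 0.4, 0.8)) {
    ppi <- particle_probability_image(tf$frame, feat, thr)
    n <- nrow(detect_seeds(tf$frame, ppi)$seeds)
    expect_lte(n, prev)
    prev <- n
  }
})

test_that("every seed lies inside an initial region", {
  set.seed(23)
  app <- sample_echo_appearance(12)
  tf <- tile_frame(4, 3, 25, app, noise_sigma = 0.1, seed = 24)
  ppi <- particle_probability_image(tf$frame, haar_feature_image(tf$frame), 0.1)
  sd <- detect_seeds(tf$frame, ppi)
  expect_true(all(sd$regions[cbind(sd$seeds$row, sd$seeds$col)] > 0))
  expect_setequal(unique(sd$seeds$region), setdiff(unique(as.integer(sd$regions)), 0))
})

test_that("noiseless single echoes are seeded exactly once each", {
  app <- sample_echo_appearance(1000, seed = 25)
  set.seed(26)
  counts <- vapply(seq_len(nrow(app)), function(i) {
    pos <- data.frame(x_um = (12 + runif(1, -0.5, 0.5)) * 132,
                      y_um = (12 + runif(1, -0.5, 0.5)) * 132)
    f <- render_frame(pos, app[i, ], shape = c(24, 24), noise_sigma = 0)
    ppi <- particle_probability_image(f, haar_feature_image(f), 0.1)
    nrow(detect_seeds(f, ppi)$seeds)
  }, numeric(1))
  expect_true(all(counts == 1))
})
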