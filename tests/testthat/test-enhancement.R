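test_that("underwater dark channel takes the patch minimum of G and B only", {
  expect_equal(underwater_dark_channel(const_img(9, 9, c(0.7, 0, 0)), 3L),
               matrix(0, 9, 9))
  expect_equal(underwater_dark_channel(const_img(9, 9, c(0.3, 1, 1)), 5L),
               matrix(1, 9, 9))
  set.seed(21)
  img <- array(runif(3 * 3 * 3), dim = c(3, 3, 3))
  img[2, 2, 2] <- 0.2
  img[, , 2:3] <- pmax(img[, , 2:3], 0.2)  # overall G/B minimum is exactly 0.2
  expect_equal(underwater_dark_channel(img, 3L), matrix(0.2, 3, 3))
  expect_error(underwater_dark_channel(img, 4L), "odd")
  expect_error(underwater_dark_channel(img, -3L), "odd|positive")
})

test_that("dark channel equals naive patch minimum on random images", {
  set.seed(22)
  img <- array(runif(20 * 16 * 3), dim = c(20, 16, 3))
  expect_equal(underwater_dark_channel(img, 7L),
               naive_min_filter(pmin(img[, , 2], img[, , 3]), 7L))
})

test_that("background light averages the brightest fraction per channel", {
  expect_equal(unclass(estimate_background_light(const_img(10, 10, c(0.3, 0.5, 0.7)))),
               c(R = 0.3, G = 0.5, B = 0.7), ignore_attr = TRUE)
  # 1000 pixels, one bright pixel, fraction 0.001 -> that pixel alone
  img <- const_img(25, 40, c(0.5, 0.5, 0.5))
  img[3, 7, 2] <- 0.9
  A <- estimate_background_light(img, top_fraction = 0.001)
  expect_equal(A[["G"]], 0.9)
  expect_equal(A[["R"]], 0.5)
  # fraction so small that ceil gives one pixel -> channel maximum
  set.seed(23)
  img2 <- array(runif(12 * 11 * 3), dim = c(12, 11, 3))
  A2 <- estimate_background_light(img2, top_fraction = 1e-9)
  expect_equal(unclass(A2), c(R = max(img2[, , 1]), G = max(img2[, , 2]),
                              B = max(img2[, , 3])), ignore_attr = TRUE)
  # sort-and-select oracle at an intermediate fraction
  k <- ceiling(0.01 * 12 * 11)
  expect_equal(A3 <- estimate_background_light(img2, 0.01)[["B"]],
               mean(sort(img2[, , 3], decreasing = TRUE)[1:k]))
})

test_that("attenuation ratios follow the linear scattering model", {
  m <- attenuation_ratios(c(R = 0.5, G = 0.5, B = 0.5))
  expect_equal(m$ratio_GR, 1.01497 / 0.92457, tolerance = 1e-4)
  expect_equal(m$ratio_BR, 1.11667 / 0.92457, tolerance = 1e-4)
  m2 <- attenuation_ratios(c(R = 0.2, G = 0.8, B = 0.5))
  expect_equal(m2$ratio_GR, (1.01497 / 0.92457) * 0.25, tolerance = 1e-4)
  m3 <- attenuation_ratios(c(R = 0.4, G = 0.4, B = 0.9),
                           wavelengths = c(R = 620, G = 620, B = 450))
  expect_equal(m3$ratio_GR, 1)
  expect_error(attenuation_ratios(c(R = 0, G = 0.5, B = 0.5)), "positive")
})

test_that("with equal background light, blue attenuates faster than green than red", {
  m <- attenuation_ratios(c(R = 0.6, G = 0.6, B = 0.6))
  expect_gt(m$ratio_BR, m$ratio_GR)
  expect_gt(m$ratio_GR, 1)
})

test_that("rough transmission matches the dark-channel estimate", {
  cfg <- enhancement_config()
  A <- c(R = 0.6, G = 0.7, B = 0.8)
  # I == A: saturated haze -> 1 - omega
  rt <- rough_transmission(const_img(20, 20, A), A, cfg)
  expect_equal(rt$t0G, matrix(0.05, 20, 20), tolerance = 1e-12)
  expect_equal(rt$t0B, matrix(0.05, 20, 20), tolerance = 1e-12)
  # I == 0: zero radiance -> 1
  rt0 <- rough_transmission(const_img(20, 20, c(0, 0, 0)), A, cfg)
  expect_equal(rt0$t0G, matrix(1, 20, 20))
  # patch minimum ratio 0.4 -> 0.62
  img <- const_img(20, 20, c(0.1, 0.7 * 0.4, 0.9))
  rt4 <- rough_transmission(img, A, cfg)
  expect_equal(rt4$t0G, matrix(1 - 0.95 * 0.4, 20, 20), tolerance = 1e-12)
})

test_that("rough transmission decreases as the dark channel grows", {
  cfg <- enhancement_config(patch_size = 3L)
  A <- c(R = 0.5, G = 0.8, B = 0.8)
  set.seed(24)
  base <- array(runif(15 * 15 * 3, 0, 0.5), dim = c(15, 15, 3))
  brighter <- base
  brighter[, , 2:3] <- brighter[, , 2:3] + 0.2
  t1 <- rough_transmission(base, A, cfg)
  t2 <- rough_transmission(brighter, A, cfg)
  expect_true(all(t2$t0G <= t1$t0G + 1e-12))
  expect_true(all(t2$t0B <= t1$t0B + 1e-12))
})

test_that("joint red transmission averages the power-law conversions", {
  m <- list(ratio_GR = 1.1, ratio_BR = 1.2)
  one <- matrix(1, 4, 4)
  expect_equal(joint_red_transmission(one, one, m), one)
  tG <- matrix(0.81, 4, 4); tB <- matrix(0.64, 4, 4)
  expect_equal(joint_red_transmission(tG, tB, m),
               matrix(0.5 * (0.81^(1 / 1.1) + 0.64^(1 / 1.2)), 4, 4),
               tolerance = 1e-12)
  munit <- list(ratio_GR = 1, ratio_BR = 1)
  tt <- matrix(0.37, 4, 4)
  expect_equal(joint_red_transmission(tt, tt, munit), tt)
  expect_error(joint_red_transmission(matrix(1, 2, 2), matrix(1, 3, 3), m), "shape")
})

test_that("amend_transmissions applies the exponent law exactly", {
  m <- attenuation_ratios(c(R = 0.5, G = 0.5, B = 0.5))
  one <- matrix(1, 3, 3)
  ts1 <- amend_transmissions(one, m)
  expect_equal(ts1$tG, one)
  expect_equal(ts1$tB, one)
  ts <- amend_transmissions(matrix(0.5, 3, 3), m)
  expect_equal(ts$tG, matrix(0.5^m$ratio_GR, 3, 3), tolerance = 1e-12)
  expect_equal(ts$tB, matrix(0.5^m$ratio_BR, 3, 3), tolerance = 1e-12)
  expect_equal(ts$tG, ts$tR^m$ratio_GR, tolerance = 1e-12)
  expect_equal(ts$tB, ts$tR^m$ratio_BR, tolerance = 1e-12)
  mu <- list(ratio_GR = 1, ratio_BR = 1)
  tsu <- amend_transmissions(matrix(0.3, 3, 3), mu)
  expect_equal(tsu$tG, tsu$tR)
})

test_that("guided refinement preserves constants, mean limit, and edges", {
  set.seed(25)
  guide <- array(runif(24 * 24 * 3), dim = c(24, 24, 3))
  cm <- matrix(0.4, 24, 24)
  expect_equal(refine_transmission(cm, guide, radius = 5), cm, tolerance = 1e-10)
  # eps -> Inf limit: twice box-averaged input
  p <- matrix(runif(24 * 24, 0.2, 0.9), 24, 24)
  g <- as_gray(guide)
  q <- guided_filter(p, g, radius = 4, eps = 1e9)
  n <- uwmosaic:::box_count(24, 24, 4L)
  expect_equal(q, uwmosaic:::box_sum(uwmosaic:::box_sum(p, 4L) / n, 4L) / n,
               tolerance = 1e-6)
  # edge preservation: step transition stays sharper than a Gaussian blur
  tmap <- cbind(matrix(0.2, 24, 12), matrix(0.8, 24, 12))
  gedge <- cbind(matrix(0.1, 24, 12), matrix(0.9, 24, 12))
  ref <- guided_filter(tmap, gedge, radius = 8, eps = 1e-4)
  blur <- uwmosaic:::gauss_blur(tmap, sigma = 8 / 3)
  grad_at_edge <- function(m) max(abs(m[, 13] - m[, 12]))
  expect_gt(grad_at_edge(ref), grad_at_edge(blur))
})

test_that("recover inverts the degradation model with the t0 clamp", {
  A <- c(R = 0.3, G = 0.5, B = 0.7)
  tset <- amend_transmissions(matrix(0.4, 8, 8), list(ratio_GR = 1.1, ratio_BR = 1.2))
  imgA <- const_img(8, 8, A)
  expect_equal(recover(imgA, tset, A), imgA, tolerance = 1e-12)
  set.seed(26)
  img <- array(runif(8 * 8 * 3), dim = c(8, 8, 3))
  tone <- amend_transmissions(matrix(1, 8, 8), list(ratio_GR = 1, ratio_BR = 1))
  expect_equal(recover(img, tone, A), img, tolerance = 1e-12)
  # (0.6 - 0.8)/0.1 + 0.8 = -1.2 -> clipped to 0
  imgc <- const_img(4, 4, c(0.6, 0.6, 0.6))
  Ac <- c(R = 0.8, G = 0.8, B = 0.8)
  tlow <- amend_transmissions(matrix(0.05, 4, 4), list(ratio_GR = 1, ratio_BR = 1))
  expect_equal(recover(imgc, tlow, Ac, t0 = 0.1), const_img(4, 4, c(0, 0, 0)))
})

test_that("degrade-then-recover with the true transmission and light is exact", {
  clean <- generate_seabed_texture(31, c(64, 64))
  depth <- generate_depth_map(32, c(64, 64))
  m <- attenuation_ratios(default_A)
  dg <- degrade(clean, depth, 1.0, m, default_A)
  # without the clamp binding (all t > t0), recovery is an algebraic inverse
  rec <- recover(dg$image, dg$transmission, default_A, t0 = 1e-9)
  expect_lt(max(abs(rec - clean)), 1e-9)
})

test_that("enhance is near-identity on undegraded input and deterministic", {
  clean <- generate_seabed_texture(33, c(96, 96))
  m <- attenuation_ratios(default_A)
  dg0 <- degrade(clean, matrix(0, 96, 96), 1.0, m, default_A)
  expect_equal(dg0$image, clean, tolerance = 1e-12)
  out <- enhance(dg0$image)
  expect_lt(mean(abs(out - clean)), 0.02)
  expect_identical(out, enhance(dg0$image))
})

test_that("the full pipeline moves a degraded image toward the clean scene", {
  clean <- generate_seabed_texture(34, c(128, 128))
  depth <- generate_depth_map(35, c(128, 128))
  m <- attenuation_ratios(default_A)
  dg <- degrade(clean, depth, 1.0, m, default_A)
  det <- enhance(dg$image, details = TRUE)
  rmse <- function(a, b) sqrt(mean((a - b)^2))
  expect_lt(rmse(det$image, clean), rmse(dg$image, clean))
  # at this small fixture size the guided-filter window is large relative to
  # the depth field, so the correlation bound is looser than at survey scale
  expect_gt(cor(as.vector(det$transmission$tR), as.vector(dg$transmission$tR)), 0.6)
})

test_that("enhancement config validates its parameters", {
  expect_error(enhancement_config(patch_size = 14), "odd")
  expect_error(enhancement_config(omega = 0), "omega")
  expect_error(enhancement_config(t0 = 1.2), "t0")
})
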