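test_that("matching an image with itself recovers the identity warp", {
  img <- generate_seabed_texture(41, c(96, 128))
  ms <- detect_and_match(img, img, seed = 1)
  expect_s3_class(ms, "match_set")
  H <- estimate_warp(ms, "similarity")$H
  expect_lt(max(abs(H - diag(3))), 1e-3)
})

test_that("an integer translation is recovered to sub-pixel accuracy", {
  scene <- generate_seabed_texture(42, c(96, 180))
  imgA <- scene[, 1:128, , drop = FALSE]
  imgB <- scene[, 31:158, , drop = FALSE]  # imgA translated by 30 columns
  ms <- detect_and_match(imgA, imgB, seed = 2)
  H <- estimate_warp(ms, "similarity")$H
  expect_lt(abs(H[1, 3] - 30), 0.5)
  expect_lt(abs(H[2, 3] - 0), 0.5)
  expect_lt(max(abs(H[1:2, 1:2] - diag(2))), 0.01)
})

test_that("structureless noise raises a registration failure", {
  set.seed(43)
  a <- array(runif(64 * 64 * 3), dim = c(64, 64, 3))
  b <- array(runif(64 * 64 * 3), dim = c(64, 64, 3))
  expect_error(detect_and_match(a, b, seed = 3, pair = "7-8"),
               class = "uwmosaic_registration_error")
})

test_that("estimate_warp recovers exact similarity parameters from clean matches", {
  s <- 1.2; th <- 10 * pi / 180; tx <- 5; ty <- 3
  a <- s * cos(th); b <- s * sin(th)
  set.seed(44)
  xB <- runif(25, 1, 100); yB <- runif(25, 1, 80)
  xA <- a * xB - b * yB + tx
  yA <- b * xB + a * yB + ty
  wp <- estimate_warp(data.frame(uA = yA, vA = xA, uB = yB, vB = xB), "similarity")
  expect_equal(wp$H[1, 1], a, tolerance = 1e-6)
  expect_equal(wp$H[2, 1], b, tolerance = 1e-6)
  expect_equal(wp$H[1, 3], tx, tolerance = 1e-6)
  expect_equal(wp$H[2, 3], ty, tolerance = 1e-6)
  expect_lt(wp$rms, 1e-9)
})

test_that("projective estimation rejects under-determined and degenerate input", {
  df3 <- data.frame(uA = c(1, 2, 3), vA = c(1, 5, 2),
                    uB = c(1, 2, 3), vB = c(1, 5, 2))
  expect_error(estimate_warp(df3, "projective"), "at least 4")
  # collinear-only correspondences
  xB <- seq(1, 40, length.out = 8); yB <- 2 * xB + 1
  dfc <- data.frame(uA = yB, vA = xB, uB = yB, vB = xB)
  expect_error(estimate_warp(dfc, "projective"),
               class = "uwmosaic_degenerate_error")
})

test_that("similarity least squares beats any rigid (no-scale) fit", {
  set.seed(45)
  for (i in 1:20) {
    xB <- runif(12, 0, 100); yB <- runif(12, 0, 100)
    s <- runif(1, 0.8, 1.3); th <- runif(1, -0.3, 0.3)
    xA <- s * cos(th) * xB - s * sin(th) * yB + runif(1, -5, 5) + rnorm(12, 0, 0.5)
    yA <- s * sin(th) * xB + s * cos(th) * yB + runif(1, -5, 5) + rnorm(12, 0, 0.5)
    wp <- estimate_warp(data.frame(uA = yA, vA = xA, uB = yB, vB = xB), "similarity")
    expect_lte(wp$rms, rigid_fit_residual(xB, yB, xA, yA) + 1e-9)
  }
})

test_that("warp_to_canvas preserves images under identity and integer translations", {
  img <- generate_seabed_texture(46, c(40, 50))
  layout <- list(height = 60L, width = 70L)
  w1 <- warp_to_canvas(img, planar_warp(diag(3)), layout)
  expect_equal(w1$image[1:40, 1:50, ], img, tolerance = 1e-12)
  expect_true(all(w1$mask[1:40, 1:50]))
  expect_false(any(w1$mask[41:60, ]))
  Ht <- matrix(c(1, 0, 0, 0, 1, 0, 15, 10, 1), 3, 3)
  w2 <- warp_to_canvas(img, planar_warp(Ht), layout)
  expect_equal(w2$image[11:50, 16:65, ], img, tolerance = 1e-12)
})

test_that("warped corners match the analytic projection of a homography", {
  img <- generate_seabed_texture(47, c(64, 64))
  H <- matrix(c(1.05, 0.02, 1e-4, -0.03, 0.98, -5e-5, 12, 8, 1), 3, 3)
  layout <- list(height = 120L, width = 120L)
  w <- warp_to_canvas(img, planar_warp(H, "projective"), layout)
  crn <- apply_warp(H, cbind(c(1, 64, 1, 64), c(1, 1, 64, 64)))
  rng_r <- range(which(rowSums(w$mask) > 0))
  rng_c <- range(which(colSums(w$mask) > 0))
  expect_lt(abs(rng_c[1] - min(crn[, 1])), 1.5)
  expect_lt(abs(rng_c[2] - max(crn[, 1])), 1.5)
  expect_lt(abs(rng_r[1] - min(crn[, 2])), 1.5)
  expect_lt(abs(rng_r[2] - max(crn[, 2])), 1.5)
})

test_that("overlap_region computes tight intersection boxes and flags empties", {
  mA <- matrix(FALSE, 20, 30); mA[3:15, 4:20] <- TRUE
  mB <- matrix(FALSE, 20, 30); mB[10:20, 15:28] <- TRUE
  ov <- overlap_region(mA, mB)
  expect_equal(ov$u, c(10, 15))
  expect_equal(ov$v, c(15, 20))
  expect_true(all(ov$both))
  ovf <- overlap_region(mA, mA)
  expect_equal(ovf$u, c(3, 15)); expect_equal(ovf$v, c(4, 20))
  mC <- matrix(FALSE, 20, 30); mC[18:20, 25:30] <- TRUE
  expect_error(overlap_region(mA, mC), class = "uwmosaic_empty_overlap")
})

test_that("chained pairwise warps agree with direct estimation on a drift-free sweep", {
  scene <- generate_seabed_texture(48, c(96, 260))
  crops <- lapply(c(1, 41, 81), function(x0) scene[, x0:(x0 + 127), , drop = FALSE])
  H12 <- estimate_warp(detect_and_match(crops[[1]], crops[[2]], seed = 5), "similarity")$H
  H23 <- estimate_warp(detect_and_match(crops[[2]], crops[[3]], seed = 6), "similarity")$H
  H13 <- estimate_warp(detect_and_match(crops[[1]], crops[[3]], seed = 7), "similarity")$H
  pts <- cbind(c(10, 60, 110, 64), c(10, 40, 80, 48))
  err <- sqrt(rowSums((apply_warp(H12 %*% H23, pts) - apply_warp(H13, pts))^2))
  expect_lt(mean(err), 0.5)
})
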