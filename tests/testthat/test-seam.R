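test_that("superpixel boundary masks are subsets that grow under dilation", {
  img <- generate_seabed_texture(51, c(80, 80))
  labs <- slic_segment(img, region_size = 20)
  expect_true(all(labs >= 1))
  bm <- uwmosaic:::label_boundaries(labs)
  cfg <- seam_config(slic_region_size = 20)
  mask <- superpixel_boundary_mask(img, img, cfg)
  expect_gt(sum(mask), sum(bm))      # dilation strictly grows the boundary set
  expect_lt(sum(mask), length(mask)) # and remains a strict subset of the overlap
})

test_that("a strong vertical edge puts its dilated boundary in the mask", {
  img <- array(0.15, dim = c(60, 60, 3))
  img[, 31:60, ] <- 0.85
  cfg <- seam_config(slic_region_size = 20)
  mask <- superpixel_boundary_mask(img, img, cfg)
  # the SLIC boundary tracks the edge between columns 30 and 31; the 5x5
  # dilation spreads it at least two columns to each side
  expect_true(all(mask[, 29:32]))
})

test_that("hue difference handles primaries and circularity", {
  red <- const_img(6, 6, c(1, 0, 0))
  green <- const_img(6, 6, c(0, 1, 0))
  blue <- const_img(6, 6, c(0, 0, 1))
  expect_equal(hue_difference(red, red), matrix(0, 6, 6))
  expect_equal(hue_difference(red, green), matrix(1 / 3, 6, 6), tolerance = 1e-12)
  expect_equal(hue_difference(red, blue), matrix(2 / 3, 6, 6), tolerance = 1e-12)
  expect_equal(hue_difference(red, blue, circular = TRUE), matrix(1 / 3, 6, 6),
               tolerance = 1e-12)
})

test_that("intensity difference is exact for constants and symmetric", {
  a <- const_img(8, 8, c(0.5, 0.5, 0.5))
  b <- const_img(8, 8, c(0.3, 0.3, 0.3))
  expect_equal(intensity_difference(a, a), matrix(0, 8, 8))
  expect_equal(intensity_difference(a, b), matrix(0.2, 8, 8), tolerance = 1e-12)
  expect_equal(intensity_difference(b, a), intensity_difference(a, b),
               tolerance = 1e-12)
})

test_that("gradient difference vanishes for constants and matches the Scharr step response", {
  a <- const_img(8, 8, c(0.4, 0.4, 0.4))
  b <- const_img(8, 8, c(0.9, 0.9, 0.9))
  expect_equal(gradient_difference(a, a), matrix(0, 8, 8))
  expect_equal(gradient_difference(a, b), matrix(0, 8, 8), tolerance = 1e-20)
  # unit step across columns in A, B flat: horizontal Scharr response at the
  # two columns adjacent to the step is 3 + 10 + 3 = 16, squared 256
  A <- array(0, dim = c(8, 8, 3)); A[, 5:8, ] <- 1
  B <- array(0, dim = c(8, 8, 3))
  es <- gradient_difference(A, B)
  expect_equal(es[4, 4], 256)
  expect_equal(es[4, 5], 256)
  expect_equal(es[4, 3], 0)
})

test_that("energy map reduces to its single terms and matches a naive recomputation", {
  img <- generate_seabed_texture(52, c(24, 20))
  img2 <- generate_seabed_texture(53, c(24, 20))
  valid <- matrix(TRUE, 24, 20)
  Eh <- energy_map(img, img2, seam_config(alpha_w = 1, beta_w = 0, gamma_w = 0))
  expect_equal(unname(Eh[3, 3]),
               uwmosaic:::norm01_over(hue_difference(img, img2), valid)[3, 3])
  # identical constant overlaps carry zero energy; for identical textured
  # overlaps the hue and gradient terms vanish (the neighborhood intensity
  # term measures local roughness and does not)
  cimg <- const_img(24, 20, c(0.2, 0.5, 0.6))
  expect_equal(energy_map(cimg, cimg, seam_config()), matrix(0, 24, 20),
               ignore_attr = TRUE)
  Eid <- energy_map(img, img, seam_config())
  expect_equal(max(attr(Eid, "Ehue")), 0)
  expect_equal(max(attr(Eid, "Estr")), 0)
  E <- energy_map(img, img2, seam_config(alpha_w = 0.2, beta_w = 0.5, gamma_w = 0.3))
  En <- naive_energy_map(img, img2, 0.2, 0.5, 0.3)
  expect_equal(E, En, tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("a constant offset added to both images leaves hue and gradient terms at zero", {
  img <- generate_seabed_texture(54, c(16, 16))
  shifted <- clamp01(img + 0.08)
  expect_equal(gradient_difference(img, img), gradient_difference(shifted, shifted))
  expect_equal(max(hue_difference(shifted, shifted)), 0)
})

test_that("dp_seam solves canonical grids with leftmost tie-breaks", {
  e1 <- matrix(0.3, 5, 1)
  s1 <- dp_seam(e1)
  expect_equal(s1$tr, rep(1L, 5))
  E <- matrix(c(1, 0, 1, 1, 0, 1, 1, 0, 1), 3, 3, byrow = TRUE)
  s <- dp_seam(E, 1L)
  expect_equal(s$tr, rep(2L, 3))
  expect_equal(s$cost, 0)
  Eq <- matrix(0.25, 6, 5)
  expect_equal(dp_seam(Eq)$tr, rep(1L, 6))
  expect_null(dp_seam(matrix(Inf, 4, 4)))
})

test_that("dp_seam cost equals exhaustive path enumeration on random grids", {
  set.seed(55)
  for (i in 1:25) {
    h <- sample(2:6, 1); w <- sample(2:7, 1)
    rv <- sample(1:2, 1)
    E <- matrix(runif(h * w), h, w)
    expect_equal(dp_seam(E, rv)$cost, brute_force_seam_cost(E, rv),
                 tolerance = 1e-12)
  }
})

test_that("the seam respects the connectivity bound", {
  set.seed(56)
  E <- matrix(runif(40 * 30), 40, 30)
  for (rv in 1:3) {
    s <- dp_seam(E, rv)
    expect_true(all(abs(diff(s$tr)) <= rv))
  }
})

test_that("seams stay inside the restriction when a feasible path exists", {
  set.seed(57)
  E <- matrix(runif(20 * 9, 0.1, 1), 20, 9)
  allowed <- matrix(FALSE, 20, 9)
  path <- pmin(pmax(cumsum(c(5, sample(-1:1, 19, TRUE))), 1), 9)
  for (u in 1:20) allowed[u, max(1, path[u] - 1):min(9, path[u] + 1)] <- TRUE
  E[!allowed] <- Inf
  s <- dp_seam(E, 1L)
  expect_true(all(allowed[cbind(1:20, s$tr)]))
})

test_that("increasing the gradient weight never lowers the seam's gradient cost", {
  img <- generate_seabed_texture(58, c(40, 24))
  img2 <- generate_seabed_texture(59, c(40, 24))
  es <- gradient_difference(img, img2)
  seam_grad <- function(g) {
    E <- energy_map(img, img2, seam_config(alpha_w = (1 - g) / 2,
                                           beta_w = (1 - g) / 2, gamma_w = g))
    s <- dp_seam(E)
    sum(es[cbind(seq_along(s$tr), s$tr)])
  }
  costs <- vapply(c(0.1, 0.5, 0.9), seam_grad, numeric(1))
  expect_true(all(diff(costs) <= 1e-9))
})

test_that("seam label masks split the overlap as counted per row", {
  s <- structure(list(tr = rep(1L, 5), rV = 1L, transposed = FALSE), class = "seam")
  m <- seam_to_label_mask(s, c(5, 8))
  expect_equal(unname(rowSums(m)), rep(1, 5))
  smid <- structure(list(tr = rep(4L, 6), rV = 1L, transposed = FALSE), class = "seam")
  mm <- seam_to_label_mask(smid, c(6, 8))
  expect_true(all(mm[, 1:4]) && !any(mm[, 5:8]))
  set.seed(60)
  tr <- pmin(pmax(cumsum(c(4, sample(-1:1, 9, TRUE))), 1), 7)
  sz <- structure(list(tr = tr, rV = 1L, transposed = FALSE), class = "seam")
  mz <- seam_to_label_mask(sz, c(10, 7))
  expect_equal(unname(rowSums(mz)), as.numeric(tr))
})

test_that("wide overlaps are seamed across their short direction", {
  ref <- generate_seabed_texture(61, c(30, 90))
  wrp <- generate_seabed_texture(62, c(30, 90))
  s <- suppressWarnings(find_seam(ref, wrp, cfg = seam_config(slic_region_size = 15)))
  expect_true(s$transposed)
  expect_length(s$tr, 90)
  lm <- seam_to_label_mask(s, c(30, 90))
  expect_equal(dim(lm), c(30L, 90L))
})
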