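# Core image representation and vectorized raster utilities.
#
# Images are plain numeric arrays H x W x 3 with values in [0, 1]; single
# channel maps are H x W matrices. Pixel (u, v) = (row, col), 1-based.
# Warps act on homogeneous (x, y, 1) coordinates with x = column, y = row.

#' Coerce to the package's RGB image representation
#'
#' An RGB image is a numeric `H x W x 3` array with values in `[0, 1]`,
#' indexed `(row, col, channel)` with channels ordered R, G, B. A matrix is
#' promoted to a gray triplet.
#'
#' @param x A numeric `H x W x 3` array or an `H x W` matrix.
#' @return A numeric `H x W x 3` array.
#' @export
as_rgb_image <- function(x) {
  if (is.matrix(x)) x <- array(rep(as.numeric(x), 3L), dim = c(dim(x), 3L))
  if (!(is.array(x) && length(dim(x)) == 3L && dim(x)[3L] == 3L))
    stop("expected an H x W x 3 array or an H x W matrix")
  storage.mode(x) <- "double"
  x
}

check_rgb_image <- function(img, what = "image") {
  if (!(is.array(img) && length(dim(img)) == 3L && dim(img)[3L] == 3L))
    stop(sprintf("%s must be an H x W x 3 numeric array", what))
  if (!is.numeric(img)) stop(sprintf("%s must be numeric", what))
  rng <- range(img)
  if (!all(is.finite(rng)) || rng[1L] < -1e-9 || rng[2L] > 1 + 1e-9)
    stop(sprintf("%s values must lie in [0, 1]", what))
  invisible(img)
}

clamp01 <- function(x) pmin(pmax(x, 0), 1)

#' Convert an RGB image to grayscale luminance
#'
#' @param img RGB image array.
#' @return `H x W` matrix of luminance (0.299 R + 0.587 G + 0.114 B).
#' @export
as_gray <- function(img) {
  if (is.matrix(img) || is.null(dim(img))) return(img)
  0.299 * img[, , 1L] + 0.587 * img[, , 2L] + 0.114 * img[, , 3L]
}

# Shifted copy with replicate (clamped-index) borders: out(u,v) = m(u+du, v+dv).
shift_mat <- function(m, du, dv) {
  h <- nrow(m); w <- ncol(m)
  ri <- pmin(pmax(seq_len(h) + du, 1L), h)
  ci <- pmin(pmax(seq_len(w) + dv, 1L), w)
  m[ri, ci, drop = FALSE]
}

# Separable running min/max over a k x k window, borders handled by window
# truncation (equivalently replicate padding).
filter_extreme <- function(m, k, fun) {
  if (k %% 2L != 1L || k < 1L) stop("window size must be a positive odd integer")
  r <- (k - 1L) %/% 2L
  out <- m
  if (r > 0L) for (o in seq_len(r)) out <- fun(out, shift_mat(m, -o, 0L), shift_mat(m, o, 0L))
  m2 <- out
  out <- m2
  if (r > 0L) for (o in seq_len(r)) out <- fun(out, shift_mat(m2, 0L, -o), shift_mat(m2, 0L, o))
  out
}

min_filter <- function(m, k) filter_extreme(m, k, pmin)
max_filter <- function(m, k) filter_extreme(m, k, pmax)

# Windowed sum over a (2r+1)^2 window with window truncation at borders,
# computed with cumulative sums (O(1) per pixel).
box_sum <- function(m, r) {
  h <- nrow(m); w <- ncol(m)
  cs <- apply(m, 2L, cumsum)
  if (h == 1L) cs <- matrix(cs, 1L, w)
  hi <- pmin(seq_len(h) + r, h)
  lo <- seq_len(h) - r - 1L
  a <- cs[hi, , drop = FALSE]
  pos <- which(lo >= 1L)
  if (length(pos)) a[pos, ] <- a[pos, , drop = FALSE] - cs[lo[pos], , drop = FALSE]
  cs2 <- t(apply(a, 1L, cumsum))
  if (w == 1L) cs2 <- matrix(cs2, h, 1L)
  hj <- pmin(seq_len(w) + r, w)
  lj <- seq_len(w) - r - 1L
  b <- cs2[, hj, drop = FALSE]
  pos <- which(lj >= 1L)
  if (length(pos)) b[, pos] <- b[, pos, drop = FALSE] - cs2[, lj[pos], drop = FALSE]
  b
}

box_count <- function(h, w, r) box_sum(matrix(1, h, w), r)

# Separable correlation with a 1-D kernel applied along rows then columns,
# replicate borders.
sep_filter <- function(m, k) {
  r <- (length(k) - 1L) %/% 2L
  out <- 0
  for (i in -r:r) out <- out + k[i + r + 1L] * shift_mat(m, i, 0L)
  m2 <- out
  out <- 0
  for (j in -r:r) out <- out + k[j + r + 1L] * shift_mat(m2, 0L, j)
  out
}

gauss_kernel <- function(sigma) {
  r <- max(1L, as.integer(ceiling(3 * sigma)))
  k <- stats::dnorm(-r:r, sd = sigma)
  k / sum(k)
}

gauss_blur <- function(m, sigma) sep_filter(m, gauss_kernel(sigma))

gauss_blur_rgb <- function(img, sigma) {
  k <- gauss_kernel(sigma)
  for (c in 1:3) img[, , c] <- sep_filter(img[, , c], k)
  img
}

# 3x3 correlation with replicate borders: out(u,v) = sum K[i+2,j+2] m(u+i,v+j).
conv3 <- function(m, K) {
  out <- 0
  for (i in -1:1) for (j in -1:1) {
    kk <- K[i + 2L, j + 2L]
    if (kk != 0) out <- out + kk * shift_mat(m, i, j)
  }
  out
}

#' RGB to HSV conversion
#'
#' @param img RGB image array.
#' @return `H x W x 3` array of hue, saturation, value, each in `[0, 1]`
#'   (hue as a fraction of the full circle).
#' @export
rgb_to_hsv_img <- function(img) {
  check_rgb_image(img)
  d <- dim(img)
  m <- grDevices::rgb2hsv(rbind(as.vector(img[, , 1L]),
                                as.vector(img[, , 2L]),
                                as.vector(img[, , 3L])), maxColorValue = 1)
  array(c(m[1L, ], m[2L, ], m[3L, ]), dim = d)
}

# Numeric HSV -> RGB on matrices (h as fraction of the circle).
hsv_to_rgb_img <- function(h, s, v) {
  hh <- (h %% 1) * 6
  i <- floor(hh)
  f <- hh - i
  p <- v * (1 - s); q <- v * (1 - s * f); tt <- v * (1 - s * (1 - f))
  r <- ifelse(i == 0, v, ifelse(i == 1, q, ifelse(i == 2, p, ifelse(i == 3, p, ifelse(i == 4, tt, v)))))
  g <- ifelse(i == 0, tt, ifelse(i == 1, v, ifelse(i == 2, v, ifelse(i == 3, q, p))))
  b <- ifelse(i <= 1, p, ifelse(i == 2, tt, ifelse(i == 3, v, ifelse(i == 4, v, q))))
  array(c(r, g, b), dim = c(dim(as.matrix(h)), 3L))
}

rgb_to_lab <- function(img) {
  n <- prod(dim(img)[1:2])
  m <- matrix(img, n, 3L)
  grDevices::convertColor(m, from = "sRGB", to = "Lab")
}

# Bilinear sampling of matrix m at real coordinates (x = col, y = row),
# clamped to the image domain.
bilinear_sample <- function(m, x, y) {
  h <- nrow(m); w <- ncol(m)
  x <- pmin(pmax(x, 1), w)
  y <- pmin(pmax(y, 1), h)
  x0 <- pmin(floor(x), w - 1L); y0 <- pmin(floor(y), h - 1L)
  if (w == 1L) x0 <- rep(1, length(x))
  if (h == 1L) y0 <- rep(1, length(y))
  fx <- x - x0; fy <- y - y0
  i00 <- (x0 - 1) * h + y0
  v00 <- m[i00]
  v10 <- if (w > 1L) m[i00 + h] else v00
  v01 <- if (h > 1L) m[i00 + 1] else v00
  v11 <- if (w > 1L && h > 1L) m[i00 + h + 1] else v00
  v00 * (1 - fx) * (1 - fy) + v10 * fx * (1 - fy) +
    v01 * (1 - fx) * fy + v11 * fx * fy
}

# Evaluate code with a temporarily fixed RNG state.
with_local_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(seed)
  code
}

#' Read an image file
#'
#' Reads PNG, JPEG or TIFF into the package's `H x W x 3` float
#' representation (values in `[0, 1]`); gray images are promoted, alpha
#' channels dropped.
#'
#' @param path File path.
#' @return RGB image array.
#' @export
load_image <- function(path) {
  x <- EBImage::readImage(path)
  a <- EBImage::imageData(x)
  if (length(dim(a)) == 2L) a <- array(rep(a, 3L), dim = c(dim(a), 3L))
  if (dim(a)[3L] > 3L) a <- a[, , 1:3, drop = FALSE]
  if (dim(a)[3L] == 1L) a <- array(rep(a, 3L), dim = c(dim(a)[1:2], 3L))
  clamp01(aperm(a, c(2L, 1L, 3L)))
}

#' Write an image file
#'
#' Writes an RGB image (or a single-channel map) to PNG, JPEG or TIFF,
#' chosen from the file extension. 16-bit output is used for TIFF.
#'
#' @param img RGB image array or `H x W` matrix.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
save_image <- function(img, path) {
  is_tiff <- grepl("\\.tiff?$", path, ignore.case = TRUE)
  if (is.matrix(img)) {
    obj <- EBImage::Image(t(clamp01(img)))
  } else {
    check_rgb_image(img)
    obj <- EBImage::Image(aperm(clamp01(img), c(2L, 1L, 3L)), colormode = "Color")
  }
  if (is_tiff) EBImage::writeImage(obj, path, bits.per.sample = 16L)
  else EBImage::writeImage(obj, path)
  invisible(path)
}
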