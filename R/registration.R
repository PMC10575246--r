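# Feature-based registration onto a common seabed projection plane.
#
# Keypoints come from a Harris corner detector on blurred luminance;
# descriptors are bias/gain-normalized patches sampled on an 8x8 grid, which
# makes matching invariant to the contrast compression that underwater
# degradation causes. Matches pass a 2-NN ratio test plus a cross-check and
# are screened by RANSAC before the final least-squares warp fit. Warps are
# global similarity (4 DOF) or projective (8 DOF) 3x3 matrices acting on
# homogeneous (x, y, 1) pixel coordinates, x = column.

scharr_u <- function() matrix(c(-3, -10, -3, 0, 0, 0, 3, 10, 3), 3L, 3L)
scharr_v <- function() t(scharr_u())

#' Construct a planar warp
#'
#' @param H Invertible 3x3 matrix acting on homogeneous `(x, y, 1)` pixel
#'   coordinates (x = column), normalized so `H[3,3] = 1`.
#' @param kind `"similarity"` or `"projective"`.
#' @param rms Optional reprojection RMS of the fit (pixels).
#' @return Object of class `planar_warp`.
#' @export
planar_warp <- function(H, kind = c("similarity", "projective"), rms = NA_real_) {
  kind <- match.arg(kind)
  H <- matrix(as.numeric(H), 3L, 3L)
  if (abs(det(H)) < 1e-12) stop("warp matrix must be invertible")
  H <- H / H[3L, 3L]
  structure(list(H = H, kind = kind, rms = rms), class = "planar_warp")
}

#' Apply a warp to points
#'
#' @param warp A `planar_warp` or bare 3x3 matrix.
#' @param pts Two-column matrix of `(x, y)` coordinates.
#' @return Two-column matrix of transformed coordinates.
#' @export
apply_warp <- function(warp, pts) {
  H <- if (inherits(warp, "planar_warp")) warp$H else warp
  pts <- matrix(as.numeric(pts), ncol = 2L)
  den <- H[3L, 1L] * pts[, 1L] + H[3L, 2L] * pts[, 2L] + H[3L, 3L]
  cbind((H[1L, 1L] * pts[, 1L] + H[1L, 2L] * pts[, 2L] + H[1L, 3L]) / den,
        (H[2L, 1L] * pts[, 1L] + H[2L, 2L] * pts[, 2L] + H[2L, 3L]) / den)
}

#' Detect Harris corners
#'
#' Harris cornerness on Scharr gradients of the blurred luminance, 3x3
#' non-maximum suppression, absolute response threshold, strongest points
#' first. The absolute threshold makes the detector sensitive to contrast:
#' attenuation-degraded images yield fewer corners than restored ones.
#'
#' @param img RGB image or luminance matrix.
#' @param max_points Keep at most this many corners.
#' @param threshold Absolute cornerness threshold.
#' @param min_points If fewer maxima pass the threshold, fall back to the
#'   strongest `min_points` positive maxima so low-contrast frames can still
#'   register.
#' @param sigma_d Derivative (pre-)smoothing scale, pixels.
#' @param sigma_i Integration scale for the structure tensor, pixels.
#' @param border Margin (pixels) excluded at the image border.
#' @return Data frame with columns `u`, `v` (row, col) and `response`.
#' @export
detect_keypoints <- function(img, max_points = 500L, threshold = 3e-7,
                             min_points = 50L, sigma_d = 1.0, sigma_i = 2.0,
                             border = 10L) {
  g <- as_gray(img)
  gs <- gauss_blur(g, sigma_d)
  gx <- conv3(gs, scharr_u()) / 32
  gy <- conv3(gs, scharr_v()) / 32
  Sxx <- gauss_blur(gx * gx, sigma_i)
  Syy <- gauss_blur(gy * gy, sigma_i)
  Sxy <- gauss_blur(gx * gy, sigma_i)
  R <- (Sxx * Syy - Sxy^2) - 0.06 * (Sxx + Syy)^2
  is_max <- R >= max_filter(R, 3L) & R > threshold
  if (sum(is_max) < min_points) {
    cand <- R >= max_filter(R, 3L) & R > 0
    if (sum(cand) > min_points) {
      cut <- sort(R[cand], decreasing = TRUE)[min_points]
      cand <- cand & R >= cut
    }
    is_max <- cand
  }
  h <- nrow(R); w <- ncol(R)
  is_max[c(seq_len(min(border, h)), seq.int(max(1L, h - border + 1L), h)), ] <- FALSE
  is_max[, c(seq_len(min(border, w)), seq.int(max(1L, w - border + 1L), w))] <- FALSE
  idx <- which(is_max)
  if (!length(idx)) return(data.frame(u = numeric(), v = numeric(), response = numeric()))
  u <- ((idx - 1L) %% h) + 1L
  v <- ((idx - 1L) %/% h) + 1L
  # sub-pixel localization: 1-D quadratic fit of the response along each axis
  sub_off <- function(rm, r0, rp) {
    den <- rm - 2 * r0 + rp
    off <- ifelse(abs(den) > 1e-30, 0.5 * (rm - rp) / den, 0)
    pmin(pmax(off, -0.5), 0.5)
  }
  du <- sub_off(R[cbind(u - 1L, v)], R[idx], R[cbind(u + 1L, v)])
  dv <- sub_off(R[cbind(u, v - 1L)], R[idx], R[cbind(u, v + 1L)])
  resp <- R[idx]
  ord <- order(resp, decreasing = TRUE)
  ord <- ord[seq_len(min(length(ord), max_points))]
  data.frame(u = u[ord] + du[ord], v = v[ord] + dv[ord], response = resp[ord])
}

#' Describe keypoints with normalized patches
#'
#' Samples a `patch_n x patch_n` grid of blurred luminance around each
#' keypoint (bilinear, `spacing` pixels apart) and normalizes each patch to
#' zero mean and unit norm.
#'
#' @param img RGB image or luminance matrix.
#' @param kp Keypoint data frame from [detect_keypoints()].
#' @param patch_n Grid side (default 8).
#' @param spacing Sample spacing in pixels (default 2).
#' @param sigma Blur applied before sampling.
#' @return List with `desc` (n x patch_n^2 matrix) and `kp` (the rows kept;
#'   near-constant patches are dropped).
#' @export
describe_keypoints <- function(img, kp, patch_n = 8L, spacing = 2, sigma = 1.5) {
  g <- gauss_blur(as_gray(img), sigma)
  n <- nrow(kp)
  if (n == 0L) return(list(desc = matrix(0, 0L, patch_n^2), kp = kp))
  offs <- (seq_len(patch_n) - (patch_n + 1) / 2) * spacing
  ox <- rep(offs, times = patch_n)
  oy <- rep(offs, each = patch_n)
  X <- matrix(kp$v, n, patch_n^2) + matrix(ox, n, patch_n^2, byrow = TRUE)
  Y <- matrix(kp$u, n, patch_n^2) + matrix(oy, n, patch_n^2, byrow = TRUE)
  D <- matrix(bilinear_sample(g, as.vector(X), as.vector(Y)), n, patch_n^2)
  D <- D - rowMeans(D)
  nrm <- sqrt(rowSums(D^2))
  keep <- nrm > 1e-8
  D <- D[keep, , drop = FALSE] / nrm[keep]
  list(desc = D, kp = kp[keep, , drop = FALSE])
}

# 2-NN ratio test + cross-check matching of unit-norm descriptor rows.
match_descriptors <- function(dA, dB, ratio = 0.75) {
  nA <- nrow(dA); nB <- nrow(dB)
  if (nA == 0L || nB == 0L || nB < 2L) return(integer(0))
  S <- tcrossprod(dA, dB)
  b1 <- max.col(S, ties.method = "first")
  s1 <- S[cbind(seq_len(nA), b1)]
  S2 <- S
  S2[cbind(seq_len(nA), b1)] <- -Inf
  s2 <- S2[cbind(seq_len(nA), max.col(S2, ties.method = "first"))]
  d1 <- sqrt(pmax(2 - 2 * s1, 0))
  d2 <- sqrt(pmax(2 - 2 * s2, 0))
  bB <- max.col(t(S), ties.method = "first")
  ok <- (d1 < ratio * d2) & (bB[b1] == seq_len(nA))
  out <- rep(NA_integer_, nA)
  out[ok] <- b1[ok]
  out
}

registration_failure <- function(msg, pair = NULL) {
  if (!is.null(pair)) msg <- sprintf("%s (pair %s)", msg, pair)
  stop(errorCondition(msg, class = c("uwmosaic_registration_error", "error")))
}

#' Detect, describe and match features between two images
#'
#' Harris keypoints, normalized patch descriptors, 2-NN ratio-test matching
#' with cross-check, and RANSAC inlier screening under the requested warp
#' model. Deterministic for a fixed `seed`.
#'
#' @param imgA,imgB RGB images (A is the reference).
#' @param ratio 2-NN ratio-test threshold.
#' @param kind Warp model used for RANSAC screening.
#' @param ransac_threshold Inlier reprojection threshold, pixels.
#' @param ransac_max_iter RANSAC iteration cap.
#' @param seed RANSAC seed.
#' @param min_matches Minimum raw matches required.
#' @param min_inliers Minimum RANSAC inliers required.
#' @param max_points Keypoint budget per image.
#' @param detect_threshold Harris threshold passed to [detect_keypoints()].
#' @param pair Optional label naming the pair in error messages.
#' @return Object of class `match_set`: data frame with columns
#'   `uA, vA, uB, vB, inlier`.
#' @export
detect_and_match <- function(imgA, imgB, ratio = 0.75,
                             kind = c("similarity", "projective"),
                             ransac_threshold = 3, ransac_max_iter = 2000L,
                             seed = 42L, min_matches = 8L, min_inliers = 6L,
                             max_points = 500L, detect_threshold = 3e-7,
                             pair = NULL) {
  kind <- match.arg(kind)
  kpA <- detect_keypoints(imgA, max_points = max_points, threshold = detect_threshold)
  kpB <- detect_keypoints(imgB, max_points = max_points, threshold = detect_threshold)
  dA <- describe_keypoints(imgA, kpA)
  dB <- describe_keypoints(imgB, kpB)
  mi <- match_descriptors(dA$desc, dB$desc, ratio)
  sel <- which(!is.na(mi))
  if (length(sel) < max(min_matches, if (kind == "similarity") 2L else 4L))
    registration_failure(sprintf("only %d feature matches found", length(sel)), pair)
  ms <- data.frame(uA = dA$kp$u[sel], vA = dA$kp$v[sel],
                   uB = dB$kp$u[mi[sel]], vB = dB$kp$v[mi[sel]],
                   inlier = FALSE)
  rs <- ransac_warp(ms, kind, threshold = ransac_threshold,
                    max_iter = ransac_max_iter, seed = seed)
  if (is.null(rs) || sum(rs$inlier) < min_inliers)
    registration_failure("RANSAC found too few inliers", pair)
  ms$inlier <- rs$inlier
  structure(ms, class = c("match_set", "data.frame"))
}

# Least-squares warp fit mapping B points onto A points.
fit_warp_points <- function(xB, yB, xA, yA, kind) {
  n <- length(xB)
  if (kind == "similarity") {
    if (n < 2L) stop("similarity estimation needs at least 2 point pairs")
    X <- rbind(cbind(xB, -yB, 1, 0), cbind(yB, xB, 0, 1))
    yv <- c(xA, yA)
    qx <- qr(X)
    if (qx$rank < 4L)
      stop(errorCondition("degenerate configuration for similarity fit",
                          class = c("uwmosaic_degenerate_error", "error")))
    p <- qr.coef(qx, yv)
    H <- matrix(c(p[1L], p[2L], 0, -p[2L], p[1L], 0, p[3L], p[4L], 1), 3L, 3L)
  } else {
    if (n < 4L) stop("projective estimation needs at least 4 point pairs")
    # Hartley normalization
    norm_pts <- function(x, y) {
      cx <- mean(x); cy <- mean(y)
      s <- sqrt(2) / max(mean(sqrt((x - cx)^2 + (y - cy)^2)), 1e-12)
      list(T = matrix(c(s, 0, 0, 0, s, 0, -s * cx, -s * cy, 1), 3L, 3L),
           x = s * (x - cx), y = s * (y - cy))
    }
    nb <- norm_pts(xB, yB); na <- norm_pts(xA, yA)
    A <- matrix(0, 2L * n, 9L)
    A[seq_len(n), ] <- cbind(nb$x, nb$y, 1, 0, 0, 0,
                             -na$x * nb$x, -na$x * nb$y, -na$x)
    A[n + seq_len(n), ] <- cbind(0, 0, 0, nb$x, nb$y, 1,
                                 -na$y * nb$x, -na$y * nb$y, -na$y)
    sv <- svd(A, nu = 0L, nv = 9L)
    if (n > 4L && sv$d[8L] < 1e-8 * sv$d[1L])
      stop(errorCondition("degenerate (near-collinear) configuration for projective fit",
                          class = c("uwmosaic_degenerate_error", "error")))
    Hn <- matrix(sv$v[, 9L], 3L, 3L, byrow = TRUE)
    H <- solve(na$T) %*% Hn %*% nb$T
    if (abs(det(H)) < 1e-10)
      stop(errorCondition("degenerate configuration for projective fit",
                          class = c("uwmosaic_degenerate_error", "error")))
    H <- H / H[3L, 3L]
  }
  H
}

# RANSAC screening; returns list(H, inlier) or NULL.
ransac_warp <- function(matches, kind, threshold = 3, max_iter = 2000L, seed = 42L) {
  n <- nrow(matches)
  m_min <- if (kind == "similarity") 2L else 4L
  if (n < m_min) return(NULL)
  ptsB <- cbind(matches$vB, matches$uB)
  ptsA <- cbind(matches$vA, matches$uA)
  with_local_seed(seed, {
    best_in <- NULL; best_n <- 0L
    needed <- max_iter; it <- 0L
    while (it < min(max_iter, needed)) {
      it <- it + 1L
      idx <- sample.int(n, m_min)
      H <- tryCatch(fit_warp_points(ptsB[idx, 1L], ptsB[idx, 2L],
                                    ptsA[idx, 1L], ptsA[idx, 2L], kind),
                    error = function(e) NULL)
      if (is.null(H)) next
      pr <- apply_warp(H, ptsB)
      err <- sqrt((pr[, 1L] - ptsA[, 1L])^2 + (pr[, 2L] - ptsA[, 2L])^2)
      inl <- is.finite(err) & err < threshold
      nin <- sum(inl)
      if (nin > best_n) {
        best_n <- nin; best_in <- inl
        frac <- max(nin / n, 1e-6)
        needed <- min(max_iter,
                      ceiling(log(0.001) / log(pmax(1 - frac^m_min, 1e-12))))
      }
    }
    if (is.null(best_in) || best_n < m_min) return(NULL)
    list(inlier = best_in, n_inlier = best_n)
  })
}

#' Estimate a planar warp from matches
#'
#' Least-squares fit (similarity closed form or normalized DLT) on the
#' RANSAC inliers of a [detect_and_match()] match set; maps image-B pixel
#' coordinates into image A's frame.
#'
#' @param matches A `match_set` (or any data frame with `uA, vA, uB, vB`
#'   and optionally `inlier`).
#' @param kind `"similarity"` or `"projective"`.
#' @param inliers_only Use only rows flagged as inliers (default when the
#'   flag is present).
#' @return A `planar_warp` with the reprojection RMS of the fit.
#' @export
estimate_warp <- function(matches, kind = c("similarity", "projective"),
                          inliers_only = TRUE) {
  kind <- match.arg(kind)
  df <- as.data.frame(matches)
  if (inliers_only && "inlier" %in% names(df) && any(df$inlier))
    df <- df[df$inlier, , drop = FALSE]
  m_min <- if (kind == "similarity") 2L else 4L
  if (nrow(df) < m_min)
    stop(sprintf("%s estimation needs at least %d point pairs", kind, m_min))
  H <- fit_warp_points(df$vB, df$uB, df$vA, df$uA, kind)
  pr <- apply_warp(H, cbind(df$vB, df$uB))
  rms <- sqrt(mean((pr[, 1L] - df$vA)^2 + (pr[, 2L] - df$uA)^2))
  planar_warp(H, kind, rms = rms)
}

#' Canvas layout for a set of warped images
#'
#' Computes panorama extents covering the warped corners of every image and
#' re-expresses each warp in the canvas frame (top-left pixel = (1, 1)).
#'
#' @param warps List of `planar_warp`s mapping each image into the reference
#'   frame.
#' @param sizes List of `c(height, width)` per image.
#' @return Object of class `canvas_layout`: `height`, `width`, `offset`
#'   (x, y translation applied), `warps` (canvas-frame `planar_warp`s).
#' @export
canvas_layout <- function(warps, sizes) {
  corners <- lapply(seq_along(warps), function(i) {
    h <- sizes[[i]][1L]; w <- sizes[[i]][2L]
    apply_warp(warps[[i]], cbind(c(1, w, 1, w), c(1, 1, h, h)))
  })
  allc <- do.call(rbind, corners)
  eps <- 1e-6  # absorb float fuzz so near-integer extents stay put
  x0 <- floor(min(allc[, 1L]) + eps); x1 <- ceiling(max(allc[, 1L]) - eps)
  y0 <- floor(min(allc[, 2L]) + eps); y1 <- ceiling(max(allc[, 2L]) - eps)
  off <- c(x = 1 - x0, y = 1 - y0)
  Tm <- matrix(c(1, 0, 0, 0, 1, 0, off[1L], off[2L], 1), 3L, 3L)
  cw <- lapply(warps, function(wp) planar_warp(Tm %*% wp$H, wp$kind, rms = wp$rms))
  structure(list(height = as.integer(y1 - y0 + 1), width = as.integer(x1 - x0 + 1),
                 offset = off, warps = cw),
            class = "canvas_layout")
}

#' Warp an image onto a canvas
#'
#' Inverse-mapping bilinear resampling of `img` through `warp` into a canvas
#' of the layout's size. The validity mask is true exactly where the canvas
#' pixel maps inside the source image.
#'
#' @param img RGB image array.
#' @param warp `planar_warp` mapping source pixels into the canvas frame.
#' @param layout A [canvas_layout()] (only `height`/`width` are used).
#' @return List with `image` (canvas-sized RGB, zeros outside coverage) and
#'   `mask` (logical matrix).
#' @export
warp_to_canvas <- function(img, warp, layout) {
  check_rgb_image(img)
  hc <- layout$height; wc <- layout$width
  h <- dim(img)[1L]; w <- dim(img)[2L]
  H <- if (inherits(warp, "planar_warp")) warp$H else warp
  crn <- apply_warp(H, cbind(c(1, w, 1, w), c(1, 1, h, h)))
  c0 <- max(1L, floor(min(crn[, 1L]))); c1 <- min(wc, ceiling(max(crn[, 1L])))
  r0 <- max(1L, floor(min(crn[, 2L]))); r1 <- min(hc, ceiling(max(crn[, 2L])))
  out <- array(0, dim = c(hc, wc, 3L))
  mask <- matrix(FALSE, hc, wc)
  if (c1 < c0 || r1 < r0) return(list(image = out, mask = mask))
  Hi <- solve(H)
  nx <- c1 - c0 + 1L; ny <- r1 - r0 + 1L
  xs <- rep(c0:c1, each = ny)
  ys <- rep(r0:r1, times = nx)
  den <- Hi[3L, 1L] * xs + Hi[3L, 2L] * ys + Hi[3L, 3L]
  ok_den <- abs(den) > 1e-12
  sx <- (Hi[1L, 1L] * xs + Hi[1L, 2L] * ys + Hi[1L, 3L]) / den
  sy <- (Hi[2L, 1L] * xs + Hi[2L, 2L] * ys + Hi[2L, 3L]) / den
  tol <- 1e-9
  inside <- ok_den & sx >= 1 - tol & sx <= w + tol & sy >= 1 - tol & sy <= h + tol
  sub_mask <- matrix(inside, ny, nx)
  mask[r0:r1, c0:c1] <- sub_mask
  for (c in 1:3) {
    vals <- bilinear_sample(img[, , c], sx, sy)
    vals[!inside] <- 0
    plane <- out[, , c]
    plane[r0:r1, c0:c1] <- matrix(vals, ny, nx)
    out[, , c] <- plane
  }
  list(image = out, mask = mask)
}

empty_overlap_error <- function() {
  stop(errorCondition("images have no overlapping coverage",
                      class = c("uwmosaic_empty_overlap", "error")))
}

#' Overlap region of two validity masks
#'
#' Tight bounding box of `maskA & maskB` with the cropped masks.
#'
#' @param maskA,maskB Logical matrices of equal size.
#' @return Object of class `overlap_region`: `u` and `v` bounding-box ranges
#'   (rows, cols) and cropped `maskA`, `maskB`, `both`. An empty overlap
#'   raises a condition of class `uwmosaic_empty_overlap`.
#' @export
overlap_region <- function(maskA, maskB) {
  if (!identical(dim(maskA), dim(maskB))) stop("masks must share a shape")
  both <- maskA & maskB
  if (!any(both)) empty_overlap_error()
  rr <- range(which(rowSums(both) > 0L))
  cc <- range(which(colSums(both) > 0L))
  structure(list(u = rr, v = cc,
                 maskA = maskA[rr[1L]:rr[2L], cc[1L]:cc[2L], drop = FALSE],
                 maskB = maskB[rr[1L]:rr[2L], cc[1L]:cc[2L], drop = FALSE],
                 both = both[rr[1L]:rr[2L], cc[1L]:cc[2L], drop = FALSE]),
            class = "overlap_region")
}
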