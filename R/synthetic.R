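# Ground-truthed synthetic seabed surveys.
#
# The generator emulates exactly the image-formation model the enhancement
# inverts: a planar seabed texture viewed through water with per-channel
# Beer-Lambert transmission (tR = exp(-betaR d), tG/tB as power laws of tR)
# plus additive background light, and a sweep of overlapping camera views
# related by known similarity or projective warps. It is the oracle for the
# other modules: every degraded pixel satisfies I = J t + A (1 - t) exactly
# (before optional 8-bit quantization) and every warp is stored.

# Smoothly interpolated value noise on a lattice with the given cell size.
value_noise <- function(h, w, cell) {
  gh <- as.integer(ceiling(h / cell)) + 2L
  gw <- as.integer(ceiling(w / cell)) + 2L
  g <- matrix(stats::runif(gh * gw), gh, gw)
  xs <- (seq_len(w) - 1) / cell + 1
  ys <- (seq_len(h) - 1) / cell + 1
  x0 <- pmin(floor(xs), gw - 1L); y0 <- pmin(floor(ys), gh - 1L)
  fx <- xs - x0; fy <- ys - y0
  fx <- fx * fx * (3 - 2 * fx)  # smoothstep
  fy <- fy * fy * (3 - 2 * fy)
  g[y0, x0] * ((1 - fy) %o% (1 - fx)) +
    g[y0, x0 + 1L] * ((1 - fy) %o% fx) +
    g[y0 + 1L, x0] * (fy %o% (1 - fx)) +
    g[y0 + 1L, x0 + 1L] * (fy %o% fx)
}

# Sum of value-noise octaves, min-max normalized to [0, 1].
fractal_noise <- function(h, w, cell, octaves = 4L, gain = 0.5) {
  out <- 0; amp <- 1; cl <- cell
  for (o in seq_len(octaves)) {
    out <- out + amp * value_noise(h, w, max(cl, 1.5))
    amp <- amp * gain
    cl <- cl / 2
  }
  rng <- range(out)
  if (diff(rng) < 1e-12) return(matrix(0.5, h, w))
  (out - rng[1L]) / diff(rng)
}

#' Generate a synthetic seabed texture
#'
#' Deterministic per seed: a multi-octave value-noise sand/rubble background
#' with elliptical high-frequency "coral" blobs in contrasting hues, dark
#' crevice shadows (which give the dark-channel prior its near-zero minima)
#' and fine speckle (which gives corner detectors and superpixels structure).
#'
#' The texture is the scene radiance J of the degradation model: what the
#' camera would record at zero viewing distance. Underwater that radiance is
#' itself dim and blue-green shifted, because the illumination reaching the
#' seabed has been filtered by the water column above it — targets show the
#' low target-to-background contrast typical of turbid shallow water. The
#' `illumination` tint and `brightness` scale encode this; set both to 1 for
#' an unfiltered (in-air) texture.
#'
#' @param seed Integer seed.
#' @param size `c(height, width)` in pixels.
#' @param illumination Per-channel (R, G, B) illumination transmittance
#'   applied to the surface color.
#' @param brightness Overall radiance scale in `(0, 1]`.
#' @return RGB image array.
#' @export
generate_seabed_texture <- function(seed, size = c(512L, 512L),
                                    illumination = c(R = 0.40, G = 0.85, B = 0.90),
                                    brightness = 0.75) {
  h <- as.integer(size[1L]); w <- as.integer(size[2L])
  with_local_seed(seed, {
    base <- fractal_noise(h, w, cell = 64, octaves = 5L)
    hue <- 0.06 + 0.08 * fractal_noise(h, w, 96, 3L)
    sat <- 0.25 + 0.35 * fractal_noise(h, w, 48, 3L)
    val <- 0.30 + 0.60 * base
    # coral blobs
    n_blob <- max(3L, as.integer(round(h * w / 8000)))
    blob_hues <- c(0.95, 0.83, 0.33, 0.55, 0.08)
    fine <- fractal_noise(h, w, 8, 3L)
    for (i in seq_len(n_blob)) {
      cy <- stats::runif(1, 1, h); cx <- stats::runif(1, 1, w)
      ra <- stats::runif(1, 7, 26); rb <- stats::runif(1, 0.5, 1) * ra
      th <- stats::runif(1, 0, pi)
      bh <- sample(blob_hues, 1L) + stats::runif(1, -0.03, 0.03)
      r0 <- max(1L, floor(cy - ra - 2)); r1 <- min(h, ceiling(cy + ra + 2))
      c0 <- max(1L, floor(cx - ra - 2)); c1 <- min(w, ceiling(cx + ra + 2))
      if (r1 <= r0 || c1 <= c0) next
      yy <- matrix(r0:r1 - cy, r1 - r0 + 1L, c1 - c0 + 1L)
      xx <- matrix(c0:c1 - cx, r1 - r0 + 1L, c1 - c0 + 1L, byrow = TRUE)
      xr <- cos(th) * xx + sin(th) * yy
      yr <- -sin(th) * xx + cos(th) * yy
      e <- sqrt((xr / ra)^2 + (yr / rb)^2)
      wgt <- pmax(0, 1 - e^3)
      sub <- fine[r0:r1, c0:c1, drop = FALSE]
      hue[r0:r1, c0:c1] <- (1 - wgt) * hue[r0:r1, c0:c1] + wgt * bh
      sat[r0:r1, c0:c1] <- (1 - wgt) * sat[r0:r1, c0:c1] + wgt * (0.45 + 0.3 * sub)
      val[r0:r1, c0:c1] <- (1 - wgt) * val[r0:r1, c0:c1] + wgt * (0.30 + 0.65 * sub)
    }
    # crevice shadows (clumped) plus grain-shadow speckle (scattered): the
    # near-black minima that dark-channel methods rely on occur in every
    # local neighborhood of rubble/coral texture
    sh <- fractal_noise(h, w, 20, 3L)
    dark <- sh < stats::quantile(sh, 0.08)
    dark <- dark | (stats::runif(h * w) < 0.025)
    val[dark] <- val[dark] * stats::runif(sum(dark), 0.03, 0.25)
    # fine speckle
    val <- clamp01(val * (0.85 + 0.30 * value_noise(h, w, 2)))
    img <- hsv_to_rgb_img(hue %% 1, clamp01(sat), val * brightness)
    for (c in 1:3) img[, , c] <- img[, , c] * illumination[[c]]
    img
  })
}

#' Smooth random depth map
#'
#' Low-octave value noise rescaled to `[d_range[1], d_range[2]]`.
#'
#' @param seed Integer seed.
#' @param size `c(height, width)`.
#' @param d_range Depth range (arbitrary path-length units).
#' @return `H x W` matrix.
#' @export
generate_depth_map <- function(seed, size, d_range = c(0.2, 2.0)) {
  h <- as.integer(size[1L]); w <- as.integer(size[2L])
  with_local_seed(seed, {
    d_range[1L] + diff(d_range) * fractal_noise(h, w, cell = max(h, w) / 3, octaves = 2L)
  })
}

#' Degrade a clean image through the underwater attenuation model
#'
#' `tR = exp(-betaR d)`, `tG = tR^(cG/cR)`, `tB = tR^(cB/cR)`, and per
#' channel `I = J t + A (1 - t)`.
#'
#' @param clean Clean RGB image (scene radiance).
#' @param depth Nonnegative path-length matrix, same `H x W`.
#' @param betaR Red attenuation coefficient (1/unit of depth).
#' @param model An [attenuation_ratios()] model giving the channel ratios.
#' @param A Background light (named vector `R`, `G`, `B`).
#' @return List with `image` (degraded RGB) and `transmission`
#'   (a `transmission_set` of the true maps).
#' @export
degrade <- function(clean, depth, betaR, model, A) {
  check_rgb_image(clean)
  if (!identical(dim(depth), dim(clean)[1:2])) stop("depth must match the image shape")
  if (any(depth < 0)) stop("depth must be nonnegative")
  A <- unclass(A)
  tR <- exp(-betaR * depth)
  tset <- amend_transmissions(tR, model)
  out <- clean
  maps <- list(tset$tR, tset$tG, tset$tB)
  for (c in 1:3) out[, , c] <- clean[, , c] * maps[[c]] + A[[c]] * (1 - maps[[c]])
  list(image = out, transmission = tset)
}

default_background_light <- function() {
  structure(c(R = 0.25, G = 0.55, B = 0.70), class = "background_light")
}

#' Generate a ground-truthed synthetic survey
#'
#' A sweep of `n_views` overlapping views of one seabed scene. View k is a
#' crop translated by `(1 - overlap) * view width` with a jittered similarity
#' (or mildly projective) warp; each view is degraded through the attenuation
#' model with the scene's smooth depth field. Warps map view pixel
#' coordinates `(x, y, 1)` (x = column) to scene coordinates.
#'
#' @param seed Integer seed; the survey is byte-identical per seed.
#' @param n_views Number of views (>= 2).
#' @param overlap Requested overlap fraction between consecutive views.
#' @param warp_kind `"similarity"` or `"projective"`.
#' @param view_size `c(height, width)` of each view.
#' @param jitter Named vector: `rot` (degrees), `scale` (relative), `trans`
#'   (pixels). `c(rot=0, scale=0, trans=0)` gives pure translations.
#' @param betaR Red attenuation coefficient.
#' @param d_range Depth range of the smooth depth field; with the defaults
#'   `betaR * d` spans `[0.2, 2.0]`.
#' @param A Background light; the default bluish-greenish
#'   `c(R=0.25, G=0.55, B=0.70)` mimics coastal water.
#' @param quantize If `TRUE`, degraded views are rounded to 8-bit levels,
#'   exercising the real I/O path.
#' @return Object of class `synthetic_survey`: `scene`, `depth`, `betaR`,
#'   `model`, `A`, `seed`, and `views`, a list of
#'   `list(warp, image, clean, tR)`.
#' @export
generate_survey <- function(seed, n_views = 5L, overlap = 0.5,
                            warp_kind = c("similarity", "projective"),
                            view_size = c(192L, 256L),
                            jitter = c(rot = 2, scale = 0.03, trans = 3),
                            betaR = 1.0, d_range = c(0.2, 2.0),
                            A = default_background_light(),
                            quantize = FALSE) {
  warp_kind <- match.arg(warp_kind)
  n_views <- as.integer(n_views)
  if (n_views < 2L) stop("a survey needs at least two views")
  vh <- as.integer(view_size[1L]); vw <- as.integer(view_size[2L])
  stride <- max(1L, as.integer(round((1 - overlap) * vw)))
  margin <- 28L
  sw <- vw + (n_views - 1L) * stride + 2L * margin
  sh <- vh + 2L * margin
  scene <- generate_seabed_texture(seed, c(sh, sw))
  depth <- generate_depth_map(seed + 1000003L, c(sh, sw), d_range)
  model <- attenuation_ratios(A)
  xs <- rep(seq_len(vw), each = vh)
  ys <- rep(seq_len(vh), times = vw)
  views <- with_local_seed(seed + 2000003L, lapply(seq_len(n_views), function(k) {
    tx <- margin + (k - 1L) * stride
    ty <- margin
    th <- stats::runif(1, -1, 1) * jitter[["rot"]] * pi / 180
    s <- 1 + stats::runif(1, -1, 1) * jitter[["scale"]]
    dt <- stats::runif(2, -1, 1) * jitter[["trans"]]
    a <- s * cos(th); b <- s * sin(th)
    cx <- (vw + 1) / 2; cy <- (vh + 1) / 2
    # similarity about the view center, then translate the center into place
    e <- (cx + tx + dt[1L]) - (a * cx - b * cy)
    f <- (cy + ty + dt[2L]) - (b * cx + a * cy)
    H <- matrix(c(a, b, 0, -b, a, 0, e, f, 1), 3L, 3L)
    if (warp_kind == "projective") {
      H[3L, 1:2] <- stats::runif(2, -1, 1) * 5e-5
      # keep the view center mapping fixed under the perspective terms
      wc <- H[3L, 1L] * cx + H[3L, 2L] * cy + 1
      H[1:2, ] <- H[1:2, ] * wc
    }
    den <- H[3L, 1L] * xs + H[3L, 2L] * ys + H[3L, 3L]
    sx <- (H[1L, 1L] * xs + H[1L, 2L] * ys + H[1L, 3L]) / den
    sy <- (H[2L, 1L] * xs + H[2L, 2L] * ys + H[2L, 3L]) / den
    cleanv <- array(0, dim = c(vh, vw, 3L))
    for (c in 1:3) cleanv[, , c] <- matrix(bilinear_sample(scene[, , c], sx, sy), vh, vw)
    dv <- matrix(bilinear_sample(depth, sx, sy), vh, vw)
    deg <- degrade(cleanv, dv, betaR, model, A)
    img <- deg$image
    if (quantize) img <- round(img * 255) / 255
    list(warp = planar_warp(H, warp_kind), image = img, clean = cleanv,
         tR = deg$transmission$tR)
  }))
  structure(list(scene = scene, depth = depth, betaR = betaR, model = model,
                 A = A, views = views, seed = seed, overlap = overlap,
                 view_size = c(vh, vw), stride = stride, margin = margin,
                 warp_kind = warp_kind, quantize = quantize),
            class = "synthetic_survey")
}

#' Measured overlap fraction between consecutive survey views
#'
#' Maps each view's pixel grid into the previous view's frame through the
#' stored ground-truth warps and reports the inside fraction.
#'
#' @param survey A `synthetic_survey`.
#' @return Numeric vector of length `n_views - 1`.
#' @export
survey_overlap_fractions <- function(survey) {
  vh <- survey$view_size[1L]; vw <- survey$view_size[2L]
  xs <- rep(seq_len(vw), each = vh)
  ys <- rep(seq_len(vh), times = vw)
  vapply(seq_len(length(survey$views) - 1L), function(k) {
    Hrel <- solve(survey$views[[k]]$warp$H) %*% survey$views[[k + 1L]]$warp$H
    den <- Hrel[3L, 1L] * xs + Hrel[3L, 2L] * ys + Hrel[3L, 3L]
    px <- (Hrel[1L, 1L] * xs + Hrel[1L, 2L] * ys + Hrel[1L, 3L]) / den
    py <- (Hrel[2L, 1L] * xs + Hrel[2L, 2L] * ys + Hrel[2L, 3L]) / den
    mean(px >= 1 & px <= vw & py >= 1 & py <= vh)
  }, numeric(1))
}

#' Generate a misaligned overlapping pair with ground truth
#'
#' Two exact crops of one scene related by a known integer translation,
#' placed on a shared canvas with their warps perturbed in opposite
#' directions by `misalignment / 2` pixels each, so the relative
#' registration error is `misalignment` pixels and the true geometry lies
#' between the two placements (as it does around an estimated registration).
#' The ground-truth panorama is the scene at the unperturbed position on the
#' same canvas, so composites can be scored against truth.
#'
#' @param seed Integer seed.
#' @param size `c(height, width)` of each view.
#' @param overlap Overlap fraction between the views.
#' @param misalignment Residual warp error magnitude, pixels.
#' @return List: `ref`, `new` (canvas images), `ref_mask`, `new_mask`,
#'   `truth` (ground-truth canvas image), `layout`.
#' @export
generate_misaligned_pair <- function(seed, size = c(192L, 256L), overlap = 0.5,
                                     misalignment = 1.5) {
  vh <- as.integer(size[1L]); vw <- as.integer(size[2L])
  stride <- max(1L, as.integer(round((1 - overlap) * vw)))
  scene <- generate_seabed_texture(seed, c(vh, vw + stride))
  v1 <- scene[, seq_len(vw), , drop = FALSE]
  v2 <- scene[, stride + seq_len(vw), , drop = FALSE]
  dxy <- with_local_seed(seed + 500009L, {
    d <- stats::runif(2, -1, 1)
    d / max(sqrt(sum(d^2)), 1e-9) * misalignment / 2
  })
  H1 <- matrix(c(1, 0, 0, 0, 1, 0, -dxy[1L], -dxy[2L], 1), 3L, 3L)
  H2 <- matrix(c(1, 0, 0, 0, 1, 0, stride + dxy[1L], dxy[2L], 1), 3L, 3L)
  warps <- list(planar_warp(H1), planar_warp(H2))
  layout <- canvas_layout(warps, list(c(vh, vw), c(vh, vw)))
  w1 <- warp_to_canvas(v1, layout$warps[[1L]], layout)
  w2 <- warp_to_canvas(v2, layout$warps[[2L]], layout)
  Ts <- planar_warp(layout$warps[[1L]]$H)  # scene frame == view-1 frame
  tw <- warp_to_canvas(scene, Ts, layout)
  list(ref = w1$image, new = w2$image, ref_mask = w1$mask, new_mask = w2$mask,
       truth = tw$image, truth_mask = tw$mask, layout = layout)
}

#' Write a survey to disk
#'
#' PNG views, single-channel TIFF true-transmission maps and a JSON manifest
#' (warps as row-major 3x3 matrices, background light, attenuation ratios,
#' depth statistics).
#'
#' @param survey A `synthetic_survey`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_survey <- function(survey, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  n <- length(survey$views)
  for (k in seq_len(n)) {
    v <- survey$views[[k]]
    save_image(v$image, file.path(dir, sprintf("view_%02d.png", k)))
    save_image(v$tR, file.path(dir, sprintf("tR_%02d.tif", k)))
  }
  manifest <- list(
    seed = survey$seed, n_views = n, overlap = survey$overlap,
    view_size = survey$view_size, warp_kind = survey$warp_kind,
    betaR = survey$betaR,
    background_light = as.list(unclass(survey$A)),
    attenuation_ratios = list(GR = survey$model$ratio_GR, BR = survey$model$ratio_BR),
    depth = list(min = min(survey$depth), max = max(survey$depth),
                 mean = mean(survey$depth)),
    warps = lapply(survey$views, function(v) as.vector(t(v$warp$H)))
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
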