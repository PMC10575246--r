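# Attenuation-aware dark-channel restoration of underwater images.
#
# Seawater attenuates red light much faster than green and blue, so the
# classic dark channel prior (which assumes all three channels can go dark)
# misreads underwater scenes. Here the dark channel is taken over G and B
# only, rough per-channel transmissions for G and B are converted to the red
# channel through the wavelength dependence of the attenuation coefficient,
# averaged into a single red transmission, re-expanded to all channels as
# power laws, refined with a guided filter, and inverted through the
# image-formation model I = J t + A (1 - t).

#' Enhancement configuration
#'
#' Parameters of the attenuation-aware dark-channel restoration.
#'
#' @param patch_size Odd side length (pixels) of the local minimum patch used
#'   by the dark channel and rough transmission estimates. Default 15.
#' @param omega Haze retention factor in the rough transmission estimate
#'   (`1` reproduces the pure dark-channel estimate). Default 0.95.
#' @param top_fraction Fraction of brightest pixels per channel averaged into
#'   the background light estimate. Default 0.001 (the top 0.1%).
#' @param t0 Lower bound on transmission in the recovery step. Default 0.1.
#' @param t_floor Floor applied to transmission maps before power/refinement
#'   operations. Default 0.05.
#' @param guided_radius Guided filter window radius in pixels. Default 40.
#' @param guided_eps Guided filter regularization. Default 1e-3.
#' @param a_floor Floor on background-light components (the recovery divides
#'   by them). Default 1e-3.
#' @param refine_before_amend If `TRUE` (default) the guided filter refines
#'   the red transmission before it is expanded to G and B; otherwise each
#'   channel map is refined after expansion.
#' @param wavelengths Named vector of representative wavelengths (nm) for the
#'   R, G, B channels. Default `c(R = 620, G = 540, B = 450)`.
#' @return An object of class `enhancement_config`.
#' @export
enhancement_config <- function(patch_size = 15L, omega = 0.95, top_fraction = 0.001,
                               t0 = 0.1, t_floor = 0.05, guided_radius = 40L,
                               guided_eps = 1e-3, a_floor = 1e-3,
                               refine_before_amend = TRUE,
                               wavelengths = c(R = 620, G = 540, B = 450)) {
  patch_size <- as.integer(patch_size)
  if (patch_size < 3L || patch_size %% 2L != 1L)
    stop("patch_size must be an odd integer >= 3")
  if (omega <= 0 || omega > 1) stop("omega must be in (0, 1]")
  if (top_fraction <= 0 || top_fraction > 1) stop("top_fraction must be in (0, 1]")
  if (t0 <= 0 || t0 >= 1) stop("t0 must be in (0, 1)")
  if (t_floor <= 0 || t_floor >= 1) stop("t_floor must be in (0, 1)")
  structure(list(patch_size = patch_size, omega = omega,
                 top_fraction = top_fraction, t0 = t0, t_floor = t_floor,
                 guided_radius = as.integer(guided_radius),
                 guided_eps = guided_eps, a_floor = a_floor,
                 refine_before_amend = isTRUE(refine_before_amend),
                 wavelengths = wavelengths),
            class = "enhancement_config")
}

#' Underwater dark channel
#'
#' Local minimum over a square patch of the pixelwise minimum of the green
#' and blue channels. Red is excluded because it attenuates so fast in water
#' that it carries little information about medium thickness.
#'
#' @param img RGB image array.
#' @param patch_size Odd patch side length (pixels).
#' @return `H x W` matrix in `[0, 1]`.
#' @export
underwater_dark_channel <- function(img, patch_size = 15L) {
  check_rgb_image(img)
  patch_size <- as.integer(patch_size)
  if (patch_size < 1L || patch_size %% 2L != 1L)
    stop("patch_size must be a positive odd integer")
  min_filter(pmin(img[, , 2L], img[, , 3L]), patch_size)
}

#' Estimate the background (veiling) light
#'
#' Per channel, the mean of the brightest `top_fraction` of pixels.
#'
#' @param img RGB image array.
#' @param top_fraction Fraction of pixels averaged; `ceiling(top_fraction * H * W)`
#'   pixels are used (at least one).
#' @param floor Lower floor substituted for near-black channels.
#' @return Named numeric vector `c(R=, G=, B=)`, class `background_light`.
#' @export
estimate_background_light <- function(img, top_fraction = 0.001, floor = 1e-3) {
  check_rgb_image(img)
  n_pix <- prod(dim(img)[1:2])
  if (n_pix < 1L) stop("empty image")
  if (top_fraction <= 0 || top_fraction > 1) stop("top_fraction must be in (0, 1]")
  k <- max(1L, as.integer(ceiling(top_fraction * n_pix)))
  a <- vapply(1:3, function(c) {
    v <- sort(as.vector(img[, , c]), decreasing = TRUE)
    mean(v[seq_len(k)])
  }, numeric(1))
  a <- pmax(a, floor)
  structure(stats::setNames(a, c("R", "G", "B")), class = "background_light")
}

#' Attenuation-coefficient ratios between color channels
#'
#' The scattering coefficient of seawater is approximately linear in
#' wavelength, `b(lambda) = (-0.00113 lambda + 1.62517) b_ref`, and the
#' background light of channel c is proportional to `b_c / c_c` (scattering
#' over attenuation). Combining the two gives the attenuation ratios
#' `cG/cR = (bG AR) / (bR AG)` and `cB/cR = (bB AR) / (bR AB)`, which link
#' the per-channel transmission maps as power laws
#' `tG = tR^(cG/cR)`, `tB = tR^(cB/cR)`.
#'
#' @param A Background light (named vector `R`, `G`, `B`); all components
#'   must be strictly positive.
#' @param wavelengths Representative wavelengths (nm), default
#'   `c(R = 620, G = 540, B = 450)`.
#' @return Object of class `attenuation_model` with elements `ratio_GR`,
#'   `ratio_BR` and `wavelengths`.
#' @export
attenuation_ratios <- function(A, wavelengths = c(R = 620, G = 540, B = 450)) {
  A <- unclass(A)
  if (length(A) != 3L || any(!is.finite(A)) || any(A <= 0))
    stop("background light must have three strictly positive components")
  b <- -0.00113 * wavelengths + 1.62517
  if (any(b <= 0)) stop("wavelengths outside the validity of the linear scattering model")
  structure(list(ratio_GR = as.numeric((b[[2L]] / b[[1L]]) * (A[[1L]] / A[[2L]])),
                 ratio_BR = as.numeric((b[[3L]] / b[[1L]]) * (A[[1L]] / A[[3L]])),
                 wavelengths = wavelengths),
            class = "attenuation_model")
}

#' Rough green/blue transmission maps
#'
#' Dark-channel estimate per channel: `t0c = 1 - omega * min_patch(I_c / A_c)`
#' for c in G, B, with the radiance ratio clamped to at most 1 and the result
#' clamped to `[t_floor, 1]`.
#'
#' @param img RGB image array.
#' @param A Background light.
#' @param cfg An [enhancement_config()].
#' @return List with matrices `t0G` and `t0B`.
#' @export
rough_transmission <- function(img, A, cfg = enhancement_config()) {
  check_rgb_image(img)
  A <- unclass(A)
  if (any(A <= 0)) stop("background light components must be positive")
  one <- function(ch, a) {
    ratio <- pmin(img[, , ch] / a, 1)
    t0 <- 1 - cfg$omega * min_filter(ratio, cfg$patch_size)
    pmin(pmax(t0, cfg$t_floor), 1)
  }
  list(t0G = one(2L, A[[2L]]), t0B = one(3L, A[[3L]]))
}

#' Joint red transmission from the green and blue estimates
#'
#' Each rough map is converted to the red channel through the inverse power
#' law (`t0c^(cR/cc)`) and the two converted maps are averaged.
#'
#' @param t0G,t0B Rough transmission matrices in `(0, 1]`.
#' @param model An [attenuation_ratios()] model.
#' @return `H x W` red transmission matrix.
#' @export
joint_red_transmission <- function(t0G, t0B, model) {
  if (!identical(dim(t0G), dim(t0B))) stop("transmission maps must share a shape")
  0.5 * (t0G^(1 / model$ratio_GR) + t0B^(1 / model$ratio_BR))
}

#' Expand the red transmission to all channels
#'
#' Applies the power-law links `tG = tR^(cG/cR)`, `tB = tR^(cB/cR)`.
#'
#' @param tR Red transmission matrix in `(0, 1]`.
#' @param model An [attenuation_ratios()] model.
#' @return Object of class `transmission_set` with `tR`, `tG`, `tB` and a
#'   `refined` flag.
#' @export
amend_transmissions <- function(tR, model) {
  structure(list(tR = tR, tG = tR^model$ratio_GR, tB = tR^model$ratio_BR,
                 refined = FALSE),
            class = "transmission_set")
}

#' Guided filter (gray guide)
#'
#' Edge-preserving local linear smoother: within each window the output is
#' an affine function of the guide, with coefficients averaged over all
#' windows covering a pixel. Window sums use border truncation.
#'
#' @param p Input matrix to smooth.
#' @param guide Guidance matrix (same shape).
#' @param radius Window radius in pixels.
#' @param eps Regularization added to the guide variance.
#' @return Smoothed matrix.
#' @export
guided_filter <- function(p, guide, radius = 40L, eps = 1e-3) {
  if (!identical(dim(p), dim(guide))) stop("guide must match the input shape")
  n <- box_count(nrow(p), ncol(p), radius)
  mI <- box_sum(guide, radius) / n
  mp <- box_sum(p, radius) / n
  mIp <- box_sum(guide * p, radius) / n
  mII <- box_sum(guide * guide, radius) / n
  cov_Ip <- mIp - mI * mp
  var_I <- mII - mI * mI
  a <- cov_Ip / (var_I + eps)
  b <- mp - a * mI
  ma <- box_sum(a, radius) / n
  mb <- box_sum(b, radius) / n
  ma * guide + mb
}

#' Refine a transmission map by guided filtering
#'
#' @param t Transmission matrix.
#' @param guide RGB image (converted to luminance) or matrix guide.
#' @param radius,eps Guided filter parameters.
#' @param t_floor Lower clamp applied after refinement.
#' @return Refined transmission matrix in `[t_floor, 1]`.
#' @export
refine_transmission <- function(t, guide, radius = 40L, eps = 1e-3, t_floor = 0.05) {
  g <- as_gray(guide)
  if (!identical(dim(t), dim(g))) stop("guide must match the transmission shape")
  pmin(pmax(guided_filter(t, g, radius, eps), t_floor), 1)
}

#' Invert the degradation model
#'
#' Per channel, `J = (I - A) / max(t, t0) + A`, clipped to `[0, 1]`.
#'
#' @param img Observed RGB image.
#' @param tset A `transmission_set` (or a single matrix applied to all
#'   channels).
#' @param A Background light.
#' @param t0 Transmission lower bound in the division (typical value 0.1).
#' @return Recovered RGB image.
#' @export
recover <- function(img, tset, A, t0 = 0.1) {
  check_rgb_image(img)
  A <- unclass(A)
  tl <- if (is.matrix(tset)) list(tR = tset, tG = tset, tB = tset) else tset
  out <- img
  maps <- list(tl$tR, tl$tG, tl$tB)
  for (c in 1:3) {
    tc <- pmax(maps[[c]], t0)
    out[, , c] <- clamp01((img[, , c] - A[[c]]) / tc + A[[c]])
  }
  out
}

#' Enhance an underwater image
#'
#' Full restoration pipeline: background light from the brightest pixels,
#' attenuation ratios from the scattering model, rough G/B transmissions from
#' the per-channel dark-channel estimate, joint red transmission, guided
#' refinement, power-law expansion and model inversion.
#'
#' @param img Observed RGB image.
#' @param cfg An [enhancement_config()].
#' @param details If `TRUE`, return a list with the intermediate products.
#' @return The enhanced RGB image, or (with `details = TRUE`) a list with
#'   elements `image`, `transmission`, `background`, `model`.
#' @export
enhance <- function(img, cfg = enhancement_config(), details = FALSE) {
  check_rgb_image(img)
  A <- estimate_background_light(img, cfg$top_fraction, cfg$a_floor)
  model <- attenuation_ratios(A, cfg$wavelengths)
  rt <- rough_transmission(img, A, cfg)
  tR <- joint_red_transmission(rt$t0G, rt$t0B, model)
  guide <- as_gray(img)
  if (cfg$refine_before_amend) {
    tR <- refine_transmission(tR, guide, cfg$guided_radius, cfg$guided_eps, cfg$t_floor)
    tset <- amend_transmissions(tR, model)
  } else {
    tset <- amend_transmissions(tR, model)
    for (nm in c("tR", "tG", "tB"))
      tset[[nm]] <- refine_transmission(tset[[nm]], guide, cfg$guided_radius,
                                        cfg$guided_eps, cfg$t_floor)
  }
  tset$refined <- TRUE
  out <- recover(img, tset, A, cfg$t0)
  if (details) list(image = out, transmission = tset, background = A, model = model)
  else out
}

#' Classic single-transmission dark-channel baseline
#'
#' Minimal implementation of conventional dark-channel dehazing (dark channel
#' over all three channels, one shared transmission map), kept as a
#' comparison baseline for feature-matching experiments.
#'
#' @param img Observed RGB image.
#' @param cfg An [enhancement_config()].
#' @return Enhanced RGB image.
#' @export
enhance_dcp_baseline <- function(img, cfg = enhancement_config()) {
  check_rgb_image(img)
  A <- estimate_background_light(img, cfg$top_fraction, cfg$a_floor)
  ratio <- pmin(pmin(img[, , 1L] / A[[1L]], img[, , 2L] / A[[2L]]),
                img[, , 3L] / A[[3L]])
  t <- 1 - cfg$omega * min_filter(pmin(ratio, 1), cfg$patch_size)
  t <- pmin(pmax(t, cfg$t_floor), 1)
  t <- refine_transmission(t, as_gray(img), cfg$guided_radius, cfg$guided_eps, cfg$t_floor)
  recover(img, t, A, cfg$t0)
}
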