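# Optimal seam-line search restricted to superpixel boundaries.
#
# The overlap of the aligned images is segmented into SLIC superpixels;
# their dilated boundaries form the region in which a row-monotone,
# rV-connected seam is found by dynamic programming on a three-term energy
# (hue difference, neighborhood-weighted intensity difference, Scharr
# gradient difference).

#' Seam configuration
#'
#' @param alpha_w,beta_w,gamma_w Weights of the hue, squared-intensity and
#'   gradient terms (each term is min-max normalized to `[0, 1]` first).
#'   Defaults 1/3 each.
#' @param rV Seam connectivity bound: successive seam columns may differ by
#'   at most `rV` (default 1, an 8-connected path).
#' @param slic_region_size Nominal SLIC superpixel spacing, pixels.
#' @param slic_compactness SLIC compactness (color-vs-space trade-off).
#' @param slic_iterations SLIC k-means iterations.
#' @param dilation Side of the square structuring element dilating the
#'   superpixel boundaries (default 5).
#' @param hue_circular Treat hue as circular when differencing.
#' @param boundary_union If `TRUE`, the restricted mask is the union of the
#'   boundary maps of the two overlap images segmented separately; default
#'   segments their pixel mean once.
#' @return Object of class `seam_config`.
#' @export
seam_config <- function(alpha_w = 1 / 3, beta_w = 1 / 3, gamma_w = 1 / 3,
                        rV = 1L, slic_region_size = 40L, slic_compactness = 10,
                        slic_iterations = 10L, dilation = 5L,
                        hue_circular = FALSE, boundary_union = FALSE) {
  if (any(c(alpha_w, beta_w, gamma_w) < 0) || alpha_w + beta_w + gamma_w <= 0)
    stop("energy weights must be nonnegative and not all zero")
  if (rV < 1L) stop("rV must be >= 1")
  if (dilation %% 2L != 1L) stop("dilation size must be odd")
  structure(list(alpha_w = alpha_w, beta_w = beta_w, gamma_w = gamma_w,
                 rV = as.integer(rV),
                 slic_region_size = as.integer(slic_region_size),
                 slic_compactness = slic_compactness,
                 slic_iterations = as.integer(slic_iterations),
                 dilation = as.integer(dilation),
                 hue_circular = isTRUE(hue_circular),
                 boundary_union = isTRUE(boundary_union)),
            class = "seam_config")
}

#' SLIC superpixel segmentation
#'
#' Localized k-means in the 5-D (L, a, b, row, col) space: cluster centers
#' start on a regular grid (perturbed to the lowest local gradient), each
#' center competes for pixels within a 2S window, and distances combine the
#' CIELAB distance with the spatial distance scaled by `compactness / S`.
#'
#' @param img RGB image array.
#' @param region_size Nominal superpixel spacing S, pixels.
#' @param compactness Spatial regularity weight.
#' @param iterations Number of assignment/update sweeps.
#' @return Integer label matrix (`H x W`, labels from 1).
#' @export
slic_segment <- function(img, region_size = 40L, compactness = 10, iterations = 10L) {
  check_rgb_image(img)
  h <- dim(img)[1L]; w <- dim(img)[2L]
  S <- max(4L, as.integer(region_size))
  lab <- rgb_to_lab(img)
  L <- matrix(lab[, 1L], h, w); a <- matrix(lab[, 2L], h, w); b <- matrix(lab[, 3L], h, w)
  cy <- seq(from = min(S / 2 + 0.5, h), to = h, by = S)
  cx <- seq(from = min(S / 2 + 0.5, w), to = w, by = S)
  if (!length(cy)) cy <- (h + 1) / 2
  if (!length(cx)) cx <- (w + 1) / 2
  centers <- expand.grid(y = round(cy), x = round(cx))
  # move centers to the lowest-gradient position in their 3x3 neighborhood
  grad <- abs(shift_mat(L, 0L, 1L) - shift_mat(L, 0L, -1L)) +
    abs(shift_mat(L, 1L, 0L) - shift_mat(L, -1L, 0L))
  for (i in seq_len(nrow(centers))) {
    y <- centers$y[i]; x <- centers$x[i]
    ys <- pmin(pmax(y + (-1:1), 1L), h); xs <- pmin(pmax(x + (-1:1), 1L), w)
    sub <- grad[ys, xs, drop = FALSE]
    k <- which.min(sub)
    centers$y[i] <- ys[(k - 1L) %% 3L + 1L]
    centers$x[i] <- xs[(k - 1L) %/% 3L + 1L]
  }
  nC <- nrow(centers)
  cf <- cbind(L[cbind(centers$y, centers$x)],
              a[cbind(centers$y, centers$x)],
              b[cbind(centers$y, centers$x)],
              centers$x, centers$y)
  m2 <- (compactness / S)^2
  labels <- matrix(0L, h, w)
  for (it in seq_len(iterations)) {
    dists <- matrix(Inf, h, w)
    for (i in seq_len(nC)) {
      y0 <- max(1L, as.integer(cf[i, 5L]) - S); y1 <- min(h, as.integer(cf[i, 5L]) + S)
      x0 <- max(1L, as.integer(cf[i, 4L]) - S); x1 <- min(w, as.integer(cf[i, 4L]) + S)
      if (y1 < y0 || x1 < x0) next
      yy <- y0:y1; xx <- x0:x1
      dc <- (L[yy, xx, drop = FALSE] - cf[i, 1L])^2 +
        (a[yy, xx, drop = FALSE] - cf[i, 2L])^2 +
        (b[yy, xx, drop = FALSE] - cf[i, 3L])^2
      dx <- matrix(xx - cf[i, 4L], length(yy), length(xx), byrow = TRUE)
      dy <- matrix(yy - cf[i, 5L], length(yy), length(xx))
      D <- dc + m2 * (dx * dx + dy * dy)
      sub <- dists[yy, xx, drop = FALSE]
      upd <- D < sub
      if (any(upd)) {
        sub[upd] <- D[upd]
        dists[yy, xx] <- sub
        lsub <- labels[yy, xx, drop = FALSE]
        lsub[upd] <- i
        labels[yy, xx] <- lsub
      }
    }
    # update centers
    lv <- as.vector(labels)
    assigned <- lv > 0L
    feats <- cbind(as.vector(L), as.vector(a), as.vector(b),
                   rep(seq_len(w), each = h), rep(seq_len(h), times = w))
    sums <- rowsum(feats[assigned, , drop = FALSE], lv[assigned])
    cnt <- as.vector(rowsum(rep(1, sum(assigned)), lv[assigned]))
    ids <- as.integer(rownames(sums))
    cf[ids, ] <- sums / cnt
  }
  # unassigned pixels (possible when centers do not cover a margin): nearest center spatially
  if (any(labels == 0L)) {
    idx <- which(labels == 0L)
    uy <- ((idx - 1L) %% h) + 1L; ux <- ((idx - 1L) %/% h) + 1L
    for (j in seq_along(idx)) {
      d2 <- (cf[, 4L] - ux[j])^2 + (cf[, 5L] - uy[j])^2
      labels[idx[j]] <- which.min(d2)
    }
  }
  labels
}

# Boundary pixels of a label map: label differs from any 4-neighbor.
label_boundaries <- function(labels) {
  (labels != shift_mat(labels, 0L, 1L)) | (labels != shift_mat(labels, 0L, -1L)) |
    (labels != shift_mat(labels, 1L, 0L)) | (labels != shift_mat(labels, -1L, 0L))
}

#' Superpixel-boundary restriction mask for the seam
#'
#' SLIC is run on the pixel mean of the two aligned overlap images (or on
#' each separately with `boundary_union`); the boundaries of the label map
#' are dilated with a square structuring element and intersected with the
#' both-covered validity mask.
#'
#' @param refOverlap,warpOverlap RGB overlap crops of the reference and
#'   warped images (equal size).
#' @param cfg A [seam_config()].
#' @param valid Logical matrix of both-covered pixels (default all).
#' @return Logical `H x W` mask (`TRUE` = seam allowed).
#' @export
superpixel_boundary_mask <- function(refOverlap, warpOverlap,
                                     cfg = seam_config(), valid = NULL) {
  d <- dim(refOverlap)[1:2]
  if (is.null(valid)) valid <- matrix(TRUE, d[1L], d[2L])
  if (!any(valid)) empty_overlap_error()
  fill_invalid <- function(img) {
    for (c in 1:3) {
      pl <- img[, , c]
      m <- mean(pl[valid])
      pl[!valid] <- m
      img[, , c] <- pl
    }
    img
  }
  if (cfg$boundary_union) {
    bm <- label_boundaries(slic_segment(fill_invalid(refOverlap), cfg$slic_region_size,
                                        cfg$slic_compactness, cfg$slic_iterations)) |
      label_boundaries(slic_segment(fill_invalid(warpOverlap), cfg$slic_region_size,
                                    cfg$slic_compactness, cfg$slic_iterations))
  } else {
    avg <- fill_invalid((refOverlap + warpOverlap) / 2)
    bm <- label_boundaries(slic_segment(avg, cfg$slic_region_size,
                                        cfg$slic_compactness, cfg$slic_iterations))
  }
  dil <- max_filter(bm * 1, cfg$dilation) > 0
  dil & valid
}

#' Hue difference of two aligned images
#'
#' Absolute difference of HSV hue (normalized to `[0, 1)`); the circular
#' option measures the shorter way around the hue circle.
#'
#' @param refOverlap,warpOverlap RGB overlap crops.
#' @param circular Use circular hue distance.
#' @return `H x W` matrix.
#' @export
hue_difference <- function(refOverlap, warpOverlap, circular = FALSE) {
  hA <- rgb_to_hsv_img(refOverlap)[, , 1L]
  hB <- rgb_to_hsv_img(warpOverlap)[, , 1L]
  d <- abs(hA - hB)
  if (circular) d <- pmin(d, 1 - d)
  d
}

# Center-weighted neighborhood kernel of the intensity term: center 8,
# surround 1, normalizer N = 16 (a constant difference yields |delta|).
eint_weights <- function() matrix(c(1, 1, 1, 1, 8, 1, 1, 1, 1), 3L, 3L)

#' Neighborhood-weighted intensity difference
#'
#' `Eint(u,v) = (1/N) sum_{(i,j)} |VA(u+i, v+j) - VB(u,v)| F(i,j)` over the
#' 3x3 neighborhood with the center-weighted kernel F (center 8, surround 1,
#' N = 16), borders replicated. Intensity is the HSV value channel.
#'
#' @param refOverlap,warpOverlap RGB overlap crops.
#' @return `H x W` matrix.
#' @export
intensity_difference <- function(refOverlap, warpOverlap) {
  VA <- rgb_to_hsv_img(refOverlap)[, , 3L]
  VB <- rgb_to_hsv_img(warpOverlap)[, , 3L]
  FW <- eint_weights()
  out <- 0
  for (i in -1:1) for (j in -1:1)
    out <- out + FW[i + 2L, j + 2L] * abs(shift_mat(VA, i, j) - VB)
  out / sum(FW)
}

#' Scharr gradient difference
#'
#' `Estr = (VA * SU - VB * SU)^2 + (VA * SV - VB * SV)^2` with the standard
#' 3x3 Scharr kernels, replicate borders, on the HSV value channel. Returned
#' unnormalized; [energy_map()] min-max normalizes each term.
#'
#' @param refOverlap,warpOverlap RGB overlap crops.
#' @return `H x W` matrix (nonnegative).
#' @export
gradient_difference <- function(refOverlap, warpOverlap) {
  VA <- rgb_to_hsv_img(refOverlap)[, , 3L]
  VB <- rgb_to_hsv_img(warpOverlap)[, , 3L]
  SU <- scharr_u(); SV <- scharr_v()
  du <- conv3(VA, SU) - conv3(VB, SU)
  dv <- conv3(VA, SV) - conv3(VB, SV)
  du * du + dv * dv
}

norm01_over <- function(x, valid) {
  v <- x[valid]
  rng <- range(v)
  if (!is.finite(diff(rng)) || diff(rng) < 1e-15) return(x * 0)
  (x - rng[1L]) / diff(rng)
}

#' Seam energy map
#'
#' Weighted combination `alpha * Ehue + beta * Eint^2 + gamma * Estr`, each
#' term min-max normalized to `[0, 1]` over the valid overlap first. Pixels
#' outside the validity mask or the restriction mask are set to `+Inf`.
#' The raw terms are attached as attributes `Ehue`, `Eint`, `Estr`.
#'
#' @param refOverlap,warpOverlap RGB overlap crops.
#' @param cfg A [seam_config()].
#' @param restricted Optional logical restriction mask (seam allowed).
#' @param valid Optional logical both-covered mask.
#' @return `H x W` numeric matrix with `+Inf` entries where the seam may not
#'   pass.
#' @export
energy_map <- function(refOverlap, warpOverlap, cfg = seam_config(),
                       restricted = NULL, valid = NULL) {
  d <- dim(refOverlap)[1:2]
  if (!identical(d, dim(warpOverlap)[1:2])) stop("overlap crops must share a shape")
  if (is.null(valid)) valid <- matrix(TRUE, d[1L], d[2L])
  if (!any(valid)) empty_overlap_error()
  eh <- hue_difference(refOverlap, warpOverlap, cfg$hue_circular)
  ei <- intensity_difference(refOverlap, warpOverlap)
  es <- gradient_difference(refOverlap, warpOverlap)
  E <- cfg$alpha_w * norm01_over(eh, valid) +
    cfg$beta_w * norm01_over(ei, valid)^2 +
    cfg$gamma_w * norm01_over(es, valid)
  E[!valid] <- Inf
  if (!is.null(restricted)) E[!restricted] <- Inf
  attr(E, "Ehue") <- eh
  attr(E, "Eint") <- ei
  attr(E, "Estr") <- es
  E
}

#' Dynamic-programming optimal seam
#'
#' Cumulative energy `Eacc(u,v) = min_{|k-v| <= rV} Eacc(u-1,k) + E(u,v)`
#' from the first to the last row; the terminal column is the argmin of the
#' last row and the path is traced back through the window argmins. Ties
#' break to the smallest column. The returned path attains the global
#' minimum cumulative energy among all rV-connected row-monotone paths.
#'
#' @param E Energy matrix (`+Inf` marks forbidden pixels).
#' @param rV Connectivity bound.
#' @return Object of class `seam`: `tr` (seam column per row, 1-based),
#'   `rV`, `cost`, `transposed = FALSE`; or `NULL` when no finite-cost path
#'   reaches the last row.
#' @export
dp_seam <- function(E, rV = 1L) {
  h <- nrow(E); w <- ncol(E)
  rV <- as.integer(rV)
  if (!any(is.finite(E[1L, ]))) return(NULL)
  acc <- matrix(Inf, h, w)
  acc[1L, ] <- E[1L, ]
  if (h > 1L) for (u in 2L:h) {
    prev <- acc[u - 1L, ]
    wmin <- prev
    for (o in seq_len(rV)) {
      wmin <- pmin(wmin,
                   c(prev[-seq_len(o)], rep(Inf, o)),      # shift left by o
                   c(rep(Inf, o), prev[seq_len(w - o)]))   # shift right by o
    }
    acc[u, ] <- wmin + E[u, ]
  }
  if (!any(is.finite(acc[h, ]))) return(NULL)
  tr <- integer(h)
  tr[h] <- which.min(acc[h, ])
  if (h > 1L) for (u in (h - 1L):1L) {
    ks <- max(1L, tr[u + 1L] - rV):min(w, tr[u + 1L] + rV)
    tr[u] <- ks[which.min(acc[u, ks])]
  }
  structure(list(tr = tr, rV = rV, cost = acc[h, tr[h]], transposed = FALSE),
            class = "seam")
}

#' Find the restricted optimal seam in an overlap
#'
#' Builds the superpixel restriction mask and energy, and runs [dp_seam()].
#' If the overlap box is wider than tall the problem is transposed so the
#' seam crosses its short direction. If no feasible restricted path exists,
#' the restriction is lifted with a warning.
#'
#' @param refOverlap,warpOverlap RGB overlap crops.
#' @param valid Logical both-covered mask.
#' @param cfg A [seam_config()].
#' @return A `seam` object (`transposed` records the orientation).
#' @export
find_seam <- function(refOverlap, warpOverlap, valid = NULL, cfg = seam_config()) {
  d <- dim(refOverlap)[1:2]
  if (is.null(valid)) valid <- matrix(TRUE, d[1L], d[2L])
  transposed <- d[2L] > d[1L]
  if (transposed) {
    refOverlap <- aperm(refOverlap, c(2L, 1L, 3L))
    warpOverlap <- aperm(warpOverlap, c(2L, 1L, 3L))
    valid <- t(valid)
  }
  mask <- superpixel_boundary_mask(refOverlap, warpOverlap, cfg, valid)
  if (!any(mask)) mask <- NULL
  E <- energy_map(refOverlap, warpOverlap, cfg, restricted = mask, valid = valid)
  s <- dp_seam(E, cfg$rV)
  if (is.null(s)) {
    warning("no feasible restricted seam; lifting the superpixel restriction")
    E <- energy_map(refOverlap, warpOverlap, cfg, restricted = NULL, valid = valid)
    s <- dp_seam(E, cfg$rV)
    if (is.null(s)) stop("no feasible seam path through the overlap")
  }
  s$transposed <- transposed
  s
}

#' Seam label mask
#'
#' Logical mask over the overlap, `TRUE` on and left of the seam column per
#' row (top of the seam row per column for transposed seams): the side that
#' takes the reference image in the composite.
#'
#' @param seam A `seam`.
#' @param overlapShape `c(height, width)` of the (untransposed) overlap.
#' @return Logical matrix.
#' @export
seam_to_label_mask <- function(seam, overlapShape) {
  h <- overlapShape[1L]; w <- overlapShape[2L]
  if (isTRUE(seam$transposed)) {
    m <- matrix(seq_len(h), w, h, byrow = TRUE) <= seam$tr  # in transposed frame
    t(m)
  } else {
    matrix(seq_len(w), h, w, byrow = TRUE) <= seam$tr
  }
}

#' Write a seam polyline to CSV
#'
#' Two columns `row,col`, 0-based, in the untransposed overlap frame.
#'
#' @param seam A `seam`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_seam_csv <- function(seam, path) {
  if (isTRUE(seam$transposed)) {
    df <- data.frame(row = seam$tr - 1L, col = seq_along(seam$tr) - 1L)
  } else {
    df <- data.frame(row = seq_along(seam$tr) - 1L, col = seam$tr - 1L)
  }
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
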