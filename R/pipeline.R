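# Pipeline orchestration: enhance -> register -> seam -> fuse, plus
# evaluation metrics and configuration I/O.

#' Pipeline configuration
#'
#' Nested configuration of all stitching stages.
#'
#' @param enhancement An [enhancement_config()].
#' @param seam A [seam_config()].
#' @param registration List of registration parameters: `warp`
#'   ("similarity" or "projective"), `ratio` (2-NN ratio test),
#'   `ransac_threshold` (px), `ransac_max_iter`, `min_matches`,
#'   `min_inliers`, `max_points`, `detect_threshold`,
#'   `match_on_enhanced` (match features on enhanced images, the default,
#'   or on the originals).
#' @param fusion List: `alpha` (stripe half-width, px), `levels` (pyramid
#'   levels), `replace_half_stripe` (replace only an `alpha`-wide central
#'   band instead of the full `2*alpha` stripe), `enabled`.
#' @param reference `"middle"` or the index of the reference frame.
#' @param seed Integer seed for all stochastic steps (RANSAC).
#' @param enhance Run the underwater enhancement before registration.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(enhancement = enhancement_config(),
                            seam = seam_config(),
                            registration = list(),
                            fusion = list(),
                            reference = "middle",
                            seed = 42L,
                            enhance = TRUE) {
  reg_def <- list(warp = "similarity", ratio = 0.75, ransac_threshold = 3,
                  ransac_max_iter = 2000L, min_matches = 8L, min_inliers = 6L,
                  max_points = 500L, detect_threshold = 3e-7,
                  match_on_enhanced = TRUE)
  fus_def <- list(alpha = 30L, levels = 3L, replace_half_stripe = FALSE,
                  enabled = TRUE)
  bad <- setdiff(names(registration), names(reg_def))
  if (length(bad)) stop("unknown registration option(s): ", paste(bad, collapse = ", "))
  bad <- setdiff(names(fusion), names(fus_def))
  if (length(bad)) stop("unknown fusion option(s): ", paste(bad, collapse = ", "))
  reg <- utils::modifyList(reg_def, registration)
  fus <- utils::modifyList(fus_def, fusion)
  if (!reg$warp %in% c("similarity", "projective"))
    stop("registration$warp must be 'similarity' or 'projective'")
  structure(list(enhancement = enhancement, seam = seam, registration = reg,
                 fusion = fus, reference = reference,
                 seed = as.integer(seed), enhance = isTRUE(enhance)),
            class = "pipeline_config")
}

config_to_list <- function(cfg) {
  strip <- function(x) {
    if (is.list(x)) return(lapply(unclass(x), strip))
    if (!is.null(names(x)) && length(x) > 1L) as.list(x) else x
  }
  strip(cfg)
}

list_to_config <- function(x) {
  known <- names(config_to_list(pipeline_config()))
  bad <- setdiff(names(x), known)
  if (length(bad)) stop("unknown configuration key(s): ", paste(bad, collapse = ", "))
  args <- list()
  if (!is.null(x$enhancement)) {
    defaults <- enhancement_config()
    bad <- setdiff(names(x$enhancement), names(unclass(defaults)))
    if (length(bad)) stop("unknown enhancement option(s): ", paste(bad, collapse = ", "))
    enh <- x$enhancement
    if (!is.null(enh$wavelengths)) enh$wavelengths <- unlist(enh$wavelengths)
    args$enhancement <- do.call(enhancement_config, enh)
  }
  if (!is.null(x$seam)) {
    defaults <- seam_config()
    bad <- setdiff(names(x$seam), names(unclass(defaults)))
    if (length(bad)) stop("unknown seam option(s): ", paste(bad, collapse = ", "))
    args$seam <- do.call(seam_config, x$seam)
  }
  if (!is.null(x$registration)) args$registration <- x$registration
  if (!is.null(x$fusion)) args$fusion <- x$fusion
  if (!is.null(x$reference)) args$reference <- x$reference
  if (!is.null(x$seed)) args$seed <- x$seed
  if (!is.null(x$enhance)) args$enhance <- x$enhance
  do.call(pipeline_config, args)
}

#' Read / write a pipeline configuration
#'
#' YAML (canonical) or JSON, chosen from the file extension. Unknown keys
#' are rejected.
#'
#' @param path File path ending in `.yaml`, `.yml` or `.json`.
#' @return `read_pipeline_config`: a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  x <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  list_to_config(x)
}

#' @rdname read_pipeline_config
#' @param cfg A `pipeline_config`.
#' @export
write_pipeline_config <- function(cfg, path) {
  x <- config_to_list(cfg)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  } else {
    yaml::write_yaml(x, path)
  }
  invisible(path)
}

#' Peak signal-to-noise ratio
#'
#' `20 log10(1 / sqrt(MSE))` for float images on `[0, 1]`; identical inputs
#' give `Inf`.
#'
#' @param a,b Numeric arrays of equal size.
#' @return PSNR in dB.
#' @export
psnr <- function(a, b) {
  if (!identical(dim(a), dim(b))) stop("inputs must share a shape")
  mse <- mean((a - b)^2)
  if (mse == 0) return(Inf)
  20 * log10(1 / sqrt(mse))
}

#' Histogram mutual information
#'
#' MI (base-2) of the joint gray-level histogram of the two images.
#'
#' @param a,b RGB images or matrices of equal pixel count (converted to
#'   luminance).
#' @param bins Number of histogram bins per image (default 64).
#' @return Mutual information in bits.
#' @export
mutual_information <- function(a, b, bins = 64L) {
  x <- as.vector(as_gray(a)); y <- as.vector(as_gray(b))
  if (length(x) != length(y)) stop("inputs must have equal pixel counts")
  bx <- pmin(floor(clamp01(x) * bins) + 1L, bins)
  by <- pmin(floor(clamp01(y) * bins) + 1L, bins)
  counts <- tabulate((by - 1L) * bins + bx, nbins = bins * bins)
  p <- matrix(counts / length(x), bins, bins)
  px <- rowSums(p); py <- colSums(p)
  nz <- p > 0
  sum(p[nz] * log2(p[nz] / (px[row(p)[nz]] * py[col(p)[nz]])))
}

# Chain pairwise warps (H[[j]] maps image j+1 into image j's frame) into the
# reference frame: returns list of H_{ref <- j}.
chain_warps <- function(pair_H, ref, n) {
  out <- vector("list", n)
  out[[ref]] <- diag(3)
  if (ref < n) for (j in (ref + 1L):n) out[[j]] <- out[[j - 1L]] %*% pair_H[[j - 1L]]
  if (ref > 1L) for (j in (ref - 1L):1L) out[[j]] <- out[[j + 1L]] %*% solve(pair_H[[j]])
  out
}

#' Composite a warped image onto the mosaic canvas
#'
#' One post-processing step of the stitching pipeline: finds the
#' superpixel-restricted optimal seam in the overlap of the accumulated
#' mosaic and an incoming warped image, composites the two on opposite
#' sides of the seam, and (optionally) Laplacian-blends the stripe around
#' the seam and merges it back. Exposed so that fused and unfused
#' composites can be compared directly.
#'
#' @param acc_img,acc_mask Accumulated canvas image and validity mask.
#' @param new_img,new_mask Incoming warped image and mask (same canvas).
#' @param cfg A [pipeline_config()].
#' @return List: `image` (composite after fusion), `unfused` (hard seam
#'   composite), `mask`, `seam`, `roi` (canvas-sized logical stripe mask,
#'   all-`FALSE` when fusion is disabled), `seam_cost`, and the
#'   fused-vs-unfused `psnr`/`mi` diagnostics within the stripe.
#' @export
composite_pair <- function(acc_img, acc_mask, new_img, new_mask, cfg = pipeline_config()) {
  ov <- overlap_region(acc_mask, new_mask)
  rr <- ov$u; cc <- ov$v
  ref_crop <- acc_img[rr[1L]:rr[2L], cc[1L]:cc[2L], , drop = FALSE]
  new_crop <- new_img[rr[1L]:rr[2L], cc[1L]:cc[2L], , drop = FALSE]
  valid <- ov$both
  # fill single-covered pixels with the other image for energy/blending
  ref_f <- ref_crop; new_f <- new_crop
  for (c in 1:3) {
    rp <- ref_f[, , c]; np <- new_f[, , c]
    rp[!ov$maskA] <- np[!ov$maskA]
    np[!ov$maskB] <- ref_f[, , c][!ov$maskB]
    ref_f[, , c] <- rp; new_f[, , c] <- np
  }
  seam <- find_seam(ref_f, new_f, valid, cfg$seam)
  lm <- seam_to_label_mask(seam, dim(valid))
  # which side of the seam keeps the accumulated image: the side where its
  # exclusive coverage lies
  acc_only <- acc_mask & !new_mask
  new_only <- new_mask & !acc_mask
  coord <- if (isTRUE(seam$transposed)) row(acc_mask) else col(acc_mask)
  ca <- if (any(acc_only)) mean(coord[acc_only]) else NA_real_
  cb <- if (any(new_only)) mean(coord[new_only]) else NA_real_
  acc_takes_true <- is.na(ca) || is.na(cb) || ca <= cb
  side_acc <- if (acc_takes_true) lm else !lm
  # hard seam composite over the full canvas
  side_full <- matrix(FALSE, nrow(acc_mask), ncol(acc_mask))
  side_full[rr[1L]:rr[2L], cc[1L]:cc[2L]] <- side_acc
  both_full <- matrix(FALSE, nrow(acc_mask), ncol(acc_mask))
  both_full[rr[1L]:rr[2L], cc[1L]:cc[2L]] <- valid
  take_acc <- acc_only | (both_full & side_full)
  out <- new_img
  for (c in 1:3) {
    pl <- out[, , c]; ap <- acc_img[, , c]
    pl[take_acc] <- ap[take_acc]
    out[, , c] <- pl
  }
  out_mask <- acc_mask | new_mask
  unfused <- out
  roi_full <- matrix(FALSE, nrow(acc_mask), ncol(acc_mask))
  diag_psnr <- NA_real_; diag_mi <- NA_real_
  if (isTRUE(cfg$fusion$enabled)) {
    alpha <- cfg$fusion$alpha
    roi <- seam_stripe_roi(seam, dim(valid), alpha)
    roi <- roi & (ov$maskA | ov$maskB)
    roi_rep <- if (isTRUE(cfg$fusion$replace_half_stripe)) {
      seam_stripe_roi(seam, dim(valid), max(1L, floor(alpha / 2))) & roi
    } else roi
    blended <- blend_stripe(ref_f, new_f, side_acc, cfg$fusion$levels)
    unfused_crop <- out[rr[1L]:rr[2L], cc[1L]:cc[2L], , drop = FALSE]
    merged_crop <- merge_panorama(unfused_crop, clamp01(blended), roi_rep)
    if (any(roi_rep)) {
      sel <- function(img) sapply(1:3, function(c) img[, , c][roi_rep])
      fa <- sel(merged_crop); fb <- sel(unfused_crop)
      diag_psnr <- psnr(fa, fb)
      diag_mi <- mutual_information(matrix(rowMeans(fa), ncol = 1L),
                                    matrix(rowMeans(fb), ncol = 1L))
    }
    out[rr[1L]:rr[2L], cc[1L]:cc[2L], ] <- merged_crop
    roi_full[rr[1L]:rr[2L], cc[1L]:cc[2L]] <- roi_rep
  }
  list(image = out, unfused = unfused, mask = out_mask, seam = seam,
       roi = roi_full, seam_cost = seam$cost,
       fused_vs_unfused_psnr = diag_psnr, fused_vs_unfused_mi = diag_mi)
}

#' Stitch an image sequence into a mosaic
#'
#' Full pipeline: optional enhancement of every frame, pairwise feature
#' registration between consecutive frames, chaining of warps onto the
#' reference frame (middle frame by default), canvas layout, and sequential
#' compositing of each frame through a superpixel-restricted optimal seam
#' with stripe-confined Laplacian fusion. Deterministic for a fixed
#' configuration and seed.
#'
#' @param images List of RGB image arrays (or file paths).
#' @param cfg A [pipeline_config()].
#' @return Object of class `mosaic_result`: `panorama`, `mask`, `layout`,
#'   `warps` (canvas-frame `planar_warp` per image), `diagnostics` (one row
#'   per stitched pair), `config`.
#' @export
stitch_sequence <- function(images, cfg = pipeline_config()) {
  if (is.character(images)) images <- as.list(images)
  images <- lapply(images, function(x) if (is.character(x)) load_image(x) else x)
  n <- length(images)
  if (n < 2L) stop("need at least two images")
  lapply(images, check_rgb_image)
  work <- if (cfg$enhance) lapply(images, enhance, cfg = cfg$enhancement) else images
  match_imgs <- if (cfg$registration$match_on_enhanced) work else images
  reg <- cfg$registration
  pair_H <- vector("list", n - 1L)
  match_counts <- integer(n - 1L); inlier_counts <- integer(n - 1L)
  for (j in seq_len(n - 1L)) {
    ms <- detect_and_match(match_imgs[[j]], match_imgs[[j + 1L]],
                           ratio = reg$ratio, kind = reg$warp,
                           ransac_threshold = reg$ransac_threshold,
                           ransac_max_iter = reg$ransac_max_iter,
                           seed = cfg$seed + 7919L * j,
                           min_matches = reg$min_matches,
                           min_inliers = reg$min_inliers,
                           max_points = reg$max_points,
                           detect_threshold = reg$detect_threshold,
                           pair = sprintf("%d-%d", j, j + 1L))
    match_counts[j] <- nrow(ms)
    inlier_counts[j] <- sum(ms$inlier)
    pair_H[[j]] <- estimate_warp(ms, reg$warp)$H
  }
  ref <- if (identical(cfg$reference, "middle")) (n + 1L) %/% 2L
         else as.integer(cfg$reference)
  chained <- chain_warps(pair_H, ref, n)
  warps <- lapply(chained, planar_warp, kind = reg$warp)
  layout <- canvas_layout(warps, lapply(images, function(im) dim(im)[1:2]))
  order_idx <- order(abs(seq_len(n) - ref))
  w0 <- warp_to_canvas(work[[ref]], layout$warps[[ref]], layout)
  acc <- w0$image; acc_mask <- w0$mask
  diags <- list()
  for (j in order_idx[-1L]) {
    wj <- warp_to_canvas(work[[j]], layout$warps[[j]], layout)
    cp <- tryCatch(composite_pair(acc, acc_mask, wj$image, wj$mask, cfg),
                   uwmosaic_empty_overlap = function(e)
                     stop(sprintf("image %d does not overlap the mosaic", j)))
    acc <- cp$image; acc_mask <- cp$mask
    diags[[length(diags) + 1L]] <- data.frame(
      image = j, seam_cost = cp$seam_cost,
      fused_vs_unfused_psnr = cp$fused_vs_unfused_psnr,
      fused_vs_unfused_mi = cp$fused_vs_unfused_mi)
  }
  pair_diag <- data.frame(pair = seq_len(n - 1L), matches = match_counts,
                          inliers = inlier_counts)
  structure(list(panorama = acc, mask = acc_mask, layout = layout,
                 warps = layout$warps, reference = ref,
                 diagnostics = list(pairs = pair_diag,
                                    composites = do.call(rbind, diags)),
                 config = cfg),
            class = "mosaic_result")
}

#' @export
print.mosaic_result <- function(x, ...) {
  d <- dim(x$panorama)
  cat(sprintf("uwmosaic mosaic: %d x %d px, reference frame %d\n",
              d[2L], d[1L], x$reference))
  cat(sprintf("  coverage: %.1f%% of canvas\n", 100 * mean(x$mask)))
  p <- x$diagnostics$pairs
  cat(sprintf("  pairs: %s matches (%s inliers)\n",
              paste(p$matches, collapse = "/"),
              paste(p$inliers, collapse = "/")))
  invisible(x)
}

#' Feature-match counts under different preprocessing modes
#'
#' For each consecutive pair, the number of ratio-test matches and RANSAC
#' inliers with no preprocessing, with the classic dark-channel baseline,
#' and with the attenuation-aware enhancement. Registration failures are
#' reported as zero counts.
#'
#' @param images List of RGB image arrays.
#' @param cfg A [pipeline_config()].
#' @return Data frame with columns `pair`, `mode`, `matches`, `inliers`.
#' @export
match_count_report <- function(images, cfg = pipeline_config()) {
  n <- length(images)
  if (n < 2L) stop("need at least two images")
  reg <- cfg$registration
  modes <- list(
    original = identity,
    dcp = function(im) enhance_dcp_baseline(im, cfg$enhancement),
    proposed = function(im) enhance(im, cfg$enhancement))
  rows <- list()
  for (mode in names(modes)) {
    prep <- lapply(images, modes[[mode]])
    for (j in seq_len(n - 1L)) {
      res <- tryCatch(
        detect_and_match(prep[[j]], prep[[j + 1L]], ratio = reg$ratio,
                         kind = reg$warp,
                         ransac_threshold = reg$ransac_threshold,
                         ransac_max_iter = reg$ransac_max_iter,
                         seed = cfg$seed + 7919L * j,
                         min_matches = reg$min_matches,
                         min_inliers = reg$min_inliers,
                         max_points = reg$max_points,
                         detect_threshold = reg$detect_threshold),
        uwmosaic_registration_error = function(e) NULL)
      rows[[length(rows) + 1L]] <- data.frame(
        pair = j, mode = mode,
        matches = if (is.null(res)) 0L else nrow(res),
        inliers = if (is.null(res)) 0L else sum(res$inlier))
    }
  }
  do.call(rbind, rows)
}
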