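# Independent oracles and small fixtures shared across the suite.

# Exhaustive enumeration of all rV-connected row-monotone paths; returns the
# minimum total cost. Complexity O(w * (2 rV + 1)^(h-1)); use on tiny grids.
brute_force_seam_cost <- function(E, rV = 1L) {
  h <- nrow(E); w <- ncol(E)
  paths <- matrix(seq_len(w), ncol = 1L)
  costs <- E[1L, ]
  if (h > 1L) for (u in 2L:h) {
    np <- list(); nc <- list()
    for (i in seq_len(nrow(paths))) {
      last <- paths[i, u - 1L]
      ks <- max(1L, last - rV):min(w, last + rV)
      np[[i]] <- cbind(paths[rep(i, length(ks)), , drop = FALSE], ks)
      nc[[i]] <- costs[i] + E[u, ks]
    }
    paths <- do.call(rbind, np)
    costs <- unlist(nc)
  }
  min(costs)
}

# Straight-line (naive, loop-based) recomputation of the three energy terms
# and their weighted, per-term-normalized combination.
naive_energy_map <- function(ref, wrp, alpha_w, beta_w, gamma_w,
                             circular = FALSE) {
  h <- dim(ref)[1L]; w <- dim(ref)[2L]
  cl <- function(i, n) min(max(i, 1L), n)
  hsv_of <- function(img) {
    m <- grDevices::rgb2hsv(rbind(as.vector(img[, , 1]), as.vector(img[, , 2]),
                                  as.vector(img[, , 3])), maxColorValue = 1)
    list(h = matrix(m[1, ], h, w), v = matrix(m[3, ], h, w))
  }
  A <- hsv_of(ref); B <- hsv_of(wrp)
  eh <- abs(A$h - B$h)
  if (circular) eh <- pmin(eh, 1 - eh)
  FW <- matrix(c(1, 1, 1, 1, 8, 1, 1, 1, 1), 3, 3)
  ei <- matrix(0, h, w)
  for (u in seq_len(h)) for (v in seq_len(w)) {
    s <- 0
    for (i in -1:1) for (j in -1:1)
      s <- s + FW[i + 2, j + 2] * abs(A$v[cl(u + i, h), cl(v + j, w)] - B$v[u, v])
    ei[u, v] <- s / 16
  }
  SU <- matrix(c(-3, -10, -3, 0, 0, 0, 3, 10, 3), 3, 3)
  SV <- t(SU)
  convn <- function(m, K) {
    out <- matrix(0, h, w)
    for (u in seq_len(h)) for (v in seq_len(w)) {
      s <- 0
      for (i in -1:1) for (j in -1:1)
        s <- s + K[i + 2, j + 2] * m[cl(u + i, h), cl(v + j, w)]
      out[u, v] <- s
    }
    out
  }
  es <- (convn(A$v, SU) - convn(B$v, SU))^2 + (convn(A$v, SV) - convn(B$v, SV))^2
  n01 <- function(x) {
    r <- range(x)
    if (diff(r) < 1e-15) return(x * 0)
    (x - r[1]) / diff(r)
  }
  alpha_w * n01(eh) + beta_w * n01(ei)^2 + gamma_w * n01(es)
}

# Naive O(h w k^2) minimum filter with window truncation at borders.
naive_min_filter <- function(m, k) {
  r <- (k - 1L) %/% 2L
  h <- nrow(m); w <- ncol(m)
  out <- m
  for (u in seq_len(h)) for (v in seq_len(w)) {
    out[u, v] <- min(m[max(1L, u - r):min(h, u + r), max(1L, v - r):min(w, v + r)])
  }
  out
}

# Rigid (rotation + translation, no scale) least-squares fit, for comparing
# against the similarity fit. Kabsch on 2-D points.
rigid_fit_residual <- function(xB, yB, xA, yA) {
  PB <- cbind(xB, yB); PA <- cbind(xA, yA)
  cb <- colMeans(PB); ca <- colMeans(PA)
  Qb <- sweep(PB, 2, cb); Qa <- sweep(PA, 2, ca)
  sv <- svd(t(Qb) %*% Qa)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, d)) %*% t(sv$u)
  pred <- sweep(Qb %*% t(R), 2, ca, "+")
  sqrt(mean(rowSums((pred - PA)^2)))
}

# Constant-color image helper.
const_img <- function(h, w, rgb) {
  array(rep(rgb, each = h * w), dim = c(h, w, 3L))
}

default_A <- c(R = 0.25, G = 0.55, B = 0.70)

# Mean ground-truth grid reprojection error (px) of a stitched survey.
survey_reproj_error <- function(sv, mr) {
  n <- length(sv$views); ref <- mr$reference
  grid <- as.matrix(expand.grid(x = seq(20, sv$view_size[2L] - 20, by = 40),
                                y = seq(20, sv$view_size[1L] - 20, by = 40)))
  mean(sapply(seq_len(n), function(j) {
    G <- solve(sv$views[[ref]]$warp$H) %*% sv$views[[j]]$warp$H
    Hc <- solve(mr$warps[[ref]]$H) %*% mr$warps[[j]]$H
    mean(sqrt(rowSums((apply_warp(G, grid) - apply_warp(Hc, grid))^2)))
  }))
}
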