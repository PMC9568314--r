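# Independent reference implementations used as oracles. These deliberately
# use slow, literal formulations (loops, pair counting, per-pixel
# inequalities) and never call the code paths they check.

# Exhaustive between-class variance scan; smallest maximizing t.
oracle_otsu <- function(p, levels = seq_along(p) - 1L) {
  G <- max(levels)
  best_t <- NA_integer_
  best_v <- -Inf
  for (t in levels[levels < G]) {
    in0 <- levels <= t
    P0 <- sum(p[in0])
    P1 <- 1 - P0
    if (P0 <= 0 || P1 <= 0) next
    mu0 <- sum(p[in0] * levels[in0]) / P0
    mu1 <- sum(p[!in0] * levels[!in0]) / P1
    v <- P0 * P1 * (mu0 - mu1)^2
    if (v > best_v + 1e-15) {
      best_v <- v
      best_t <- t
    }
  }
  best_t
}

# Mann-Whitney pair counting with ties counted half.
oracle_auc <- function(scores, labels, positive = 1) {
  sp <- scores[labels == positive]
  sn <- scores[labels != positive]
  total <- 0
  for (a in sp) {
    total <- total + sum(a > sn) + 0.5 * sum(a == sn)
  }
  total / (length(sp) * length(sn))
}

# 90-degree counter-clockwise rotation of a square matrix as a pure index
# permutation: out[i, j] = m[j, n + 1 - i].
oracle_rot90_ccw <- function(m) {
  n <- nrow(m)
  out <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      out[i, j] <- m[j, n + 1 - i]
    }
  }
  out
}

# Slow per-pixel inverse-mapped bilinear rotation about the image center
# (0-based pixel centers, y axis up), fill value for out-of-frame samples.
oracle_rotate_bilinear <- function(img, theta_deg, fill = 0) {
  h <- nrow(img)
  w <- ncol(img)
  cy <- (h - 1) / 2
  cx <- (w - 1) / 2
  th <- theta_deg * pi / 180
  out <- matrix(fill, h, w)
  for (r in 0:(h - 1)) {
    for (c in 0:(w - 1)) {
      x <- c - cx
      y <- -(r - cy)
      xs <- cos(th) * x + sin(th) * y
      ys <- -sin(th) * x + cos(th) * y
      sc <- xs + cx
      sr <- cy - ys
      if (sr >= 0 && sr <= h - 1 && sc >= 0 && sc <= w - 1) {
        r0 <- min(floor(sr), h - 2)
        c0 <- min(floor(sc), w - 2)
        fr <- sr - r0
        fc <- sc - c0
        out[r + 1, c + 1] <-
          (1 - fr) * ((1 - fc) * img[r0 + 1, c0 + 1] + fc * img[r0 + 1, c0 + 2]) +
          fr * ((1 - fc) * img[r0 + 2, c0 + 1] + fc * img[r0 + 2, c0 + 2])
      }
    }
  }
  out
}

# Per-pixel annulus membership at pixel centers, 0-based coordinates.
oracle_annulus_mask <- function(h, w, center, r, width) {
  out <- matrix(FALSE, h, w)
  for (i in 0:(h - 1)) {
    for (j in 0:(w - 1)) {
      d2 <- (i - center[1])^2 + (j - center[2])^2
      out[i + 1, j + 1] <- d2 >= (r - width / 2)^2 && d2 <= (r + width / 2)^2
    }
  }
  out
}

# Per-pixel ellipse membership at pixel centers, 0-based coordinates,
# fractional center/axes as used by phantom_spec.
oracle_ellipse_count <- function(h, w, center_frac, axes_frac) {
  cy <- center_frac[1] * (h - 1)
  cx <- center_frac[2] * (w - 1)
  ay <- axes_frac[1] * h
  ax <- axes_frac[2] * w
  n <- 0L
  for (i in 0:(h - 1)) {
    for (j in 0:(w - 1)) {
      if (((i - cy) / ay)^2 + ((j - cx) / ax)^2 <= 1) n <- n + 1L
    }
  }
  n
}

random_image <- function(h, w, seed) {
  set.seed(seed)
  matrix(runif(h * w), h, w)
}

# Small labeled feature tibble built directly from 2-D points.
points_to_features <- function(pts, labels) {
  tibble::tibble(
    source_id = sprintf("p%02d", seq_len(nrow(pts))),
    label = labels,
    sv01 = pts[, 1],
    sv02 = pts[, 2]
  )
}
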