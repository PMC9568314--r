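#' Convert an RGB image to grayscale (NTSC luma weights)
#'
#' Applies the NTSC luminance formula `0.299 R + 0.587 G + 0.114 B`
#' per pixel. Channels on a 0-255 integer scale are detected (any value
#' above 1) and the result is normalized back to the unit interval; unit-
#' scale input passes through the same weights unchanged.
#'
#' @param img Numeric `H x W x 3` array (channels R, G, B).
#' @return An `H x W` matrix in `[0, 1]`.
#' @examples
#' px <- array(c(255, 0, 0), dim = c(1, 1, 3))
#' rgb_to_gray(px) * 255  # 0.299 * 255 = 76.245
#' @export
rgb_to_gray <- function(img) {
  if (!is.array(img) || length(dim(img)) != 3L || dim(img)[3] != 3L) {
    abort("`img` must be an H x W x 3 array.")
  }
  if (!all(is.finite(img))) abort("`img` contains non-finite values.")
  gray <- matrix(0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3],
                 nrow = dim(img)[1], ncol = dim(img)[2])
  if (max(img) > 1) gray <- gray / 255
  clip01(gray)
}

#' Gray-level histogram of an image
#'
#' Quantizes unit-scale intensities to integer gray levels `0..max_level`
#' and tallies their empirical probabilities, the form consumed by
#' [otsu_threshold()].
#'
#' @param img Grayscale matrix in `[0, 1]`.
#' @param max_level Maximum gray level G (default 255).
#' @return An object of class `gray_histogram`: list with `p` (probabilities
#'   summing to 1) and `levels` (`0:max_level`).
#' @export
gray_histogram <- function(img, max_level = 255L) {
  check_gray_image(img)
  check_scalar(max_level, "max_level", lower = 1, integerish = TRUE)
  g <- round(img * max_level)
  counts <- tabulate(g + 1L, nbins = max_level + 1L)
  structure(
    list(p = counts / sum(counts), levels = 0:max_level),
    class = "gray_histogram"
  )
}

#' Otsu's threshold from a gray-level histogram
#'
#' Picks the gray level `t` that maximizes the between-class variance
#' of the two segments `g <= t` (mass `P0(t)`) and `g > t` (mass
#' `P1(t) = 1 - P0(t)`) — equivalently, makes the spread within each
#' segment as small as possible. Ties are broken toward the smallest
#' maximizing `t`, which makes the result deterministic and directly
#' comparable to an exhaustive search.
#'
#' @param hist A [gray_histogram()], or a grayscale matrix (quantized to
#'   255 levels internally).
#' @return Integer threshold `t` on the gray-level scale; pixels with level
#'   `> t` form the bright class.
#' @export
otsu_threshold <- function(hist) {
  if (is.matrix(hist)) hist <- gray_histogram(hist)
  if (!inherits(hist, "gray_histogram")) {
    abort("`hist` must be a gray_histogram or a grayscale matrix.")
  }
  p <- hist$p
  if (any(p < 0) || abs(sum(p) - 1) > 1e-9) {
    abort("histogram probabilities must be non-negative and sum to 1.")
  }
  if (sum(p > 0) < 2L) {
    abort("degenerate histogram: need at least two gray levels with mass.")
  }
  g <- hist$levels
  G <- max(g)
  # cumulative class mass and class means over candidate thresholds t < G
  P0 <- cumsum(p)
  mu_cum <- cumsum(p * g)
  mu_T <- mu_cum[length(mu_cum)]
  t_cand <- seq_len(length(g) - 1L)            # indices of t = 0..G-1
  P0t <- P0[t_cand]
  P1t <- 1 - P0t
  num <- (mu_T * P0t - mu_cum[t_cand])^2
  sigma_b <- ifelse(P0t > 0 & P1t > 0, num / (P0t * P1t), 0)
  best <- which(sigma_b >= max(sigma_b) - 1e-15)[1L]
  g[best]
}

# Unit-scale Otsu threshold of an image (t / max_level).
otsu_threshold_unit <- function(img, max_level = 255L) {
  otsu_threshold(gray_histogram(img, max_level)) / max_level
}

#' Specify a patient-motion (rotation) artifact
#'
#' Patient movement between projections is emulated as an in-plane rotation
#' of the reconstructed slice by the 2-D rotation matrix
#' `[[cos t, -sin t], [sin t, cos t]]`, applied by inverse mapping about the
#' image center.
#'
#' @param theta Rotation angle in degrees; positive is counter-clockwise in
#'   standard orientation.
#' @param interpolation `"bilinear"` (default) or `"nearest"`.
#' @param fill_value Intensity for samples falling outside the frame
#'   (default 0, the dark CT background).
#' @return An object of class `motion_spec`.
#' @export
motion_spec <- function(theta, interpolation = c("bilinear", "nearest"),
                        fill_value = 0) {
  check_scalar(theta, "theta")
  check_scalar(fill_value, "fill_value", lower = 0, upper = 1)
  interpolation <- match.arg(interpolation)
  structure(
    list(theta = theta, interpolation = interpolation, fill_value = fill_value),
    class = "motion_spec"
  )
}

#' Simulate a motion artifact by in-plane rotation
#'
#' Rotates the image about its geometric center `((H-1)/2, (W-1)/2)` using
#' inverse mapping: each output pixel samples the source image at the
#' back-rotated location with the requested interpolation. Output dimensions
#' equal input dimensions; samples from outside the frame take
#' `fill_value`; the result is clipped to `[0, 1]`.
#'
#' @param img Grayscale matrix in `[0, 1]`.
#' @param spec A [motion_spec()].
#' @return Rotated matrix with the same dimensions.
#' @export
simulate_motion <- function(img, spec) {
  check_gray_image(img)
  if (!inherits(spec, "motion_spec")) abort("`spec` must be a motion_spec.")
  h <- nrow(img)
  w <- ncol(img)
  cy <- (h - 1) / 2
  cx <- (w - 1) / 2
  th <- spec$theta * pi / 180
  rows <- matrix(0:(h - 1), h, w)
  cols <- matrix(0:(w - 1), h, w, byrow = TRUE)
  # standard orientation: x right (columns), y up (rows point down)
  x <- cols - cx
  y <- -(rows - cy)
  # inverse map: source = R(-theta) %*% target
  xs <- cos(th) * x + sin(th) * y
  ys <- -sin(th) * x + cos(th) * y
  src_col <- xs + cx
  src_row <- cy - ys
  out <- matrix(spec$fill_value, h, w)
  if (spec$interpolation == "nearest") {
    r0 <- round(src_row)
    c0 <- round(src_col)
    ok <- r0 >= 0 & r0 <= h - 1 & c0 >= 0 & c0 <= w - 1
    out[ok] <- img[cbind(r0[ok] + 1L, c0[ok] + 1L)]
  } else {
    ok <- src_row >= 0 & src_row <= h - 1 & src_col >= 0 & src_col <= w - 1
    r0 <- pmin(floor(src_row[ok]), h - 2)
    c0 <- pmin(floor(src_col[ok]), w - 2)
    fr <- src_row[ok] - r0
    fc <- src_col[ok] - c0
    i00 <- img[cbind(r0 + 1L, c0 + 1L)]
    i01 <- img[cbind(r0 + 1L, c0 + 2L)]
    i10 <- img[cbind(r0 + 2L, c0 + 1L)]
    i11 <- img[cbind(r0 + 2L, c0 + 2L)]
    out[ok] <- (1 - fr) * ((1 - fc) * i00 + fc * i01) +
      fr * ((1 - fc) * i10 + fc * i11)
  }
  clip01(out)
}

#' Specify a concentric-ring artifact
#'
#' Miscalibrated detector elements produce circular bands centered on the
#' rotation axis. The artifact is emulated as a family of concentric
#' annuli — circles `(x - h)^2 + (y - k)^2 = r^2` thickened to a fixed
#' width — overlaid on the image with a signed intensity offset.
#'
#' @param radii Strictly increasing radii in pixels.
#' @param center `(row, col)` center in 0-based pixel coordinates, or `NULL`
#'   for the image center.
#' @param ring_width Annulus width in pixels; must not exceed the smallest
#'   spacing between consecutive radii (rings may not overlap).
#' @param amplitude Signed intensity offset in `[-1, 1]` (additive mode) or
#'   replacement intensity in `[0, 1]` (replace mode).
#' @param mode `"additive"` (default) or `"replace"`.
#' @return An object of class `ring_spec`.
#' @export
ring_spec <- function(radii, center = NULL, ring_width = 2,
                      amplitude = 0.25, mode = c("additive", "replace")) {
  mode <- match.arg(mode)
  if (length(radii) < 1L || any(radii <= 0)) abort("`radii` must be positive.")
  if (is.unsorted(radii, strictly = TRUE)) {
    abort("`radii` must be strictly increasing.")
  }
  check_scalar(ring_width, "ring_width", lower = 1e-9)
  if (length(radii) > 1L && ring_width > min(diff(radii))) {
    abort("`ring_width` exceeds the spacing between radii (rings overlap).")
  }
  check_scalar(amplitude, "amplitude", lower = -1, upper = 1)
  if (mode == "replace" && amplitude < 0) {
    abort("replacement intensity must be in [0, 1].")
  }
  structure(
    list(radii = as.numeric(radii), center = center, ring_width = ring_width,
         amplitude = amplitude, mode = mode),
    class = "ring_spec"
  )
}

#' Default ring layout for an image
#'
#' Four equally spaced rings spanning 15-45 percent of the smaller image
#' dimension, 2 px wide, +0.25 additive offset — the classic appearance of
#' detector-calibration ring artifacts.
#'
#' @param img Grayscale matrix (only its dimensions are used).
#' @param n_rings Number of rings.
#' @param amplitude Additive intensity offset.
#' @return A [ring_spec()].
#' @export
default_ring_spec <- function(img, n_rings = 4, amplitude = 0.25) {
  d <- min(dim(img))
  radii <- seq(0.15, 0.45, length.out = n_rings) * d
  ring_spec(radii = radii, amplitude = amplitude)
}

#' Simulate a concentric-ring artifact
#'
#' For each radius `r`, pixels whose Euclidean distance (at pixel centers)
#' from the ring center lies within `[r - w/2, r + w/2]` are modified —
#' offset by `amplitude` in additive mode, or set to `amplitude` in replace
#' mode. All other pixels are untouched; the result is clipped to `[0, 1]`.
#'
#' @param img Grayscale matrix in `[0, 1]`.
#' @param spec A [ring_spec()].
#' @return Matrix with the same dimensions.
#' @export
simulate_rings <- function(img, spec) {
  check_gray_image(img)
  if (!inherits(spec, "ring_spec")) abort("`spec` must be a ring_spec.")
  h <- nrow(img)
  w <- ncol(img)
  center <- spec$center %||% c((h - 1) / 2, (w - 1) / 2)
  if (center[1] < 0 || center[1] > h - 1 || center[2] < 0 || center[2] > w - 1) {
    abort("ring `center` must lie inside the image.")
  }
  rows <- matrix(0:(h - 1), h, w)
  cols <- matrix(0:(w - 1), h, w, byrow = TRUE)
  dist <- sqrt((rows - center[1])^2 + (cols - center[2])^2)
  half <- spec$ring_width / 2
  out <- img
  for (r in spec$radii) {
    m <- dist >= r - half & dist <= r + half
    if (spec$mode == "additive") {
      out[m] <- out[m] + spec$amplitude
    } else {
      out[m] <- spec$amplitude
    }
  }
  clip01(out)
}

#' Specify a beam-hardening artifact
#'
#' Dense bone preferentially absorbs low-energy photons, darkening bright
#' structures and obscuring the skull's internal detail. The artifact is
#' emulated by attenuating the whites: every pixel brighter than
#' `attenuation_threshold` is pulled toward the threshold by the soft-knee
#' law `out = in - strength * (in - threshold)`. Optionally, attenuation is
#' restricted to the Otsu foreground of the image (the bright segment of
#' its binarization).
#'
#' @param attenuation_threshold Unit-scale knee (default 0.4).
#' @param attenuation_strength Fraction of the excess over the threshold
#'   removed, in `[0, 1]`; 1 maps every bright pixel exactly to the
#'   threshold.
#' @param use_otsu_mask If `TRUE` (default), attenuate only inside the Otsu
#'   foreground.
#' @return An object of class `beam_hardening_spec`.
#' @export
beam_hardening_spec <- function(attenuation_threshold = 0.4,
                                attenuation_strength = 0.5,
                                use_otsu_mask = TRUE) {
  check_scalar(attenuation_threshold, "attenuation_threshold", 0, 1)
  check_scalar(attenuation_strength, "attenuation_strength", 0, 1)
  stopifnot(is.logical(use_otsu_mask), length(use_otsu_mask) == 1L)
  structure(
    list(attenuation_threshold = attenuation_threshold,
         attenuation_strength = attenuation_strength,
         use_otsu_mask = use_otsu_mask),
    class = "beam_hardening_spec"
  )
}

#' Simulate a beam-hardening artifact
#'
#' Applies the attenuation law of [beam_hardening_spec()]: pixels at or
#' below the threshold are unchanged; pixels above it (and inside the Otsu
#' foreground, when masking is on) are darkened by
#' `strength * (in - threshold)`. The mapping is monotone non-decreasing in
#' the input and never brightens any pixel.
#'
#' @param img Grayscale matrix in `[0, 1]`.
#' @param spec A [beam_hardening_spec()].
#' @return Matrix with the same dimensions.
#' @export
simulate_beam_hardening <- function(img, spec = beam_hardening_spec()) {
  check_gray_image(img)
  if (!inherits(spec, "beam_hardening_spec")) {
    abort("`spec` must be a beam_hardening_spec.")
  }
  sel <- img > spec$attenuation_threshold
  if (spec$use_otsu_mask && any(sel)) {
    hist <- gray_histogram(img)
    # a flat image has no two-class binarization; treat it all as foreground
    if (sum(hist$p > 0) >= 2L) {
      fg <- img > otsu_threshold(hist) / 255
      sel <- sel & fg
    }
  }
  out <- img
  out[sel] <- img[sel] -
    spec$attenuation_strength * (img[sel] - spec$attenuation_threshold)
  clip01(out)
}
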