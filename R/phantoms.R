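#' Specify a synthetic head-CT phantom
#'
#' Builds the parameter record for a single-slice head phantom: a bright
#' elliptical bone shell (the calvaria / skull base), a mid-gray soft-tissue
#' fill, dark air-filled sinus-like cavities, and mild additive acquisition
#' noise. The phantom emulates the statistical structure of paranasal-sinus
#' CT slices — bright closed shell, dark cavities on a tissue background —
#' not their anatomy.
#'
#' Centers and axes are fractional (relative to image height/width), so the
#' same spec scales across canvas sizes. All intensities live on the unit
#' scale; bone must be brighter than tissue, and tissue brighter than every
#' cavity.
#'
#' @param height,width Canvas size in pixels (at least 32).
#' @param skull_center Fractional (row, col) center of the skull ellipse.
#' @param skull_axes Fractional (row, col) semi-axes of the outer bone shell.
#' @param shell_thickness Bone-shell thickness as a fraction of the smaller
#'   skull semi-axis.
#' @param bone_intensity,tissue_intensity Unit-scale intensities of bone and
#'   soft tissue.
#' @param cavities List of cavities, each a list with elements `center`
#'   (fractional row/col), `axes` (fractional semi-axes) and `intensity`.
#'   Defaults depend on `plane_style`.
#' @param noise_sd Standard deviation of additive Gaussian noise (intensity
#'   units); 0 gives a piecewise-constant phantom.
#' @param plane_style One of `"axial"`, `"coronal"`, `"sagittal"`; a cosmetic
#'   layout variant controlling the default cavity arrangement.
#' @param seed Integer seed for the noise draw.
#' @return An object of class `phantom_spec`.
#' @examples
#' spec <- phantom_spec(noise_sd = 0)
#' img <- generate_phantom(spec)
#' range(img)
#' @export
phantom_spec <- function(height = 256, width = 256,
                         skull_center = c(0.5, 0.5),
                         skull_axes = c(0.40, 0.34),
                         shell_thickness = 0.14,
                         bone_intensity = 0.9,
                         tissue_intensity = 0.35,
                         cavities = NULL,
                         noise_sd = 0.02,
                         plane_style = c("axial", "coronal", "sagittal"),
                         seed = 1L) {
  plane_style <- match.arg(plane_style)
  check_scalar(height, "height", lower = 32, integerish = TRUE)
  check_scalar(width, "width", lower = 32, integerish = TRUE)
  check_scalar(shell_thickness, "shell_thickness", lower = 1e-6, upper = 1)
  check_scalar(bone_intensity, "bone_intensity", lower = 0, upper = 1)
  check_scalar(tissue_intensity, "tissue_intensity", lower = 0, upper = 1)
  check_scalar(noise_sd, "noise_sd", lower = 0)
  stopifnot(length(skull_center) == 2L, length(skull_axes) == 2L)
  if (any(skull_axes <= 0)) abort("`skull_axes` must be positive.")
  if (is.null(cavities)) cavities <- default_cavities(plane_style)
  for (cv in cavities) {
    if (!all(c("center", "axes", "intensity") %in% names(cv))) {
      abort("each cavity needs `center`, `axes` and `intensity`.")
    }
    check_scalar(cv$intensity, "cavity intensity", lower = 0, upper = 1)
    if (cv$intensity >= tissue_intensity) {
      abort("cavity intensities must be below `tissue_intensity`.")
    }
  }
  if (!(bone_intensity > tissue_intensity)) {
    abort("`bone_intensity` must exceed `tissue_intensity`.")
  }
  structure(
    list(
      height = as.integer(height), width = as.integer(width),
      skull_center = as.numeric(skull_center),
      skull_axes = as.numeric(skull_axes),
      shell_thickness = shell_thickness,
      bone_intensity = bone_intensity,
      tissue_intensity = tissue_intensity,
      cavities = cavities,
      noise_sd = noise_sd,
      plane_style = plane_style,
      seed = as.integer(seed)
    ),
    class = "phantom_spec"
  )
}

# Sinus-like cavity layouts per body plane. Purely cosmetic variants: all
# three give dark elliptical holes inside the tissue region.
default_cavities <- function(plane_style) {
  switch(plane_style,
    axial = list(
      list(center = c(0.40, 0.40), axes = c(0.08, 0.07), intensity = 0.05),
      list(center = c(0.40, 0.60), axes = c(0.08, 0.07), intensity = 0.05),
      list(center = c(0.62, 0.50), axes = c(0.06, 0.10), intensity = 0.08)
    ),
    coronal = list(
      list(center = c(0.55, 0.38), axes = c(0.10, 0.08), intensity = 0.05),
      list(center = c(0.55, 0.62), axes = c(0.10, 0.08), intensity = 0.05),
      list(center = c(0.35, 0.50), axes = c(0.05, 0.06), intensity = 0.08)
    ),
    sagittal = list(
      list(center = c(0.45, 0.35), axes = c(0.07, 0.09), intensity = 0.05),
      list(center = c(0.62, 0.45), axes = c(0.08, 0.07), intensity = 0.08)
    )
  )
}

# Pixel-center ellipse membership, 0-based (row, col) coordinates: pixel
# (i, j) is inside iff ((i - cy)/ay)^2 + ((j - cx)/ax)^2 <= 1.
ellipse_mask <- function(height, width, center_frac, axes_frac) {
  cy <- center_frac[1] * (height - 1)
  cx <- center_frac[2] * (width - 1)
  ay <- axes_frac[1] * height
  ax <- axes_frac[2] * width
  rows <- matrix(0:(height - 1), nrow = height, ncol = width)
  cols <- matrix(0:(width - 1), nrow = height, ncol = width, byrow = TRUE)
  ((rows - cy) / ay)^2 + ((cols - cx) / ax)^2 <= 1
}

#' Generate one synthetic head-CT phantom
#'
#' Rasterizes a [phantom_spec()] into a grayscale matrix in `[0, 1]`:
#' background air at 0, an elliptical bone shell at `bone_intensity`, the
#' interior filled with `tissue_intensity`, cavities painted dark, and
#' seeded Gaussian noise added last and clipped to the unit range. With
#' `noise_sd = 0` the output is piecewise constant on exactly the
#' configured intensity levels.
#'
#' @param spec A [phantom_spec()].
#' @return A `height` x `width` numeric matrix in `[0, 1]`.
#' @export
generate_phantom <- function(spec) {
  if (!inherits(spec, "phantom_spec")) abort("`spec` must be a phantom_spec.")
  h <- spec$height
  w <- spec$width
  outer <- ellipse_mask(h, w, spec$skull_center, spec$skull_axes)
  inner_axes <- spec$skull_axes * (1 - spec$shell_thickness)
  inner <- ellipse_mask(h, w, spec$skull_center, inner_axes)
  img <- matrix(0, h, w)
  img[outer & !inner] <- spec$bone_intensity
  img[inner] <- spec$tissue_intensity
  for (cv in spec$cavities) {
    m <- ellipse_mask(h, w, cv$center, cv$axes) & inner
    img[m] <- cv$intensity
  }
  if (spec$noise_sd > 0) {
    img <- with_seed(spec$seed, img + rnorm(h * w, sd = spec$noise_sd))
  }
  clip01(img)
}

#' Generate a jittered set of phantoms
#'
#' Emulates a cohort of slices from different patients: each image reuses
#' the base spec with its skull center and axes jittered uniformly by up to
#' 5 percent, under a per-image sub-seed (`seed + index`), so the whole set
#' is reproducible from one integer.
#'
#' @param n Number of images (default 43, a typical single-site cohort).
#' @param spec Base [phantom_spec()].
#' @param seed Integer seed for the set.
#' @return A list of `n` matrices, all of the same dimensions.
#' @export
generate_image_set <- function(n = 43, spec = phantom_spec(), seed = 1L) {
  check_scalar(n, "n", lower = 1, integerish = TRUE)
  lapply(seq_len(n), function(i) {
    s <- sub_seed(seed, i - 1L)
    jit <- with_seed(s, runif(4, min = 0.95, max = 1.05))
    spec_i <- spec
    spec_i$skull_center <- spec$skull_center * jit[1:2]
    spec_i$skull_axes <- spec$skull_axes * jit[3:4]
    spec_i$seed <- as.integer(s)
    generate_phantom(spec_i)
  })
}
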