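#' Full singular-value spectrum of an image
#'
#' Treats the intensity matrix itself as the object of interest and returns
#' its complete singular-value spectrum, sorted non-increasing, of length
#' `min(H, W)`. The spectrum is a compact, orientation-tolerant fingerprint
#' of the image: it satisfies the Parseval identity (the sum of squared
#' singular values equals the squared Frobenius norm) and is preserved
#' exactly by transposition and by exact 90-degree rotations.
#'
#' @param img Grayscale matrix (finite values).
#' @return Numeric vector of non-negative singular values.
#' @export
singular_values <- function(img) {
  if (!is.matrix(img) || !is.numeric(img)) abort("`img` must be a numeric matrix.")
  if (!all(is.finite(img))) abort("`img` contains non-finite values.")
  svd(img, nu = 0, nv = 0)$d
}

#' Truncated singular-value feature vector
#'
#' Computes the spectrum with [singular_values()], discards the null values
#' — entries below `null_tol * sigma_1` are zeroed, treating them as
#' numerical noise — and keeps the leading `k` entries as the image's
#' feature vector.
#'
#' @param img Grayscale matrix.
#' @param k Number of leading singular values to retain (`k <= min(H, W)`).
#' @param null_tol Relative tolerance under which a singular value counts as
#'   null (relative to the largest).
#' @param label Optional class label attached to the result.
#' @param source_id Optional image identifier.
#' @return A tibble with one row: `source_id`, `label`, and columns
#'   `sv01..sv<k>`.
#' @export
extract_features <- function(img, k = 32, null_tol = 1e-10,
                             label = NA_character_, source_id = NA_character_) {
  check_scalar(k, "k", lower = 1, integerish = TRUE)
  check_scalar(null_tol, "null_tol", lower = 0)
  sv <- singular_values(img)
  if (k > length(sv)) {
    abort(sprintf("`k` = %d exceeds the spectrum length %d.", k, length(sv)))
  }
  if (sv[1] > 0) sv[sv < null_tol * sv[1]] <- 0
  out <- tibble::as_tibble(as.list(stats::setNames(
    sv[seq_len(k)], sprintf("sv%02d", seq_len(k))
  )))
  dplyr::bind_cols(
    tibble::tibble(source_id = source_id, label = label),
    out
  )
}

# Bilinear resize to (height, width); shares the inverse-mapping convention
# of simulate_motion (pixel centers, 0-based coordinates).
resize_bilinear <- function(img, height, width) {
  h <- nrow(img)
  w <- ncol(img)
  if (h == height && w == width) return(img)
  src_row <- if (height == 1) rep((h - 1) / 2, 1) else (0:(height - 1)) * (h - 1) / (height - 1)
  src_col <- if (width == 1) rep((w - 1) / 2, 1) else (0:(width - 1)) * (w - 1) / (width - 1)
  r0 <- pmin(floor(src_row), h - 2)
  c0 <- pmin(floor(src_col), w - 2)
  fr <- src_row - r0
  fc <- src_col - c0
  top <- img[r0 + 1L, , drop = FALSE] * (1 - fr) + img[r0 + 2L, , drop = FALSE] * fr
  out <- top[, c0 + 1L, drop = FALSE] %*% diag(1 - fc, length(fc)) +
    top[, c0 + 2L, drop = FALSE] %*% diag(fc, length(fc))
  out
}

#' Build the general feature matrix for a labeled image set
#'
#' Runs [extract_features()] over every image and stacks the rows into one
#' tidy feature table — the "general matrix" fed to the classifiers. All
#' images must share one size; if not, they are first resized bilinearly to
#' `resize_to` (equal matrix size is required by the SVD features and is
#' enforced explicitly rather than assumed).
#'
#' @param images List of grayscale matrices.
#' @param labels Character vector of class labels, one per image.
#' @param k,null_tol Passed to [extract_features()].
#' @param groups Optional grouping vector (one entry per image) identifying
#'   images derived from the same source, e.g. an original and its artifact
#'   variants; carried as a `group` column and honoured by the paired
#'   cross-validation (see [cross_validate_scores()]).
#' @param resize_to `(height, width)` target when dimensions are mixed, or
#'   `NULL` to forbid mixed sizes.
#' @return A tibble with columns `source_id`, `label` (plus `group` when
#'   given), `sv01..sv<k>`; one row per image, input order preserved.
#' @export
build_feature_dataset <- function(images, labels, k = 32, null_tol = 1e-10,
                                  groups = NULL, resize_to = c(256, 256)) {
  if (length(images) == 0L) {
    return(tibble::tibble(source_id = character(), label = character()))
  }
  if (length(labels) != length(images)) {
    abort("`labels` must have one entry per image.")
  }
  if (!is.null(groups) && length(groups) != length(images)) {
    abort("`groups` must have one entry per image.")
  }
  dims <- vapply(images, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
    if (is.null(resize_to)) {
      abort("images have mixed dimensions; supply `resize_to` or resize first.")
    }
    images <- lapply(images, resize_bilinear,
                     height = resize_to[1], width = resize_to[2])
  }
  ids <- names(images) %||% sprintf("img%03d", seq_along(images))
  out <- purrr::map2_dfr(seq_along(images), ids, function(i, id) {
    extract_features(images[[i]], k = k, null_tol = null_tol,
                     label = labels[i], source_id = id)
  })
  if (!is.null(groups)) {
    out <- dplyr::mutate(out, group = groups, .after = "label")
  }
  out
}

#' Feature matrix of a feature dataset
#'
#' Extracts the numeric `sv*` columns of a feature tibble as a plain matrix
#' (rows = images, columns = singular-value features).
#'
#' @param dataset Tibble from [build_feature_dataset()].
#' @return Numeric matrix.
#' @export
feature_matrix <- function(dataset) {
  sv_cols <- grep("^sv[0-9]+$", names(dataset), value = TRUE)
  if (length(sv_cols) == 0L) abort("`dataset` has no sv* feature columns.")
  as.matrix(dataset[, sv_cols])
}
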