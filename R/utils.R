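#' @importFrom rlang abort %||%
#' @importFrom stats runif rnorm var
NULL

# Run `expr` under a private, seeded RNG stream, restoring the caller's RNG
# state afterwards. All stochastic code in the package funnels through this
# so that a single integer seed pins every draw.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    abort("`seed` must be a single finite number.")
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Derive a bounded sub-seed from a base seed and an index; keeps results
# inside the 32-bit integer range R requires of set.seed().
sub_seed <- function(seed, index) {
  (as.numeric(seed) + as.numeric(index)) %% 2147483647
}

clip01 <- function(x) pmin(pmax(x, 0), 1)

#' Validate a grayscale image matrix
#'
#' The package's universal currency is a plain numeric matrix with all
#' intensities in the unit interval. This checks that contract and returns
#' the matrix invisibly, so it can be dropped into pipes.
#'
#' @param img Numeric matrix.
#' @param arg Name used in error messages.
#' @return `img`, invisibly.
#' @export
check_gray_image <- function(img, arg = "img") {
  if (!is.matrix(img) || !is.numeric(img)) {
    abort(sprintf("`%s` must be a numeric matrix.", arg))
  }
  if (nrow(img) < 1L || ncol(img) < 1L) {
    abort(sprintf("`%s` must have positive dimensions.", arg))
  }
  if (!all(is.finite(img))) {
    abort(sprintf("`%s` contains non-finite values.", arg))
  }
  if (min(img) < 0 || max(img) > 1) {
    abort(sprintf("`%s` must have intensities in [0, 1].", arg))
  }
  invisible(img)
}

check_scalar <- function(x, arg, lower = -Inf, upper = Inf, integerish = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number.", arg))
  }
  if (x < lower || x > upper) {
    abort(sprintf("`%s` must be in [%s, %s].", arg, format(lower), format(upper)))
  }
  if (integerish && abs(x - round(x)) > 1e-8) {
    abort(sprintf("`%s` must be a whole number.", arg))
  }
  invisible(x)
}
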