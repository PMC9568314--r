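#' Specify an SVM kernel
#'
#' The classifier separates artifact from original feature vectors with a
#' soft-margin SVM; because the singular-value features of artifacted
#' images are not linearly separable from the originals in general, a
#' Gaussian (RBF) or polynomial kernel is used. Hyperparameter defaults
#' follow common heuristics: `C = 1`; for the Gaussian kernel
#' `gamma = 1 / (n_features * var(features))` when left `NULL`; degree-3
#' polynomial with `coef0 = 1`.
#'
#' @param family `"gaussian"` (default), `"polynomial"`, or `"linear"`.
#' @param C Soft-margin penalty (> 0).
#' @param gamma Kernel width (> 0), or `NULL` to use the variance heuristic
#'   at fit time.
#' @param degree,coef0 Polynomial kernel parameters.
#' @return An object of class `kernel_spec`.
#' @export
kernel_spec <- function(family = c("gaussian", "polynomial", "linear"),
                        C = 1, gamma = NULL, degree = 3, coef0 = 1) {
  family <- match.arg(family)
  check_scalar(C, "C", lower = 1e-12)
  if (!is.null(gamma)) check_scalar(gamma, "gamma", lower = 1e-15)
  check_scalar(degree, "degree", lower = 1, integerish = TRUE)
  check_scalar(coef0, "coef0")
  structure(
    list(family = family, C = C, gamma = gamma, degree = degree, coef0 = coef0),
    class = "kernel_spec"
  )
}

#' Evaluate a kernel between two feature vectors
#'
#' Closed forms: linear `u . v`; polynomial `(gamma u . v + coef0)^degree`;
#' gaussian `exp(-gamma ||u - v||^2)`. Symmetric in its arguments.
#'
#' @param spec A [kernel_spec()] (with `gamma` resolved to a number for the
#'   gaussian and polynomial families).
#' @param u,v Numeric vectors of equal length.
#' @return A single number.
#' @export
kernel_eval <- function(spec, u, v) {
  if (!inherits(spec, "kernel_spec")) abort("`spec` must be a kernel_spec.")
  if (length(u) != length(v)) abort("`u` and `v` must have equal lengths.")
  gamma <- spec$gamma %||% (1 / length(u))
  switch(spec$family,
    linear = sum(u * v),
    polynomial = (gamma * sum(u * v) + spec$coef0)^spec$degree,
    gaussian = exp(-gamma * sum((u - v)^2))
  )
}

# Kernel matrix between the rows of X and the rows of Y.
kernel_matrix <- function(spec, X, Y) {
  gamma <- spec$gamma %||% (1 / ncol(X))
  switch(spec$family,
    linear = X %*% t(Y),
    polynomial = (gamma * X %*% t(Y) + spec$coef0)^spec$degree,
    gaussian = {
      d2 <- outer(rowSums(X^2), rowSums(Y^2), "+") - 2 * X %*% t(Y)
      exp(-gamma * pmax(d2, 0))
    }
  )
}

#' Train a binary artifact-vs-original SVM
#'
#' Fits a soft-margin SVM on the two classes present in `data`, mapping the
#' `negative` class (by convention `"original"`) to -1 and the `positive`
#' class (the artifact) to +1, so that positive decision scores mean
#' "artifact detected". Features are optionally standardized per dimension
#' using statistics of this training set only, and the standardization
#' constants travel with the model so new data is transformed identically.
#'
#' The soft-margin dual is solved by the SMO solver of libsvm (via
#' \pkg{e1071}); the fitted decision function
#' `f(x) = sum_i alpha_i y_i K(x_i, x) + b` is stored explicitly (support
#' vectors, signed dual coefficients, bias) so that [decision_scores()] can
#' evaluate it from the kernel alone and the model serializes to plain
#' JSON.
#'
#' @param data Feature tibble (from [build_feature_dataset()]) restricted to
#'   exactly two classes.
#' @param kernel A [kernel_spec()].
#' @param positive Label mapped to +1; default: the label that is not
#'   `"original"`.
#' @param standardize Standardize features from the training set (default
#'   `TRUE`; Gaussian kernels are scale-sensitive).
#' @return An object of class `artifact_svm`.
#' @export
train_svm <- function(data, kernel = kernel_spec(), positive = NULL,
                      standardize = TRUE) {
  labs <- unique(data$label)
  if (length(labs) != 2L) {
    abort(sprintf("`data` must contain exactly two classes, found %d.", length(labs)))
  }
  if (is.null(positive)) {
    positive <- if ("original" %in% labs) setdiff(labs, "original") else labs[2]
  }
  negative <- setdiff(labs, positive)
  X <- feature_matrix(data)
  y <- ifelse(data$label == positive, 1, -1)
  if (standardize) {
    center <- colMeans(X)
    scale_ <- apply(X, 2, stats::sd)
    scale_[scale_ < 1e-12] <- 1
  } else {
    center <- rep(0, ncol(X))
    scale_ <- rep(1, ncol(X))
  }
  Xs <- sweep(sweep(X, 2, center), 2, scale_, "/")
  gamma <- kernel$gamma %||% {
    v <- stats::var(as.vector(Xs))
    if (!is.finite(v) || v < 1e-12) v <- 1
    1 / (ncol(Xs) * v)
  }
  resolved <- kernel
  resolved$gamma <- gamma
  fit <- e1071::svm(
    x = Xs, y = factor(y, levels = c(-1, 1)),
    scale = FALSE, type = "C-classification",
    kernel = switch(kernel$family, gaussian = "radial", kernel$family),
    cost = kernel$C, gamma = gamma,
    degree = kernel$degree, coef0 = kernel$coef0,
    tolerance = 1e-6
  )
  # libsvm's coefs/rho are oriented toward the first training label; flip so
  # that positive decision values always mean the positive (artifact) class
  first_level <- fit$levels[fit$labels[1]]
  s <- if (first_level == "1") 1 else -1
  structure(
    list(
      kernel = resolved,
      support_vectors = Xs[fit$index, , drop = FALSE],
      dual_coefs = as.numeric(fit$coefs) * s,
      bias = -fit$rho * s,
      classes = c(negative = negative, positive = positive),
      center = center,
      scale = scale_,
      feature_names = colnames(X)
    ),
    class = "artifact_svm"
  )
}

#' Decision scores of a fitted SVM
#'
#' Evaluates the stored decision function
#' `f(x) = sum_i alpha_i y_i K(x_i, x) + b` on new feature rows, after
#' applying the model's standardization. Positive scores predict the
#' positive (artifact) class; the scores feed the ROC analysis.
#'
#' @param model An [train_svm()] fit.
#' @param data Feature tibble or numeric matrix with the training feature
#'   dimension.
#' @return Numeric vector of signed decision values.
#' @export
decision_scores <- function(model, data) {
  if (!inherits(model, "artifact_svm")) abort("`model` must be an artifact_svm.")
  X <- if (is.matrix(data)) data else feature_matrix(data)
  if (ncol(X) != ncol(model$support_vectors)) {
    abort("feature dimension does not match the training data.")
  }
  Xs <- sweep(sweep(X, 2, model$center), 2, model$scale, "/")
  K <- kernel_matrix(model$kernel, Xs, model$support_vectors)
  as.numeric(K %*% model$dual_coefs + model$bias)
}

#' Predicted labels of a fitted SVM
#'
#' @param object An `artifact_svm`.
#' @param newdata Feature tibble or matrix.
#' @param ... Unused.
#' @return Character vector of predicted class labels (score 0 falls to the
#'   negative class).
#' @export
predict.artifact_svm <- function(object, newdata, ...) {
  f <- decision_scores(object, newdata)
  unname(ifelse(f > 0, object$classes[["positive"]], object$classes[["negative"]]))
}

#' Serialize / restore an SVM model as JSON
#'
#' The model file is self-describing: kernel spec, support vectors, signed
#' dual coefficients, bias, class mapping and standardization constants.
#' A round-tripped model reproduces decision scores exactly.
#'
#' @param model An `artifact_svm`.
#' @param path File path.
#' @return `read_svm_json()` returns the restored `artifact_svm`;
#'   `write_svm_json()` returns `path` invisibly.
#' @export
write_svm_json <- function(model, path) {
  obj <- list(
    kernel = unclass(model$kernel),
    support_vectors = unname(apply(model$support_vectors, 1, as.numeric,
                                   simplify = FALSE)),
    dual_coefs = model$dual_coefs,
    bias = model$bias,
    classes = as.list(model$classes),
    center = model$center,
    scale = model$scale,
    feature_names = model$feature_names
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_svm_json
#' @export
read_svm_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  sv <- obj$support_vectors
  if (!is.matrix(sv)) {
    sv <- if (is.list(sv)) do.call(rbind, sv) else matrix(sv, nrow = 1)
  }
  structure(
    list(
      kernel = structure(
        list(family = obj$kernel$family, C = obj$kernel$C,
             gamma = obj$kernel$gamma, degree = obj$kernel$degree,
             coef0 = obj$kernel$coef0),
        class = "kernel_spec"
      ),
      support_vectors = sv,
      dual_coefs = obj$dual_coefs,
      bias = obj$bias,
      classes = c(negative = obj$classes$negative,
                  positive = obj$classes$positive),
      center = obj$center,
      scale = obj$scale,
      feature_names = obj$feature_names
    ),
    class = "artifact_svm"
  )
}

#' @exportS3Method
tidy.artifact_svm <- function(x, ...) {
  tibble::tibble(
    support_vector = seq_along(x$dual_coefs),
    dual_coef = x$dual_coefs,
    at_bound = abs(abs(x$dual_coefs) - x$kernel$C) < 1e-8
  )
}

#' @exportS3Method
glance.artifact_svm <- function(x, ...) {
  tibble::tibble(
    kernel = x$kernel$family,
    C = x$kernel$C,
    gamma = x$kernel$gamma %||% NA_real_,
    n_support = length(x$dual_coefs),
    positive_class = x$classes[["positive"]],
    negative_class = x$classes[["negative"]]
  )
}

#' @export
print.artifact_svm <- function(x, ...) {
  cat("Binary artifact SVM (", x$kernel$family, " kernel)\n", sep = "")
  cat("  classes: ", x$classes[["negative"]], " (-1) vs ",
      x$classes[["positive"]], " (+1)\n", sep = "")
  cat("  support vectors:", length(x$dual_coefs), "\n")
  invisible(x)
}
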