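#' k-fold cross-validation split
#'
#' Shuffles indices `1..n` under the given seed and deals them into `k`
#' disjoint folds whose sizes differ by at most one; the folds partition
#' the index set exactly.
#'
#' @param n Number of samples.
#' @param k Number of folds (`2 <= k <= n`).
#' @param seed Integer seed for the shuffle.
#' @return List of `k` integer vectors (test indices per fold).
#' @export
kfold_split <- function(n, k, seed = 1L) {
  check_scalar(n, "n", lower = 1, integerish = TRUE)
  check_scalar(k, "k", lower = 2, integerish = TRUE)
  if (k > n) abort("`k` cannot exceed `n`.")
  perm <- with_seed(seed, sample.int(n))
  sizes <- rep(n %/% k, k)
  extra <- n %% k
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  split(perm, rep(seq_len(k), times = sizes))
}

#' Leave-one-out split
#'
#' Each of the `n` splits holds out exactly one sample; the procedure is
#' repeated until every sample has been left out once.
#'
#' @param n Number of samples (`n >= 2`).
#' @return List of `n` singleton integer vectors.
#' @export
loo_split <- function(n) {
  check_scalar(n, "n", lower = 2, integerish = TRUE)
  as.list(seq_len(n))
}

#' Cross-validation scheme
#'
#' @param scheme `"kfold"` or `"leave_one_out"`.
#' @param k Folds for the k-fold scheme.
#' @param iterations Number of repeated CV rounds with fresh shuffles
#'   (default 30); iteration `i` reuses `seed + i` so the whole protocol is
#'   reproducible.
#' @param seed Base integer seed.
#' @return An object of class `cv_spec`.
#' @export
cv_spec <- function(scheme = c("kfold", "leave_one_out"), k = 4,
                    iterations = 30, seed = 1L) {
  scheme <- match.arg(scheme)
  if (scheme == "kfold") check_scalar(k, "k", lower = 2, integerish = TRUE)
  check_scalar(iterations, "iterations", lower = 1, integerish = TRUE)
  structure(
    list(scheme = scheme, k = as.integer(k),
         iterations = as.integer(iterations), seed = as.integer(seed)),
    class = "cv_spec"
  )
}

#' ROC curve and AUC from decision scores
#'
#' Sweeps the decision threshold `c` from above the largest score down to
#' below the smallest (predicting positive when `score >= c`) and records
#' the true-positive fraction against the false-positive fraction at every
#' distinct score. The area under the curve is the trapezoidal integral,
#' which — with ties counted half — equals the Mann-Whitney probability
#' that a random positive outranks a random negative. AUC below 0.5
#' (a worse-than-chance ranking) is possible and is flagged on printing.
#'
#' @param scores Numeric decision values.
#' @param labels Labels with exactly two values; either `+1`/`-1` numerics
#'   or anything coercible with `positive`.
#' @param positive Value of `labels` counted as positive (default `1`).
#' @return An object of class `roc_curve`: tibble of
#'   `(threshold, fpf, tpf)` plus the scalar `auc`.
#' @export
roc_curve <- function(scores, labels, positive = 1) {
  if (length(scores) != length(labels)) {
    abort("`scores` and `labels` must have equal lengths.")
  }
  pos <- labels == positive
  if (!any(pos) || all(pos)) {
    abort("ROC undefined: both classes must be present.")
  }
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  p <- pos[ord]
  # one operating point after each distinct score value
  last_of_tie <- c(s[-1] != s[-length(s)], TRUE)
  tp <- cumsum(p)[last_of_tie]
  fp <- cumsum(!p)[last_of_tie]
  n_pos <- sum(pos)
  n_neg <- sum(!pos)
  tpf <- c(0, tp / n_pos)
  fpf <- c(0, fp / n_neg)
  thresholds <- c(Inf, s[last_of_tie])
  auc <- sum(diff(fpf) * (utils::head(tpf, -1) + utils::tail(tpf, -1)) / 2)
  structure(
    list(
      points = tibble::tibble(threshold = thresholds, fpf = fpf, tpf = tpf),
      auc = auc,
      n_pos = n_pos,
      n_neg = n_neg
    ),
    class = "roc_curve"
  )
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("ROC curve: %d positives vs %d negatives, AUC = %.4f\n",
              x$n_pos, x$n_neg, x$auc))
  if (x$auc < 0.5) {
    cat("  note: AUC < 0.5 — ranking is worse than chance\n")
  }
  invisible(x)
}

#' @exportS3Method
tidy.roc_curve <- function(x, ...) x$points

#' @exportS3Method
glance.roc_curve <- function(x, ...) {
  tibble::tibble(auc = x$auc, n_pos = x$n_pos, n_neg = x$n_neg)
}

#' Confusion counts at a decision threshold
#'
#' @param scores Decision values.
#' @param labels `+1`/`-1` truth (or values matching `positive`).
#' @param threshold Operating point; scores strictly above it predict
#'   positive (default 0, the SVM decision boundary).
#' @param positive Label value counted as positive.
#' @return Named integer vector with `tp`, `fp`, `fn`, `tn`.
#' @export
confusion_counts <- function(scores, labels, threshold = 0, positive = 1) {
  pos <- labels == positive
  pred <- scores > threshold
  c(tp = sum(pred & pos), fp = sum(pred & !pos),
    fn = sum(!pred & pos), tn = sum(!pred & !pos))
}

#' Precision, recall and F-score
#'
#' The standard confusion-matrix metrics: precision `TP / (TP + FP)` (how
#' many detections are genuine), recall `TP / (TP + FN)` (how many genuine
#' artifacts are detected), and their harmonic mean
#' `F = 2 * precision * recall / (precision + recall)`.
#'
#' @param counts Named vector with `tp`, `fp`, `fn` (from
#'   [confusion_counts()]).
#' @return A single number in `[0, 1]`.
#' @export
precision <- function(counts) {
  if (counts[["tp"]] + counts[["fp"]] == 0) {
    abort("precision undefined: no positive predictions.")
  }
  counts[["tp"]] / (counts[["tp"]] + counts[["fp"]])
}

#' @rdname precision
#' @export
recall <- function(counts) {
  if (counts[["tp"]] + counts[["fn"]] == 0) {
    abort("recall undefined: no positive samples.")
  }
  counts[["tp"]] / (counts[["tp"]] + counts[["fn"]])
}

#' @rdname precision
#' @param precision,recall Scalar metrics.
#' @export
f_score <- function(precision, recall) {
  if (precision + recall == 0) abort("F-score undefined: precision + recall = 0.")
  2 * precision * recall / (precision + recall)
}

#' Repeated cross-validated decision scores for one binary comparison
#'
#' Runs `iterations` rounds of seeded cross-validation on a two-class
#' feature table. In each round the data are re-shuffled (`seed + i`),
#' split, and for every fold an SVM is trained on the remaining folds only
#' — standardization included — and scored on the held-out fold, so every
#' sample receives exactly one out-of-fold score per iteration and no model
#' ever sees its own test sample.
#'
#' When a grouping is available (a `group` column or the `groups`
#' argument), the split is *paired*: folds are drawn over groups, so an
#' original and the artifact images derived from it are always held out
#' together. This prevents twin leakage — with weak or absent artifacts, an
#' image and its near-identical derivative on opposite sides of a fold
#' boundary would let the model read the held-out label off the training
#' twin and bias the AUC.
#'
#' @param data Two-class feature tibble.
#' @param kernel A [kernel_spec()].
#' @param cv A [cv_spec()].
#' @param positive Label mapped to +1 (see [train_svm()]).
#' @param groups Optional grouping vector (defaults to `data$group` when
#'   present; `NULL` falls back to plain row-level splits).
#' @return Tibble with columns `iteration`, `fold`, `row` (index into
#'   `data`), `score`, `label`.
#' @export
cross_validate_scores <- function(data, kernel = kernel_spec(),
                                  cv = cv_spec(), positive = NULL,
                                  groups = NULL) {
  n <- nrow(data)
  if (is.null(groups) && "group" %in% names(data)) groups <- data$group
  if (!is.null(groups) && length(groups) != n) {
    abort("`groups` must have one entry per row of `data`.")
  }
  purrr::map_dfr(seq_len(cv$iterations), function(it) {
    folds <- if (is.null(groups)) {
      if (cv$scheme == "kfold") {
        kfold_split(n, cv$k, seed = sub_seed(cv$seed, it))
      } else {
        loo_split(n)
      }
    } else {
      ids <- unique(groups)
      id_folds <- if (cv$scheme == "kfold") {
        kfold_split(length(ids), cv$k, seed = sub_seed(cv$seed, it))
      } else {
        loo_split(length(ids))
      }
      lapply(id_folds, function(f) which(groups %in% ids[f]))
    }
    purrr::imap_dfr(folds, function(test_idx, fold_id) {
      train <- data[-test_idx, , drop = FALSE]
      model <- train_svm(train, kernel = kernel, positive = positive)
      tibble::tibble(
        iteration = it,
        fold = as.integer(fold_id),
        row = as.integer(test_idx),
        score = decision_scores(model, data[test_idx, , drop = FALSE]),
        label = data$label[test_idx]
      )
    })
  })
}

#' Evaluate one artifact-vs-original comparison
#'
#' Summarizes repeated cross-validation into an evaluation report: one AUC
#' per iteration from that iteration's pooled out-of-fold scores, their
#' mean, standard deviation and max-min spread, plus confusion counts
#' pooled over all out-of-fold predictions at the stated score threshold,
#' and the derived accuracy, precision, recall and F-score.
#'
#' @param scores_tbl Output of [cross_validate_scores()].
#' @param comparison Character label pair, e.g. `"original vs motion"`.
#' @param positive Label counted as positive.
#' @param threshold Operating point for the confusion counts (default 0).
#' @return An object of class `eval_report`.
#' @export
summarize_evaluation <- function(scores_tbl, comparison, positive,
                                 threshold = 0) {
  per_iter <- scores_tbl |>
    dplyr::group_by(.data$iteration) |>
    dplyr::summarise(
      auc = roc_curve(.data$score, .data$label, positive = positive)$auc,
      .groups = "drop"
    )
  counts <- confusion_counts(scores_tbl$score, scores_tbl$label,
                             threshold = threshold, positive = positive)
  prec <- precision(counts)
  rec <- recall(counts)
  structure(
    list(
      comparison = comparison,
      positive = positive,
      iteration_auc = per_iter$auc,
      mean_auc = mean(per_iter$auc),
      sd_auc = stats::sd(per_iter$auc),
      range_auc = diff(range(per_iter$auc)),
      counts = counts,
      accuracy = (counts[["tp"]] + counts[["tn"]]) / sum(counts),
      precision = prec,
      recall = rec,
      f_score = f_score(prec, rec),
      threshold = threshold
    ),
    class = "eval_report"
  )
}

#' @export
print.eval_report <- function(x, ...) {
  cat("Evaluation report:", x$comparison, "\n")
  cat(sprintf("  AUC over %d iterations: mean %.3f (sd %.3f, range %.3f)\n",
              length(x$iteration_auc), x$mean_auc, x$sd_auc, x$range_auc))
  if (x$mean_auc < 0.5) cat("  note: mean AUC < 0.5 — worse than chance\n")
  cat(sprintf("  pooled confusion (threshold %g): TP %d FP %d FN %d TN %d\n",
              x$threshold, x$counts[["tp"]], x$counts[["fp"]],
              x$counts[["fn"]], x$counts[["tn"]]))
  cat(sprintf("  accuracy %.3f | precision %.3f | recall %.3f | F %.3f\n",
              x$accuracy, x$precision, x$recall, x$f_score))
  invisible(x)
}

#' @exportS3Method
tidy.eval_report <- function(x, ...) {
  tibble::tibble(
    comparison = x$comparison,
    iteration = seq_along(x$iteration_auc),
    auc = x$iteration_auc
  )
}

#' @exportS3Method
glance.eval_report <- function(x, ...) {
  tibble::tibble(
    comparison = x$comparison,
    mean_auc = x$mean_auc,
    sd_auc = x$sd_auc,
    range_auc = x$range_auc,
    tp = x$counts[["tp"]], fp = x$counts[["fp"]],
    fn = x$counts[["fn"]], tn = x$counts[["tn"]],
    accuracy = x$accuracy,
    precision = x$precision,
    recall = x$recall,
    f_score = x$f_score
  )
}

#' Run the full pairwise artifact-recognition experiment
#'
#' For each artifact class present in the labeled image set, runs the
#' complete binary pipeline against the originals: singular-value feature
#' extraction, repeated seeded k-fold cross-validation of a kernel SVM,
#' per-iteration ROC/AUC from pooled out-of-fold scores, and pooled
#' confusion-matrix metrics. Fully deterministic given `cv$seed`.
#'
#' @param images List of grayscale matrices.
#' @param labels Character labels, one per image; must include
#'   `"original"` and at least one artifact class.
#' @param k,null_tol Feature parameters (see [extract_features()]).
#' @param groups Optional source-image grouping for paired CV (see
#'   [cross_validate_scores()]); use it whenever the artifact images derive
#'   from the originals in the set.
#' @param kernel A [kernel_spec()].
#' @param cv A [cv_spec()].
#' @param threshold Confusion-matrix operating point.
#' @return Named list of [summarize_evaluation()] reports, one per artifact
#'   class, with class `eval_report_set`.
#' @export
run_experiment <- function(images, labels, k = 32, null_tol = 1e-10,
                           groups = NULL, kernel = kernel_spec(),
                           cv = cv_spec(), threshold = 0) {
  features <- build_feature_dataset(images, labels, k = k,
                                    null_tol = null_tol, groups = groups)
  evaluate_features(features, kernel = kernel, cv = cv, threshold = threshold)
}

#' Evaluate a prebuilt feature table pairwise against the originals
#'
#' The evaluation stage of [run_experiment()], exposed for workflows that
#' already hold a feature tibble (e.g. read back from the feature CSV).
#'
#' @param features Feature tibble with an `"original"` class and at least
#'   one artifact class.
#' @inheritParams run_experiment
#' @return An `eval_report_set`.
#' @export
evaluate_features <- function(features, kernel = kernel_spec(),
                              cv = cv_spec(), threshold = 0) {
  labels <- features$label
  if (!"original" %in% labels) abort("`label` must include \"original\".")
  artifact_classes <- setdiff(unique(labels), "original")
  if (length(artifact_classes) == 0L) {
    abort("`label` must include at least one artifact class.")
  }
  reports <- lapply(artifact_classes, function(cls) {
    sub <- dplyr::filter(features, .data$label %in% c("original", cls))
    scores <- cross_validate_scores(sub, kernel = kernel, cv = cv,
                                    positive = cls)
    summarize_evaluation(scores, comparison = paste("original vs", cls),
                         positive = cls, threshold = threshold)
  })
  names(reports) <- artifact_classes
  structure(reports, class = "eval_report_set")
}

#' @export
print.eval_report_set <- function(x, ...) {
  for (r in x) print(r)
  invisible(x)
}

#' @exportS3Method
glance.eval_report_set <- function(x, ...) {
  purrr::map_dfr(x, glance)
}

#' @exportS3Method
tidy.eval_report_set <- function(x, ...) {
  purrr::map_dfr(x, tidy)
}
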