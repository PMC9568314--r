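test_that("k-fold splits partition the indices with balanced sizes", {
  folds <- kfold_split(10, 3, seed = 1)
  expect_setequal(lengths(folds), c(4L, 3L, 3L))
  expect_setequal(unlist(folds), 1:10)
  expect_identical(sum(lengths(folds)), 10L)

  folds <- kfold_split(172, 4, seed = 2)
  expect_identical(unname(lengths(folds)), rep(43L, 4))
  expect_setequal(unlist(folds), 1:172)

  folds <- kfold_split(10, 5, seed = 3)
  expect_identical(unname(lengths(folds)), rep(2L, 5))

  expect_identical(kfold_split(20, 4, seed = 9), kfold_split(20, 4, seed = 9))
  expect_false(identical(kfold_split(20, 4, seed = 9),
                         kfold_split(20, 4, seed = 10)))
  expect_error(kfold_split(3, 5), "exceed")
})

test_that("leave-one-out holds out each sample exactly once", {
  splits <- loo_split(3)
  expect_identical(splits, list(1L, 2L, 3L))
  expect_length(loo_split(172), 172)
  for (i in seq_along(splits)) {
    train <- setdiff(1:3, splits[[i]])
    expect_length(train, 2)
    expect_false(splits[[i]] %in% train)
  }
  expect_error(loo_split(1), "must be in")
})

test_that("ROC handles perfect, uninformative and toy rankings", {
  perfect <- roc_curve(c(3, 2, 1, 0), c(1, 1, -1, -1))
  expect_equal(perfect$auc, 1)
  ties <- roc_curve(rep(0.5, 6), c(1, 1, 1, -1, -1, -1))
  expect_equal(ties$auc, 0.5)
  toy <- roc_curve(c(0.9, 0.8, 0.3, 0.1), c(1, -1, 1, -1))
  expect_equal(toy$auc, 0.75)
  expect_equal(toy$auc, oracle_auc(c(0.9, 0.8, 0.3, 0.1), c(1, -1, 1, -1)))
})

test_that("ROC curves start at (0,0), end at (1,1) and are monotone", {
  set.seed(41)
  for (rep in 1:10) {
    sc <- rnorm(30)
    lb <- sample(c(-1, 1), 30, replace = TRUE, prob = c(0.4, 0.6))
    if (length(unique(lb)) < 2) next
    r <- roc_curve(sc, lb)
    expect_equal(r$points$fpf[1], 0)
    expect_equal(r$points$tpf[1], 0)
    expect_equal(dplyr::last(r$points$fpf), 1)
    expect_equal(dplyr::last(r$points$tpf), 1)
    expect_true(all(diff(r$points$fpf) >= 0))
    expect_true(all(diff(r$points$tpf) >= 0))
  }
  expect_error(roc_curve(1:3, c(1, 1, 1)), "both classes")
})

test_that("trapezoidal AUC equals Mann-Whitney pair counting", {
  set.seed(42)
  for (rep in 1:100) {
    n <- sample(8:40, 1)
    # draw from a coarse grid so score ties genuinely occur
    sc <- sample(seq(0, 1, 0.125), n, replace = TRUE)
    lb <- sample(c(-1, 1), n, replace = TRUE)
    if (length(unique(lb)) < 2) next
    r <- roc_curve(sc, lb)
    expect_equal(r$auc, oracle_auc(sc, lb), tolerance = 1e-12)
  }
})

test_that("AUC agrees with an independent ROC implementation", {
  set.seed(43)
  for (rep in 1:10) {
    sc <- rnorm(50)
    lb <- sample(c(-1, 1), 50, replace = TRUE)
    if (length(unique(lb)) < 2) next
    ref <- as.numeric(pROC::auc(pROC::roc(lb, sc, levels = c(-1, 1),
                                          direction = "<", quiet = TRUE)))
    expect_equal(roc_curve(sc, lb)$auc, ref, tolerance = 1e-12)
  }
})

test_that("confusion-matrix metrics evaluate their formulas", {
  expect_equal(precision(c(tp = 8, fp = 2, fn = 0, tn = 0)), 0.8)
  expect_equal(precision(c(tp = 5, fp = 0, fn = 1, tn = 1)), 1)
  expect_equal(precision(c(tp = 1, fp = 3, fn = 0, tn = 0)), 0.25)
  expect_equal(recall(c(tp = 9, fp = 0, fn = 1, tn = 0)), 0.9)
  expect_equal(recall(c(tp = 4, fp = 0, fn = 0, tn = 2)), 1)
  expect_equal(recall(c(tp = 3, fp = 0, fn = 1, tn = 0)), 0.75)
  expect_equal(f_score(0.8, 0.9), 2 * 0.8 * 0.9 / 1.7)
  expect_equal(f_score(0.6, 0.6), 0.6)
  expect_equal(f_score(1, 0.5), 2 / 3)
  expect_error(precision(c(tp = 0, fp = 0, fn = 1, tn = 1)), "undefined")
  expect_error(recall(c(tp = 0, fp = 1, fn = 0, tn = 1)), "undefined")
  expect_error(f_score(0, 0), "undefined")
})

test_that("F-score lies between precision and recall", {
  set.seed(44)
  for (rep in 1:50) {
    p <- runif(1, 0.05, 1)
    r <- runif(1, 0.05, 1)
    f <- f_score(p, r)
    expect_gte(f, min(p, r) - 1e-12)
    expect_lte(f, max(p, r) + 1e-12)
  }
})

test_that("confusion counts partition the evaluated samples", {
  set.seed(45)
  sc <- rnorm(25)
  lb <- sample(c(-1, 1), 25, replace = TRUE)
  counts <- confusion_counts(sc, lb)
  expect_identical(sum(counts), 25L)
})

test_that("out-of-fold predictions never come from a model trained on them", {
  set.seed(46)
  pts <- rbind(matrix(rnorm(20, 0), 10, 2), matrix(rnorm(20, 1), 10, 2))
  data <- points_to_features(pts, rep(c("original", "art"), each = 10))
  cv <- cv_spec("kfold", k = 2, iterations = 3, seed = 99)
  scores <- cross_validate_scores(data, kernel_spec("gaussian", C = 1),
                                  cv = cv, positive = "art")
  expect_identical(nrow(scores), 20L * 3L)
  for (it in 1:3) {
    sub <- dplyr::filter(scores, iteration == it)
    # every sample scored exactly once per iteration
    expect_setequal(sub$row, 1:20)
    # fold bookkeeping reproduces the seeded split: the row must sit in its
    # recorded test fold, hence outside that fold's training set
    folds <- kfold_split(20, 2, seed = ctartsim:::sub_seed(99, it))
    for (f in seq_along(folds)) {
      rows_f <- sort(dplyr::filter(sub, fold == f)$row)
      expect_identical(rows_f, sort(folds[[f]]))
      train_f <- setdiff(1:20, folds[[f]])
      expect_length(intersect(rows_f, train_f), 0)
    }
  }
})

test_that("paired grouping keeps all derivatives of a source in one fold", {
  set.seed(47)
  pts <- matrix(rnorm(48), 24, 2)
  data <- points_to_features(pts, rep(c("original", "art"), each = 12))
  data$group <- rep(1:12, times = 2)
  cv <- cv_spec("kfold", k = 3, iterations = 2, seed = 5)
  scores <- cross_validate_scores(data, kernel_spec("gaussian", C = 1),
                                  cv = cv, positive = "art")
  by_fold <- scores |>
    dplyr::mutate(group = data$group[row]) |>
    dplyr::distinct(iteration, group, fold)
  # each group appears in exactly one fold per iteration
  expect_identical(nrow(by_fold), 12L * 2L)
})

test_that("evaluation reports carry bounded metrics and per-iteration AUCs", {
  set.seed(48)
  pts <- rbind(matrix(rnorm(24, 0, 0.5), 12, 2),
               matrix(rnorm(24, 2, 0.5), 12, 2))
  data <- points_to_features(pts, rep(c("original", "art"), each = 12))
  cv <- cv_spec("kfold", k = 3, iterations = 4, seed = 6)
  scores <- cross_validate_scores(data, kernel_spec("gaussian", C = 1),
                                  cv = cv, positive = "art")
  rep_ <- summarize_evaluation(scores, "original vs art", positive = "art")
  expect_length(rep_$iteration_auc, 4)
  for (v in c(rep_$mean_auc, rep_$accuracy, rep_$precision, rep_$recall,
              rep_$f_score)) {
    expect_gte(v, 0)
    expect_lte(v, 1)
  }
  expect_gte(rep_$sd_auc, 0)
  expect_gte(rep_$range_auc, 0)
  expect_identical(sum(rep_$counts), nrow(scores))
  gl <- glance(rep_)
  expect_identical(gl$comparison, "original vs art")
  td <- tidy(rep_)
  expect_identical(nrow(td), 4L)
  expect_equal(mean(td$auc), rep_$mean_auc)
})

test_that("run_experiment requires the original class and reports per artifact", {
  imgs <- generate_image_set(6, phantom_spec(height = 48, width = 48), seed = 8)
  arts <- simulate_artifact_set(imgs, seed = 8)
  all_images <- c(list(original = imgs), arts)
  flat <- unlist(all_images, recursive = FALSE)
  labels <- rep(names(all_images), times = lengths(all_images))
  reports <- run_experiment(flat, labels, k = 16,
                            groups = rep(1:6, 4),
                            cv = cv_spec(k = 2, iterations = 2, seed = 1))
  expect_named(reports, c("motion", "rings", "beam_hardening"))
  expect_s3_class(reports, "eval_report_set")
  expect_identical(nrow(glance(reports)), 3L)
  expect_error(run_experiment(flat, rep("motion", length(flat))),
               "original")
})
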