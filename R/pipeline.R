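#' Configuration for the end-to-end pipeline
#'
#' One flat record pinning every tunable of the four-stage methodology
#' (image set, artifact simulation, SVD features, SVM + validation). The
#' whole run is reproducible from `seed`; every stochastic stage derives a
#' sub-seed from it.
#'
#' @param n_images Number of synthetic originals (default 43; each artifact
#'   simulator is applied to all of them, so the full set has
#'   `4 * n_images` images).
#' @param image_size Square canvas size in pixels.
#' @param noise_sd,plane_style Phantom parameters (see [phantom_spec()]).
#' @param motion_theta_range Magnitude range (degrees) of the per-image
#'   rotation draw; the sign is random.
#' @param ring_count,ring_amplitude,ring_width Ring-artifact parameters.
#' @param beam_threshold,beam_strength,beam_otsu_mask Beam-hardening
#'   parameters.
#' @param k,null_tol Feature parameters.
#' @param kernel_family,C,gamma,degree,coef0 SVM kernel parameters
#'   (see [kernel_spec()]).
#' @param cv_k,iterations Cross-validation folds and repeat count.
#' @param decision_threshold Operating point for confusion counts.
#' @param seed Global integer seed.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(n_images = 43,
                            image_size = 256,
                            noise_sd = 0.02,
                            plane_style = "axial",
                            motion_theta_range = c(5, 25),
                            ring_count = 4,
                            ring_amplitude = 0.25,
                            ring_width = 2,
                            beam_threshold = 0.4,
                            beam_strength = 0.5,
                            beam_otsu_mask = TRUE,
                            k = 32,
                            null_tol = 1e-10,
                            kernel_family = "gaussian",
                            C = 1,
                            gamma = NULL,
                            degree = 3,
                            coef0 = 1,
                            cv_k = 4,
                            iterations = 30,
                            decision_threshold = 0,
                            seed = 1L) {
  cfg <- list(
    n_images = as.integer(n_images), image_size = as.integer(image_size),
    noise_sd = noise_sd, plane_style = plane_style,
    motion_theta_range = as.numeric(motion_theta_range),
    ring_count = as.integer(ring_count), ring_amplitude = ring_amplitude,
    ring_width = ring_width,
    beam_threshold = beam_threshold, beam_strength = beam_strength,
    beam_otsu_mask = beam_otsu_mask,
    k = as.integer(k), null_tol = null_tol,
    kernel_family = kernel_family, C = C, gamma = gamma,
    degree = as.integer(degree), coef0 = coef0,
    cv_k = as.integer(cv_k), iterations = as.integer(iterations),
    decision_threshold = decision_threshold,
    seed = as.integer(seed)
  )
  # every sub-spec must validate under its own constructor
  phantom_spec(height = cfg$image_size, width = cfg$image_size,
               noise_sd = cfg$noise_sd, plane_style = cfg$plane_style)
  stopifnot(length(cfg$motion_theta_range) == 2L,
            all(cfg$motion_theta_range >= 0))
  beam_hardening_spec(cfg$beam_threshold, cfg$beam_strength, cfg$beam_otsu_mask)
  kernel_spec(cfg$kernel_family, C = cfg$C, gamma = cfg$gamma,
              degree = cfg$degree, coef0 = cfg$coef0)
  cv_spec("kfold", k = cfg$cv_k, iterations = cfg$iterations, seed = cfg$seed)
  structure(cfg, class = "pipeline_config")
}

#' Serialize / restore a pipeline configuration (YAML)
#'
#' `read_config(write_config(cfg, path))` reproduces `cfg` exactly.
#'
#' @param config A [pipeline_config()].
#' @param path File path.
#' @return `read_config()` returns the restored `pipeline_config`;
#'   `write_config()` returns `path` invisibly.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  obj <- yaml::read_yaml(path)
  do.call(pipeline_config, obj)
}

#' Apply all three artifact simulators to an image set
#'
#' Produces the three artifact variants of every original: a per-image
#' seeded rotation (magnitude uniform in `theta_range`, random sign),
#' the default concentric-ring overlay, and beam hardening. Per-image
#' rotation draws use sub-seeds derived from `seed`, so the set is
#' reproducible.
#'
#' @param originals List of grayscale matrices.
#' @param seed Integer seed for the rotation draws.
#' @param theta_range Magnitude range of rotation angles in degrees.
#' @param rings A [ring_spec()], or `NULL` for [default_ring_spec()] of the
#'   first image.
#' @param beam A [beam_hardening_spec()].
#' @return Named list with elements `motion`, `rings`, `beam_hardening`,
#'   each a list parallel to `originals`.
#' @export
simulate_artifact_set <- function(originals, seed = 1L,
                                  theta_range = c(5, 25),
                                  rings = NULL,
                                  beam = beam_hardening_spec()) {
  if (length(originals) == 0L) abort("`originals` is empty.")
  if (is.null(rings)) rings <- default_ring_spec(originals[[1]])
  motion <- lapply(seq_along(originals), function(i) {
    draw <- with_seed(sub_seed(seed, 10000 + i), {
      c(runif(1, theta_range[1], theta_range[2]), sample(c(-1, 1), 1))
    })
    theta <- draw[1] * draw[2]
    simulate_motion(originals[[i]], motion_spec(theta = theta))
  })
  list(
    motion = motion,
    rings = lapply(originals, simulate_rings, spec = rings),
    beam_hardening = lapply(originals, simulate_beam_hardening, spec = beam)
  )
}

#' Run the end-to-end pipeline
#'
#' Executes the four-stage methodology: (1) generate the seeded synthetic
#' image set; (2) apply the three artifact simulators to every original;
#' (3) extract singular-value features into one tidy table; (4) run the
#' repeated cross-validated SVM evaluation for each artifact-vs-original
#' comparison. When `out_dir` is given, writes the labeled image
#' directories (`original/`, `motion/`, `rings/`, `beam_hardening/`), the
#' feature CSV, one serialized full-data SVM model per comparison, the
#' evaluation report JSON, a per-iteration AUC CSV, and a manifest
#' recording the full configuration plus an MD5 of every written file.
#' Rerunning with the same config reproduces all numeric outputs.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory, or `NULL` to skip writing files.
#' @return List with `features` (tibble), `reports`
#'   (an `eval_report_set`), `images` (named list of image lists), and
#'   `paths` (written files, when `out_dir` is used), invisibly.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL) {
  if (!inherits(config, "pipeline_config")) {
    abort("`config` must be a pipeline_config.")
  }
  base_spec <- phantom_spec(height = config$image_size,
                           width = config$image_size,
                           noise_sd = config$noise_sd,
                           plane_style = config$plane_style)
  originals <- generate_image_set(config$n_images, base_spec,
                                  seed = config$seed)
  first <- originals[[1]]
  rings <- ring_spec(
    radii = seq(0.15, 0.45, length.out = config$ring_count) * min(dim(first)),
    ring_width = config$ring_width, amplitude = config$ring_amplitude
  )
  beam <- beam_hardening_spec(config$beam_threshold, config$beam_strength,
                              config$beam_otsu_mask)
  artifacts <- simulate_artifact_set(
    originals, seed = config$seed,
    theta_range = config$motion_theta_range,
    rings = rings, beam = beam
  )
  images <- c(list(original = originals), artifacts)
  all_images <- unlist(images, recursive = FALSE)
  labels <- rep(names(images), times = lengths(images))
  names(all_images) <- sprintf("%s_%03d", labels,
                               unlist(lapply(lengths(images), seq_len)))
  kernel <- kernel_spec(config$kernel_family, C = config$C,
                        gamma = config$gamma, degree = config$degree,
                        coef0 = config$coef0)
  cv <- cv_spec("kfold", k = config$cv_k, iterations = config$iterations,
                seed = config$seed)
  groups <- rep(seq_len(config$n_images), length(images))
  features <- build_feature_dataset(all_images, labels, k = config$k,
                                    null_tol = config$null_tol,
                                    groups = groups)
  reports <- evaluate_features(features, kernel = kernel, cv = cv,
                               threshold = config$decision_threshold)
  paths <- character()
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (cls in names(images)) {
      d <- file.path(out_dir, "images", cls)
      dir.create(d, recursive = TRUE, showWarnings = FALSE)
      for (i in seq_along(images[[cls]])) {
        p <- file.path(d, sprintf("%s_%03d.png", cls, i))
        write_image(images[[cls]][[i]], p)
        paths <- c(paths, p)
      }
    }
    fpath <- file.path(out_dir, "features.csv")
    utils::write.csv(features, fpath, row.names = FALSE)
    paths <- c(paths, fpath)
    for (cls in names(reports)) {
      sub <- dplyr::filter(features, .data$label %in% c("original", cls))
      model <- train_svm(sub, kernel = kernel, positive = cls)
      mpath <- file.path(out_dir, sprintf("model_%s.json", cls))
      write_svm_json(model, mpath)
      paths <- c(paths, mpath)
    }
    rpath <- file.path(out_dir, "reports.json")
    jsonlite::write_json(
      list(summary = glance(reports), per_iteration_auc = tidy(reports)),
      rpath, dataframe = "rows", digits = NA
    )
    apath <- file.path(out_dir, "iteration_auc.csv")
    utils::write.csv(tidy(reports), apath, row.names = FALSE)
    paths <- c(paths, rpath, apath)
    cpath <- file.path(out_dir, "config.yaml")
    write_config(config, cpath)
    paths <- c(paths, cpath)
    manifest <- list(
      config = unclass(config),
      n_images_total = length(all_images),
      class_counts = as.list(table(labels)),
      files = lapply(paths, function(p) {
        list(path = p, md5 = unname(tools::md5sum(p)))
      })
    )
    mpath <- file.path(out_dir, "manifest.json")
    jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, digits = NA)
    paths <- c(paths, mpath)
  }
  invisible(list(features = features, reports = reports, images = images,
                 paths = paths))
}
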