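#' Pipeline configuration
#'
#' One object collecting every tunable of the counting pipeline, with
#' defaults matching the published method where it states them (SVM
#' C = 1.0, gamma "scale", 4 selected features, 4:1 split, 3 x 3 elliptic
#' erosion, 5 x 5 rectangular dilation, 8-connectivity, alpha = 0.05)
#' and this package's documented choices elsewhere (index thresholds).
#' Serializable to/from a single YAML file.
#'
#' @param veg_threshold,soil_threshold Background-removal thresholds, see
#'   [background_mask()].
#' @param se_erode,se_dilate Structuring elements ([struct_elem()]) or
#'   lists `list(shape=, size=)`.
#' @param classifier A [classifier_config()].
#' @param min_area Minimum component area kept when counting (default 1).
#' @param seed Integer seed.
#' @param alpha Significance level for genotype comparisons.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(veg_threshold = 0, soil_threshold = 0.25,
                            se_erode = struct_elem("elliptic", c(3, 3)),
                            se_dilate = struct_elem("rectangular", c(5, 5)),
                            classifier = classifier_config(),
                            min_area = 1L, seed = 1L, alpha = 0.05) {
  as_se <- function(x) {
    if (inherits(x, "struct_elem")) x
    else struct_elem(x$shape, unlist(x$size))
  }
  structure(list(veg_threshold = veg_threshold, soil_threshold = soil_threshold,
                 se_erode = as_se(se_erode), se_dilate = as_se(se_dilate),
                 classifier = classifier, min_area = as.integer(min_area),
                 seed = as.integer(seed), alpha = alpha),
            class = "pipeline_config")
}

#' Read / write a pipeline configuration as YAML
#'
#' Fields absent from the file keep their defaults; `...` overrides win
#' over the file (the CLI maps flags onto it).
#'
#' @param path YAML file path.
#' @param ... Named overrides applied after reading.
#' @return A [pipeline_config()].
#' @export
read_pipeline_config <- function(path = NULL, ...) {
  vals <- if (!is.null(path)) yaml::read_yaml(path) else list()
  overrides <- list(...)
  vals[names(overrides)] <- overrides
  cls_fields <- vals$classifier %||% list()
  cls <- do.call(classifier_config,
                 cls_fields[intersect(names(cls_fields),
                                      names(formals(classifier_config)))])
  vals$classifier <- cls
  known <- intersect(names(vals), names(formals(pipeline_config)))
  do.call(pipeline_config, vals[known])
}

#' @rdname read_pipeline_config
#' @param config A [pipeline_config()] to serialize.
#' @export
write_pipeline_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  out <- list(
    veg_threshold = config$veg_threshold,
    soil_threshold = config$soil_threshold,
    se_erode = list(shape = config$se_erode$shape,
                    size = as.integer(config$se_erode$size)),
    se_dilate = list(shape = config$se_dilate$shape,
                     size = as.integer(config$se_dilate$size)),
    classifier = unclass(config$classifier),
    min_area = config$min_area, seed = config$seed, alpha = config$alpha)
  yaml::write_yaml(out, path)
  invisible(path)
}

#' Estimate the boll count of one plot image
#'
#' Runs the full per-plot pipeline: color-index background removal,
#' feature extraction for retained pixels, SVM prediction, rasterization,
#' morphological post-processing and 8-connected component counting.
#' Per-stage pixel counts are attached as the `stage_counts` attribute.
#'
#' @param image A [plot_image()].
#' @param classifier A trained [train_svm()] model.
#' @param config A [pipeline_config()].
#' @return A [count_components()] result for the plot.
#' @export
estimate_plot_yield <- function(image, classifier, config = pipeline_config()) {
  stopifnot(inherits(image, "plot_image"), inherits(classifier, "pixel_svm"))
  bg <- background_mask(image, config$veg_threshold, config$soil_threshold)
  feats <- extract_features(image, bg)
  labels <- predict_pixels(classifier, feats)
  mask <- labels_to_mask(feats, labels, dim(image$pixels)[1:2])
  post <- morph_postprocess(mask, config$se_erode, config$se_dilate)
  res <- count_components(post, connectivity = 8, min_area = config$min_area)
  attr(res, "stage_counts") <- c(bg$counts,
                                 list(predicted_cotton = sum(labels == 1L),
                                      after_morphology = sum(post)))
  attr(res, "plot_id") <- image$plot_id
  res
}

#' Train the pixel classifier from one annotated plot
#'
#' The training recipe applied to a single annotated plot image:
#' background removal, labeled feature extraction, 4:1 train/test split,
#' recursive feature elimination, SVM fit, and held-out metrics.
#'
#' @param image A [plot_image()].
#' @param mask The paired [annotation_mask()].
#' @param config A [pipeline_config()].
#' @return A `pixel_svm` with `metrics` (held-out
#'   [compute_metrics()] report), `split_sizes` and `retention`
#'   (stage pixel counts) attached.
#' @export
train_pipeline <- function(image, mask, config = pipeline_config()) {
  m <- if (inherits(mask, "annotation_mask")) mask else annotation_mask(mask)
  if (!all(dim(m$mask) == dim(image$pixels)[1:2]))
    stop_validation("mask dimensions do not match the image")
  bg <- background_mask(image, config$veg_threshold, config$soil_threshold)
  table <- extract_features(image, bg, m)
  parts <- split_dataset(table, config$classifier$split_ratio,
                         config$classifier$seed)
  fit <- train_svm(parts$train, config$classifier)
  test_pred <- predict_pixels(fit, parts$test)
  fit$metrics <- compute_metrics(test_pred, parts$test$label)
  fit$split_sizes <- c(train = nrow(parts$train), test = nrow(parts$test))
  fit$retention <- bg$counts
  fit
}

validate_count <- function(x, what) {
  if (!is_scalar_number(x) || x < 0 || x != round(x))
    stop_validation(sprintf("%s must be a non-negative integer", what))
  as.integer(x)
}

#' Pipeline commands
#'
#' The four batch entry points orchestrating the pipeline; the
#' `bollcount` command-line script (`system.file("cli", "bollcount.R",
#' package = "bollcount")`) is a thin wrapper over them. Each command is
#' deterministic given its inputs, configuration and seed.
#'
#' `cmd_simulate()` writes a synthetic scene (image, mask, truth JSON).
#' `cmd_train()` trains the classifier from one annotated plot and saves
#' the artifact plus a JSON metrics report. `cmd_count()` counts bolls on
#' a batch of plot images, writing a counts CSV and per-plot label maps.
#' `cmd_evaluate()` compares counts with ground truth, writing the
#' regression report, per-plot residuals and the genotype summary.
#'
#' @param out_dir Output directory.
#' @param n_bolls,seed Scene parameters for `cmd_simulate`.
#' @param scene Optional full [scene_config()] (overrides `n_bolls`/`seed`).
#' @param config A [pipeline_config()].
#' @return See each command: `cmd_simulate` the fixture paths,
#'   `cmd_train` the classifier (invisibly), `cmd_count` the counts
#'   tibble, `cmd_evaluate` a list with the regression report and
#'   genotype summary.
#' @name pipeline-commands
NULL

#' @rdname pipeline-commands
#' @export
cmd_simulate <- function(out_dir, n_bolls = 60L, seed = 1L, scene = NULL) {
  cfg <- scene %||% scene_config(n_bolls = validate_count(n_bolls, "n_bolls"),
                                 seed = seed)
  sc <- generate_scene(cfg)
  paths <- scene_to_training_fixture(sc, out_dir)
  message(sprintf("simulated scene '%s': %d bolls -> %s",
                  sc$image$plot_id, sc$true_count, out_dir))
  invisible(paths)
}

#' @rdname pipeline-commands
#' @param image_path,mask_path Paths to the annotated training plot.
#' @param model_path Where to save the classifier artifact.
#' @export
cmd_train <- function(image_path, mask_path, model_path,
                      config = pipeline_config()) {
  image <- read_plot_image(image_path)
  mask <- read_mask(mask_path)
  fit <- train_pipeline(image, mask, config)
  save_classifier(fit, model_path)
  report <- c(
    list(selected_features = fit$selected_features,
         n_train = unname(fit$split_sizes["train"]),
         n_test = unname(fit$split_sizes["test"]),
         retention = fit$retention),
    as.list(glance(fit$metrics)))
  jsonlite::write_json(report, paste0(model_path, ".metrics.json"),
                       auto_unbox = TRUE, digits = NA)
  message(sprintf("selected features: %s",
                  paste(fit$selected_features, collapse = ", ")))
  print(fit$metrics)
  invisible(fit)
}

#' @rdname pipeline-commands
#' @param image_paths Character vector of plot image paths.
#' @param classifier_path Path to a saved classifier artifact.
#' @param write_maps Write per-plot label-map TIFFs and RGB cluster
#'   visualizations next to the CSV.
#' @export
cmd_count <- function(image_paths, classifier_path, out_dir,
                      config = pipeline_config(), write_maps = TRUE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  classifier <- load_classifier(classifier_path)
  if (!length(image_paths)) warn("no input images; writing an empty counts table")
  rows <- purrr::map(image_paths, function(p) {
    img <- read_plot_image(p)
    res <- estimate_plot_yield(img, classifier, config)
    if (write_maps) {
      write_label_map(res, file.path(out_dir, paste0(img$plot_id, "_labels.tif")))
      write_plot_image(label_map_rgb(res),
                       file.path(out_dir, paste0(img$plot_id, "_clusters.png")))
    }
    sc <- attr(res, "stage_counts")
    message(sprintf("%s: %d bolls (%d px raw -> %d retained -> %d cotton)",
                    img$plot_id, res$boll_count, sc$raw_pixels,
                    sc$after_soil, sc$predicted_cotton))
    tibble(plot_id = img$plot_id, boll_count = res$boll_count)
  })
  counts <- if (length(rows)) bind_rows(rows)
            else tibble(plot_id = character(), boll_count = integer())
  readr::write_csv(counts, file.path(out_dir, "counts.csv"))
  counts
}

#' @rdname pipeline-commands
#' @param counts_csv CSV with `plot_id`, `boll_count` predictions.
#' @param truth_csv Ground-truth CSV (see [read_ground_truth()]).
#' @export
cmd_evaluate <- function(counts_csv, truth_csv, out_dir,
                         config = pipeline_config()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  counts <- readr::read_csv(counts_csv, show_col_types = FALSE)
  truth <- read_ground_truth(truth_csv)
  report <- regress_counts(counts, truth)
  summary <- genotype_summary(dplyr::inner_join(
    counts, truth[c("plot_id", "genotype")], by = "plot_id"),
    alpha = config$alpha)
  readr::write_csv(tidy(report), file.path(out_dir, "residuals.csv"))
  readr::write_csv(tidy(summary), file.path(out_dir, "genotype_summary.csv"))
  jsonlite::write_json(
    c(as.list(glance(report))[c("n", "slope", "intercept", "r_squared",
                                "nrmse", "mape_pct")],
      list(anova_f = summary$anova$f, anova_p = summary$anova$p,
           df_between = summary$anova$df_between,
           df_within = summary$anova$df_within)),
    file.path(out_dir, "metrics.json"), auto_unbox = TRUE, digits = NA)
  print(report)
  print(summary)
  invisible(list(regression = report, genotypes = summary))
}
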