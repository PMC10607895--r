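#' Default end-to-end run configuration
#'
#' A desk-scale configuration: 8 synthetic classes at 64 x 64 with the
#' kernel-size-1 variant and the channel schedule divided by 8. All seeds
#' derive from one master seed and are recorded in the outputs.
#'
#' @param out_dir output directory.
#' @param seed master seed.
#' @param n_classes,image_size,images_per_variant synthetic dataset knobs.
#' @param variant,width_divisor model knobs.
#' @param epochs,level_mode training knobs; `level_mode` is `"slm"`
#'   (leaf-level only) or `"mlm"` (all four levels).
#' @param method mask generation method (1 or 2).
#' @param n_scenes,scene_k evaluation scenes: how many composites, and the
#'   candidate ingredient counts sampled per scene.
#' @param scene_size side of the composed evaluation scenes; defaults to 4x
#'   the training crops, mirroring the usual crop-to-dish-photo size ratio.
#' @return A `run_config` list (YAML-serialisable).
#' @export
run_config <- function(out_dir, seed = 1L, n_classes = 8L, image_size = 64L,
                       images_per_variant = 6L, variant = "1",
                       width_divisor = 8L, epochs = 30L, level_mode = "slm",
                       method = 2L, n_scenes = 10L, scene_k = c(2L, 3L),
                       scene_size = 4L * image_size) {
  stopifnot(level_mode %in% c("slm", "mlm"), method %in% c(1L, 2L))
  structure(list(out_dir = out_dir, seed = as.integer(seed),
                 n_classes = as.integer(n_classes),
                 image_size = as.integer(image_size),
                 images_per_variant = as.integer(images_per_variant),
                 variant = variant, width_divisor = as.integer(width_divisor),
                 epochs = as.integer(epochs), level_mode = level_mode,
                 method = as.integer(method), n_scenes = as.integer(n_scenes),
                 scene_k = as.integer(scene_k),
                 scene_size = as.integer(scene_size)),
            class = "run_config")
}

#' Read a run configuration from YAML
#'
#' @param path YAML file; fields as in [run_config()].
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- yaml::read_yaml(path)
  if (is.null(raw$out_dir)) stop("config must set out_dir")
  do.call(run_config, raw)
}

# toy four-level taxonomy over n leaf classes: leaves are distributed over
# ceiling(n/4) level-3 nodes, 2 level-2 nodes, 1 root
toy_taxonomy <- function(n_leaves, leaf_names = paste0("ing", seq_len(n_leaves))) {
  n3 <- max(1L, ceiling(n_leaves / 4L))
  n2 <- min(2L, n3)
  ingredient_taxonomy(
    levels = list("root",
                  paste0("group", seq_len(n2)),
                  paste0("family", seq_len(n3)),
                  leaf_names),
    parents = list(rep(0L, n2),
                   (seq_len(n3) - 1L) %% n2,
                   (seq_len(n_leaves) - 1L) %% n3))
}

#' Run the full pipeline: synthesise, train, segment, evaluate
#'
#' Generates a synthetic single-ingredient dataset, trains a classifier,
#' segments freshly composed multi-ingredient scenes with the configured
#' method, scores the masks against the exact ground truth, and writes all
#' artifacts (manifest, checkpoint, history, masks, per-image and dataset
#' metric CSVs, resolved config with seeds) under `cfg$out_dir`.
#'
#' @param cfg a [run_config()] or path to a YAML file.
#' @param quiet suppress progress messages.
#' @return Invisibly, `list(model, report, test_report, out_dir)` where
#'   `report` is the [dataset_metrics()] result and `test_report` the
#'   held-out [classification_report()].
#' @export
run_pipeline <- function(cfg, quiet = FALSE) {
  if (is.character(cfg)) cfg <- read_run_config(cfg)
  stopifnot(inherits(cfg, "run_config"))
  say <- function(...) if (!quiet) message("[wingseg] ", ...)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)

  say("stage synth: generating dataset")
  specs <- default_class_specs(cfg$n_classes)
  tax <- toy_taxonomy(cfg$n_classes)
  ds <- tryCatch(
    generate_dataset(specs, tax, cfg$images_per_variant, cfg$image_size,
                     seed = cfg$seed),
    error = function(e) stop("stage synth failed: ", conditionMessage(e)))
  utils::write.csv(ds$manifest, file.path(cfg$out_dir, "manifest.csv"),
                   row.names = FALSE)
  tr <- ds$manifest$split == "train"

  say("stage train (", cfg$level_mode, "): ", sum(tr), " images, ",
      cfg$epochs, " epochs")
  gcfg <- gcnn_config(cfg$variant, cfg$n_classes,
                      input_size = cfg$image_size,
                      width_divisor = cfg$width_divisor)
  tcfg <- train_config(epochs = cfg$epochs, seed = cfg$seed)
  fit <- tryCatch({
    if (cfg$level_mode == "mlm") {
      model <- build_multilevel_gcnn(gcfg, tax, seed = cfg$seed)
      train_mlm(model, ds$images[tr], ds$hierarchical[tr, , drop = FALSE],
                tcfg)
    } else {
      model <- build_gated_cnn(gcfg, seed = cfg$seed)
      train_slm(model, ds$images[tr], ds$labels[tr], tcfg)
    }
  }, error = function(e) stop("stage train failed: ", conditionMessage(e)))
  utils::write.csv(fit$history, file.path(cfg$out_dir, "history.csv"),
                   row.names = FALSE)
  save_model(fit$model, file.path(cfg$out_dir, "model.rds"))
  test_report <- evaluate_classification(fit$model, ds$images[!tr],
                                         ds$labels[!tr])
  say(sprintf("held-out accuracy %.3f", test_report$accuracy))

  say("stage segment: ", cfg$n_scenes, " scenes, method ", cfg$method)
  scene_seeds <- with_seed(cfg$seed + 1L,
    sample.int(.Machine$integer.max - 1L, cfg$n_scenes))
  records <- NULL
  for (s in seq_len(cfg$n_scenes)) {
    k <- cfg$scene_k[((s - 1L) %% length(cfg$scene_k)) + 1L]
    sc <- compose_multi_ingredient_scene(
      scene_spec(k, cfg$scene_size, seed = scene_seeds[s]), specs)
    params <- if (cfg$method == 2L) {
      method2_params(k, background_present = TRUE, seed = scene_seeds[s])
    } else method1_params()
    seg <- tryCatch(
      segment_image(fit$model, sc$image, cfg$method, params),
      error = function(e) stop("stage segment failed on scene ", s, ": ",
                               conditionMessage(e)))
    sdir <- file.path(cfg$out_dir, sprintf("scene_%03d", s))
    write_masks(seg$masks, sdir,
                extra = list(seed = scene_seeds[s], k = k))
    write_image(sc$image, file.path(sdir, "scene.png"))
    write_label_map(sc$label_map, file.path(sdir, "label_map.png"))
    rec <- image_metrics(sc$masks, seg$masks)
    rec$scene <- s
    rec$k <- k
    records <- rbind(records, rec)
  }

  say("stage evaluate")
  report <- dataset_metrics(records)
  utils::write.csv(records, file.path(cfg$out_dir, "per_image_metrics.csv"),
                   row.names = FALSE)
  summary_row <- as.data.frame(t(report$dataset))
  utils::write.csv(summary_row, file.path(cfg$out_dir, "summary_metrics.csv"),
                   row.names = FALSE)
  resolved <- unclass(cfg)
  resolved$scene_seeds <- scene_seeds
  resolved$test_accuracy <- test_report$accuracy
  yaml::write_yaml(resolved, file.path(cfg$out_dir, "config_resolved.yaml"))
  say(sprintf("done: mIoU %.3f, mLoGTs %.3f",
              report$dataset[["mIoU"]], report$dataset[["mLoGTs"]]))
  invisible(list(model = fit$model, report = report,
                 test_report = test_report, out_dir = cfg$out_dir))
}
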