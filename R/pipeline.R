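# End-to-end pipeline: synthesize (or load) images -> preprocess ->
# VHT + deep feature extraction -> ACO selection -> serial fusion ->
# classifier variants -> evaluation report.  Every random stage carries an
# explicit seed so a rerun with the same configuration reproduces identical
# artifacts byte for byte.

#' Pipeline run configuration
#'
#' All arguments have working defaults; the configuration round-trips
#' losslessly through JSON ([write_config()] / [read_config()]).
#'
#' @param source `"synthetic"` or `"directory"`.
#' @param n_per_class synthetic images per class (synthetic source).
#' @param root class-directory root (directory source).
#' @param side standard square side after preprocessing.
#' @param target_per_class if non-`NULL`, classes are augmented up to this
#'   size before feature extraction.
#' @param data_seed seed of the synthetic generator / augmentation.
#' @param vht_grid pooling grid of the VHT extractor.
#' @param deep_dim,deep_seed surrogate deep backend dimension and seed.
#' @param aco ACO parameter list (see [aco_select()]).
#' @param fusion_grid list of `c(k_deep, k_vht)` pairs.
#' @param variants classifier variants to fit.
#' @param split_seed train/test split (and selection) seed.
#' @return A named list of class `pipeline_config`.
#' @export
pipeline_config <- function(source = "synthetic", n_per_class = 150,
                            root = NULL, side = 200, target_per_class = NULL,
                            data_seed = 1L, vht_grid = 4,
                            deep_dim = 4096, deep_seed = 11L,
                            aco = list(), fusion_grid = list(c(100, 100)),
                            variants = "cubic-svm", split_seed = 7L) {
  stopifnot(source %in% c("synthetic", "directory"))
  structure(list(source = source, n_per_class = n_per_class, root = root,
                 side = side, target_per_class = target_per_class,
                 data_seed = as.integer(data_seed), vht_grid = vht_grid,
                 deep_dim = deep_dim, deep_seed = as.integer(deep_seed),
                 aco = aco, fusion_grid = fusion_grid, variants = variants,
                 split_seed = as.integer(split_seed)),
            class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param config a `pipeline_config`.
#' @param path JSON file path.
#' @export
write_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname pipeline_config
#' @export
read_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!is.null(raw$fusion_grid)) {
    if (is.matrix(raw$fusion_grid)) {
      raw$fusion_grid <- lapply(seq_len(nrow(raw$fusion_grid)),
                                function(i) raw$fusion_grid[i, ])
    } else if (!is.list(raw$fusion_grid)) {
      raw$fusion_grid <- list(raw$fusion_grid)
    }
  }
  do.call(pipeline_config, raw)
}

stage_log <- function(stage, t0) {
  message(sprintf("[vhtrellis] %-12s %6.1fs", stage,
                  as.numeric(Sys.time() - t0, units = "secs")))
}

#' Run the full pipeline
#'
#' Executes all stages in order and writes per-stage artifacts under
#' `out_dir`: `config.json`, `manifest.csv`, `vht_features.csv`,
#' `deep_features.csv`, one `selection_*.json` per grid point,
#' `report.csv`, and `report.json`.  The report files contain no paths or
#' timestamps, so a rerun with an identical configuration reproduces them
#' byte for byte.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory for artifacts.
#' @param quiet suppress stage timing messages.
#' @return Invisibly, a list with the grid `table`, the named
#'   `eval_report`s, the ACO `selections`, and the artifact `paths`.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir,
                         quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log <- if (quiet) function(...) invisible() else stage_log
  write_config(config, file.path(out_dir, "config.json"))

  t0 <- Sys.time()
  img_dir <- file.path(out_dir, "images")
  if (config$source == "synthetic") {
    cfg <- smear_config(image_size = config$side, seed = config$data_seed)
    manifest <- generate_dataset(config$n_per_class, cfg, img_dir)
  } else {
    if (is.null(config$root) || !dir.exists(config$root)) {
      stop("stage data: directory source needs an existing 'root'")
    }
    files <- list.files(config$root, pattern = "\\.png$", recursive = TRUE,
                        full.names = TRUE)
    if (!length(files)) stop("stage data: no PNG images under ", config$root)
    manifest <- data.frame(path = sort(files),
                           label = basename(dirname(sort(files))),
                           provenance = "real")
    manifest <- preprocess_manifest(manifest, img_dir, side = config$side)
  }
  log("data", t0)

  if (!is.null(config$target_per_class)) {
    t0 <- Sys.time()
    manifest <- balance_dataset(manifest, config$target_per_class,
                                seed = config$data_seed, out_dir = img_dir)
    log("augment", t0)
  }
  data.table::fwrite(manifest, file.path(out_dir, "manifest.csv"))

  t0 <- Sys.time()
  vht_tab <- extract_vht_features(manifest, grid = config$vht_grid,
                                  side = config$side,
                                  out_file = file.path(out_dir,
                                                       "vht_features.csv"))
  log("vht", t0)

  t0 <- Sys.time()
  backend <- surrogate_backend(config$deep_seed, config$deep_dim)
  deep_tab <- featurize(manifest, backend,
                        out_file = file.path(out_dir, "deep_features.csv"))
  log("deep", t0)

  t0 <- Sys.time()
  table <- run_fusion_grid(deep_tab, vht_tab, grid = config$fusion_grid,
                           variants = config$variants,
                           seed = config$split_seed, aco = config$aco)
  log("fuse+classify", t0)

  selections <- attr(table, "selections")
  for (nm in names(selections)) {
    write_selection(selections[[nm]],
                    file.path(out_dir, sprintf("selection_%s.json", nm)))
  }
  data.table::fwrite(table, file.path(out_dir, "report.csv"))

  reports <- attr(table, "reports")
  grid_plain <- table
  attr(grid_plain, "reports") <- NULL
  attr(grid_plain, "selections") <- NULL
  report_json <- list(
    seeds = list(data = config$data_seed, deep = config$deep_seed,
                 split = config$split_seed),
    grid = grid_plain,
    reports = lapply(reports, function(r) {
      list(confusion = r$confusion, per_class = r$per_class,
           macro = as.list(r$macro), overall_accuracy = r$overall_accuracy,
           error = r$error, auc = as.list(r$auc))
    }))
  jsonlite::write_json(report_json, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "columns")

  invisible(list(table = table, reports = reports, selections = selections,
                 paths = list(
                   config = file.path(out_dir, "config.json"),
                   manifest = file.path(out_dir, "manifest.csv"),
                   vht = file.path(out_dir, "vht_features.csv"),
                   deep = file.path(out_dir, "deep_features.csv"),
                   report_csv = file.path(out_dir, "report.csv"),
                   report_json = file.path(out_dir, "report.json"))))
}
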