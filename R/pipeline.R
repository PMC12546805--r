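# Pipeline orchestration: a single entry point chaining the stages
# (simulate -> prepare -> quantify -> explore) from a flat key=value config,
# with logging and fixed seeds. Every run writes its resolved configuration
# next to its outputs so runs are self-describing.

pipeline_defaults <- function() list(
  seed = 42,
  output_root = "pipeline_out",
  # simulate
  n_phantoms = 5, length_min_um = 2, length_max_um = 10,
  radius_um = 0.25, snr = 5, background_level = 100,
  voxel_x_um = 0.08, voxel_y_um = 0.08, voxel_z_um = 0.5,
  psf_xy_um = 0.1, psf_z_um = 0.3, curvature = 0.05,
  grid_x = 160, grid_y = 160, grid_z = 10,
  # prepare
  channel = 1, method = "Otsu", style = "keep-intensities",
  histogram_source = "max-projection",
  bg_radius_px = NA_real_, blur_sigma_px = NA_real_,
  include_unsegmented_copy = 1,
  # quantify
  min_size_voxels = 10, exclude_border_x = 1, exclude_border_y = 1,
  exclude_border_z = 1, increase_range = 1, gauss_xy_sigma = 0.5,
  # explore
  alpha = 0.05, no_stats = 0, plot_format = "both")

#' Read a pipeline configuration
#'
#' Flat `key=value` file (one pair per line, `#` comments); unknown keys are
#' an error, unspecified keys take the documented defaults. The parsed
#' configuration round-trips losslessly through [write_config()].
#'
#' @param path config file path, or `NULL` for pure defaults.
#' @return named list of class `pipeline_config`.
#' @export
read_config <- function(path = NULL) {
  cfg <- pipeline_defaults()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path)
    lines <- readLines(path)
    lines <- trimws(sub("#.*$", "", lines))
    lines <- lines[nzchar(lines)]
    for (l in lines) {
      kv <- strsplit(l, "=", fixed = TRUE)[[1]]
      if (length(kv) < 2L) stop("malformed config line: ", l)
      key <- trimws(kv[1])
      val <- trimws(paste(kv[-1], collapse = "="))
      if (!key %in% names(cfg)) stop("unknown config key: ", key)
      num <- suppressWarnings(as.numeric(val))
      cfg[[key]] <- if (identical(val, "NA")) NA_real_
                    else if (!is.na(num)) num else val
    }
  }
  structure(cfg, class = "pipeline_config")
}

#' Write a pipeline configuration
#'
#' @param config a `pipeline_config`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  lines <- vapply(names(config), function(k)
    sprintf("%s=%s", k, format(config[[k]], scientific = FALSE)), "")
  writeLines(lines, path)
  invisible(path)
}

log_msg <- function(logfile, ...) {
  msg <- paste0(format(Sys.time(), "%H:%M:%S"), " ", ...)
  message(msg)
  if (!is.null(logfile)) cat(msg, "\n", file = logfile, append = TRUE)
}

#' Run the pipeline
#'
#' Executes the requested stage(s) in order with the seed and parameters in
#' `config`. `simulate` renders phantom stacks (with ground-truth tables),
#' `prepare` segments every TIFF in the input folder, `quantify` measures
#' every prepared stack into per-cilium tables, `explore` pools group folders
#' and runs QC/statistics/plots, and `all` chains the four on the simulated
#' phantoms end to end. Each stage writes into its own subfolder of
#' `output_root` together with the resolved config.
#'
#' @param command one of `"simulate"`, `"prepare"`, `"quantify"`,
#'   `"explore"`, `"all"`.
#' @param config a `pipeline_config` from [read_config()].
#' @param input input folder (stage-dependent; defaults to the previous
#'   stage's output under `output_root`).
#' @return (invisibly) a list of stage outputs.
#' @export
run_pipeline <- function(command = c("all", "simulate", "prepare",
                                     "quantify", "explore"),
                         config = read_config(), input = NULL) {
  command <- match.arg(command)
  root <- config$output_root
  dir.create(root, recursive = TRUE, showWarnings = FALSE)
  logfile <- file.path(root, "pipeline.log")
  write_config(config, file.path(root, "config_resolved.txt"))
  writeLines(paste("tool version", pipeline_version()),
             file.path(root, "VERSION.txt"))
  log_msg(logfile, "pipeline ", pipeline_version(), " | command=", command,
          " | seed=", config$seed)
  out <- list()
  stages <- if (command == "all")
    c("simulate", "prepare", "quantify", "explore") else command
  for (st in stages) {
    out[[st]] <- switch(st,
      simulate = stage_simulate(config, root, logfile),
      prepare = stage_prepare(config, root, logfile,
                              input %||% file.path(root, "simulated")),
      quantify = stage_quantify(config, root, logfile,
                                input %||% file.path(root, "prepared")),
      explore = stage_explore(config, root, logfile,
                              input %||% file.path(root, "tables")))
  }
  log_msg(logfile, "done")
  invisible(out)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

pipeline_version <- function() {
  as.character(utils::packageVersion("ciliometry"))
}

stage_simulate <- function(cfg, root, logfile) {
  dir <- file.path(root, "simulated")
  dir.create(dir, showWarnings = FALSE)
  vs <- c(cfg$voxel_x_um, cfg$voxel_y_um, cfg$voxel_z_um)
  bounds <- c(cfg$grid_x, cfg$grid_y, cfg$grid_z) * vs
  truth_rows <- list()
  for (i in seq_len(cfg$n_phantoms)) {
    cl <- generate_centerline(cfg$seed + i, bounds,
                              c(cfg$length_min_um, cfg$length_max_um),
                              curvature = cfg$curvature,
                              radius_um = cfg$radius_um)
    truth <- phantom_truth(list(cl), vs, snr = cfg$snr,
                           background_level = cfg$background_level,
                           psf_sigma_um = c(cfg$psf_xy_um, cfg$psf_xy_um,
                                            cfg$psf_z_um),
                           seed = cfg$seed + i)
    stk <- rasterize_scene(truth, c(cfg$grid_x, cfg$grid_y, cfg$grid_z))
    f <- file.path(dir, sprintf("phantom_%03d.tif", i))
    write_image_stack(stk, f)
    truth_rows[[i]] <- data.frame(phantom = basename(f),
                                  arc_length_um = cl$arc_length_um)
    log_msg(logfile, "simulated ", basename(f), " (truth ",
            sprintf("%.3f", cl$arc_length_um), " um)")
  }
  truth_df <- do.call(rbind, truth_rows)
  write.table(truth_df, file.path(dir, "ground_truth.tsv"), sep = "\t",
              row.names = FALSE, quote = FALSE)
  dir
}

stage_prepare <- function(cfg, root, logfile, input) {
  if (!dir.exists(input)) stop("input folder not found: ", input)
  files <- list.files(input, pattern = "\\.tif$", full.names = TRUE)
  if (!length(files)) stop("no TIFF stacks in ", input)
  dir <- file.path(root, "prepared")
  dir.create(dir, showWarnings = FALSE)
  settings <- segmentation_settings(
    channel_index = cfg$channel,
    include_unsegmented_copy = cfg$include_unsegmented_copy != 0,
    bg_radius_px = if (!is.na(cfg$bg_radius_px)) cfg$bg_radius_px,
    blur_sigma_px = if (!is.na(cfg$blur_sigma_px)) cfg$blur_sigma_px,
    method = cfg$method, style = cfg$style,
    histogram_source = cfg$histogram_source)
  for (f in files) {
    stk <- read_image_stack(f)
    seg <- segment_stack(stk, settings, tool_version = pipeline_version())
    out <- file.path(dir, sub("\\.tif$", "_CQP.tif", basename(f)))
    write_image_stack(seg, out)
    meta <- attr(seg, "metadata")
    writeLines(meta_to_lines(meta), sub("\\.tif$", "_settings.txt", out))
    log_msg(logfile, "prepared ", basename(out))
  }
  dir
}

stage_quantify <- function(cfg, root, logfile, input) {
  if (!dir.exists(input)) stop("input folder not found: ", input)
  files <- list.files(input, pattern = "_CQP\\.tif$", full.names = TRUE)
  if (!length(files)) stop("no prepared stacks (_CQP.tif) in ", input)
  dir <- file.path(root, "tables", "phantoms")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (f in files) {
    stk <- read_image_stack(f)
    tab <- quantify_stack(
      stk, min_size_voxels = cfg$min_size_voxels,
      exclude_borders = c(cfg$exclude_border_x != 0,
                          cfg$exclude_border_y != 0,
                          cfg$exclude_border_z != 0),
      increase_range = cfg$increase_range != 0,
      gauss_xy_sigma = cfg$gauss_xy_sigma,
      tool_version = pipeline_version())
    out <- file.path(dir, sub("_CQP\\.tif$", "_CQ.tsv", basename(f)))
    write_cilia_table(tab, out)
    log_msg(logfile, "quantified ", basename(f), ": ", nrow(tab$records),
            " cilium/cilia")
  }
  file.path(root, "tables")
}

stage_explore <- function(cfg, root, logfile, input) {
  if (!dir.exists(input)) stop("input folder not found: ", input)
  groups <- list.dirs(input, recursive = FALSE)
  if (!length(groups)) stop("no group folders in ", input)
  ds <- pool_groups(groups)
  qc <- qc_screen(ds)
  stats <- if (cfg$no_stats == 0)
    run_stats(ds, alpha = cfg$alpha) else NULL
  emb <- NULL
  feat <- tryCatch(select_features(ds), error = function(e) NULL)
  if (!is.null(feat) && nrow(feat$features) > 2L) {
    emb <- list(pca = embed_cilia(feat$features, "pca"))
    umap_try <- tryCatch(
      embed_cilia(feat$features, "umap", seed = cfg$seed),
      error = function(e) {
        log_msg(logfile, "umap unavailable: ", conditionMessage(e))
        NULL
      })
    if (!is.null(umap_try)) emb$umap <- umap_try
  }
  fmts <- switch(cfg$plot_format, png = "png", svg = "svg",
                 c("png", "svg"))
  files <- write_outputs(ds, qc, stats, first_group_path = groups[1],
                         embeddings = emb, alpha = cfg$alpha,
                         plot_formats = fmts)
  write_config(cfg, file.path(groups[1], "Analysis",
                              "config_resolved.txt"))
  log_msg(logfile, "explore wrote ", length(files), " files under ",
          file.path(groups[1], "Analysis"))
  file.path(groups[1], "Analysis")
}
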