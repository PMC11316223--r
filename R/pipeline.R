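#' Default pipeline configuration
#'
#' Returns the full parameter set of the pipeline as a nested list, the
#' same structure accepted as YAML by [run_all()]. `conditions` entries
#' accept any [scene_spec()] argument under `scene`.
#'
#' @param seed base RNG seed; per-image seeds are derived from it.
#' @return Named list.
#' @export
default_config <- function(seed = 1L) {
  list(
    seed = as.integer(seed),
    anchors = list(control = "control", myo = "TGFb"),
    params = list(
      autocontrast_saturated = 0.0035,
      tophat_radius = 5,
      min_nucleus_area = 50,
      max_nucleus_area = 500,
      min_fa_area = 0.4,
      exclude_border = TRUE,
      vesselness_scales = c(1, 2, 4)
    ),
    conditions = list(
      list(name = "control", n_images = 2,
           scene = list(n_cells = 6, cell_length = c(55, 6),
                        fa_radial_placement = 0.85,
                        fa_major = c(1.8, 0.3), fa_minor = c(1.1, 0.1))),
      list(name = "TGFb", n_images = 2,
           scene = list(n_cells = 6, cell_length = c(75, 6),
                        cell_width = c(24, 3),
                        fa_radial_placement = 0.25,
                        fa_major = c(2.8, 0.3), fa_minor = c(1.0, 0.1),
                        fa_per_cell = c(12, 1))),
      list(name = "20x20", n_images = 2,
           pattern = list(width = 20, spacing = 20, angle = 30),
           scene = list(n_cells = 6, cell_length = c(80, 8),
                        cell_width = c(14, 2),
                        cell_orientation_concentration = 4,
                        fa_radial_placement = 0.6,
                        fa_major = c(2.6, 0.3), fa_minor = c(0.9, 0.1)))
    )
  )
}

read_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  if (is.null(config$seed)) config$seed <- 1L
  if (is.null(config$anchors$control) || is.null(config$anchors$myo))
    stop("config validation: both anchor conditions (anchors$control, ",
         "anchors$myo) must be named")
  cond_names <- vapply(config$conditions, function(cn) cn$name, character(1))
  for (anchor in unlist(config$anchors))
    if (!anchor %in% cond_names)
      stop("config validation: anchor condition '", anchor,
           "' is not among the configured conditions")
  defaults <- default_config()$params
  for (nm in names(defaults))
    if (is.null(config$params[[nm]])) config$params[[nm]] <- defaults[[nm]]
  config
}

#' Run the full morphotyping pipeline
#'
#' Executes simulate -> preprocess -> segment -> measure -> heatmap ->
#' spatial -> rank -> stats on the configured (simulated) dataset, writing
#' every stage output as CSV plus a provenance manifest and a log to
#' `outdir`. All randomness derives from `config$seed`, so re-running with
#' the same configuration yields byte-identical CSV outputs.
#'
#' @param config configuration list or path to a YAML file; see
#'   [default_config()].
#' @param outdir output directory (created if needed).
#' @param log_level `"info"` or `"quiet"`.
#' @return Invisibly, a list with the main in-memory results
#'   (`morphometry`, `features`, `heatmap`, `distances`, `orientation`,
#'   `shap`, `stats`, `manifest`).
#' @export
run_all <- function(config, outdir, log_level = c("info", "quiet")) {
  log_level <- match.arg(log_level)
  config <- read_config(config)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(outdir, "pipeline.log")
  logf <- make_logger(log_path, quiet = log_level == "quiet")
  stage_times <- list()
  timed <- function(stage, expr) {
    t0 <- proc.time()[["elapsed"]]
    logf("stage %s: start", stage)
    out <- tryCatch(expr, error = function(e)
      stop("stage '", stage, "' failed: ", conditionMessage(e), call. = FALSE))
    dt <- proc.time()[["elapsed"]] - t0
    stage_times[[stage]] <<- dt
    logf("stage %s: done in %.2f s", stage, dt)
    out
  }
  p <- config$params

  # ---- simulate ----
  scenes <- timed("simulate", {
    out <- list()
    img_idx <- 0L
    for (cn in config$conditions) {
      for (k in seq_len(cn$n_images %||% 1L)) {
        img_idx <- img_idx + 1L
        args <- cn$scene %||% list()
        if (!is.null(cn$pattern))
          args$pattern <- pattern_spec(cn$pattern$width, cn$pattern$spacing,
                                       cn$pattern$angle %||% 0)
        args$seed <- config$seed * 1000L + img_idx
        sc <- do.call(scene_spec, args)
        scene <- generate_scene(sc)
        scene$images$condition <- cn$name
        scene$images$replicate <- sprintf("%s_img%d", cn$name, k)
        scene$spec <- sc
        out[[scene$images$replicate]] <- scene
      }
    }
    out
  })

  # ---- preprocess + segment + measure ----
  morph <- timed("segment_measure", {
    tabs <- list()
    for (id in names(scenes)) {
      sc <- scenes[[id]]
      pre <- preprocess_image_set(sc$images,
                                  saturated = p$autocontrast_saturated,
                                  tophat_radius = p$tophat_radius)
      nuc <- segment_nuclei(pre$channels$nuclei,
                            min_area = p$min_nucleus_area,
                            max_area = p$max_nucleus_area,
                            exclude_border = p$exclude_border)
      cell <- segment_cells(pre$channels$actin, nuc)
      fa <- segment_fas(pre$channels$fa, cell, min_area = p$min_fa_area)
      ps_um <- pre$channels$nuclei$pixel_size
      for (lm in list(nuc, cell, fa))
        tabs[[paste(id, lm$level)]] <- measure_objects(
          lm, ps_um, image_id = id, condition = sc$images$condition)
    }
    do.call(rbind, tabs)
  })
  write_table(morph, file.path(outdir, "morphometry.csv"))

  features <- timed("features", assemble_feature_matrix(morph))
  write_table(features, file.path(outdir, "feature_matrix.csv"))

  heat <- timed("heatmap", normalize_to_anchors(
    features, config$anchors$control, config$anchors$myo))
  write_table(as.data.frame(heat), file.path(outdir, "normalized_heatmap.csv"))
  timed("heatmap_figure", try(plot_heatmap(
    heat, file.path(outdir, "normalized_heatmap.pdf")), silent = TRUE))

  spatial <- timed("spatial", {
    ps_um <- scenes[[1]]$images$channels$nuclei$pixel_size
    dist <- fa_nucleus_distances(morph[morph$level == "fa", ],
                                 morph[morph$level == "nucleus", ],
                                 pixel_size = ps_um)
    orient <- cell_orientation(morph[morph$level == "cell", ])
    list(dist = dist, orient = orient)
  })
  write_table(spatial$dist$per_fa[, c("image_id", "condition", "label",
                                      "parent", "distance")],
              file.path(outdir, "fa_nucleus_distances.csv"))
  write_table(spatial$dist$per_condition,
              file.path(outdir, "fa_nucleus_distance_summary.csv"))
  write_table(spatial$orient$per_condition,
              file.path(outdir, "orientation_summary.csv"))
  timed("orientation_figure", try(plot_orientation(
    spatial$orient, file.path(outdir, "orientation.pdf")), silent = TRUE))

  shap <- timed("rank", rank_features_shap(
    features, control = config$anchors$control, seed = config$seed))
  write_table(shap$importance, file.path(outdir, "shap_importance.csv"))

  stats_res <- timed("stats", {
    top <- shap$importance$feature[1:min(3L, nrow(shap$importance))]
    res <- list()
    for (f in top) {
      groups <- split(features[[f]], features$condition)
      groups <- groups[order(names(groups) != config$anchors$control)]
      r <- anova_dunnett(groups, control = config$anchors$control,
                         seed = config$seed)
      res[[f]] <- cbind(feature = f, r$comparisons,
                        F = r$F, p_anova = r$p)
    }
    do.call(rbind, res)
  })
  write_table(stats_res, file.path(outdir, "group_stats.csv"))

  manifest <- list(
    package_version = as.character(utils::packageVersion("fibromorph")),
    seed = config$seed,
    anchors = config$anchors,
    conditions = vapply(config$conditions, function(cn) cn$name, character(1)),
    images = names(scenes),
    config_hash = config_hash(config),
    stage_seconds = stage_times,
    outputs = list.files(outdir))
  yaml::write_yaml(manifest, file.path(outdir, "manifest.yaml"))
  logf("pipeline complete; %d output file(s)", length(manifest$outputs))

  invisible(list(morphometry = morph, features = features, heatmap = heat,
                 distances = spatial$dist, orientation = spatial$orient,
                 shap = shap, stats = stats_res, manifest = manifest))
}

make_logger <- function(path, quiet = FALSE) {
  function(fmt, ...) {
    line <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"),
                    sprintf(fmt, ...))
    cat(line, "\n", file = path, append = TRUE, sep = "")
    if (!quiet) message(line)
  }
}

config_hash <- function(config) {
  tf <- tempfile()
  on.exit(unlink(tf))
  yaml::write_yaml(config, tf)
  unname(tools::md5sum(tf))
}

#' Plot the normalized morphometric heat map
#'
#' @param heat result of [normalize_to_anchors()].
#' @param path output PDF path.
#' @return `path`, invisibly.
#' @export
plot_heatmap <- function(heat, path) {
  d <- heat[heat$defined, ]
  g <- ggplot2::ggplot(d, ggplot2::aes(
    x = condition, y = feature, fill = normalized)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "#2166ac", mid = "white",
                                  high = "#b2182b", midpoint = 0.5,
                                  name = "FMT axis") +
    ggplot2::labs(x = "condition", y = NULL) +
    ggplot2::theme_minimal(base_size = 9)
  ggplot2::ggsave(path, g, width = 6, height = 8)
  invisible(path)
}

#' Plot pattern-relative cell orientation distributions
#'
#' @param orient result of [cell_orientation()].
#' @param path output PDF path.
#' @return `path`, invisibly.
#' @export
plot_orientation <- function(orient, path) {
  d <- orient$per_cell
  g <- ggplot2::ggplot(d, ggplot2::aes(x = condition, y = theta_rel)) +
    ggplot2::geom_violin(fill = "grey85") +
    ggplot2::geom_jitter(width = 0.08, size = 0.6) +
    ggplot2::scale_y_continuous(limits = c(-90, 90),
                                breaks = c(-90, -45, 0, 45, 90)) +
    ggplot2::labs(x = "condition",
                  y = "orientation relative to pattern (degrees)") +
    ggplot2::theme_minimal(base_size = 10)
  ggplot2::ggsave(path, g, width = 5, height = 4)
  invisible(path)
}

utils::globalVariables(c("condition", "feature", "normalized", "theta_rel"))
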