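# The fixed per-level descriptor catalog used in the per-cell feature matrix.
DESCRIPTOR_FEATURES <- c("area", "perimeter", "equivalent_diameter",
                         "major_axis", "minor_axis", "aspect_ratio",
                         "eccentricity", "solidity", "extent", "form_factor",
                         "compactness", "feret_max", "feret_min")

FA_AGGREGATE_FEATURES <- c("fa_area_mean", "fa_area_sd", "fa_area_total",
                           "fa_perimeter_mean", "fa_perimeter_sd",
                           "fa_major_axis_mean", "fa_major_axis_sd",
                           "fa_minor_axis_mean", "fa_aspect_ratio_mean",
                           "fa_eccentricity_mean", "fa_eccentricity_sd",
                           "fa_form_factor_mean", "fa_solidity_mean")

#' The fixed, ordered 40-feature morphometric catalog
#'
#' 13 shape descriptors at the cell level, the same 13 at the nucleus level,
#' 13 per-cell focal-adhesion aggregate summaries, and the per-cell FA
#' count: 40 features in a stable documented order. Includes the canonical
#' morphotype determinants (`fa_eccentricity_mean`, `cell_major_axis`,
#' `nucleus_eccentricity`).
#'
#' @return Character vector of length 40.
#' @export
feature_catalog <- function() {
  c(paste0("cell_", DESCRIPTOR_FEATURES),
    paste0("nucleus_", DESCRIPTOR_FEATURES),
    FA_AGGREGATE_FEATURES,
    "fa_count")
}

#' Assemble the per-cell feature matrix from per-level morphometry tables
#'
#' Joins each cell row with its nucleus (the nucleus with the same label,
#' since cells are seeded from nuclei and share labels) and aggregates its
#' focal adhesions into the fixed 40-feature catalog of [feature_catalog()].
#' Cells with zero FAs get all FA aggregates set to 0 and `zero_fa = TRUE`.
#'
#' @param tables a data.frame of [measure_objects()] rows covering levels
#'   `cell`, `nucleus` and (optionally) `fa`, or a list of such tables
#'   (rbound).
#' @return A data.frame with id columns (`image_id`, `condition`, `day`,
#'   `cell_label`, `zero_fa`) followed by the 40 feature columns, in
#'   catalog order. Attribute `feature_names` holds the catalog.
#' @export
assemble_feature_matrix <- function(tables) {
  if (is.list(tables) && !is.data.frame(tables))
    tables <- do.call(rbind, tables)
  stopifnot(is.data.frame(tables))
  cells <- tables[tables$level == "cell", , drop = FALSE]
  nucs <- tables[tables$level == "nucleus", , drop = FALSE]
  fas <- tables[tables$level == "fa", , drop = FALSE]

  out <- vector("list", nrow(cells))
  for (i in seq_len(nrow(cells))) {
    cl <- cells[i, ]
    nu <- nucs[nucs$image_id == cl$image_id & nucs$label == cl$label, ,
               drop = FALSE]
    if (nrow(nu) != 1L)
      stop("cell ", cl$label, " in image '", cl$image_id,
           "' has no unique matching nucleus (broken bijection)")
    fa <- fas[fas$image_id == cl$image_id & !is.na(fas$parent) &
                fas$parent == cl$label, , drop = FALSE]
    row <- data.frame(image_id = cl$image_id, condition = cl$condition,
                      day = cl$day, cell_label = cl$label,
                      zero_fa = nrow(fa) == 0L,
                      stringsAsFactors = FALSE)
    for (f in DESCRIPTOR_FEATURES) {
      row[[paste0("cell_", f)]] <- cl[[f]]
      row[[paste0("nucleus_", f)]] <- nu[[f]]
    }
    agg <- fa_aggregates(fa)
    for (f in names(agg)) row[[f]] <- agg[[f]]
    row$fa_count <- nrow(fa)
    out[[i]] <- row
  }
  res <- do.call(rbind, out)
  if (is.null(res)) {
    res <- data.frame()
  } else {
    res <- res[, c("image_id", "condition", "day", "cell_label", "zero_fa",
                   feature_catalog())]
  }
  attr(res, "feature_names") <- feature_catalog()
  res
}

fa_aggregates <- function(fa) {
  agg <- stats::setNames(as.list(rep(0, length(FA_AGGREGATE_FEATURES))),
                         FA_AGGREGATE_FEATURES)
  if (nrow(fa) == 0L) return(agg)
  sd0 <- function(x) if (length(x) > 1L) stats::sd(x) else 0
  agg$fa_area_mean <- mean(fa$area)
  agg$fa_area_sd <- sd0(fa$area)
  agg$fa_area_total <- sum(fa$area)
  agg$fa_perimeter_mean <- mean(fa$perimeter)
  agg$fa_perimeter_sd <- sd0(fa$perimeter)
  agg$fa_major_axis_mean <- mean(fa$major_axis)
  agg$fa_major_axis_sd <- sd0(fa$major_axis)
  agg$fa_minor_axis_mean <- mean(fa$minor_axis)
  agg$fa_aspect_ratio_mean <- mean(fa$aspect_ratio)
  agg$fa_eccentricity_mean <- mean(fa$eccentricity)
  agg$fa_eccentricity_sd <- sd0(fa$eccentricity)
  agg$fa_form_factor_mean <- mean(fa$form_factor)
  agg$fa_solidity_mean <- mean(fa$solidity)
  agg
}

#' Two-point phenotype-axis normalization of condition means
#'
#' For every feature, the per-condition means are mapped through the affine
#' transformation that sends the control-condition mean to 0 and the
#' myofibroblast-anchor mean to 1:
#' \deqn{n = (\bar x - \bar x_{ctrl}) / (\bar x_{myo} - \bar x_{ctrl}).}
#' The result is the normalized heat-map table of the
#' fibroblast-to-myofibroblast (FMT) phenotype axis. Features whose anchor
#' gap is below `tol` (relative to the anchor scale) are flagged
#' `defined = FALSE` rather than dropped.
#'
#' @param matrix a feature matrix from [assemble_feature_matrix()].
#' @param control_condition,myo_condition the two anchor condition labels;
#'   each must have at least 2 cells.
#' @param tol relative tolerance for a vanishing anchor gap.
#' @return A long data.frame of class `normalized_heatmap` with columns
#'   `condition`, `feature`, `mean`, `normalized`, `defined`.
#' @export
normalize_to_anchors <- function(matrix, control_condition, myo_condition,
                                 tol = 1e-9) {
  feats <- attr(matrix, "feature_names")
  if (is.null(feats)) feats <- intersect(feature_catalog(), names(matrix))
  stopifnot(length(feats) > 0, "condition" %in% names(matrix))
  conds <- unique(matrix$condition)
  for (anchor in c(control_condition, myo_condition)) {
    if (sum(matrix$condition == anchor) < 2L)
      stop("anchor condition '", anchor, "' needs at least 2 cells")
  }
  rows <- list()
  for (f in feats) {
    means <- tapply(matrix[[f]], matrix$condition, mean)
    m_ctrl <- means[[control_condition]]
    m_myo <- means[[myo_condition]]
    gap <- m_myo - m_ctrl
    scale <- max(abs(m_ctrl), abs(m_myo), 1e-12)
    defined <- is.finite(gap) && abs(gap) > tol * scale
    for (cd in conds) {
      rows[[length(rows) + 1L]] <- data.frame(
        condition = cd, feature = f, mean = means[[cd]],
        normalized = if (defined) (means[[cd]] - m_ctrl) / gap else NA_real_,
        defined = defined, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("normalized_heatmap", class(out))
  out
}
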