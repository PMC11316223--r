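#' @useDynLib fibromorph, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

CHANNEL_ROLES <- c("nuclei", "actin", "fa", "asma", "pattern")
LABEL_LEVELS <- c("nucleus", "cell", "fa")

#' Single-channel intensity image
#'
#' A `channel_image` wraps a 2D intensity matrix together with its physical
#' pixel size and the biological role of the channel. All downstream
#' operations consume this type rather than raw matrices, so unit handling
#' (micrometres vs pixels) is explicit throughout the pipeline.
#'
#' @param pixels numeric matrix of non-negative, finite intensities
#'   (rows x columns). Integer 8/16-bit input is converted to double.
#' @param pixel_size physical size of one pixel in micrometres (> 0).
#' @param role channel role, one of `"nuclei"`, `"actin"`, `"fa"`,
#'   `"asma"`, `"pattern"`.
#' @return An object of class `channel_image` with fields `pixels`,
#'   `pixel_size`, `role`.
#' @export
channel_image <- function(pixels, pixel_size, role) {
  if (!is.matrix(pixels) || length(pixels) == 0L)
    stop("`pixels` must be a non-empty matrix")
  storage.mode(pixels) <- "double"
  if (any(!is.finite(pixels)))
    stop("channel intensities must be finite")
  if (any(pixels < 0))
    stop("channel intensities must be non-negative")
  if (!is.numeric(pixel_size) || length(pixel_size) != 1L ||
      !is.finite(pixel_size) || pixel_size <= 0)
    stop("`pixel_size` must be a single positive number (µm per pixel)")
  role <- match.arg(role, CHANNEL_ROLES)
  structure(list(pixels = pixels, pixel_size = pixel_size, role = role),
            class = "channel_image")
}

#' @export
print.channel_image <- function(x, ...) {
  cat(sprintf("<channel_image> role=%s  %d x %d px  %.4g µm/px  range [%.4g, %.4g]\n",
              x$role, nrow(x$pixels), ncol(x$pixels), x$pixel_size,
              min(x$pixels), max(x$pixels)))
  invisible(x)
}

#' One imaged field of view: a set of co-registered channels
#'
#' @param channels named list of [channel_image] objects; names are channel
#'   roles. Roles `nuclei`, `actin` and `fa` are required; `asma` and
#'   `pattern` are optional. All channels must share shape and pixel size.
#' @param condition experimental condition label (character scalar).
#' @param day culture day, an integer (typically 2, 4 or 8) or `NA`.
#' @param replicate replicate/field identifier.
#' @return An object of class `image_set`.
#' @export
image_set <- function(channels, condition = "unspecified", day = NA_integer_,
                      replicate = "r1") {
  if (!is.list(channels) || is.null(names(channels)))
    stop("`channels` must be a named list of channel_image objects")
  required <- c("nuclei", "actin", "fa")
  missing_roles <- setdiff(required, names(channels))
  if (length(missing_roles))
    stop("missing required channel role(s): ", paste(missing_roles, collapse = ", "))
  for (nm in names(channels)) {
    if (!inherits(channels[[nm]], "channel_image"))
      stop("channel '", nm, "' is not a channel_image")
  }
  ref <- channels[[1L]]
  for (ch in channels) {
    if (!identical(dim(ch$pixels), dim(ref$pixels)))
      stop("all channels must share the same shape")
    if (!isTRUE(all.equal(ch$pixel_size, ref$pixel_size)))
      stop("all channels must share the same pixel size")
  }
  structure(list(channels = channels,
                 condition = as.character(condition),
                 day = if (is.na(day)) NA_integer_ else as.integer(day),
                 replicate = as.character(replicate)),
            class = "image_set")
}

#' @export
print.image_set <- function(x, ...) {
  cat(sprintf("<image_set> condition=%s day=%s replicate=%s channels: %s\n",
              x$condition, ifelse(is.na(x$day), "?", x$day), x$replicate,
              paste(names(x$channels), collapse = ", ")))
  invisible(x)
}

#' Linear micropattern geometry
#'
#' Describes a periodic line pattern of adhesive protein: stripes of width
#' `width` separated by gaps of width `spacing`, running at `angle` degrees.
#' The conventional shorthand "20 x 20 lines" means `width = 20`,
#' `spacing = 20` micrometres.
#'
#' @param width stripe width w in micrometres (> 0).
#' @param spacing gap width s in micrometres (>= 0); `0` degenerates to a
#'   homogeneous (fully coated) surface.
#' @param angle direction of the lines in degrees, in (-90, 90].
#' @return An object of class `pattern_spec`.
#' @export
pattern_spec <- function(width, spacing, angle = 0) {
  stopifnot(is.numeric(width), length(width) == 1L, is.finite(width), width > 0)
  stopifnot(is.numeric(spacing), length(spacing) == 1L, is.finite(spacing),
            spacing >= 0)
  stopifnot(is.numeric(angle), length(angle) == 1L, is.finite(angle))
  structure(list(width = width, spacing = spacing,
                 angle = wrap_orientation(angle)),
            class = "pattern_spec")
}

#' Integer-labelled segmentation mask
#'
#' @param labels integer matrix; `0` is background, objects are labelled
#'   `1..N` (contiguous after relabelling).
#' @param level object level, one of `"nucleus"`, `"cell"`, `"fa"`.
#' @param parent optional named integer vector mapping each label (names) to
#'   its parent cell label; required for `level = "fa"` when any label exists.
#' @return An object of class `label_map`.
#' @export
label_map <- function(labels, level, parent = NULL) {
  if (!is.matrix(labels)) stop("`labels` must be a matrix")
  storage.mode(labels) <- "integer"
  if (any(labels < 0L, na.rm = TRUE)) stop("labels must be >= 0")
  level <- match.arg(level, LABEL_LEVELS)
  n <- n_labels(labels)
  if (level == "fa" && n > 0L) {
    if (is.null(parent))
      stop("FA label maps require a parent map (FA label -> cell label)")
    miss <- setdiff(as.character(seq_len(n)), names(parent))
    if (length(miss))
      stop("parent missing for FA label(s): ", paste(miss, collapse = ", "))
  }
  structure(list(labels = labels, level = level, parent = parent),
            class = "label_map")
}

n_labels <- function(labels) {
  m <- max(labels)
  if (m == 0L) 0L else m
}

#' @export
print.label_map <- function(x, ...) {
  cat(sprintf("<label_map> level=%s  %d x %d px  %d object(s)\n",
              x$level, nrow(x$labels), ncol(x$labels), n_labels(x$labels)))
  invisible(x)
}

# wrap an angle in degrees into (-90, 90] (axial/orientation convention)
wrap_orientation <- function(theta) {
  w <- ((theta + 90) %% 180) - 90
  ifelse(w == -90, 90, w)
}
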