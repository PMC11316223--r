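#' Maximum-intensity projection of a z-stack
#'
#' @param stack list of [channel_image] planes with identical shape, pixel
#'   size and role.
#' @return A [channel_image] holding the per-pixel maximum over planes.
#' @export
max_project <- function(stack) {
  if (!is.list(stack) || length(stack) == 0L)
    stop("`stack` must be a non-empty list of channel_image planes")
  ref <- stack[[1L]]
  stopifnot(inherits(ref, "channel_image"))
  out <- ref$pixels
  for (pl in stack[-1L]) {
    stopifnot(inherits(pl, "channel_image"))
    if (!identical(dim(pl$pixels), dim(out)))
      stop("all planes must share the same shape")
    out <- pmax(out, pl$pixels)
  }
  channel_image(out, pixel_size = ref$pixel_size, role = ref$role)
}

#' Percentile autocontrast (linear rescale with saturated tails)
#'
#' Linearly rescales intensities so that the lower `saturated/2` and the
#' upper `1 - saturated/2` intensity quantiles map to 0 and 1; values beyond
#' the quantiles are clipped. This is the usual "enhance contrast with p%%
#' saturated pixels" operation; the default saturates 0.35%% of pixels
#' (0.175%% per tail).
#'
#' @param img a [channel_image].
#' @param saturated total fraction of pixels allowed to saturate, in
#'   `[0, 0.5)`. Default `0.0035` (i.e. 0.35%%).
#' @return A [channel_image] with intensities in `[0, 1]`. A constant input
#'   is returned unchanged with attribute `degenerate = TRUE`.
#' @export
autocontrast <- function(img, saturated = 0.0035) {
  stopifnot(inherits(img, "channel_image"))
  stopifnot(is.numeric(saturated), length(saturated) == 1L,
            saturated >= 0, saturated < 0.5)
  px <- img$pixels
  lo <- stats::quantile(px, saturated / 2, names = FALSE, type = 7)
  hi <- stats::quantile(px, 1 - saturated / 2, names = FALSE, type = 7)
  if (hi <= lo) {
    out <- img
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  scaled <- (px - lo) / (hi - lo)
  scaled[scaled < 0] <- 0
  scaled[scaled > 1] <- 1
  out <- channel_image(scaled, pixel_size = img$pixel_size, role = img$role)
  attr(out, "degenerate") <- FALSE
  out
}

#' White top-hat filter (disk structuring element)
#'
#' Subtracts the morphological opening with a flat disk from the image,
#' retaining bright structures smaller than the disk — the standard
#' enhancement for focal-adhesion puncta against diffuse cytoplasmic signal.
#'
#' @param img a [channel_image].
#' @param radius disk radius in pixels (>= 1). Default 5.
#' @return A [channel_image]; all values >= 0.
#' @export
tophat <- function(img, radius = 5) {
  stopifnot(inherits(img, "channel_image"))
  stopifnot(is.numeric(radius), length(radius) == 1L, radius >= 1)
  r <- as.integer(radius)
  brush <- EBImage::makeBrush(2L * r + 1L, shape = "disc")
  px <- img$pixels
  lo <- min(px); hi <- max(px)
  if (hi == lo)  # constant image: opening is the image itself
    return(channel_image(px * 0, img$pixel_size, img$role))
  # opening commutes with monotone affine maps: rescale into [0, 1] (the
  # EBImage intensity range), open on a replicate-padded copy (border-safe),
  # crop and map back
  q <- (px - lo) / (hi - lo)
  pad <- q[c(rep(1L, r), seq_len(nrow(q)), rep(nrow(q), r)), , drop = FALSE]
  pad <- pad[, c(rep(1L, r), seq_len(ncol(q)), rep(ncol(q), r)),
             drop = FALSE]
  opened <- EBImage::imageData(EBImage::opening(pad, kern = brush))
  opened <- opened[(r + 1L):(r + nrow(q)), (r + 1L):(r + ncol(q))]
  out <- px - (opened * (hi - lo) + lo)
  out[out < 0] <- 0  # guard against float round-off
  channel_image(out, pixel_size = img$pixel_size, role = img$role)
}

#' Preprocess an image set for segmentation
#'
#' Applies [autocontrast()] to every channel; the FA channel is first
#' enhanced with [tophat()] (removing the diffuse cytoplasmic pool) and
#' then rescaled to `[0, 1]`. The FA channel uses its own saturated
#' fraction, 0 by default: punctae typically occupy far less than the
#' default saturated fraction of the field, so a clipping rescale would
#' saturate every punctum together with the upper noise tail and destroy
#' exactly the contrast the top-hat created; `saturated = 0` is a lossless
#' monotone rescale.
#'
#' @param set an [image_set].
#' @param saturated autocontrast saturated fraction (see [autocontrast()])
#'   for the nuclei/actin/asma/pattern channels.
#' @param tophat_radius disk radius in pixels for the FA channel top-hat.
#' @param fa_saturated saturated fraction for the enhanced FA channel
#'   (default 0, no clipping).
#' @return A preprocessed [image_set].
#' @export
preprocess_image_set <- function(set, saturated = 0.0035, tophat_radius = 5,
                                 fa_saturated = 0) {
  stopifnot(inherits(set, "image_set"))
  channels <- set$channels
  for (nm in setdiff(names(channels), "fa"))
    channels[[nm]] <- autocontrast(channels[[nm]], saturated = saturated)
  channels$fa <- autocontrast(tophat(channels$fa, radius = tophat_radius),
                              saturated = fa_saturated)
  image_set(channels, condition = set$condition, day = set$day,
            replicate = set$replicate)
}
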