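#' Otsu threshold of an intensity histogram
#'
#' Exhaustively maximizes the two-class inter-class variance
#' \eqn{\sigma_b^2(t) = w_0 w_1 (\mu_0 - \mu_1)^2} over all bin boundaries.
#' The background class is `intensity <= t`, foreground `intensity > t`.
#' Ties are broken toward the smallest threshold, so for a two-spike
#' histogram the threshold sits at the lower spike.
#'
#' @param counts non-negative histogram counts per bin (total > 0).
#' @param bin_values intensity value of each bin (strictly increasing).
#'   Defaults to `0:(length(counts)-1)` (e.g. 8-bit levels).
#' @return A list of class `threshold_result` with fields `t` (threshold
#'   intensity), `sigma_b2` (inter-class variance at `t`) and `degenerate`
#'   (`TRUE` when only one intensity value is populated; then `t` is that
#'   value and the foreground is empty).
#' @export
otsu_threshold <- function(counts, bin_values = seq_along(counts) - 1) {
  if (length(counts) == 0L) stop("empty histogram")
  stopifnot(length(bin_values) == length(counts), all(counts >= 0))
  bin_values <- as.numeric(bin_values)
  total <- sum(counts)
  if (total <= 0) stop("histogram has zero total count")
  nz <- which(counts > 0)
  if (length(nz) == 1L) {
    return(structure(list(t = bin_values[nz], sigma_b2 = 0, degenerate = TRUE),
                     class = "threshold_result"))
  }
  w <- counts / total
  mu_total <- sum(w * bin_values)
  w0 <- cumsum(w)                    # P(intensity <= t) for t = bin_values[k]
  m0 <- cumsum(w * bin_values)       # partial first moment
  k <- seq_len(length(counts) - 1L)  # split after bin k; both classes can be empty
  w1 <- 1 - w0[k]
  valid <- w0[k] > 0 & w1 > 0
  sigma <- rep(-Inf, length(k))
  mu0 <- m0[k][valid] / w0[k][valid]
  mu1 <- (mu_total - m0[k][valid]) / w1[valid]
  sigma[valid] <- w0[k][valid] * w1[valid] * (mu0 - mu1)^2
  best <- which.max(sigma)           # first maximizer = smallest threshold
  structure(list(t = bin_values[best], sigma_b2 = sigma[best],
                 degenerate = FALSE),
            class = "threshold_result")
}

# Otsu threshold of a (possibly masked) float image via a binned histogram.
# Returns a threshold on the intensity scale; foreground is `pixels > t`.
otsu_image <- function(pixels, mask = NULL, n_bins = 256L) {
  v <- if (is.null(mask)) as.vector(pixels) else pixels[mask]
  if (length(v) == 0L) stop("no pixels to threshold")
  rng <- range(v)
  if (rng[1] == rng[2]) {
    return(structure(list(t = rng[1], sigma_b2 = 0, degenerate = TRUE),
                     class = "threshold_result"))
  }
  breaks <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  counts <- tabulate(
    pmin(pmax(findInterval(v, breaks, rightmost.closed = TRUE), 1L), n_bins),
    nbins = n_bins)
  centers <- (breaks[-1L] + breaks[-(n_bins + 1L)]) / 2
  otsu_threshold(counts, centers)
}

#' Segment nuclei (primary objects)
#'
#' Otsu thresholding of the nuclei channel, hole filling, 8-connected
#' component labelling, area filtering, and optional removal of
#' border-touching objects; survivors are relabelled `1..N` in scan order.
#'
#' @param nuclei_img preprocessed nuclei [channel_image].
#' @param min_area,max_area area filter bounds in square micrometres.
#' @param exclude_border drop objects touching the image border
#'   (default `TRUE`).
#' @return A [label_map] with `level = "nucleus"`.
#' @export
segment_nuclei <- function(nuclei_img, min_area = 50, max_area = 500,
                           exclude_border = TRUE) {
  stopifnot(inherits(nuclei_img, "channel_image"))
  px <- nuclei_img$pixels
  thr <- otsu_image(px)
  fg <- if (thr$degenerate) matrix(FALSE, nrow(px), ncol(px)) else px > thr$t
  fg <- EBImage::imageData(EBImage::fillHull(fg * 1L)) > 0
  lab <- .cc_label8(matrix(as.integer(fg), nrow(px)))
  lab <- filter_labels(lab, pixel_size = nuclei_img$pixel_size,
                       min_area = min_area, max_area = max_area,
                       exclude_border = exclude_border)
  label_map(lab, level = "nucleus")
}

# area filter (µm²) + border removal + relabel 1..N preserving scan order
filter_labels <- function(lab, pixel_size, min_area = 0, max_area = Inf,
                          exclude_border = FALSE) {
  n <- max(lab)
  if (n == 0L) return(lab)
  px_area <- tabulate(lab[lab > 0L], nbins = n)
  keep <- px_area * pixel_size^2 >= min_area &
    px_area * pixel_size^2 <= max_area & px_area > 0
  if (exclude_border) {
    border <- unique(c(lab[1, ], lab[nrow(lab), ], lab[, 1], lab[, ncol(lab)]))
    keep[border[border > 0L]] <- FALSE
  }
  remap <- integer(n)
  remap[keep] <- seq_len(sum(keep))
  out <- lab
  out[out > 0L] <- remap[out[out > 0L]]
  out
}

#' Segment cells (secondary objects seeded from nuclei)
#'
#' The foreground is the union of the Otsu foreground of the actin channel
#' and all nucleus pixels. Every foreground pixel is assigned to the nucleus
#' seed with the smallest geodesic (within-foreground) distance, so exactly
#' one cell is produced per nucleus and each nucleus is contained in its own
#' cell. Foreground regions unreachable from any seed remain background.
#'
#' @param actin_img preprocessed actin [channel_image].
#' @param nuclei a nucleus [label_map] computed on the same field.
#' @return A [label_map] with `level = "cell"`.
#' @export
segment_cells <- function(actin_img, nuclei) {
  stopifnot(inherits(actin_img, "channel_image"),
            inherits(nuclei, "label_map"), nuclei$level == "nucleus")
  px <- actin_img$pixels
  stopifnot(identical(dim(px), dim(nuclei$labels)))
  thr <- otsu_image(px)
  fg <- if (thr$degenerate) matrix(FALSE, nrow(px), ncol(px)) else px > thr$t
  fgm <- matrix(as.integer(fg | nuclei$labels > 0L), nrow(px))
  lab <- .geodesic_assign(nuclei$labels, fgm)
  label_map(lab, level = "cell")
}

#' Segment focal adhesions (tertiary objects within cell masks)
#'
#' The Otsu threshold is computed over pixels inside the union of the cell
#' masks only (cell boundaries are masked first); restricting the histogram to
#' the cell interior keeps the punctae fraction high enough for two-class
#' Otsu to separate them from the cytoplasmic residue. Components are
#' 8-connected within cells, small components are removed, and each FA is
#' assigned the parent cell covering the majority of its pixels.
#'
#' @param fa_img top-hat-filtered FA [channel_image].
#' @param cells a cell [label_map].
#' @param min_area minimum FA area in square micrometres (default 0.4).
#' @param smooth_sigma Gaussian pre-smoothing sigma in pixels applied before
#'   thresholding (suppresses single-pixel noise speckle; 0 disables).
#' @return A [label_map] with `level = "fa"` and a parent map.
#' @export
segment_fas <- function(fa_img, cells, min_area = 0.4, smooth_sigma = 1) {
  stopifnot(inherits(fa_img, "channel_image"),
            inherits(cells, "label_map"), cells$level == "cell")
  px <- fa_img$pixels
  stopifnot(identical(dim(px), dim(cells$labels)))
  if (smooth_sigma > 0) px <- gauss_smooth(px, smooth_sigma)
  inside <- cells$labels > 0L
  if (!any(inside)) {
    warning("no cell pixels; returning empty FA label map")
    return(label_map(matrix(0L, nrow(px), ncol(px)), level = "fa"))
  }
  thr <- otsu_image(px, mask = inside)
  fg <- inside & !thr$degenerate & px > thr$t
  lab <- .cc_label8(matrix(as.integer(fg), nrow(px)))
  lab <- filter_labels(lab, pixel_size = fa_img$pixel_size,
                       min_area = min_area)
  n <- max(lab)
  if (n == 0L) return(label_map(lab, level = "fa"))
  parent <- integer(n)
  for (i in seq_len(n)) {
    owners <- cells$labels[lab == i]
    owners <- owners[owners > 0L]
    parent[i] <- as.integer(names(which.max(table(owners))))
  }
  names(parent) <- as.character(seq_len(n))
  label_map(lab, level = "fa", parent = parent)
}
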