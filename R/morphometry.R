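#' Per-object shape descriptors for a label map
#'
#' Computes the standard moment- and boundary-based descriptor set per
#' labelled object:
#' \itemize{
#'   \item `area` (µm²): pixel count times `pixel_size^2`.
#'   \item `perimeter` (µm): outer-boundary walk length with diagonal steps
#'     weighted \eqn{\sqrt 2} (objects are hole-filled for the walk).
#'   \item `equivalent_diameter` (µm): \eqn{2\sqrt{A/\pi}}.
#'   \item `major_axis`, `minor_axis` (µm): \eqn{4\sqrt{\lambda}} for the
#'     eigenvalues of the second-central-moment matrix (each pixel treated
#'     as a unit square, adding 1/12 to the diagonal), i.e. the axes of the
#'     ellipse with matching moments. For a filled ellipse the major axis
#'     equals the full long-axis length ("cell long axis").
#'   \item `aspect_ratio`: `major_axis / minor_axis`.
#'   \item `eccentricity`: \eqn{\sqrt{1 - \lambda_{min}/\lambda_{max}}},
#'     0 for a disk, approaching 1 for a line.
#'   \item `orientation` (degrees in (-90, 90]): major-axis direction,
#'     counter-clockwise from the +column (x) axis with y pointing up
#'     (i.e. against the row index).
#'   \item `solidity`: area / area of the convex-hull image.
#'   \item `extent`: area / bounding-box area.
#'   \item `form_factor`: \eqn{4\pi A / P^2} (1 for an ideal disk);
#'     `compactness` is its reciprocal.
#'   \item `feret_max`, `feret_min` (µm): rotating-calipers maximum and
#'     minimum caliper widths over the convex hull of pixel centres, plus
#'     one pixel to account for pixel extent.
#'   \item `centroid_row`, `centroid_col` (pixels, 1-based): intensity-free
#'     centroid of the pixel centres.
#' }
#'
#' @param labels a [label_map].
#' @param pixel_size micrometres per pixel.
#' @param image_id,condition,day metadata columns replicated into the table.
#' @return A data.frame (one row per object) with the descriptor columns,
#'   `label`, `level`, `parent` (NA except for FA maps) and the metadata.
#' @export
measure_objects <- function(labels, pixel_size, image_id = "img1",
                            condition = "unspecified", day = NA_integer_) {
  stopifnot(inherits(labels, "label_map"))
  lab <- labels$labels
  n <- max(lab)
  rows <- vector("list", n)
  if (n > 0L) {
    idx_all <- which(lab > 0L)
    rr <- ((idx_all - 1L) %% nrow(lab)) + 1L
    cc <- ((idx_all - 1L) %/% nrow(lab)) + 1L
    ll <- lab[idx_all]
    ord <- order(ll)
    rr <- rr[ord]; cc <- cc[ord]; ll <- ll[ord]
    starts <- c(1L, which(diff(ll) != 0L) + 1L, length(ll) + 1L)
    for (i in seq_len(n)) {
      sel <- starts[i]:(starts[i + 1L] - 1L)
      rows[[i]] <- shape_descriptors(rr[sel], cc[sel], pixel_size)
    }
  }
  tab <- do.call(rbind, c(rows, list(empty_descriptor_row())))
  tab <- tab[seq_len(n), , drop = FALSE]
  parent <- rep(NA_integer_, n)
  if (!is.null(labels$parent) && n > 0L)
    parent <- as.integer(labels$parent[as.character(seq_len(n))])
  out <- data.frame(image_id = rep(image_id, n),
                    condition = rep(condition, n),
                    day = rep(if (is.null(day)) NA_integer_ else day, n),
                    level = rep(labels$level, n),
                    label = seq_len(n),
                    parent = parent,
                    stringsAsFactors = FALSE)
  cbind(out, tab)
}

empty_descriptor_row <- function() {
  nm <- c("area", "perimeter", "equivalent_diameter", "major_axis",
          "minor_axis", "aspect_ratio", "eccentricity", "orientation",
          "solidity", "extent", "form_factor", "compactness",
          "feret_max", "feret_min", "centroid_row", "centroid_col")
  as.data.frame(as.list(stats::setNames(rep(NA_real_, length(nm)), nm)))
}

# descriptors from the (row, col) pixel-centre coordinates of one object
shape_descriptors <- function(r, c, pixel_size) {
  npx <- length(r)
  area_px <- npx
  area <- area_px * pixel_size^2
  cr <- mean(r); cc <- mean(c)
  # moments in (x, y) with x = col, y = -row (counter-clockwise convention);
  # + 1/12 treats each pixel as a unit square rather than a point mass
  x <- c - cc; y <- -(r - cr)
  mu20 <- mean(x^2) + 1 / 12
  mu02 <- mean(y^2) + 1 / 12
  mu11 <- mean(x * y)
  tr <- mu20 + mu02
  det_ <- mu20 * mu02 - mu11^2
  disc <- sqrt(max(0, (tr / 2)^2 - det_))
  lmax <- tr / 2 + disc
  lmin <- max(tr / 2 - disc, 0)
  major <- 4 * sqrt(lmax) * pixel_size
  minor <- 4 * sqrt(lmin) * pixel_size
  ecc <- if (lmax > 0) sqrt(max(0, 1 - lmin / lmax)) else 0
  theta <- wrap_orientation(0.5 * atan2(2 * mu11, mu20 - mu02) * 180 / pi)

  # boundary walk on the hole-filled cropped mask
  rmin <- min(r); rmax <- max(r); cmin <- min(c); cmax <- max(c)
  m <- matrix(0L, rmax - rmin + 3L, cmax - cmin + 3L)
  m[cbind(r - rmin + 2L, c - cmin + 2L)] <- 1L
  filled <- matrix(as.integer(EBImage::imageData(EBImage::fillHull(m)) > 0),
                   nrow(m))
  per <- .boundary_walk_length(filled) * pixel_size

  bbox_area <- (rmax - rmin + 1L) * (cmax - cmin + 1L) * pixel_size^2
  extent <- area / bbox_area

  hull <- convex_hull_points(r, c)
  solidity <- area_px / convex_image_area(hull, rmin, rmax, cmin, cmax)
  fer <- feret_diameters(hull)

  ff <- if (per > 0) 4 * pi * area / per^2 else NA_real_
  data.frame(area = area, perimeter = per,
             equivalent_diameter = 2 * sqrt(area / pi),
             major_axis = major, minor_axis = minor,
             aspect_ratio = if (minor > 0) major / minor else NA_real_,
             eccentricity = ecc, orientation = theta,
             solidity = solidity, extent = extent,
             form_factor = ff,
             compactness = if (is.na(ff) || ff == 0) NA_real_ else 1 / ff,
             feret_max = (fer[1] + 1) * pixel_size,
             feret_min = (fer[2] + 1) * pixel_size,
             centroid_row = cr, centroid_col = cc)
}

# convex hull of pixel centres as an (n x 2) matrix of (row, col), CCW order
convex_hull_points <- function(r, c) {
  pts <- unique(cbind(r, c))
  if (nrow(pts) <= 2L) return(pts)
  h <- grDevices::chull(pts[, 2], pts[, 1])  # chull takes (x, y)
  pts[h, , drop = FALSE]
}

# number of pixels whose centres lie inside or on the convex hull
convex_image_area <- function(hull, rmin, rmax, cmin, cmax) {
  if (nrow(hull) <= 2L) return(max(nrow(hull), 1L))
  grid <- expand.grid(r = rmin:rmax, c = cmin:cmax)
  inp <- pracma::inpolygon(grid$c, grid$r, hull[, 2], hull[, 1],
                           boundary = TRUE)
  max(sum(inp), 1L)
}

# (max, min) caliper diameters of the hull (pixel-centre units)
feret_diameters <- function(hull) {
  np <- nrow(hull)
  if (np == 1L) return(c(0, 0))
  x <- hull[, 2]; y <- hull[, 1]
  d2 <- outer(x, x, "-")^2 + outer(y, y, "-")^2
  fmax <- sqrt(max(d2))
  if (np == 2L) return(c(fmax, 0))
  # min caliper width: for each hull edge, the farthest point distance
  widths <- vapply(seq_len(np), function(i) {
    j <- if (i == np) 1L else i + 1L
    ex <- x[j] - x[i]; ey <- y[j] - y[i]
    elen <- sqrt(ex^2 + ey^2)
    if (elen == 0) return(Inf)
    max(abs((x - x[i]) * ey - (y - y[i]) * ex) / elen)
  }, numeric(1))
  c(fmax, min(widths))
}
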