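#' Focal-adhesion to nucleus centroid distances
#'
#' For every FA, the Euclidean distance (µm) from the FA centroid to the
#' nucleus centroid of its *parent* cell (not the nearest nucleus), the
#' measurement behind the FA localization statistic: fibroblast FAs sit
#' farther from the nucleus than myofibroblast FAs.
#'
#' @param fa_table morphometry rows at level `"fa"` (needs `parent`,
#'   `centroid_row`, `centroid_col`, and optionally `image_id`, `condition`).
#' @param nucleus_table morphometry rows at level `"nucleus"` for the same
#'   fields (matched by `image_id` + `label`).
#' @param pixel_size micrometres per pixel.
#' @return A list of class `distance_report`: `per_fa` (one row per FA with
#'   `distance`), `per_cell` (per-cell mean/n), `per_condition` (n, mean,
#'   sd, median).
#' @export
fa_nucleus_distances <- function(fa_table, nucleus_table, pixel_size) {
  stopifnot(is.data.frame(fa_table), is.data.frame(nucleus_table),
            pixel_size > 0)
  if (nrow(fa_table) > 0 && any(is.na(fa_table$parent)))
    stop("FA row(s) with missing parent link")
  if (!"image_id" %in% names(fa_table)) fa_table$image_id <- "img1"
  if (!"image_id" %in% names(nucleus_table)) nucleus_table$image_id <- "img1"
  if (!"condition" %in% names(fa_table)) fa_table$condition <- "unspecified"
  key_n <- paste(nucleus_table$image_id, nucleus_table$label)
  if (anyDuplicated(key_n)) stop("more than one nucleus per cell")
  idx <- match(paste(fa_table$image_id, fa_table$parent), key_n)
  if (anyNA(idx) && nrow(fa_table) > 0)
    stop("FA parent cell(s) without a nucleus row")
  per_fa <- fa_table
  per_fa$distance <- sqrt(
    (fa_table$centroid_row - nucleus_table$centroid_row[idx])^2 +
      (fa_table$centroid_col - nucleus_table$centroid_col[idx])^2) * pixel_size
  per_cell <- if (nrow(per_fa)) {
    agg <- stats::aggregate(distance ~ image_id + condition + parent,
                            data = per_fa, FUN = mean)
    names(agg)[names(agg) == "distance"] <- "mean_distance"
    agg$n_fa <- stats::aggregate(distance ~ image_id + condition + parent,
                                 data = per_fa, FUN = length)$distance
    agg
  } else data.frame(image_id = character(0), condition = character(0),
                    parent = integer(0), mean_distance = numeric(0),
                    n_fa = integer(0))
  per_condition <- if (nrow(per_fa)) {
    do.call(rbind, lapply(split(per_fa, per_fa$condition), function(d) {
      data.frame(condition = d$condition[1], n = nrow(d),
                 mean = mean(d$distance), sd = stats::sd(d$distance),
                 median = stats::median(d$distance),
                 stringsAsFactors = FALSE)
    }))
  } else data.frame(condition = character(0), n = integer(0),
                    mean = numeric(0), sd = numeric(0), median = numeric(0))
  structure(list(per_fa = per_fa, per_cell = per_cell,
                 per_condition = per_condition), class = "distance_report")
}

# circular statistics on axial (180°-periodic) data via angle doubling;
# angles in degrees
axial_stats <- function(theta, weights = NULL) {
  if (length(theta) == 0L)
    return(list(mean = NA_real_, sd = NA_real_, S = NA_real_, n = 0L))
  if (is.null(weights)) weights <- rep(1, length(theta))
  w <- weights / sum(weights)
  z <- sum(w * exp(2i * theta * pi / 180))
  R <- Mod(z)
  mu <- wrap_orientation(Arg(z) / 2 * 180 / pi)
  circ_sd <- if (R > 0) sqrt(pmax(-2 * log(R), 0)) / 2 * 180 / pi else Inf
  list(mean = mu, sd = circ_sd, S = R, n = length(theta))
}

#' Pattern-relative cell orientation statistics
#'
#' Wraps each cell's major-axis orientation relative to the micropattern
#' direction into (-90, 90]: 0° means parallel alignment to the pattern,
#' +/-90° perpendicular (exact perpendicularity is reported as +90°).
#' Circular mean/SD and the orientational order parameter
#' \eqn{S = |\langle e^{2i\theta}\rangle|} are computed on doubled angles
#' (axial statistics). For homogeneous controls pass `pattern = NULL`
#' (reference angle 0).
#'
#' @param cell_table morphometry rows at level `"cell"` (needs
#'   `orientation`; `condition` optional).
#' @param pattern a [pattern_spec] or `NULL`.
#' @return A list of class `orientation_report`: `per_cell` (with
#'   `theta_rel`), `per_condition` (circular mean, circular sd, `S`, n).
#' @export
cell_orientation <- function(cell_table, pattern = NULL) {
  stopifnot(is.data.frame(cell_table))
  ref <- if (is.null(pattern)) 0 else pattern$angle
  if (!"condition" %in% names(cell_table))
    cell_table$condition <- "unspecified"
  per_cell <- cell_table
  per_cell$theta_rel <- wrap_orientation(cell_table$orientation - ref)
  per_condition <- do.call(rbind, lapply(
    split(per_cell, per_cell$condition), function(d) {
      st <- axial_stats(d$theta_rel)
      data.frame(condition = d$condition[1], n = st$n,
                 circular_mean = st$mean, circular_sd = st$sd, S = st$S,
                 stringsAsFactors = FALSE)
    }))
  rownames(per_condition) <- NULL
  structure(list(per_cell = per_cell, per_condition = per_condition,
                 reference_angle = ref), class = "orientation_report")
}

# separable Gaussian smoothing (replicated borders)
gauss_smooth <- function(px, sigma) {
  if (sigma <= 0) return(px)
  r <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(-r:r, sd = sigma)
  k <- k / sum(k)
  pad <- function(m, n) {
    m <- rbind(m[rep(1L, n), , drop = FALSE], m, m[rep(nrow(m), n), , drop = FALSE])
    cbind(m[, rep(1L, n), drop = FALSE], m, m[, rep(ncol(m), n), drop = FALSE])
  }
  p <- pad(px, r)
  p <- apply(p, 2, function(col) stats::filter(col, k, sides = 2))
  p <- t(apply(p, 1, function(row) stats::filter(row, k, sides = 2)))
  p[(r + 1):(nrow(p) - r), (r + 1):(ncol(p) - r)]
}

# central differences along rows (d/drow) and columns (d/dcol)
diff_row <- function(m) {
  out <- m
  out[2:(nrow(m) - 1), ] <- (m[3:nrow(m), ] - m[1:(nrow(m) - 2), ]) / 2
  out[1, ] <- m[2, ] - m[1, ]
  out[nrow(m), ] <- m[nrow(m), ] - m[nrow(m) - 1, ]
  out
}
diff_col <- function(m) t(diff_row(t(m)))

#' Actin fiber orientation map (multiscale vesselness + structure tensor)
#'
#' Ridge-enhances the actin image with a Frangi-style multiscale vesselness
#' filter (bright ridges; scale-normalized Gaussian Hessian at the given
#' scales), computes the local fiber orientation from the smoothed
#' structure tensor, and summarizes the vesselness-weighted orientation
#' histogram with its dominant mode and the orientational order parameter
#' \eqn{S = |\langle e^{2i\theta}\rangle_w|}.
#'
#' @param actin_img preprocessed actin [channel_image].
#' @param scales vesselness scales in pixels (Gaussian sigmas).
#' @param beta,c_factor Frangi blobness parameter and structureness scaling
#'   (the structureness cutoff is `c_factor * max` per scale).
#' @param bin_width histogram bin width in degrees.
#' @return A list of class `fiber_orientation_report`: `histogram`
#'   (data.frame `angle`, `weight`), `mode` (dominant angle, degrees),
#'   `S`, `undefined` (`TRUE` for blank images).
#' @export
fiber_orientation_map <- function(actin_img, scales = c(1, 2, 4),
                                  beta = 0.5, c_factor = 0.5,
                                  bin_width = 2) {
  stopifnot(inherits(actin_img, "channel_image"), all(scales > 0))
  px <- actin_img$pixels
  if (max(px) == min(px)) {
    hist0 <- data.frame(angle = seq(-89, 90, by = bin_width), weight = 0)
    return(structure(list(histogram = hist0, mode = NA_real_, S = NA_real_,
                          undefined = TRUE),
                     class = "fiber_orientation_report"))
  }
  vmax <- matrix(0, nrow(px), ncol(px))
  for (s in scales) {
    sm <- gauss_smooth(px, s)
    # scale-normalized Hessian (x = col, y = -row)
    hxx <- diff_col(diff_col(sm)) * s^2
    hyy <- diff_row(diff_row(sm)) * s^2
    hxy <- -diff_row(diff_col(sm)) * s^2
    tr <- hxx + hyy
    disc <- sqrt(pmax((hxx - hyy)^2 + 4 * hxy^2, 0))
    l1 <- (tr - disc) / 2  # more negative on bright ridges
    l2 <- (tr + disc) / 2
    # order by magnitude: lam2 = larger |.|
    swap <- abs(l1) > abs(l2)
    lam1 <- ifelse(swap, l2, l1)
    lam2 <- ifelse(swap, l1, l2)
    rb2 <- (lam1 / ifelse(lam2 == 0, Inf, lam2))^2
    s2 <- lam1^2 + lam2^2
    cpar <- c_factor * sqrt(max(s2))
    v <- exp(-rb2 / (2 * beta^2)) * (1 - exp(-s2 / (2 * cpar^2)))
    v[lam2 >= 0] <- 0  # bright ridges only
    vmax <- pmax(vmax, v)
  }
  # structure tensor orientation at the mid scale
  smg <- gauss_smooth(px, scales[ceiling(length(scales) / 2)])
  gx <- diff_col(smg)
  gy <- -diff_row(smg)
  rho <- 2 * scales[ceiling(length(scales) / 2)]
  jxx <- gauss_smooth(gx * gx, rho)
  jyy <- gauss_smooth(gy * gy, rho)
  jxy <- gauss_smooth(gx * gy, rho)
  grad_theta <- 0.5 * atan2(2 * jxy, jxx - jyy) * 180 / pi
  fiber_theta <- wrap_orientation(grad_theta + 90)

  w <- as.vector(vmax)
  th <- as.vector(fiber_theta)
  keep <- w > 0
  if (!any(keep)) {
    hist0 <- data.frame(angle = seq(-89, 90, by = bin_width), weight = 0)
    return(structure(list(histogram = hist0, mode = NA_real_, S = NA_real_,
                          undefined = TRUE),
                     class = "fiber_orientation_report"))
  }
  w <- w[keep]; th <- th[keep]
  edges <- seq(-90, 90, by = bin_width)
  bin <- pmin(findInterval(th, edges, rightmost.closed = TRUE),
              length(edges) - 1L)
  weight <- vapply(seq_len(length(edges) - 1L),
                   function(b) sum(w[bin == b]), numeric(1))
  centers <- (edges[-1] + edges[-length(edges)]) / 2
  st <- axial_stats(th, weights = w)
  structure(list(histogram = data.frame(angle = centers, weight = weight),
                 mode = centers[which.max(weight)], S = st$S,
                 undefined = FALSE),
            class = "fiber_orientation_report")
}

#' Orientational order parameter of a set of orientations
#'
#' \eqn{S = |\langle e^{2i\theta}\rangle|}: 1 for perfectly aligned
#' orientations, 0 for an isotropic distribution. Invariant to adding 180°
#' to any subset of the angles (axial data).
#'
#' @param theta orientations in degrees.
#' @param weights optional non-negative weights.
#' @return S in `[0, 1]`.
#' @export
order_parameter <- function(theta, weights = NULL) {
  axial_stats(theta, weights)$S
}
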