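#' Specification of a synthetic micropatterned-fibroblast scene
#'
#' Defines the study conditions emulated by the simulator: elongated
#' elliptical cell bodies (optionally clipped to a line micropattern),
#' elliptical nuclei, elongated FA puncta split between a perinuclear
#' annulus and a peripheral band, and additive Gaussian + Poisson noise.
#' Defaults describe a homogeneously coated control field at SNR near 10
#' with well-separated cells, the regime the default segmentation settings
#' are tuned for.
#'
#' @param image_shape image size in pixels, `c(rows, cols)`.
#' @param pixel_size micrometres per pixel.
#' @param pattern a [pattern_spec] or `NULL` for a homogeneous control.
#' @param n_cells number of cells to place (without overlap).
#' @param cell_length,cell_width `c(mean, sd)` of the full cell axes in µm.
#' @param cell_orientation_concentration alignment concentration: 0 gives
#'   isotropic orientations; for `conc > 0` orientations are wrapped-normal
#'   around the pattern angle with sd `45/conc` degrees.
#' @param nucleus_major,nucleus_minor `c(mean, sd)` of full nuclear axes (µm).
#' @param fa_per_cell `c(mean, sd)` of the FA count per cell (rounded, >= 0).
#' @param fa_major,fa_minor `c(mean, sd)` of full FA axes (µm); the defaults
#'   give strongly elongated puncta (eccentricity near 0.9).
#' @param fa_radial_placement fraction of FAs placed in the peripheral band
#'   (the rest are perinuclear), in `[0, 1]`.
#' @param gaussian_sd additive Gaussian noise sd (intensity units).
#' @param poisson_scale photon-count scaling for Poisson shot noise;
#'   `0` disables shot noise.
#' @param background background intensity level.
#' @param bridge_width cells are clipped to the pattern stripes only when
#'   `spacing > bridge_width` (µm); narrower gaps are bridged by the cell.
#' @param seed integer RNG seed; identical seeds give bit-identical scenes.
#' @return An object of class `scene_spec`.
#' @export
scene_spec <- function(image_shape = c(768L, 768L), pixel_size = 0.5,
                       pattern = NULL, n_cells = 10L,
                       cell_length = c(60, 8), cell_width = c(18, 3),
                       cell_orientation_concentration = 0,
                       nucleus_major = c(17, 1.5), nucleus_minor = c(10, 1),
                       fa_per_cell = c(8, 0), fa_major = c(2.4, 0.4),
                       fa_minor = c(1.0, 0.15), fa_radial_placement = 0.6,
                       gaussian_sd = 0.08, poisson_scale = 200,
                       background = 0.05, bridge_width = 12, seed = 1L) {
  stopifnot(length(image_shape) == 2L, all(image_shape >= 16),
            pixel_size > 0, n_cells >= 0,
            all(c(cell_length[1], cell_width[1], nucleus_major[1],
                  nucleus_minor[1], fa_major[1], fa_minor[1]) > 0),
            cell_orientation_concentration >= 0,
            fa_radial_placement >= 0, fa_radial_placement <= 1,
            gaussian_sd >= 0, poisson_scale >= 0, background >= 0)
  if (!is.null(pattern)) stopifnot(inherits(pattern, "pattern_spec"))
  structure(list(image_shape = as.integer(image_shape),
                 pixel_size = pixel_size, pattern = pattern,
                 n_cells = as.integer(n_cells),
                 cell_length = cell_length, cell_width = cell_width,
                 cell_orientation_concentration = cell_orientation_concentration,
                 nucleus_major = nucleus_major, nucleus_minor = nucleus_minor,
                 fa_per_cell = fa_per_cell, fa_major = fa_major,
                 fa_minor = fa_minor,
                 fa_radial_placement = fa_radial_placement,
                 gaussian_sd = gaussian_sd, poisson_scale = poisson_scale,
                 background = background, bridge_width = bridge_width,
                 seed = as.integer(seed)),
            class = "scene_spec")
}

#' Binary mask of a periodic line micropattern
#'
#' @param pattern a [pattern_spec].
#' @param shape image size in pixels `c(rows, cols)`.
#' @param pixel_size micrometres per pixel.
#' @return Integer matrix; 1 on protein stripes, 0 in gaps. `spacing = 0`
#'   gives an all-ones mask.
#' @export
generate_pattern_mask <- function(pattern, shape, pixel_size) {
  stopifnot(inherits(pattern, "pattern_spec"), length(shape) == 2L,
            all(shape >= 1), pixel_size > 0)
  if (pattern$spacing == 0)
    return(matrix(1L, shape[1], shape[2]))
  th <- pattern$angle * pi / 180
  r <- matrix(seq_len(shape[1]), shape[1], shape[2])
  cc <- matrix(seq_len(shape[2]), shape[1], shape[2], byrow = TRUE)
  x <- (cc - 0.5) * pixel_size
  y <- -(r - 0.5) * pixel_size
  perp <- -x * sin(th) + y * cos(th)
  period <- pattern$width + pattern$spacing
  matrix(as.integer((perp %% period) < pattern$width), shape[1], shape[2])
}

# pixel indices (r, c) of a filled, possibly rotated ellipse;
# center in (row, col) px, semi-axes in px, theta in degrees (CCW from +col,
# with y measured against the row index)
ellipse_pixels <- function(shape, center, a_px, b_px, theta_deg) {
  th <- theta_deg * pi / 180
  rad <- max(a_px, b_px)
  r0 <- max(1L, floor(center[1] - rad)); r1 <- min(shape[1], ceiling(center[1] + rad))
  c0 <- max(1L, floor(center[2] - rad)); c1 <- min(shape[2], ceiling(center[2] + rad))
  if (r0 > r1 || c0 > c1) return(cbind(r = integer(0), c = integer(0)))
  rr <- matrix(r0:r1, r1 - r0 + 1L, c1 - c0 + 1L)
  cc <- matrix(c0:c1, r1 - r0 + 1L, c1 - c0 + 1L, byrow = TRUE)
  dx <- cc - center[2]
  dy <- -(rr - center[1])
  u <- dx * cos(th) + dy * sin(th)
  v <- -dx * sin(th) + dy * cos(th)
  keep <- (u / a_px)^2 + (v / b_px)^2 <= 1
  cbind(r = rr[keep], c = cc[keep])
}

rnorm_pos <- function(n, mean, sd, lower) {
  v <- stats::rnorm(n, mean, sd)
  pmax(v, lower)
}

sample_orientations <- function(n, mu, conc) {
  if (conc <= 0) return(wrap_orientation(stats::runif(n, -90, 90)))
  wrap_orientation(mu + stats::rnorm(n, 0, 45 / conc))
}

#' Generate a synthetic scene with full ground truth
#'
#' Renders a multi-channel field of view (nuclei, actin, FA, and a pattern
#' channel when a micropattern is present) together with the true label maps
#' and true per-object parameter tables. Cells are placed by rejection
#' sampling so that enlarged cell outlines never overlap; an error is raised
#' if the requested packing is infeasible.
#'
#' @param spec a [scene_spec].
#' @return A list with elements `images` (an [image_set]) and `truth`
#'   (class `ground_truth`: `labels` = list of [label_map] per level,
#'   `cells` / `nuclei` / `fas` = data.frames of true parameters).
#' @export
generate_scene <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  set.seed(spec$seed)
  shape <- spec$image_shape
  ps <- spec$pixel_size
  pat_mask <- NULL
  clip <- FALSE
  pat_angle <- 0
  if (!is.null(spec$pattern)) {
    pat_mask <- generate_pattern_mask(spec$pattern, shape, ps)
    clip <- spec$pattern$spacing > spec$bridge_width
    pat_angle <- spec$pattern$angle
  }

  cell_lab <- matrix(0L, shape[1], shape[2])
  nuc_lab <- matrix(0L, shape[1], shape[2])
  fa_lab <- matrix(0L, shape[1], shape[2])
  occupied <- matrix(FALSE, shape[1], shape[2])

  cells <- list(); nucs <- list(); fas <- list()
  fa_next <- 0L
  gap_um <- 3  # minimum clearance between neighbouring cell outlines

  for (i in seq_len(spec$n_cells)) {
    placed <- FALSE
    for (try in seq_len(400L)) {
      L <- rnorm_pos(1, spec$cell_length[1], spec$cell_length[2],
                     spec$cell_width[1])
      W <- rnorm_pos(1, spec$cell_width[1], spec$cell_width[2], 4 * ps)
      W <- min(W, 0.85 * L)  # cells are elongated: keep a clear major axis
      theta <- sample_orientations(1, pat_angle,
                                   spec$cell_orientation_concentration)
      a_px <- L / 2 / ps; b_px <- W / 2 / ps
      margin <- a_px + 2
      if (2 * margin >= min(shape)) next
      ctr <- c(stats::runif(1, margin + 1, shape[1] - margin),
               stats::runif(1, margin + 1, shape[2] - margin))
      # overlap test on the outline enlarged by the clearance gap
      halo <- ellipse_pixels(shape, ctr, a_px + gap_um / ps,
                             b_px + gap_um / ps, theta)
      if (any(occupied[halo])) next
      px <- ellipse_pixels(shape, ctr, a_px, b_px, theta)
      if (!is.null(pat_mask) && clip) {
        on_pat <- pat_mask[px] > 0L
        if (sum(on_pat) < 0.2 * nrow(px)) next
        px_render <- px[on_pat, , drop = FALSE]
      } else px_render <- px
      occupied[halo] <- TRUE
      cell_lab[px_render] <- i
      cells[[i]] <- data.frame(
        label = i, centroid_row = ctr[1], centroid_col = ctr[2],
        major_axis = L, minor_axis = W, orientation = theta,
        eccentricity = sqrt(1 - (W / L)^2),
        area = pi * (L / 2) * (W / 2), area_px = nrow(px_render),
        clipped = clip && nrow(px_render) < nrow(px))
      placed <- TRUE
      break
    }
    if (!placed)
      stop("infeasible packing: could not place cell ", i,
           " after bounded retries")

    # nucleus: centred in the cell, close to the cell orientation
    aN <- rnorm_pos(1, spec$nucleus_major[1], spec$nucleus_major[2], 2 * ps) / 2
    bN <- rnorm_pos(1, spec$nucleus_minor[1], spec$nucleus_minor[2], 2 * ps) / 2
    if (bN > aN) { tmp <- aN; aN <- bN; bN <- tmp }
    bN <- min(bN, 0.8 * aN)  # fibroblast nuclei are elliptical, not round
    thN <- wrap_orientation(cells[[i]]$orientation + stats::rnorm(1, 0, 5))
    pxN <- ellipse_pixels(shape, c(cells[[i]]$centroid_row,
                                   cells[[i]]$centroid_col),
                          aN / ps, bN / ps, thN)
    # the nucleus is always part of its cell, even on clipped patterns
    newpx <- cell_lab[pxN] != i
    cell_lab[pxN] <- i
    nuc_lab[pxN] <- i
    cells[[i]]$area_px <- cells[[i]]$area_px + sum(newpx)
    nucs[[i]] <- data.frame(
      label = i, parent = i,
      centroid_row = cells[[i]]$centroid_row,
      centroid_col = cells[[i]]$centroid_col,
      major_axis = 2 * aN, minor_axis = 2 * bN, orientation = thN,
      eccentricity = sqrt(1 - (bN / aN)^2),
      area = pi * aN * bN, area_px = nrow(pxN),
      clipped = FALSE)

    # focal adhesions: mixture of perinuclear annulus and peripheral band
    n_fa <- max(0L, as.integer(round(stats::rnorm(1, spec$fa_per_cell[1],
                                                  spec$fa_per_cell[2]))))
    a_px <- cells[[i]]$major_axis / 2 / ps
    b_px <- cells[[i]]$minor_axis / 2 / ps
    thC <- cells[[i]]$orientation * pi / 180
    for (k in seq_len(n_fa)) {
      for (try in seq_len(120L)) {
        peripheral <- stats::runif(1) < spec$fa_radial_placement
        rho <- if (peripheral) stats::runif(1, 0.72, 0.90) else
          stats::runif(1, 0.15, 0.45)
        phi <- stats::runif(1, 0, 2 * pi)
        u <- a_px * rho * cos(phi); v <- b_px * rho * sin(phi)
        ctrF <- c(cells[[i]]$centroid_row - (u * sin(thC) + v * cos(thC)),
                  cells[[i]]$centroid_col + (u * cos(thC) - v * sin(thC)))
        aF <- rnorm_pos(1, spec$fa_major[1], spec$fa_major[2], 1.2 * ps) / 2
        bF <- rnorm_pos(1, spec$fa_minor[1], spec$fa_minor[2], 0.8 * ps) / 2
        if (bF > aF) { tmp <- aF; aF <- bF; bF <- tmp }
        thF <- wrap_orientation(cells[[i]]$orientation + stats::rnorm(1, 0, 10))
        pxF <- ellipse_pixels(shape, ctrF, aF / ps, bF / ps, thF)
        if (nrow(pxF) == 0L) next
        if (any(cell_lab[pxF] != i)) next       # fully inside the parent cell
        halo <- ellipse_pixels(shape, ctrF, aF / ps + 4, bF / ps + 4, thF)
        if (any(fa_lab[halo] > 0L)) next        # keep puncta separated
        fa_next <- fa_next + 1L
        fa_lab[pxF] <- fa_next
        fas[[fa_next]] <- data.frame(
          label = fa_next, parent = i,
          centroid_row = ctrF[1], centroid_col = ctrF[2],
          major_axis = 2 * aF, minor_axis = 2 * bF, orientation = thF,
          eccentricity = sqrt(1 - (bF / aF)^2),
          area = pi * aF * bF, area_px = nrow(pxF),
          peripheral = peripheral)
        break
      }
    }
  }

  bind0 <- function(lst, proto) if (length(lst)) do.call(rbind, lst) else proto
  proto_obj <- data.frame(label = integer(0), centroid_row = numeric(0),
                          centroid_col = numeric(0), major_axis = numeric(0),
                          minor_axis = numeric(0), orientation = numeric(0),
                          eccentricity = numeric(0), area = numeric(0),
                          area_px = integer(0), clipped = logical(0))
  cells_df <- bind0(cells, proto_obj)
  nucs_df <- bind0(nucs, cbind(proto_obj[0, ], parent = integer(0)))
  fas_df <- bind0(fas, data.frame(label = integer(0), parent = integer(0),
                                  centroid_row = numeric(0),
                                  centroid_col = numeric(0),
                                  major_axis = numeric(0),
                                  minor_axis = numeric(0),
                                  orientation = numeric(0),
                                  eccentricity = numeric(0),
                                  area = numeric(0), area_px = integer(0),
                                  peripheral = logical(0)))

  # rendering: amplitudes chosen so Otsu separates structures at default noise
  render <- function(signal) {
    s <- signal
    if (spec$poisson_scale > 0)
      s <- stats::rpois(length(s), s * spec$poisson_scale) / spec$poisson_scale
    s <- s + stats::rnorm(length(s), 0, spec$gaussian_sd)
    s[s < 0] <- 0
    matrix(s, shape[1], shape[2])
  }
  bg <- spec$background
  nuc_sig <- bg + 0.95 * (nuc_lab > 0L)
  act_sig <- bg + 0.75 * (cell_lab > 0L)
  fa_sig <- bg + 0.12 * (cell_lab > 0L) + 0.9 * (fa_lab > 0L)

  channels <- list(
    nuclei = channel_image(render(nuc_sig), ps, "nuclei"),
    actin = channel_image(render(act_sig), ps, "actin"),
    fa = channel_image(render(fa_sig), ps, "fa"))
  if (!is.null(pat_mask))
    channels$pattern <- channel_image(render(bg + 0.8 * pat_mask), ps,
                                      "pattern")

  condition <- if (is.null(spec$pattern)) "control" else
    sprintf("%gx%g", spec$pattern$width, spec$pattern$spacing)
  images <- image_set(channels, condition = condition)

  fa_parent <- NULL
  if (nrow(fas_df) > 0L)
    fa_parent <- stats::setNames(as.integer(fas_df$parent),
                                 as.character(fas_df$label))
  truth <- structure(list(
    labels = list(
      nucleus = label_map(nuc_lab, "nucleus"),
      cell = label_map(cell_lab, "cell"),
      fa = label_map(fa_lab, "fa", parent = fa_parent)),
    cells = cells_df, nuclei = nucs_df, fas = fas_df),
    class = "ground_truth")
  list(images = images, truth = truth)
}

#' Expand a channel into a synthetic z-stack
#'
#' Produces `n_planes` copies of the channel at decreasing intensity with
#' independent Gaussian noise, emulating a focal stack whose maximum
#' projection recovers the in-focus plane.
#'
#' @param img a [channel_image].
#' @param n_planes number of planes (>= 1).
#' @param attenuation multiplicative intensity drop per plane away from the
#'   first (in-focus) plane.
#' @param noise_sd per-plane additive Gaussian noise sd.
#' @param seed RNG seed.
#' @return A list of [channel_image] planes.
#' @export
simulate_zstack <- function(img, n_planes = 3L, attenuation = 0.7,
                            noise_sd = 0.01, seed = 1L) {
  stopifnot(inherits(img, "channel_image"), n_planes >= 1)
  set.seed(seed)
  lapply(seq_len(n_planes), function(i) {
    px <- img$pixels * attenuation^(i - 1L) +
      stats::rnorm(length(img$pixels), 0, noise_sd)
    px[px < 0] <- 0
    channel_image(matrix(px, nrow(img$pixels)), img$pixel_size, img$role)
  })
}
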