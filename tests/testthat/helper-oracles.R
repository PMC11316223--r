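# Shared fixtures and independent oracles used across test files.

# cache expensive fixtures (scenes) across test files
.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, expr, envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

default_scene <- function(seed = 7) {
  cached(paste0("scene", seed), generate_scene(scene_spec(seed = seed)))
}

segmented_scene <- function(seed = 7) {
  cached(paste0("seg", seed), {
    sc <- default_scene(seed)
    pre <- preprocess_image_set(sc$images)
    nuc <- segment_nuclei(pre$channels$nuclei)
    cell <- segment_cells(pre$channels$actin, nuc)
    fa <- segment_fas(pre$channels$fa, cell)
    list(scene = sc, pre = pre, nuc = nuc, cell = cell, fa = fa)
  })
}

# exhaustive inter-class-variance scan: the independent Otsu oracle
otsu_scan_oracle <- function(counts, bin_values = seq_along(counts) - 1) {
  bin_values <- as.numeric(bin_values)
  total <- sum(counts)
  best_t <- NA_real_
  best_s <- -Inf
  for (k in seq_len(length(counts) - 1L)) {
    w0 <- sum(counts[1:k]) / total
    w1 <- 1 - w0
    if (w0 == 0 || w1 == 0) next
    mu0 <- sum(counts[1:k] * bin_values[1:k]) / sum(counts[1:k])
    hi <- (k + 1L):length(counts)
    mu1 <- sum(counts[hi] * bin_values[hi]) / sum(counts[hi])
    s <- w0 * w1 * (mu0 - mu1)^2
    if (s > best_s + 1e-12) { best_s <- s; best_t <- bin_values[k] }
  }
  list(t = best_t, sigma_b2 = best_s)
}

# brute-force grayscale opening (erosion then dilation) with a disk
opening_oracle <- function(px, radius) {
  offs <- expand.grid(dr = -radius:radius, dc = -radius:radius)
  offs <- offs[offs$dr^2 + offs$dc^2 <= radius^2, ]
  nr <- nrow(px); nc <- ncol(px)
  shift_vals <- function(m, agg) {
    out <- matrix(NA_real_, nr, nc)
    for (r in seq_len(nr)) for (c in seq_len(nc)) {
      vals <- c()
      for (k in seq_len(nrow(offs))) {
        rr <- r + offs$dr[k]; cc <- c + offs$dc[k]
        if (rr >= 1 && rr <= nr && cc >= 1 && cc <= nc)
          vals <- c(vals, m[rr, cc])
      }
      out[r, c] <- agg(vals)
    }
    out
  }
  shift_vals(shift_vals(px, min), max)
}

# raw second-central-moment descriptors from pixel coordinates (point
# masses, no pixel-extent correction): the independent moment oracle
moment_oracle <- function(mask) {
  idx <- which(mask > 0, arr.ind = TRUE)
  x <- idx[, 2]; y <- -idx[, 1]
  mu20 <- mean((x - mean(x))^2) + 1 / 12
  mu02 <- mean((y - mean(y))^2) + 1 / 12
  mu11 <- mean((x - mean(x)) * (y - mean(y)))
  ev <- eigen(matrix(c(mu20, mu11, mu11, mu02), 2))$values
  list(ecc = sqrt(1 - min(ev) / max(ev)), major = 4 * sqrt(max(ev)),
       centroid = c(mean(idx[, 1]), mean(idx[, 2])))
}

# independent boundary-walk perimeter: walk the 8-connected outer boundary
# pixel chain of a convex-ish mask by angular sorting around the centroid
square_perimeter_oracle <- function(n) 4 * (n - 1)

# filled ellipse mask (pixel-centre rasterization)
ellipse_mask <- function(shape, center, a, b, theta_deg = 0) {
  th <- theta_deg * pi / 180
  r <- matrix(seq_len(shape[1]), shape[1], shape[2])
  cc <- matrix(seq_len(shape[2]), shape[1], shape[2], byrow = TRUE)
  dx <- cc - center[2]; dy <- -(r - center[1])
  u <- dx * cos(th) + dy * sin(th)
  v <- -dx * sin(th) + dy * cos(th)
  ((u / a)^2 + (v / b)^2 <= 1) * 1L
}

disk_mask <- function(shape, center, radius) {
  ellipse_mask(shape, center, radius, radius)
}

# periodic line texture at a given angle (for fiber orientation tests)
line_texture <- function(angle_deg, shape = c(200, 200), width = 3,
                         pitch = 12) {
  th <- angle_deg * pi / 180
  r <- matrix(seq_len(shape[1]), shape[1], shape[2])
  cc <- matrix(seq_len(shape[2]), shape[1], shape[2], byrow = TRUE)
  perp <- -(cc - 0.5) * sin(th) + (-(r - 0.5)) * cos(th)
  matrix(as.numeric((perp %% pitch) < width), shape[1], shape[2])
}

# best-overlap Jaccard of each true object vs a recovered label map
jaccard_per_object <- function(true_labels, rec_labels) {
  vapply(seq_len(max(true_labels)), function(i) {
    ti <- true_labels == i
    cand <- rec_labels[ti]
    cand <- cand[cand > 0]
    if (!length(cand)) return(0)
    j <- as.integer(names(which.max(table(cand))))
    si <- rec_labels == j
    sum(ti & si) / sum(ti | si)
  }, numeric(1))
}
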