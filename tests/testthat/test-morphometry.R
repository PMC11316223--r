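test_that("descriptors hit closed forms for square, disk and ellipse", {
  # 10x10 px solid square at 1 µm/px
  lab <- matrix(0L, 20, 20); lab[6:15, 6:15] <- 1L
  m <- measure_objects(label_map(lab, "cell"), pixel_size = 1)
  expect_identical(m$area, 100)
  expect_identical(m$extent, 1)
  expect_identical(m$solidity, 1)
  expect_lt(m$eccentricity, 1e-9)
  # sqrt(2)-weighted boundary walk of an axis-aligned square: 4 * (n - 1)
  expect_equal(m$perimeter, square_perimeter_oracle(10))

  # solid disk: eccentricity near 0, form factor near 1
  dl <- matrix(0L, 120, 120)
  dl[disk_mask(c(120, 120), c(60, 60), 45) > 0] <- 1L
  md <- measure_objects(label_map(dl, "cell"), 1)
  expect_lt(md$eccentricity, 0.05)
  expect_lt(abs(md$form_factor - 1), 0.1)
  expect_equal(md$equivalent_diameter, 2 * sqrt(md$area / pi))

  # ellipse semi-axes 40/20 px: e = sqrt(1 - (20/40)^2) = sqrt(3)/2
  el <- matrix(0L, 120, 120)
  el[ellipse_mask(c(120, 120), c(60, 60), 40, 20) > 0] <- 1L
  me <- measure_objects(label_map(el, "cell"), 1)
  expect_lt(abs(me$eccentricity - sqrt(3) / 2), 0.01)
  # and the rasterized value matches the independent pixel-moment oracle
  orc <- moment_oracle(el)
  expect_equal(me$eccentricity, orc$ecc, tolerance = 1e-9)
  expect_equal(me$major_axis, orc$major, tolerance = 1e-9)
  expect_equal(c(me$centroid_row, me$centroid_col), orc$centroid,
               tolerance = 1e-9)
})

test_that("descriptors are scale-equivariant and rotation-robust", {
  el <- matrix(0L, 100, 100)
  el[ellipse_mask(c(100, 100), c(50, 50), 35, 14, 20) > 0] <- 1L
  m1 <- measure_objects(label_map(el, "cell"), pixel_size = 1)
  m2 <- measure_objects(label_map(el, "cell"), pixel_size = 2)
  expect_equal(m2$area, 4 * m1$area)
  expect_equal(m2$perimeter, 2 * m1$perimeter)
  expect_equal(m2$major_axis, 2 * m1$major_axis)
  expect_equal(m2$feret_max, 2 * m1$feret_max)
  for (f in c("eccentricity", "solidity", "extent", "form_factor"))
    expect_equal(m2[[f]], m1[[f]], tolerance = 1e-12)

  rot <- matrix(0L, 100, 100)
  rot[ellipse_mask(c(100, 100), c(50, 50), 35, 14, 50) > 0] <- 1L
  mr <- measure_objects(label_map(rot, "cell"), 1)
  expect_lt(abs(mr$eccentricity - m1$eccentricity), 0.02)
  expect_equal(mr$orientation, 50, tolerance = 1)
  expect_equal(m1$orientation, 20, tolerance = 1)
})

test_that("morphometry recovers simulator ground truth on true label maps", {
  sc <- default_scene()
  ps <- 0.5
  for (lv in c("cell", "nucleus")) {
    meas <- measure_objects(sc$truth$labels[[lv]], ps)
    truth <- if (lv == "cell") sc$truth$cells else sc$truth$nuclei
    expect_identical(nrow(meas), nrow(truth))
    expect_true(all(abs(meas$area - truth$area) / truth$area < 0.02))
    expect_true(all(abs(meas$major_axis - truth$major_axis) /
                      truth$major_axis < 0.03))
    expect_true(all(abs(meas$eccentricity - truth$eccentricity) < 0.02))
    expect_true(all(abs(meas$centroid_row - truth$centroid_row) < 0.5))
    expect_true(all(abs(meas$centroid_col - truth$centroid_col) < 0.5))
  }
  # FA-scale objects are pixelization-dominated; centroids still recover
  mf <- measure_objects(sc$truth$labels$fa, ps)
  tf <- sc$truth$fas
  expect_true(all(abs(mf$centroid_row - tf$centroid_row) < 0.75))
  expect_true(all(abs(mf$centroid_col - tf$centroid_col) < 0.75))
})

test_that("the per-cell feature matrix has the fixed 40-feature catalog", {
  cat40 <- feature_catalog()
  expect_identical(length(cat40), 40L)
  expect_true(all(c("fa_eccentricity_mean", "cell_major_axis",
                    "nucleus_eccentricity") %in% cat40))

  base <- data.frame(image_id = "i1", condition = "ctrl", day = NA_integer_,
                     level = "cell", label = 1L, parent = NA_integer_)
  desc <- function(level, label, parent = NA_integer_, ecc = 0.5) {
    d <- base
    d$level <- level; d$label <- label; d$parent <- parent
    for (f in fibromorph:::DESCRIPTOR_FEATURES) d[[f]] <- 2
    d$eccentricity <- ecc
    d$orientation <- 0; d$centroid_row <- 5; d$centroid_col <- 5
    d
  }
  tab <- rbind(desc("cell", 1L), desc("nucleus", 1L, parent = 1L),
               desc("fa", 1L, parent = 1L), desc("fa", 2L, parent = 1L),
               desc("fa", 3L, parent = 1L))
  fm <- assemble_feature_matrix(tab)
  expect_identical(names(fm), c("image_id", "condition", "day", "cell_label",
                                "zero_fa", cat40))
  expect_identical(fm$fa_count, 3L)
  expect_identical(fm$fa_area_sd, 0)        # identical FAs: sd features 0
  expect_identical(fm$fa_eccentricity_sd, 0)
  expect_false(fm$zero_fa)

  # zero-FA cell: aggregates 0, flag set
  fm0 <- assemble_feature_matrix(rbind(desc("cell", 1L),
                                       desc("nucleus", 1L, parent = 1L)))
  expect_true(fm0$zero_fa)
  expect_identical(fm0$fa_area_mean, 0)
  expect_identical(fm0$fa_count, 0L)

  # a nucleus without a matching cell breaks the bijection
  bad <- rbind(desc("cell", 1L), desc("nucleus", 2L, parent = 2L))
  expect_error(assemble_feature_matrix(bad), "bijection")
})

test_that("two-point normalization anchors control at 0 and myo at 1", {
  set.seed(6)
  n <- 12
  mk <- function(cond, shift) {
    d <- data.frame(condition = rep(cond, n))
    for (f in feature_catalog()) d[[f]] <- rnorm(n, 10 + shift)
    d
  }
  fm <- rbind(mk("ctrl", 0), mk("mid", 0), mk("myo", 2))
  # deterministic midpoint: set mid condition means exactly halfway
  for (f in feature_catalog())
    fm[fm$condition == "mid", f] <-
      (mean(fm[fm$condition == "ctrl", f]) + mean(fm[fm$condition == "myo", f])) / 2
  fm$flat <- 1
  attr(fm, "feature_names") <- c(feature_catalog(), "flat")
  heat <- normalize_to_anchors(fm, "ctrl", "myo")
  ok <- heat$defined
  expect_true(all(abs(heat$normalized[heat$condition == "ctrl" & ok]) < 1e-12))
  expect_true(all(abs(heat$normalized[heat$condition == "myo" & ok] - 1) < 1e-12))
  expect_true(all(abs(heat$normalized[heat$condition == "mid" & ok] - 0.5) < 1e-9))
  # zero-gap feature flagged undefined, not dropped
  expect_true(all(!heat$defined[heat$feature == "flat"]))
  expect_identical(sum(heat$feature == "flat"), 3L)
  expect_error(normalize_to_anchors(fm[fm$condition != "myo", ], "ctrl", "myo"),
               "anchor")
})
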