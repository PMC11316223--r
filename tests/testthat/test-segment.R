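test_that("otsu_threshold matches the exhaustive scan oracle", {
  # two-spike histogram: any threshold between the spikes attains the same
  # inter-class variance; the smallest-maximizer convention picks the lower
  counts <- rep(0, 256)
  counts[10 + 1] <- 50; counts[200 + 1] <- 50
  res <- otsu_threshold(counts, 0:255)
  expect_identical(res$t, 10)
  expect_false(res$degenerate)
  expect_equal(res$sigma_b2, 0.25 * (200 - 10)^2)

  set.seed(8)
  for (i in 1:100) {
    counts <- rpois(256, lambda = sample(c(0.2, 2, 20), 1))
    if (sum(counts) == 0 || sum(counts > 0) < 2) next
    res <- otsu_threshold(counts, 0:255)
    orc <- otsu_scan_oracle(counts, 0:255)
    expect_identical(res$t, orc$t)
    expect_equal(res$sigma_b2, orc$sigma_b2, tolerance = 1e-9)
  }

  deg <- otsu_threshold(c(0, 0, 17, 0), 0:3)
  expect_true(deg$degenerate)
  expect_identical(deg$t, 2)
  expect_error(otsu_threshold(numeric(0)), "empty")
  expect_error(otsu_threshold(c(0, 0, 0)), "zero total")
})

test_that("nuclei segmentation counts, filters and border policy behave", {
  shape <- c(120, 120)
  centers <- list(c(20, 20), c(20, 80), c(60, 50), c(95, 20), c(95, 90))
  px <- matrix(0.05, shape[1], shape[2])
  for (ct in centers) px[disk_mask(shape, ct, 8) > 0] <- 1
  img <- channel_image(px, 1, "nuclei")
  nuc <- segment_nuclei(img, min_area = 50, max_area = 500)
  expect_identical(max(nuc$labels), 5L)

  blank <- channel_image(matrix(0.1, 50, 50), 1, "nuclei")
  expect_identical(max(segment_nuclei(blank)$labels), 0L)

  # a disk below min_area is excluded
  small <- px
  small[disk_mask(shape, c(60, 100), 3) > 0] <- 1
  n2 <- segment_nuclei(channel_image(small, 1, "nuclei"), min_area = 50)
  expect_identical(max(n2$labels), 5L)

  # border-touching object removed by default, kept when allowed
  bord <- matrix(0.05, 60, 60)
  bord[disk_mask(c(60, 60), c(3, 30), 6) > 0] <- 1
  bord[disk_mask(c(60, 60), c(40, 30), 6) > 0] <- 1
  expect_identical(max(segment_nuclei(channel_image(bord, 1, "nuclei"),
                                      min_area = 10)$labels), 1L)
  expect_identical(max(segment_nuclei(channel_image(bord, 1, "nuclei"),
                                      min_area = 10,
                                      exclude_border = FALSE)$labels), 2L)
})

test_that("seeded cell segmentation assigns foreground by geodesic distance", {
  # one nucleus in a uniform bright patch: the whole patch is one cell
  shape <- c(60, 60)
  nucpx <- matrix(0.05, shape[1], shape[2])
  nucpx[disk_mask(shape, c(30, 30), 5) > 0] <- 1
  nuc <- segment_nuclei(channel_image(nucpx, 1, "nuclei"), min_area = 10)
  actin <- matrix(0.05, shape[1], shape[2])
  actin[15:45, 10:50] <- 0.9
  cells <- segment_cells(channel_image(actin, 1, "actin"), nuc)
  expect_identical(max(cells$labels), 1L)
  expect_true(all(cells$labels[15:45, 10:50] == 1L))
  expect_identical(sum(cells$labels > 0), sum(31L * 41L))

  # two equal seeds in a symmetric rectangle: boundary at the bisector +/- 1 px
  nucpx2 <- matrix(0.05, 40, 100)
  nucpx2[disk_mask(c(40, 100), c(20, 25), 4) > 0] <- 1
  nucpx2[disk_mask(c(40, 100), c(20, 75), 4) > 0] <- 1
  nuc2 <- segment_nuclei(channel_image(nucpx2, 1, "nuclei"), min_area = 10)
  actin2 <- matrix(0.9, 40, 100)
  actin2[1, 1] <- 0.05  # keep Otsu non-degenerate
  cells2 <- segment_cells(channel_image(actin2, 1, "actin"), nuc2)
  # pixels clearly left of the bisector belong to seed 1, right to seed 2
  expect_true(all(cells2$labels[, 1:49] %in% c(0L, 1L)))
  expect_true(all(cells2$labels[, 52:100] %in% c(0L, 2L)))
  expect_identical(setdiff(sort(unique(as.vector(cells2$labels[, 1:49]))), 0L),
                   1L)

  # actin entirely below threshold: each cell equals its nucleus footprint
  flat <- channel_image(matrix(0.2, 40, 100), 1, "actin")
  cells3 <- segment_cells(flat, nuc2)
  expect_identical(cells3$labels > 0L, nuc2$labels > 0L)
})

test_that("FA segmentation masks by cells, filters by area and links parents", {
  shape <- c(80, 80)
  # three cells stacked; FA image has puncta inside cell 3, outside all
  # cells, and a 2 px speck
  nucpx <- matrix(0.05, shape[1], shape[2])
  for (i in 1:3) nucpx[disk_mask(shape, c(15 + 25 * (i - 1), 20), 5) > 0] <- 1
  nuc <- segment_nuclei(channel_image(nucpx, 1, "nuclei"), min_area = 10)
  actin <- matrix(0.05, shape[1], shape[2])
  actin[5:75, 8:45] <- 0.9
  cells <- segment_cells(channel_image(actin, 1, "actin"), nuc)
  expect_identical(max(cells$labels), 3L)

  fa_px <- matrix(0.02, shape[1], shape[2])
  fa_px[63:66, 30:33] <- 1     # inside cell 3
  fa_px[40:43, 60:63] <- 1     # outside every cell -> discarded
  fa_px[15, 34:35] <- 1        # 2 px speck inside cell 1 -> below min area
  fa <- segment_fas(channel_image(fa_px, 1, "fa"), cells, min_area = 4,
                    smooth_sigma = 0)
  expect_identical(max(fa$labels), 1L)
  expect_identical(unname(fa$parent[["1"]]), 3L)
  expect_true(all(cells$labels[fa$labels == 1L] == 3L))

  empty_cells <- label_map(matrix(0L, shape[1], shape[2]), "cell")
  expect_warning(fa0 <- segment_fas(channel_image(fa_px, 1, "fa"),
                                    empty_cells), "no cell pixels")
  expect_identical(max(fa0$labels), 0L)
})

test_that("segmentation recovers the default scene exactly and nests levels", {
  seg <- segmented_scene()
  sc <- seg$scene
  expect_identical(max(seg$nuc$labels), nrow(sc$truth$nuclei))
  expect_identical(max(seg$cell$labels), nrow(sc$truth$cells))
  expect_identical(max(seg$fa$labels), nrow(sc$truth$fas))
  # nesting: nucleus within its cell, FAs within the cell union
  nl <- seg$nuc$labels; cl <- seg$cell$labels
  expect_true(all(cl[nl > 0L] == nl[nl > 0L]))
  expect_true(all(cl[seg$fa$labels > 0L] > 0L))
  # per-cell Jaccard against the true masks
  expect_true(all(jaccard_per_object(sc$truth$labels$cell$labels,
                                     seg$cell$labels) >= 0.8))
})
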