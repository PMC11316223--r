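test_that("pattern masks have the stated geometry", {
  # equal width and spacing cover half the area
  m <- generate_pattern_mask(pattern_spec(15, 15, 0), c(300, 300), 1)
  expect_lt(abs(mean(m) - 0.5), 1 / 300 + 1e-9)
  # zero spacing degenerates to a fully coated surface
  m0 <- generate_pattern_mask(pattern_spec(10, 0, 45), c(50, 50), 1)
  expect_true(all(m0 == 1L))
  # 20x20 µm lines at 1 µm/px span exactly 5 periods of a 200 px image;
  # oracle: run-length count of foreground stripes down a single column
  m20 <- generate_pattern_mask(pattern_spec(20, 20, 0), c(200, 200), 1)
  runs <- rle(m20[, 1])
  expect_identical(sum(runs$values == 1L), 5L)
  expect_true(all(runs$lengths[runs$values == 1L] == 20))
  # every column identical for angle 0
  expect_true(all(m20 == m20[, 1]))
})

test_that("scene generation is deterministic and bookkeeping is complete", {
  spec <- scene_spec(image_shape = c(384, 384), n_cells = 4,
                     cell_length = c(45, 5), seed = 11)
  a <- generate_scene(spec)
  b <- generate_scene(spec)
  expect_identical(a$images$channels$nuclei$pixels,
                   b$images$channels$nuclei$pixels)
  expect_identical(a$truth$fas, b$truth$fas)

  sc <- default_scene()
  expect_identical(nrow(sc$truth$cells), 10L)
  expect_identical(nrow(sc$truth$nuclei), 10L)
  expect_identical(nrow(sc$truth$fas), 80L)
  expect_true(all(sc$truth$fas$parent %in% sc$truth$cells$label))
  expect_true(all(table(sc$truth$fas$parent) == 8L))
  # parent map of the true FA label map is consistent with the table
  expect_identical(as.integer(sc$truth$labels$fa$parent[
    as.character(sc$truth$fas$label)]), sc$truth$fas$parent)
})

test_that("an empty scene yields pure-noise channels and empty truth", {
  sc <- generate_scene(scene_spec(image_shape = c(64, 64), n_cells = 0,
                                  seed = 3))
  expect_identical(nrow(sc$truth$cells), 0L)
  expect_identical(nrow(sc$truth$fas), 0L)
  expect_identical(max(sc$truth$labels$cell$labels), 0L)
  # noise only: nothing near the object amplitudes
  expect_lt(max(sc$images$channels$nuclei$pixels), 0.6)
})

test_that("ground truth matches the rendered label maps", {
  sc <- default_scene()
  for (lv in c("cell", "nucleus")) {
    lab <- sc$truth$labels[[lv]]$labels
    tab <- if (lv == "cell") sc$truth$cells else sc$truth$nuclei
    for (i in tab$label) {
      idx <- which(lab == i, arr.ind = TRUE)
      expect_lt(abs(mean(idx[, 1]) - tab$centroid_row[tab$label == i]), 0.5)
      expect_lt(abs(mean(idx[, 2]) - tab$centroid_col[tab$label == i]), 0.5)
      # pixel area within 2% of pi*a*b (in px^2) for non-clipped ellipses
      a_px <- tab$major_axis[tab$label == i] / 2 / 0.5
      b_px <- tab$minor_axis[tab$label == i] / 2 / 0.5
      expect_lt(abs(nrow(idx) - pi * a_px * b_px) / (pi * a_px * b_px), 0.02)
    }
  }
})

test_that("orientation concentration tightens the true orientation spread", {
  pat <- pattern_spec(20, 20, 30)
  sds <- vapply(c(0, 2, 6), function(conc) {
    sc <- generate_scene(scene_spec(image_shape = c(640, 640), n_cells = 8,
                                    pattern = pat, bridge_width = 30,
                                    cell_orientation_concentration = conc,
                                    seed = 31))
    rel <- fibromorph:::wrap_orientation(sc$truth$cells$orientation - 30)
    fibromorph:::axial_stats(rel)$sd
  }, numeric(1))
  expect_true(all(diff(sds) < 0))
})

test_that("synthetic force curves follow the pyramidal contact law", {
  tip <- tip_spec(half_angle = 35, poisson_ratio = 0.5)
  cv <- generate_force_curve(E = 1000, tip = tip, max_indentation = 1,
                             n_points = 101)
  expect_identical(cv$force[1], 0)        # no force before contact
  # closed-form check at delta = 1 µm (independent numeric evaluation)
  expect_equal(cv$force[101],
               tan(35 * pi / 180) / (sqrt(2) * (1 - 0.5^2)) * 1000 * 1e-3,
               tolerance = 1e-12)
  cv2 <- generate_force_curve(E = 2000, tip = tip, max_indentation = 1,
                              n_points = 101)
  expect_equal(cv2$force, 2 * cv$force, tolerance = 1e-12)
  expect_error(generate_force_curve(1000, tip, max_indentation = -1), "max_indentation")
})

test_that("Ct tables are exact in the noiseless limit and recoverable with noise", {
  # fold 1 for all genes: delta-Ct equal across groups
  ct1 <- generate_ct_table(c(g1 = 1, g2 = 1), n_replicates = 4)
  fc1 <- ddct_fold_change(ct1, "control")
  expect_true(all(abs(fc1$fold - 1) < 1e-12))
  # fold 2 noiseless: ddCt = -1 exactly
  ct2 <- generate_ct_table(c(g1 = 2), n_replicates = 3)
  fc2 <- ddct_fold_change(ct2, "control")
  expect_equal(fc2$ddct[fc2$group == "treated"], -1)
  # simulation study: noisy recovery within 15% of truth across 20 seeds
  rec <- vapply(1:20, function(s) {
    ct <- generate_ct_table(c(g1 = 2), n_replicates = 6, ct_noise_sd = 0.1,
                            seed = s)
    fc <- ddct_fold_change(ct, "control")
    fc$fold[fc$group == "treated"]
  }, numeric(1))
  expect_true(all(abs(rec - 2) / 2 < 0.15))
})
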