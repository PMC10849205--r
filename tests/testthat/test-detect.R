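test_that("a blank stack yields no granules", {
  st <- blank_stack()
  g <- detect_granules(st, rect_roi())
  expect_equal(nrow(g), 0)
})

test_that("specks below min_area are filtered out", {
  st <- blank_stack()
  st <- paint_box(st, "AF488", x = 10:11, y = 10, z = 3, value = 220)
  g <- detect_granules(st, rect_roi()) # 2 px^2 < min_area = 3
  expect_equal(nrow(g), 0)
  st <- paint_box(st, "AF488", x = 10:11, y = 10:11, z = 3, value = 220)
  g <- detect_granules(st, rect_roi())
  expect_equal(nrow(g), 1)
})

test_that("missing channels raise a configuration error", {
  vox <- array(30, c(16, 16, 4, 1))
  st <- zstack(vox, 0.2, 0.5, "AF488")
  expect_error(detect_granules(st, rect_roi(x1 = 15, y1 = 15, z_bottom = 3)),
               "TRANS")
})

test_that("granule features match closed forms on constructed shapes", {
  st <- blank_stack(ny = 40, nx = 40)
  # digital disc r = 5: Crofton circularity 0.884 (frozen against an
  # independent 4-direction Crofton implementation), aspect ~1
  vox <- disc_voxels(20, 20, 5, z = 3)
  st2 <- blank_stack(ny = 40, nx = 40)
  st2$voxels[cbind(vox[, "y"] + 1, vox[, "x"] + 1, vox[, "z"] + 1, 1)] <- 200
  g <- measure_granule(vox, st2)
  expect_equal(g$area_px2, 81)
  expect_equal(g$circularity, 0.884, tolerance = 0.001)
  expect_gte(g$circularity, 0.85)
  expect_lte(g$aspect_ratio, 1.1)

  # 2 x 12 bar: clearly elongated
  bar <- as.matrix(expand.grid(y = 10:11, x = 5:16, z = 2))
  g <- measure_granule(bar, st2)
  expect_gte(g$aspect_ratio, 3)

  # bull's-eye: centre 40, annulus 180 -> ring score +140
  ring <- disc_voxels(20, 20, 4.5, z = 3)
  st3 <- blank_stack(ny = 40, nx = 40)
  d <- sqrt((ring[, "x"] - 20)^2 + (ring[, "y"] - 20)^2)
  r_eq <- sqrt(nrow(ring) / pi)
  vals <- ifelse(d <= 0.5 * r_eq, 40, 180)
  st3$voxels[cbind(ring[, "y"] + 1, ring[, "x"] + 1, ring[, "z"] + 1, 1)] <- vals
  g <- measure_granule(ring, st3)
  expect_equal(g$ring_score, 140, tolerance = 1e-9)

  # single voxel: degenerate convention
  g <- measure_granule(cbind(y = 5, x = 5, z = 1), st2)
  expect_equal(g$circularity, 1)
  expect_equal(g$aspect_ratio, 1)
})

test_that("detection is translation-equivariant for whole-pixel shifts", {
  mk <- function(dx, dy) {
    st <- blank_stack(ny = 48, nx = 48)
    for (p in list(c(12, 14, 2, 200), c(30, 22, 5, 220))) {
      vox <- disc_voxels(p[1] + dx, p[2] + dy, 2.5, z = p[3])
      st$voxels[cbind(vox[, "y"] + 1, vox[, "x"] + 1, vox[, "z"] + 1, 1)] <- p[4]
    }
    detect_granules(st, rect_roi(x1 = 47, y1 = 47))
  }
  g0 <- mk(0, 0); g1 <- mk(3, 5)
  expect_equal(nrow(g0), 2)
  expect_equal(nrow(g1), 2)
  expect_equal(sort(g1$x) - sort(g0$x), c(3, 3))
  expect_equal(sort(g1$y) - sort(g0$y), c(5, 5))
})

test_that("per-cell counts conserve the frame total", {
  scn <- cached_scene(20, 3, image_size = c(256L, 256L))
  res <- cached_analysis(20, 3, image_size = c(256L, 256L))
  expect_equal(sum(res$cells$count), nrow(res$granules))
  # no granule assigned to two cells: ids partition the table
  expect_true(all(table(res$granules$granule_id) == 1))
  # zone counts conserve cell totals
  for (cid in res$cells$cell_id[1:5]) {
    zc <- res$zones[[cid]]
    expect_equal(sum(zc[, "total"]),
                 res$cells$count[res$cells$cell_id == cid])
  }
})

test_that("noise-free scenes give perfect recall for resolvable granules", {
  # cells large enough that excluded-volume placement always succeeds;
  # compact phenotypes matched by centroid (aggregate centroids depend on
  # their sub-disc layout and are checked elsewhere)
  cfg <- scene_config(n_cells = 10, image_size = c(256, 256), seed = 12,
                      noise_sd = 0)
  scn <- simulate_scene(cfg)
  res <- analyze_scene(scn$stack, scn$rois)
  tr <- scn$truth$granules
  big <- tr[2 * tr$rx >= 3 & tr$phenotype != "L2", ]
  m <- match_granules(res$granules, big)
  expect_equal(m$recall, 1)
})

test_that("2-D mode splits what 3-D mode links across slices", {
  st <- blank_stack()
  for (z in 2:4) {
    vox <- disc_voxels(16, 16, 2.5, z = z)
    st$voxels[cbind(vox[, "y"] + 1, vox[, "x"] + 1, vox[, "z"] + 1, 1)] <- 200
  }
  g3 <- detect_granules(st, rect_roi())
  g2 <- detect_granules(st, rect_roi(), detection_params(mode = "2d"))
  expect_equal(nrow(g3), 1)
  expect_equal(nrow(g2), 3)
})
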