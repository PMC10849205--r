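test_that("zstack dimension bookkeeping and metadata survive a round trip", {
  set.seed(1)
  vox <- array(sample(0:255, 10 * 64 * 64, replace = TRUE), c(64, 64, 10, 1))
  st <- zstack(vox, 0.2, 0.5, "AF488")
  expect_equal(dim(st), c(64, 64, 10, 1))

  path <- withr::local_tempfile(fileext = ".tif")
  write_zstack(st, path)
  back <- read_zstack(path)
  expect_identical(back$voxels, st$voxels)
  expect_equal(back$pixel_size_um, 0.2)
  expect_equal(back$channel_names, "AF488")
})

test_that("16-bit stacks round-trip losslessly", {
  set.seed(2)
  vox <- array(sample(0:65535, 4 * 16 * 16, replace = TRUE), c(16, 16, 4, 1))
  st <- zstack(vox, 0.1, 0.4, "AF488", bit_depth = 16L)
  path <- withr::local_tempfile(fileext = ".tif")
  write_zstack(st, path)
  expect_identical(read_zstack(path)$voxels, st$voxels)
})

test_that("multi-channel page order is z-major channel-minor", {
  vox <- array(0, c(8, 8, 3, 2))
  for (z in 1:3) for (ch in 1:2) vox[, , z, ch] <- 10 * z + ch
  st <- zstack(vox, 0.2, 0.5, c("AF488", "TRANS"))
  path <- withr::local_tempfile(fileext = ".tif")
  write_zstack(st, path)
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  expect_equal(pages[[1]][1, 1], 11) # z1 AF
  expect_equal(pages[[2]][1, 1], 12) # z1 TRANS
  expect_equal(pages[[3]][1, 1], 21) # z2 AF
  expect_identical(read_zstack(path)$voxels, st$voxels)
})

test_that("inconsistent page shapes raise a format error", {
  path <- withr::local_tempfile(fileext = ".tif")
  tiff::writeTIFF(list(matrix(0, 8, 8), matrix(0, 8, 8), matrix(0, 4, 8)),
                  path)
  jsonlite::write_json(list(pixel_size_um = 0.2, z_step_um = 0.5,
                            channel_names = "AF488"),
                       paste0(path, ".json"), auto_unbox = TRUE)
  expect_error(read_zstack(path), "format error")
})

test_that("zstack invariants are enforced", {
  expect_error(zstack(array(300, c(2, 2, 1, 1)), 0.2, 0.5, "AF488"),
               "bit depth")
  expect_error(zstack(array(0, c(2, 2, 1, 1)), -1, 0.5, "AF488"),
               "pixel_size_um")
  expect_error(zstack(array(0, c(2, 2, 1, 2)), 0.2, 0.5, "AF488"),
               "channel")
})

test_that("ROI JSON reading validates polygons and ids", {
  path <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(list(cells = list(
    list(id = "a", polygon = list(c(0, 0), c(10, 0), c(10, 10), c(0, 10)),
         z_top = 0, z_bottom = 9))), path, auto_unbox = TRUE)
  rois <- read_rois(path)
  expect_length(rois, 1)
  expect_equal(polygon_area(rois[[1]]$polygon), 100)

  jsonlite::write_json(list(cells = list(
    list(id = "a", polygon = list(c(0, 0), c(10, 0), c(10, 10), c(0, 10)),
         z_top = 0, z_bottom = 9),
    list(id = "a", polygon = list(c(0, 0), c(5, 0), c(5, 5), c(0, 5)),
         z_top = 0, z_bottom = 9))), path, auto_unbox = TRUE)
  expect_error(read_rois(path), "duplicate")

  jsonlite::write_json(list(cells = list(
    list(id = "bow", polygon = list(c(0, 0), c(10, 10), c(10, 0), c(0, 10)),
         z_top = 0, z_bottom = 9))), path, auto_unbox = TRUE)
  expect_error(read_rois(path), "self-intersecting")

  jsonlite::write_json(list(cells = list(
    list(id = "z", polygon = list(c(0, 0), c(10, 0), c(10, 10), c(0, 10)),
         z_top = 5, z_bottom = 5))), path, auto_unbox = TRUE)
  expect_error(read_rois(path), "z_top")
})

test_that("ROI write/read round trip preserves polygons exactly", {
  rois <- list(rect_roi("a"), cell_roi("b", regular_polygon(7, 8, 20, 20),
                                       0, 7))
  path <- withr::local_tempfile(fileext = ".json")
  write_rois(rois, path)
  back <- read_rois(path)
  expect_equal(back[[2]]$polygon, rois[[2]]$polygon)
  expect_identical(back[[1]]$z_bottom, rois[[1]]$z_bottom)
})

test_that("summary CSV has the canonical columns and is reproducible", {
  g <- data.frame(area_px2 = c(4, 6), mean_af = c(100, 120),
                  volume_vox = c(8, 10),
                  family = c("MELANIN", "LIPOFUSCIN"))
  geom <- measure_cell(rect_roi("c1"), 0.2)
  rows <- do.call(rbind, lapply(1:6, function(i) {
    s <- summarize_cell(g, geom, dose = c("LOW_40", "HIGH_60")[1 + i %% 2],
                        day = c(1, 7, 30)[1 + i %% 3])
    s$cell_id <- paste0("c", i)
    s
  }))
  path <- withr::local_tempfile(fileext = ".csv")
  write_summary_tables(rows, path)
  out <- utils::read.csv(path, check.names = FALSE)
  expect_true(all(c("Count", "Total area", "Average size", "% Area",
                    "Mean") %in% names(out)))
  expect_equal(nrow(unique(out[, c("dose", "day")])), 6)
  expect_equal(out$`Average size`, rep(5, 6), tolerance = 1e-6)

  path2 <- withr::local_tempfile(fileext = ".csv")
  write_summary_tables(rows, path2)
  expect_identical(readLines(path), readLines(path2)) # byte-identical

  expect_error(write_summary_tables(rows[0, ], path), "nothing to write")
})
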