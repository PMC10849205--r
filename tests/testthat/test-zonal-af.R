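test_that("zone assignment splits a 12-slice cell into 3-slice zones", {
  expect_equal(zone_of_z(1, 0, 11), 1L)  # C1
  expect_equal(zone_of_z(6, 0, 11), 3L)  # C3
  expect_equal(zone_of_z(c(0, 2, 3, 5, 8, 9, 11), 0, 11),
               c(1L, 1L, 2L, 2L, 3L, 4L, 4L))
  # boundary position goes to the more apical zone
  expect_equal(zone_of_z(2.5, 0, 11), 1L)
})

test_that("zone counts are order-invariant and conserve the total", {
  roi <- rect_roi(z_bottom = 11)
  set.seed(5)
  g <- data.frame(granule_id = paste0("g", 1:40),
                  z = runif(40, 0, 11),
                  family = sample(c("MELANIN", "LIPOFUSCIN"), 40, TRUE))
  zp1 <- assign_zones(roi, g)
  zp2 <- assign_zones(roi, g[sample(40), ])
  expect_identical(zp1$counts, zp2$counts)
  expect_equal(sum(zp1$counts[, "total"]), 40)
  expect_equal(sum(zp1$counts[, c("MELANIN", "LIPOFUSCIN")]), 40)

  g_bad <- data.frame(granule_id = "gx", z = 13, family = "MELANIN")
  expect_error(assign_zones(roi, g_bad), "outside cell extent")
})

test_that("green histogram conserves mass and bins exactly", {
  st <- blank_stack(ny = 16, nx = 16, nz = 2, af_bg = 30)
  h <- rgb_stack_histogram(st)
  expect_equal(h[31], 16 * 16 * 2) # all mass in bin for value 30
  expect_equal(sum(h), 16 * 16 * 2)

  st$voxels[, 1:8, , 1] <- 0
  st$voxels[, 9:16, , 1] <- 255
  h <- rgb_stack_histogram(st)
  expect_equal(h[1], h[256])
  expect_equal(sum(h), 16 * 16 * 2)

  # 16-bit rescale rule: floor(v * 255 / 65535)
  v16 <- array(c(0, 257, 65535, 65278), c(2, 2, 1, 1))
  st16 <- zstack(v16, 0.2, 0.5, "AF488", bit_depth = 16L)
  h16 <- rgb_stack_histogram(st16)
  # 65278 * 255 = 254 * 65535 exactly, so it lands in bin 254
  expect_equal(which(h16 > 0) - 1L, c(0L, 1L, 254L, 255L))
})

test_that("plot profile follows ImageJ rectangular-selection semantics", {
  st <- blank_stack(ny = 16, nx = 32, nz = 2, af_bg = 50)
  p <- plot_profile(st)
  expect_true(all(p == 50))
  st$voxels[, 11:13, , 1] <- 200 # bright vertical stripe, columns 10-12
  p <- plot_profile(st)
  expect_equal(as.integer(names(which(p > 50))), 10:12)
  expect_equal(mean(p), mean(get_channel(st, "AF488"))) # conservation
  expect_error(plot_profile(st, x0 = 5, x1 = 4), "zero-width")
})

test_that("total AF sums exactly and is monotone under added intensity", {
  st <- blank_stack(ny = 20, nx = 20, nz = 1, af_bg = 0)
  roi <- cell_roi("c", rbind(c(-0.5, -0.5), c(9.5, -0.5), c(9.5, 9.5),
                             c(-0.5, 9.5)), 0, 1)
  # z extent needs >= 2 slices; use a 2-slice stack with one painted slice
  st <- blank_stack(ny = 20, nx = 20, nz = 2, af_bg = 0)
  st$voxels[1:10, 1:10, 1, 1] <- 50 # 100 in-cell pixels at 50
  rep_ <- total_af(st, roi)
  expect_equal(rep_$total_af, 5000)

  st2 <- st
  st2$voxels[3:5, 3:5, 2, 1] <- 80 # an added bright granule
  expect_gt(total_af(st2, roi)$total_af, rep_$total_af)

  roi_out <- cell_roi("o", rbind(c(100, 100), c(110, 100), c(110, 110),
                                 c(100, 110)), 0, 1)
  expect_error(total_af(st, roi_out), "outside frame")
})

test_that("background estimate finds the out-of-cell histogram mode", {
  st <- blank_stack(ny = 32, nx = 32, nz = 2, af_bg = 30)
  roi <- cell_roi("c", rbind(c(0, 0), c(15, 0), c(15, 15), c(0, 15)), 0, 1)
  st$voxels[1:16, 1:16, , 1] <- 120 # cell interior much brighter
  bg <- estimate_background(st, list(roi), "AF488")
  expect_equal(bg$mode, 30)
})
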