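test_that("zero rate plants zero granules", {
  cfg <- scene_config(n_cells = 5, image_size = c(64, 64), seed = 1,
                      granule_rate_per_cell = 0)
  mos <- generate_mosaic(cfg)
  pl <- plant_granules(cfg, mos)
  expect_equal(nrow(pl$granules), 0)
})

test_that("a pure-M2 mix plants only spindles with axis ratio >= 2", {
  cfg <- scene_config(n_cells = 10, image_size = c(160, 160), seed = 2,
                      phenotype_mix = c(L1 = 0, L2 = 0, ML1 = 0, ML2 = 0,
                                        M1 = 0, M2 = 1))
  mos <- generate_mosaic(cfg)
  pl <- plant_granules(cfg, mos)
  expect_true(all(pl$granules$phenotype == "M2"))
  expect_true(all(pl$granules$rx / pl$granules$ry >= 2))
})

test_that("granule centres stay inside their cell polygon and z extent", {
  scn <- cached_scene(20, 3, image_size = c(256L, 256L))
  g <- scn$truth$granules
  rois <- scn$rois
  names(rois) <- vapply(rois, function(r) r$cell_id, character(1))
  ok <- vapply(seq_len(nrow(g)), function(i) {
    r <- rois[[g$cell_id[i]]]
    point_in_polygon(g$x[i], g$y[i], r$polygon) &&
      g$z[i] >= r$z_top && g$z[i] <= r$z_bottom
  }, logical(1))
  expect_true(all(ok))
  # zone labels consistent with the C1-C4 rule
  expect_identical(g$zone,
                   zone_of_z(g$z, rois[[1]]$z_top, rois[[1]]$z_bottom))
})

test_that("zonal priors place families in their zones", {
  scn <- cached_scene(20, 3, image_size = c(256L, 256L))
  g <- scn$truth$granules
  mel <- g$family %in% c("MELANIN", "MELANOLIPOFUSCIN")
  expect_gte(mean(g$zone[mel] <= 2), 0.9)
  expect_gte(mean(g$zone[g$family == "LIPOFUSCIN"] == 3), 0.9)

  # near-zero prior sd: no truncation spill at all
  cfg <- scene_config(n_cells = 10, image_size = c(160, 160), seed = 4,
                      zonal_sd_mel = 0.05, zonal_sd_lip = 0.05)
  pl <- plant_granules(cfg, generate_mosaic(cfg))
  mel <- pl$granules$family != "LIPOFUSCIN"
  expect_equal(mean(pl$granules$zone[mel] <= 2), 1)
  expect_equal(mean(pl$granules$zone[!mel] == 3), 1)
})

test_that("configured trend multipliers are recoverable from truth counts", {
  # Poisson MLE of the per-cell rate is the sample mean; at 200 cells per
  # condition the day-30/day-1 rate ratio recovers the configured
  # multiplier ratio within 10%
  counts <- function(day, seed) {
    cfg <- scene_config(n_cells = 200, image_size = c(760L, 760L),
                        dose = "LOW_40", day = day, seed = seed)
    pl <- plant_granules(cfg, generate_mosaic(cfg))
    tapply(pl$granules$family, pl$granules$cell_id,
           function(f) sum(f == "MELANIN"))
  }
  m1 <- counts(1, 21); m30 <- counts(30, 22)
  ratio <- mean(m30, na.rm = TRUE) / mean(m1, na.rm = TRUE)
  expect_equal(ratio, 1.8, tolerance = 0.1)
  expect_gt(mean(m30, na.rm = TRUE), mean(m1, na.rm = TRUE))
})

test_that("rendering is deterministic and respects channel contrast", {
  cfg <- scene_config(n_cells = 5, image_size = c(96, 96), seed = 6)
  s1 <- simulate_scene(cfg)
  s2 <- simulate_scene(cfg)
  expect_identical(s1$stack$voxels, s2$stack$voxels) # byte-identical
  expect_identical(s1$truth$granules, s2$truth$granules)
})

test_that("empty truth renders a flat background", {
  cfg <- scene_config(n_cells = 2, image_size = c(64, 64), seed = 8,
                      granule_rate_per_cell = 0,
                      nuclei_probs = c(1, 0, 0, 0))
  scn <- simulate_scene(cfg)
  af <- get_channel(scn$stack, "AF488")
  # mean over N voxels concentrates around the background level
  expect_lt(abs(mean(af) - cfg$af_bg),
            3 * cfg$noise_sd / sqrt(length(af)) + 0.51) # + rounding bias
})

test_that("single planted granules carry the expected AF/TRANS signature", {
  base <- scene_config(n_cells = 1, image_size = c(48, 48), seed = 9,
                       granule_rate_per_cell = 0)
  mos <- generate_mosaic(base)
  mk_truth <- function(ph) {
    g <- data.frame(granule_id = "g_1", cell_id = mos$cells$cell_id[1],
                    phenotype = ph, family = unname(
                      c(L1 = "LIPOFUSCIN", M1 = "MELANIN")[ph]),
                    x = 24, y = 24, z = 4, rx = 2.5, ry = 2.5, rz = 1.1,
                    theta = 0, extent = 2.5, zone = 2L)
    list(mosaic = mos, granules = g,
         subdiscs = data.frame(granule_id = character(0), dx = numeric(0),
                               dy = numeric(0), r = numeric(0)))
  }
  foot <- as.matrix(expand.grid(y = 22:26, x = 22:26, z = 4))

  st <- render_scene(base, mk_truth("L1"))
  af <- get_channel(st, "AF488")
  expect_gt(mean(af[foot + 1L]), base$af_bg + 5 * base$noise_sd)

  st <- render_scene(base, mk_truth("M1"))
  af <- get_channel(st, "AF488"); tr <- get_channel(st, "TRANS")
  expect_lt(mean(tr[foot + 1L]), base$trans_bg - 5 * base$noise_sd)
  expect_lt(abs(mean(af[foot + 1L]) - base$af_bg), 3 * base$noise_sd)
})
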