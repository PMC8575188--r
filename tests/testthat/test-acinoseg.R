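test_that("stopper rasterization matches a 2D disk-membership oracle", {
  shape <- c(30L, 41L, 41L)
  st <- segmentation_stopper(c(15, 21, 21), c(1, 0, 0), radius_um = 10,
                             thickness_vox = 2L)
  plug <- rasterize_stopper(st, shape, voxel_size_um = 1)
  # oracle: per-pixel membership on one slice
  disk <- outer((1:41 - 21)^2, (1:41 - 21)^2, `+`) <= 100
  hit_z <- which(apply(plug, 1, any))
  expect_length(hit_z, 2L)  # thickness 2 along the normal
  for (z in hit_z) expect_identical(plug[z, , ], disk)

  # radius spanning the whole slice: full-slice plug
  big <- rasterize_stopper(
    segmentation_stopper(c(15, 21, 21), c(1, 0, 0), 100, 2L), shape, 1)
  expect_true(all(big[15, , ]))

  # centre at the boundary: clipped, no exception
  edge <- rasterize_stopper(
    segmentation_stopper(c(1, 1, 1), c(1, 0, 0), 5, 3L), shape, 1)
  expect_gt(sum(edge), 0)
  expect_error(rasterize_stopper(
    segmentation_stopper(c(0, 1, 1), c(1, 0, 0), 5), shape, 1),
    "outside")
})

test_that("threshold suggestion separates bimodal stacks", {
  ph <- make_phantom(n_alveoli = 4, seed = 3)
  g <- render_grayscale(ph, tissue_level = 200, air_level = 20)
  th <- suggest_threshold(g)
  expect_gt(th, 20); expect_lt(th, 200)
  expect_identical(suggest_threshold(g, override = 77), 77)
  expect_error(suggest_threshold(voxel_stack(array(5, c(4, 4, 4)), 1)),
               "constant")
})

test_that("region growing recovers the true air set exactly when noiseless", {
  ph <- make_phantom(n_alveoli = 6, seed = 8)
  g <- render_grayscale(ph)
  th <- suggest_threshold(g)
  air <- ph$labels > 0L
  # any seed inside the air set reproduces the full set (idempotence)
  air_idx <- which(air)
  set.seed(1)
  for (i in sample(air_idx, 3)) {
    zyx <- arrayInd(i, dim(air))
    seg <- region_grow(g, as.integer(zyx), th)
    expect_identical(seg$mask, air)
    expect_identical(seg$voxel_count, sum(air))
  }
  # seed errors
  tis <- arrayInd(which(!air)[1], dim(air))
  expect_error(region_grow(g, as.integer(tis), th), "tissue")
  expect_error(region_grow(g, as.integer(arrayInd(air_idx[1], dim(air))),
                           threshold = min(g$data) - 1), "tissue")
})

test_that("raising the threshold never shrinks the mask", {
  ph <- make_phantom(n_alveoli = 5, seed = 12)
  g <- render_grayscale(ph, noise_sd = 15, seed = 2)
  seed_pt <- as.integer(arrayInd(which(ph$labels == 1L)[50], dim(ph$labels)))
  m1 <- region_grow(g, seed_pt, 90)$mask
  m2 <- region_grow(g, seed_pt, 140)$mask
  expect_true(all(m2[m1]))  # superset relation
})

test_that("stoppers are airtight; without them growth leaks", {
  # two air boxes joined by a straight duct: distal [20..28], proximal [4..12]
  dims <- c(31L, 21L, 21L)
  lab <- array(0L, dims)
  lab[4:12, 6:16, 6:16] <- 1L
  lab[20:28, 6:16, 6:16] <- 1L
  lab[13:19, 9:13, 9:13] <- 1L  # connecting duct, radius ~2
  g <- render_grayscale(lab, voxel_size_um = 1)
  th <- 110
  seed_distal <- c(24L, 11L, 11L)

  free <- region_grow(g, seed_distal, th)
  expect_identical(free$voxel_count, sum(lab > 0L))  # spans both units

  st <- segmentation_stopper(c(16, 11, 11), c(1, 0, 0), radius_um = 6,
                             thickness_vox = 3L)
  blocked <- region_grow(g, seed_distal, th, list(st))
  # impermeability: nothing proximal of the plug is reached
  zidx <- slice.index(blocked$mask, 1)
  expect_identical(sum(blocked$mask & zidx <= 14), 0L)
  expect_gt(blocked$voxel_count, 0L)
  expect_error(region_grow(g, c(16L, 11L, 11L), th, list(st)),
               "stopper")
})

test_that("acinus export writes faithful provenance and detects tampering", {
  ph <- make_phantom(n_alveoli = 3, seed = 5)
  g <- render_grayscale(ph)
  th <- suggest_threshold(g)
  seed_pt <- as.integer(arrayInd(which(ph$labels == 1L)[10], dim(ph$labels)))
  st <- segmentation_stopper(c(2, 2, 2), c(1, 0, 0), 3)
  seg <- region_grow(g, seed_pt, th, list(st))
  f <- withr::local_tempfile(fileext = ".tif")
  extract_acinus(g, seg, f)

  man <- verify_acinus_export(f)
  expect_equal(man$seed_point, seg$seed_point)
  expect_equal(man$threshold, th)
  expect_equal(man$voxel_count, seg$voxel_count)
  expect_length(man$stoppers, 1L)

  # re-segmentation of the exported overlay gives the same voxel count
  mask2 <- read_overlay_mask(f)
  expect_identical(sum(mask2), seg$voxel_count)

  # tamper with the manifest -> validation error
  mpath <- sub("(\\.[^.]+)?$", "_manifest.json", f)
  man2 <- jsonlite::read_json(mpath, simplifyVector = TRUE)
  man2$voxel_count <- man2$voxel_count + 1
  jsonlite::write_json(man2, mpath, auto_unbox = TRUE, digits = NA)
  expect_error(verify_acinus_export(f), "validation failed")
})

test_that("stopper lists round trip through JSON and YAML", {
  sts <- list(list(center = c(3, 4, 5), normal = c(1, 0, 0),
                   radius_um = 7, thickness_vox = 4),
              list(center = c(9, 9, 9), normal = c(0, 0, 1),
                   radius_um = 2.5))
  fj <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(sts, fj, auto_unbox = TRUE, digits = NA)
  got <- read_stoppers(fj)
  expect_length(got, 2L)
  expect_equal(got[[1]]$center, c(3, 4, 5))
  expect_equal(got[[1]]$thickness_vox, 4L)
  expect_equal(got[[2]]$thickness_vox, 3L)  # default
  fy <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(sts, fy)
  got2 <- read_stoppers(fy)
  expect_equal(got2[[2]]$radius_um, 2.5)
})
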