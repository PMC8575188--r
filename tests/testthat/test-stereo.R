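test_that("SURS slice designs follow systematic sampling arithmetic", {
  s <- surs_slices(100, 10, offset = 1)
  expect_identical(s$indices, seq.int(1L, 91L, by = 10L))
  expect_length(s$indices, 10L)

  s2 <- surs_slices(95, 10, offset = 8)
  expect_identical(s2$indices, seq.int(8L, 88L, by = 10L))
  expect_length(s2$indices, 9L)

  # over all offsets the designs partition the sections
  all_idx <- unlist(lapply(1:10, function(o)
    surs_slices(95, 10, offset = o)$indices))
  expect_identical(sort(all_idx), 1:95)
  # mean section count times interval recovers the depth within one interval
  counts <- vapply(1:10, function(o)
    length(surs_slices(95, 10, offset = o)$indices), 1L)
  expect_lte(abs(mean(counts) * 10 - 95), 10)

  expect_error(surs_slices(5, 10), "interval")
  # offset drawn uniformly from the seed
  offs <- vapply(1:200, function(s) surs_slices(50, 5, seed = s)$offset, 1L)
  expect_identical(sort(unique(offs)), 1:5)
})

test_that("systematic acinus subsampling partitions the id list", {
  ids <- paste0("ac", 1:9)
  expect_identical(subsample_acini(ids, 3, start = 1),
                   ids[c(1, 4, 7)])
  expect_identical(subsample_acini(ids, 1), ids)
  picks <- lapply(1:3, function(s) subsample_acini(ids, 3, start = s))
  expect_identical(sort(unlist(picks)), sort(ids))
  expect_identical(sum(duplicated(unlist(picks))), 0L)
  expect_length(subsample_acini(character(0), 3), 0L)
})

test_that("point counting equals brute-force node membership", {
  set.seed(5)
  vox <- 1.48
  for (rep in 1:3) {
    mask <- matrix(runif(60 * 45) < 0.4, 60, 45)
    g <- point_grid(spacing_um = runif(1, 4, 12),
                    origin_offset_um = NULL, seed = rep)
    expect_identical(count_points(mask, g, vox),
                     brute_count_points(mask, g, vox))
  }
  full <- matrix(TRUE, 100, 100)
  g0 <- point_grid(10 * vox, origin_offset_um = c(0, 0))
  expect_identical(count_points(full, g0, vox), 100L)
  expect_identical(count_points(matrix(FALSE, 30, 30), g0, vox), 0L)
})

test_that("Cavalieri estimate is exact on aligned solids and unbiased on spheres", {
  vox <- 1.48
  cuboid <- array(TRUE, dim = c(120, 120, 120))
  sl <- surs_slices(120, 12, offset = 1)
  g <- point_grid(12 * vox, origin_offset_um = c(0, 0))
  est <- cavalieri_volume(cuboid, sl, g, vox)
  expect_equal(est$volume_mm3, (120 * vox)^3 * 1e-9, tolerance = 1e-12)
  expect_identical(est$sum_points, 1000L)

  # unbiasedness over the exhaustive offset/origin design
  dims <- c(61L, 61L, 61L)
  mask <- array(FALSE, dims)
  mask[acinostereo:::sphere_voxels(c(31, 31, 31), 24, dims)] <- TRUE
  truev <- sum(mask) * 1e-9
  tot <- 0; nn <- 0L
  for (off in 1:4) for (oy in 0:3) for (ox in 0:3) {
    s <- surs_slices(61, 4, offset = off)
    gg <- point_grid(4, origin_offset_um = c(oy, ox) + 0.5)
    tot <- tot + cavalieri_volume(mask, s, gg, 1)$volume_mm3
    nn <- nn + 1L
  }
  expect_lt(abs(tot / nn - truev) / truev, 0.005)

  # zero points -> zero volume; empty design -> error
  none <- array(FALSE, dim = c(20, 20, 20))
  z <- cavalieri_volume(none, surs_slices(20, 5, offset = 2),
                        point_grid(5), 1)
  expect_identical(z$volume_mm3, 0)
  expect_error(cavalieri_volume(mask, list(indices = integer(0)), g, 1))
})

test_that("Gundersen-Jensen CE does not grow when the interval is halved", {
  dims <- c(81L, 61L, 61L)
  mask <- array(FALSE, dims)
  mask[acinostereo:::sphere_voxels(c(41, 31, 31), 26, dims)] <- TRUE
  ce_at <- function(interval) {
    mean(vapply(seq_len(interval), function(o) {
      s <- surs_slices(81, interval, offset = o)
      cavalieri_volume(mask, s, point_grid(3, c(0.5, 0.5)), 1)$ce
    }, 1))
  }
  expect_lte(ce_at(4), ce_at(8) * 1.05)
})

test_that("exhaustive-pair disector returns the manifest count exactly", {
  ph <- make_phantom(n_alveoli = 12, seed = 6)
  d <- disector_count(ph)
  expect_identical(d$pairs_examined, d$pairs_total)
  expect_identical(d$n_estimate, 12)
  expect_identical(d$q_appear, 12L)
  expect_identical(d$q_disappear, 12L)

  empty <- array(0L, dim = c(10, 10, 10))
  expect_identical(disector_count(empty)$n_estimate, 0)
  expect_error(disector_count(array(0L, dim = c(1, 5, 5))), "2 sections")
})

test_that("reversing the section order swaps events, not the estimate", {
  ph <- make_phantom(n_alveoli = 9, seed = 14)
  fwd <- disector_count(ph)
  rev_labels <- ph$labels[rev(seq_len(dim(ph$labels)[1])), , ]
  bwd <- disector_count(rev_labels)
  expect_identical(bwd$q_appear, fwd$q_disappear)
  expect_identical(bwd$q_disappear, fwd$q_appear)
  expect_identical(bwd$n_estimate, fwd$n_estimate)
})

test_that("fractional pair sampling is unbiased over starts", {
  ph <- make_phantom(n_alveoli = 10, seed = 20)
  ests <- vapply(1:2, function(s)
    disector_count(ph, pair_interval = 2L, start = s)$n_estimate, 1)
  expect_lt(abs(mean(ests) - 10) / 10, 0.05)
})

test_that("interruption heuristic counts open mouths on constructed slices", {
  # duct profile with two alveoli attached through narrow necks
  sl <- matrix(FALSE, 60, 60)
  sl[outer((1:60 - 30)^2, (1:60 - 30)^2, `+`) <= 81] <- TRUE   # duct r=9
  sl[outer((1:60 - 30)^2, (1:60 - 48)^2, `+`) <= 49] <- TRUE   # alveolus r=7
  sl[outer((1:60 - 48)^2, (1:60 - 30)^2, `+`) <= 49] <- TRUE   # alveolus r=7
  sl[29:31, 36:44] <- TRUE  # 3-px mouth neck to the right alveolus
  sl[36:44, 29:31] <- TRUE  # 3-px mouth neck to the lower alveolus
  expect_identical(detect_interruptions(sl, neck_radius = 3L), 2L)

  closed <- matrix(FALSE, 40, 40)
  closed[outer((1:40 - 20)^2, (1:40 - 20)^2, `+`) <= 100] <- TRUE
  expect_identical(detect_interruptions(closed, neck_radius = 3L), 0L)

  expect_identical(detect_interruptions(matrix(TRUE, 20, 20)), 0L)
  expect_identical(detect_interruptions(matrix(FALSE, 20, 20)), 0L)
})

test_that("shrinkage correction is a ratio factor with exact round trip", {
  f <- shrinkage_factor(1.2, 1.0)
  expect_equal(f$factor, 1.2)
  expect_equal(apply_correction(0.5, f), 0.6)
  expect_equal(apply_correction(apply_correction(0.5, f), f, invert = TRUE),
               0.5)
  expect_identical(shrinkage_factor(3, 3)$factor, 1)
  expect_error(shrinkage_factor(0, 1), "positive")
  expect_error(shrinkage_factor(1, -2), "positive")
})
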