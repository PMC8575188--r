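make_records <- function(seed = 1, n = 30) {
  set.seed(seed)
  acinus_records(
    animal_id = rep(c("A", "B", "C"), each = n / 3),
    day = rep(c(4, 4, 60), each = n / 3),
    acinus_id = seq_len(n),
    volume_mm3 = rlnorm(n, -3, 0.8),
    n_alveoli = sample.int(200, n, replace = TRUE))
}

test_that("records keep the density-volume-count triad to machine precision", {
  rec <- make_records()
  expect_equal(rec$density_per_mm3 * rec$volume_mm3,
               as.numeric(rec$n_alveoli), tolerance = 1e-14)
  expect_error(acinus_records("A", 4, 1, -0.1, 5), "volumes")
})

test_that("per-animal summaries match the direct sample formulas", {
  rec <- make_records(seed = 2)
  tb <- summarize_by_animal(rec, "volume_mm3")
  for (a in c("A", "B", "C")) {
    x <- rec$volume_mm3[rec$animal_id == a]
    r <- tb[tb$animal_id == a, ]
    expect_equal(r$average, mean(x))
    expect_equal(r$sd, sd(x))
    expect_equal(c(r$minimum, r$maximum), range(x))
    expect_identical(r$assessed_acini, length(x))
  }
  # order invariance
  shuf <- rec[sample(nrow(rec)), ]
  class(shuf) <- class(rec)
  expect_equal(summarize_by_animal(shuf, "volume_mm3"), tb)

  single <- acinus_records("Z", 4, 1, 0.5, 10)
  ts <- summarize_by_animal(single, "volume_mm3")
  expect_identical(ts$sd, 0)
  expect_false(ts$sd_defined)
})

test_that("weighted day means equal pooled per-acinus means", {
  rec <- make_records(seed = 3)
  tb <- summarize_by_animal(rec, "n_alveoli")
  expect_equal(day_weighted_mean(tb, 4),
               mean(rec$n_alveoli[rec$day == 4]))
  expect_error(day_weighted_mean(tb, 99), "no animals")
  # single-animal day equals that animal's mean
  expect_equal(day_weighted_mean(tb, 60),
               tb$average[tb$day == 60])
})

test_that("pooled CV from a table matches the per-record CV", {
  rec <- make_records(seed = 4)
  tb <- summarize_by_animal(rec, "volume_mm3")
  # table path (exact here: no display rounding applied)
  expect_equal(cv_of_day(tb, 4), cv_of_day(rec, 4), tolerance = 1e-12)
  expect_equal(cv_of_day(acinus_records(c("A", "A"), 4, 1:2,
                                        c(1, 3), c(1, 1)), 4,
                         quantity = "volume_mm3"),
               sqrt(2) / 2)
  const <- acinus_records("A", 4, 1:5, rep(2, 5), rep(7, 5))
  expect_identical(cv_of_day(const, 4), 0)
  expect_error(cv_of_day(acinus_records("A", 4, 1, 1, 1), 4), "2 acini")
})

test_that("size-quintile ratio matches brute-force sorted tails", {
  v <- c(0.4, 1.2, 0.9, 5.0, 2.2, 0.1, 3.3, 0.7, 4.1, 1.8)
  q <- quintile_ratio(v, fraction = 0.2)
  sv <- sort(v)
  expect_equal(q$ratio, mean(sv[9:10]) / mean(sv[1:2]))
  expect_identical(q$n_per_tail, 2L)
  expect_equal(quintile_ratio(rep(3, 10))$ratio, 1)
  # tail size rounds to nearest: 20% of 43 acini -> 9 per tail
  expect_identical(quintile_ratio(seq_len(43))$n_per_tail, 9L)
  expect_identical(quintile_ratio(seq_len(125))$n_per_tail, 25L)
  expect_error(quintile_ratio(c(1, 2)), "tail")
})

test_that("volume normalization maps each day onto (0, 1] with max 1", {
  rec <- make_records(seed = 5)
  nv <- normalize_volumes(rec, 4)
  expect_equal(max(nv$normalized), 1)
  expect_true(all(nv$normalized > 0 & nv$normalized <= 1))
  # order statistics preserved
  v <- rec$volume_mm3[rec$day == 4]
  expect_identical(order(nv$normalized), order(v))
  one <- normalize_volumes(0.3)
  expect_identical(one$normalized, 1)
  expect_identical(one$median, 1)
})

test_that("lung-level identities hold and reproduce the printed values", {
  expect_equal(estimate_n_acini(1.0, 0.1), 10)
  n <- estimate_n_acini(123.4, 0.0567)
  expect_equal(n * 0.0567, 123.4)
  expect_error(estimate_n_acini(-1, 1), "positive")

  # printed day-60 inputs: 4277 acini x 702 alveoli each
  expect_lt(abs(total_alveoli(4277, 702) - 3.01) / 3.01, 0.01)
  expect_equal(total_alveoli(1, 1e6), 1)
  expect_identical(total_alveoli(0, 50), 0)

  # sphere identity and printed alveolar volumes
  expect_equal(sphere_diameter(pi / 6), 1)
  expect_equal(round(sphere_diameter(4.98e5)), 98)
  expect_equal(round(sphere_diameter(8.12e5)), 116)
  av <- alveolar_volume_and_diameter(0.5, 100, ductal_fraction = 0.8)
  expect_equal(av$volume_um3, 0.8 * 0.5e9 / 100)
  expect_error(alveolar_volume_and_diameter(0.5, 0), "count")
  expect_error(alveolar_volume_and_diameter(0.5, 10, 1.2), "ductal")
})

test_that("cross-study scale factors evaluate as published", {
  ref <- cross_study_reference()
  expect_equal(round(linear_scale_factor(
    ref$total_alveoli_millions_histology,
    ref$total_alveoli_millions_tomography, "ratio_of_sums"), 2), 5.04)
  expect_equal(round(linear_scale_factor(
    ref$alveolar_volume_1e5um3_tomography,
    ref$alveolar_volume_1e5um3_histology, "mean_of_ratios"), 2), 1.81)
  x <- c(1, 2, 3)
  expect_equal(linear_scale_factor(x, x, "ratio_of_sums"), 1)
  expect_equal(linear_scale_factor(x, x, "mean_of_ratios"), 1)
  expect_error(linear_scale_factor(x, c(1, 2)), "length")
})
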