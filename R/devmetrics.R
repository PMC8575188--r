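#' Build per-acinus records
#'
#' One row per assessed acinus: animal, postnatal day, shrinkage-corrected
#' acinar volume, alveolar (entrance-ring) count, and the derived density
#' `n_alveoli / volume_mm3`. The density is always recomputed from its two
#' parents so the consistency triad `density * volume == count` holds to
#' machine precision.
#'
#' @param animal_id,day,acinus_id,volume_mm3,n_alveoli vectors of equal
#'   length (recycled per usual rules for scalars).
#' @return An `acinus_records` data frame.
#' @export
acinus_records <- function(animal_id, day, acinus_id, volume_mm3,
                           n_alveoli) {
  df <- data.frame(animal_id = animal_id, day = day, acinus_id = acinus_id,
                   volume_mm3 = volume_mm3, n_alveoli = n_alveoli,
                   stringsAsFactors = FALSE)
  if (any(df$volume_mm3 <= 0)) stop("volumes must be > 0")
  if (any(df$n_alveoli < 0)) stop("alveolar counts must be >= 0")
  df$density_per_mm3 <- df$n_alveoli / df$volume_mm3
  structure(df, class = c("acinus_records", "data.frame"))
}

#' Summarize records per animal into a counting table
#'
#' Per-animal n, mean, sample SD (n-1 denominator), minimum and maximum of
#' one quantity — the shape of the published per-animal tables. A single
#' record yields SD 0 with `sd_defined = FALSE`. Output order is by animal
#' id, so the table is invariant to input row order.
#'
#' @param records an `acinus_records` data frame.
#' @param quantity `"n_alveoli"`, `"volume_mm3"`, or `"density_per_mm3"`.
#' @return A `counting_table` data frame (plus an `sd_defined` column).
#' @export
summarize_by_animal <- function(records,
                                quantity = c("n_alveoli", "volume_mm3",
                                             "density_per_mm3")) {
  quantity <- match.arg(quantity)
  ids <- sort(unique(records$animal_id))
  rows <- lapply(ids, function(a) {
    sub <- records[records$animal_id == a, ]
    x <- sub[[quantity]]
    n <- length(x)
    data.frame(animal_id = a, day = sub$day[1L], assessed_acini = n,
               average = mean(x),
               sd = if (n > 1L) stats::sd(x) else 0,
               minimum = min(x), maximum = max(x),
               sd_defined = n > 1L, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  structure(out, class = c("counting_table", "data.frame"),
            quantity = quantity)
}

#' Acini-weighted day mean from a per-animal table
#'
#' `sum(n_i * mean_i) / sum(n_i)` over the day's animals, which equals the
#' pooled per-acinus mean of the day exactly.
#'
#' @param table a `counting_table`.
#' @param day postnatal day present in the table.
#' @return Pooled mean (unrounded).
#' @export
day_weighted_mean <- function(table, day) {
  sub <- table[table$day == day, ]
  if (!nrow(sub)) stop(sprintf("no animals for day %s", day))
  sum(sub$assessed_acini * sub$average) / sum(sub$assessed_acini)
}

#' Pooled coefficient of variation of a day's acini
#'
#' From raw records: pooled SD over pooled mean. From a per-animal table
#' the pooled variance is recovered as
#' `[sum((n_i - 1) s_i^2) + sum(n_i (m_i - m)^2)] / (sum(n_i) - 1)`,
#' which is exact up to the table's display rounding.
#'
#' @param x an `acinus_records` data frame or a `counting_table`.
#' @param day postnatal day.
#' @param quantity column used when `x` is records.
#' @return CV (SD / mean), dimensionless.
#' @export
cv_of_day <- function(x, day, quantity = "volume_mm3") {
  if (inherits(x, "acinus_records")) {
    v <- x[[quantity]][x$day == day]
    if (length(v) < 2L) stop("need at least 2 acini for a CV")
    return(stats::sd(v) / mean(v))
  }
  sub <- x[x$day == day, ]
  if (!nrow(sub) || sum(sub$assessed_acini) < 2L)
    stop("need at least 2 acini for a CV")
  n <- sub$assessed_acini; m <- sub$average; s <- sub$sd
  mbar <- sum(n * m) / sum(n)
  pooled_var <- (sum((n - 1) * s^2) + sum(n * (m - mbar)^2)) / (sum(n) - 1)
  sqrt(pooled_var) / mbar
}

#' Ratio of mean volumes of the largest to smallest size quintile
#'
#' Sorts a day's acinar volumes, takes the `fraction` smallest and
#' `fraction` largest (tail size rounded to nearest, so 20% of 125 acini
#' gives 25 and 20% of 43 gives 9), and returns the ratio of tail means.
#'
#' @param records an `acinus_records` data frame, or a bare numeric vector
#'   of volumes.
#' @param day day filter (ignored for a bare vector).
#' @param fraction tail fraction, default 0.2.
#' @return List: `ratio`, `mean_low`, `mean_high`, `n_per_tail`.
#' @export
quintile_ratio <- function(records, day = NULL, fraction = 0.2) {
  v <- if (is.numeric(records)) records
  else records$volume_mm3[records$day == day]
  n_tail <- as.integer(round(fraction * length(v)))
  if (n_tail < 1L)
    stop("too few acini: tail would be empty")
  v <- sort(v)
  lo <- mean(v[seq_len(n_tail)])
  hi <- mean(v[seq.int(length(v) - n_tail + 1L, length(v))])
  list(ratio = hi / lo, mean_low = lo, mean_high = hi, n_per_tail = n_tail)
}

#' Normalize a day's volumes to the day maximum
#'
#' Divides each volume by the largest volume of the day, so the normalized
#' values lie in (0, 1] with maximum exactly 1; the median of the
#' normalized volumes summarizes the skew (well below 0.5 early in
#' development, 0.5 for a symmetric spread).
#'
#' @param records records data frame or numeric volume vector.
#' @param day day filter (ignored for a bare vector).
#' @return List: `normalized` (same order as input), `median`.
#' @export
normalize_volumes <- function(records, day = NULL) {
  v <- if (is.numeric(records)) records
  else records$volume_mm3[records$day == day]
  if (!length(v)) stop("no volumes to normalize")
  nv <- v / max(v)
  list(normalized = nv, median = stats::median(nv))
}

#' Estimate the number of acini per lung
#'
#' Parenchymal lung volume divided by the mean (Cavalieri-estimated)
#' acinar volume; the identity `n * mean_volume = parenchymal` holds to
#' machine precision.
#'
#' @param parenchymal_volume_mm3 parenchymal volume (> 0), an external
#'   scalar from whole-lung stereology.
#' @param mean_acinar_volume_mm3 mean acinar volume (> 0).
#' @return Estimated acinus count (real).
#' @export
estimate_n_acini <- function(parenchymal_volume_mm3,
                             mean_acinar_volume_mm3) {
  if (parenchymal_volume_mm3 <= 0 || mean_acinar_volume_mm3 <= 0)
    stop("volumes must be positive")
  parenchymal_volume_mm3 / mean_acinar_volume_mm3
}

#' Total alveoli per lung, in millions
#' @param n_acini estimated acini per lung (> 0, 0 allowed for degenerate
#'   input).
#' @param mean_alveoli_per_acinus mean entrance-ring count per acinus.
#' @return Millions of alveoli.
#' @export
total_alveoli <- function(n_acini, mean_alveoli_per_acinus) {
  n_acini * mean_alveoli_per_acinus / 1e6
}

#' Mean alveolar volume and sphere-equivalent diameter
#'
#' Mean single-alveolus volume = `ductal_fraction * mean acinar volume /
#' mean alveolar count` (the ductal fraction removes the alveolar-duct
#' share of the acinar air space), converted to um^3; the diameter assumes
#' a spherical alveolus: `d = (6 V / pi)^(1/3)`.
#'
#' @param mean_acinar_volume_mm3 mean acinar volume (mm^3).
#' @param mean_alveoli mean alveoli per acinus (> 0).
#' @param ductal_fraction fraction of acinar volume attributed to alveoli
#'   (in (0, 1]); see [ductal_fractions()] for per-day defaults.
#' @return List: `volume_um3`, `diameter_um`.
#' @export
alveolar_volume_and_diameter <- function(mean_acinar_volume_mm3,
                                         mean_alveoli,
                                         ductal_fraction = 1) {
  if (mean_alveoli <= 0) stop("mean alveolar count must be > 0")
  if (ductal_fraction <= 0 || ductal_fraction > 1)
    stop("ductal_fraction must lie in (0, 1]")
  v_um3 <- ductal_fraction * mean_acinar_volume_mm3 * 1e9 / mean_alveoli
  list(volume_um3 = v_um3, diameter_um = sphere_diameter(v_um3))
}

#' Sphere-equivalent diameter of a volume
#' @param volume_um3 volume in um^3.
#' @return Diameter in um, `(6 V / pi)^(1/3)`.
#' @export
sphere_diameter <- function(volume_um3) (6 * volume_um3 / pi)^(1 / 3)

#' Per-day alveolar volume fractions of the acinar air space
#'
#' The share of acinar volume attributed to alveoli (the complement being
#' alveolar ducts) for postnatal days 4/10/21/60. These values are not
#' directly measured here: they are reverse-engineered from the cohort's
#' published mean alveolar volumes against the exact acini-weighted day
#' means of the packaged per-animal tables, and shipped as configuration.
#'
#' @return Named numeric vector, names `"4" "10" "21" "60"`.
#' @export
ductal_fractions <- function() {
  c(`4` = 0.733, `10` = 0.739, `21` = 0.689, `60` = 0.771)
}

#' Linear scale factor between two per-day series
#'
#' Cross-study comparison helper: either the ratio of series sums
#' (`sum(ref) / sum(own)`, one factor aligning the totals) or the mean of
#' per-day ratios (`mean(ref_i / own_i)`).
#'
#' @param series_ref,series_own equal-length positive numeric vectors.
#' @param mode `"ratio_of_sums"` or `"mean_of_ratios"`.
#' @return The scale factor.
#' @export
linear_scale_factor <- function(series_ref, series_own,
                                mode = c("ratio_of_sums",
                                         "mean_of_ratios")) {
  mode <- match.arg(mode)
  if (length(series_ref) != length(series_own))
    stop("series must have equal length")
  if (any(series_ref <= 0) || any(series_own <= 0))
    stop("series must be positive")
  switch(mode,
         ratio_of_sums = sum(series_ref) / sum(series_own),
         mean_of_ratios = mean(series_ref / series_own))
}

#' Packaged cross-study reference series
#'
#' Day-level series used for cross-methodology comparison: total alveoli
#' per lung (millions) and mean alveolar volumes (1e5 um^3) from a
#' histology-based study of the same animals, alongside the
#' tomography-based values of this cohort, plus acini-per-lung estimates
#' and the day-wise size-quintile tail means (ul).
#'
#' @return Data frame with one row per day.
#' @export
cross_study_reference <- function() {
  utils::read.csv(system.file("extdata", "cross_study_reference.csv",
                              package = "acinostereo", mustWork = TRUE))
}
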