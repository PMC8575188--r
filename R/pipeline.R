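#' Default pipeline configuration
#'
#' Orchestration parameters for the end-to-end phantom pipeline. The day
#' profiles default to the developmental cohort's own aggregates
#' ([day_profiles()]); the demo settings shrink the number of acini per day
#' and the realized alveolar counts so a full run fits on a desk machine,
#' without touching any estimator (all are scale-free and count-exact).
#'
#' @param out_dir output directory.
#' @param seed master seed; every stage derives its seeds from it.
#' @param n_acini_per_day number of phantoms per day (overrides the
#'   profiles' cohort sizes), or `NULL` for the full profile sizes.
#' @param alveoli_scale divisor applied to profile mean alveolar counts
#'   when realizing phantoms (see [synthesize_cohort()]).
#' @param slice_interval SURS section period for the Cavalieri estimate.
#' @param grid_spacing_vox point-grid constant in voxels.
#' @param subsample_denominator systematic acinus subsampling fraction
#'   denominator (1 = assess all).
#' @param noise_sd rendering noise SD (gray levels).
#' @param shrinkage list with `v_displacement`, `v_cavalieri` per-animal
#'   lobe volumes (equal by default: factor 1).
#' @param voxel_size_um nominal voxel size recorded in provenance.
#' @param make_figures write box-plot figures (needs ggplot2).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(out_dir = tempfile("acinostereo_run_"),
                            seed = 1,
                            n_acini_per_day = 6L,
                            alveoli_scale = 10,
                            slice_interval = 4L,
                            grid_spacing_vox = 4L,
                            subsample_denominator = 1L,
                            noise_sd = 0,
                            shrinkage = list(v_displacement = 1,
                                             v_cavalieri = 1),
                            voxel_size_um = 1.48,
                            make_figures = FALSE) {
  cfg <- list(out_dir = out_dir, seed = as.integer(seed),
              profiles = day_profiles(),
              n_acini_per_day = n_acini_per_day,
              alveoli_scale = alveoli_scale,
              slice_interval = as.integer(slice_interval),
              grid_spacing_vox = as.integer(grid_spacing_vox),
              subsample_denominator = as.integer(subsample_denominator),
              noise_sd = noise_sd,
              shrinkage = shrinkage,
              ductal_fractions = ductal_fractions(),
              voxel_size_um = voxel_size_um,
              make_figures = isTRUE(make_figures))
  class(cfg) <- "pipeline_config"
  validate_config(cfg)
  cfg
}

#' Read a pipeline configuration from YAML
#' @param path YAML file with any subset of [pipeline_config()] arguments.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(pipeline_config, raw)
}

validate_config <- function(cfg) {
  num_pos <- c("voxel_size_um", "slice_interval", "grid_spacing_vox",
               "subsample_denominator", "alveoli_scale")
  for (f in num_pos) {
    v <- cfg[[f]]
    if (is.null(v) || !is.numeric(v) || length(v) != 1L || v <= 0)
      stop(sprintf("config: `%s` must be a single positive number", f))
  }
  if (cfg$noise_sd < 0) stop("config: `noise_sd` must be >= 0")
  if (is.null(cfg$profiles) || !length(cfg$profiles))
    stop("config: no cohort profiles")
  invisible(cfg)
}

#' Assess one phantom acinus: segment, Cavalieri volume, disector count
#'
#' The per-acinus estimation chain on a rendered phantom: Otsu threshold,
#' entrance stopper, automatic seed just distal of the stopper, bounded
#' region growing, Cavalieri volume on a SURS section set, exhaustive-pair
#' disector count on the label volume, and shrinkage correction.
#'
#' @param phantom an `acinus_phantom`.
#' @param slice_interval,grid_spacing_vox Cavalieri design parameters.
#' @param noise_sd rendering noise.
#' @param shrink a `shrinkage_factor` or bare factor (default 1).
#' @param seed integer seed for the SURS offset and grid origin.
#' @return List: `volume_mm3` (corrected Cavalieri), `ce`, `n_alveoli`,
#'   `q_appear`, `q_disappear`, `voxel_count`, `true_volume_mm3`,
#'   `true_n_alveoli`.
#' @export
assess_phantom <- function(phantom, slice_interval = 4L,
                           grid_spacing_vox = 4L, noise_sd = 0,
                           shrink = 1, seed = 1) {
  stopifnot(inherits(phantom, "acinus_phantom"))
  vs <- phantom$voxel_size_um
  gray <- render_grayscale(phantom, noise_sd = noise_sd, seed = seed)
  th <- suggest_threshold(gray)
  # plug sits proximal of the entrance plane (distal face on the plane),
  # so it blocks the conducting stub without eating acinar air
  stopper <- segmentation_stopper(
    center = phantom$entrance$point -
      phantom$entrance$normal * (3 / 2 + 0.5),
    normal = phantom$entrance$normal,
    radius_um = 1.6 * phantom$entrance$radius_um,
    thickness_vox = 3L)
  seedpt <- seed_from_stopper(stopper)
  seg <- region_grow(gray, seedpt, th, list(stopper))
  nz <- dim(phantom$labels)[1L]
  sl <- surs_slices(nz, slice_interval, seed = seed)
  grid <- point_grid(grid_spacing_vox * vs, seed = seed + 1L)
  cav <- cavalieri_volume(seg$mask, sl, grid, vs)
  dis <- disector_count(phantom$labels)
  list(volume_mm3 = apply_correction(cav$volume_mm3, shrink),
       ce = cav$ce,
       n_alveoli = dis$n_estimate,
       q_appear = dis$q_appear, q_disappear = dis$q_disappear,
       voxel_count = seg$voxel_count,
       true_volume_mm3 = phantom$truth$acinar_volume_mm3,
       true_n_alveoli = phantom$truth$n_alveoli)
}

#' Run the full phantom pipeline
#'
#' End-to-end composition: per day, synthesize a phantom cohort, subsample
#' acini systematically, assess each sampled acinus ([assess_phantom()]),
#' then aggregate into per-animal tables, day summaries, and rank-based
#' group comparisons. Every output directory carries a provenance manifest
#' (configuration, seeds, package version); a rerun with the same
#' configuration reproduces the records CSV bit for bit.
#'
#' @param config a [pipeline_config()].
#' @return Invisibly, a list with `records`, `tables` (per quantity),
#'   `day_aggregates`, `comparisons`, and `out_dir`.
#' @export
run_pipeline <- function(config) {
  validate_config(config)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  shrink <- shrinkage_factor(config$shrinkage$v_displacement,
                             config$shrinkage$v_cavalieri)
  rows <- list()
  for (pr in config$profiles) {
    day <- pr$day
    if (!is.null(config$n_acini_per_day))
      pr <- cohort_profile(day, pr$mean_volume_mm3, pr$cv_volume,
                           pr$mean_alveoli, config$n_acini_per_day,
                           pr$skew_direction)
    day_seed <- config$seed * 10L + match(day, c(4, 10, 21, 60), nomatch = 9L)
    cohort <- tryCatch(
      synthesize_cohort(pr, seed = day_seed,
                        alveoli_scale = config$alveoli_scale),
      error = function(e) stop(sprintf("stage phantom, day %s: %s",
                                       day, conditionMessage(e))))
    picked <- subsample_acini(seq_along(cohort),
                              config$subsample_denominator,
                              seed = day_seed + 1L)
    for (i in picked) {
      a <- tryCatch(
        assess_phantom(cohort[[i]], config$slice_interval,
                       config$grid_spacing_vox, config$noise_sd,
                       shrink = shrink, seed = day_seed + i),
        error = function(e) stop(sprintf("stage assess, day %s acinus %d: %s",
                                         day, i, conditionMessage(e))))
      rows[[length(rows) + 1L]] <- data.frame(
        animal_id = sprintf("%02dS", day), day = day, acinus_id = i,
        volume_mm3 = a$volume_mm3, n_alveoli = a$n_alveoli, ce = a$ce,
        true_volume_mm3 = a$true_volume_mm3,
        true_n_alveoli = a$true_n_alveoli)
    }
  }
  raw <- do.call(rbind, rows)
  rec <- acinus_records(raw$animal_id, raw$day, raw$acinus_id,
                        raw$volume_mm3, raw$n_alveoli)
  rec$ce <- raw$ce
  rec$true_volume_mm3 <- raw$true_volume_mm3
  rec$true_n_alveoli <- raw$true_n_alveoli
  utils::write.csv(rec, file.path(config$out_dir, "records.csv"),
                   row.names = FALSE)

  tables <- lapply(
    stats::setNames(nm = c("n_alveoli", "volume_mm3", "density_per_mm3")),
    function(q) summarize_by_animal(rec, q))
  for (q in names(tables))
    write_counting_table(tables[[q]],
                         file.path(config$out_dir,
                                   sprintf("summary_%s.csv", q)))
  days <- sort(unique(rec$day))
  aggr <- data.frame(
    day = days,
    n_acini = vapply(days, function(d) sum(rec$day == d), 1L),
    mean_volume_mm3 = vapply(days, function(d)
      day_weighted_mean(tables$volume_mm3, d), 1),
    mean_alveoli = vapply(days, function(d)
      day_weighted_mean(tables$n_alveoli, d), 1),
    cv_volume = vapply(days, function(d) cv_of_day(rec, d), 1))
  utils::write.csv(aggr, file.path(config$out_dir, "day_aggregates.csv"),
                   row.names = FALSE)

  groups <- lapply(stats::setNames(nm = days), function(d)
    rec$volume_mm3[rec$day == d])
  comparisons <- list(volume_mm3 = comparison_report(groups, "volume_mm3"))
  jsonlite::write_json(
    list(quantity = "volume_mm3",
         pairwise_p = comparisons$volume_mm3$pairwise_p,
         sidak_alpha = comparisons$volume_mm3$sidak_alpha,
         omnibus_p = comparisons$volume_mm3$omnibus_p),
    file.path(config$out_dir, "comparison_volume.json"),
    auto_unbox = TRUE, digits = NA, matrix = "rowmajor")

  if (config$make_figures && requireNamespace("ggplot2", quietly = TRUE))
    write_boxplots(rec, config$out_dir)

  manifest <- list(
    package = "acinostereo",
    version = as.character(utils::packageVersion("acinostereo")),
    seed = config$seed,
    config = config[setdiff(names(config), "profiles")],
    profiles = lapply(config$profiles, unclass),
    config_hash = config_hash(config))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)

  invisible(list(records = rec, tables = tables, day_aggregates = aggr,
                 comparisons = comparisons, out_dir = config$out_dir))
}

config_hash <- function(config) {
  s <- deparse(config[sort(names(unclass(config)))])
  sprintf("%08x", sum(utf8ToInt(paste(s, collapse = "\n")) *
                        (seq_along(utf8ToInt(paste(s, collapse = "\n"))) %% 97L)) %% 4294967291)
}

write_boxplots <- function(rec, out_dir) {
  for (q in c("volume_mm3", "n_alveoli", "density_per_mm3")) {
    df <- data.frame(day = factor(rec$day), y = rec[[q]])
    p <- ggplot2::ggplot(df, ggplot2::aes(x = day, y = y)) +
      ggplot2::geom_boxplot(outlier.shape = 1) +
      ggplot2::geom_jitter(width = 0.15, alpha = 0.35) +
      ggplot2::scale_y_log10() +
      ggplot2::labs(x = "postnatal day", y = q)
    ggplot2::ggsave(file.path(out_dir, sprintf("boxplot_%s.png", q)),
                    p, width = 5, height = 4, dpi = 120)
  }
}

#' Recompute the cohort's published day-level aggregates
#'
#' Recomputes, from the packaged per-animal tables and reference series,
#' the twelve acini-weighted day means (alveolar counts, acinar volumes,
#' alveolar densities), the sphere-equivalent alveolar diameters, the
#' Sidak threshold, the two cross-study linear scale factors, and the
#' day-60 size-quintile ratio, then checks each against the packaged
#' expected-values file at its display rounding. Any mismatch is an error
#' listing the failures.
#'
#' @param check error on mismatch (default TRUE).
#' @return List of recomputed aggregates (unrounded), invisibly a report
#'   attribute `checked`.
#' @export
reproduce_tables <- function(check = TRUE) {
  tabs <- list(counts = packaged_table("counts"),
               volume_mm3 = packaged_table("volume_mm3"),
               density_per_mm3 = packaged_table("density_per_mm3"))
  days <- c(4, 10, 21, 60)
  wm <- lapply(tabs, function(tb)
    stats::setNames(vapply(days, function(d) day_weighted_mean(tb, d), 1),
                    days))
  fr <- ductal_fractions()
  alv <- lapply(as.character(days), function(d) {
    alveolar_volume_and_diameter(wm$volume_mm3[[d]], wm$counts[[d]],
                                 ductal_fraction = fr[[d]])
  })
  names(alv) <- days
  ref <- cross_study_reference()
  out <- list(
    day_means = wm,
    alveolar_volume_um3 = vapply(alv, `[[`, 1, "volume_um3"),
    alveolar_diameter_um = vapply(alv, `[[`, 1, "diameter_um"),
    sidak_threshold = sidak_threshold(0.01, 6),
    scale_factor_totals = linear_scale_factor(
      ref$total_alveoli_millions_histology,
      ref$total_alveoli_millions_tomography, "ratio_of_sums"),
    scale_factor_alveolar_volume = linear_scale_factor(
      ref$alveolar_volume_1e5um3_tomography,
      ref$alveolar_volume_1e5um3_histology, "mean_of_ratios"),
    quintile_ratio_day60 = ref$quintile_high_ul[ref$day == 60] /
      ref$quintile_low_ul[ref$day == 60])
  if (check) {
    exp <- jsonlite::read_json(
      system.file("extdata", "expected_day_aggregates.json",
                  package = "acinostereo", mustWork = TRUE),
      simplifyVector = TRUE)
    fails <- character(0)
    chk <- function(name, got, want, digits) {
      if (round(got, digits) != round(want, digits))
        fails <<- c(fails, sprintf("%s: got %.6g, expected %.6g",
                                   name, got, want))
    }
    for (d in as.character(days)) {
      chk(paste0("counts_day", d), wm$counts[[d]], exp$counts[[d]], 0)
      chk(paste0("volume_day", d), wm$volume_mm3[[d]],
          exp$volume_mm3[[d]], 2)
      chk(paste0("density_day", d), wm$density_per_mm3[[d]],
          exp$density_per_mm3[[d]], 0)
      chk(paste0("diameter_day", d), out$alveolar_diameter_um[[d]],
          exp$alveolar_diameter_um[[d]], 0)
    }
    chk("sidak", out$sidak_threshold, exp$sidak_threshold, 5)
    chk("scale_totals", out$scale_factor_totals,
        exp$scale_factor_totals, 2)
    chk("scale_alveolar_volume", out$scale_factor_alveolar_volume,
        exp$scale_factor_alveolar_volume, 2)
    chk("quintile_day60", out$quintile_ratio_day60,
        exp$quintile_ratio_day60, 2)
    if (length(fails))
      stop(paste(c("aggregate reproduction failed:", fails),
                 collapse = "\n  "))
  }
  out
}
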