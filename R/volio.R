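#' Write a voxel stack as a multi-page TIFF with a JSON sidecar
#'
#' Gray values are stored as 16-bit samples; integer values in
#' `[0, 65535]` round-trip exactly. The voxel size (mandatory metadata) is
#' written to a `<path>.json` sidecar, because baseline TIFF carries no
#' physical pixel size.
#'
#' @param stack a [voxel_stack()].
#' @param path output file path (`.tif`).
#' @param bits 8 or 16 bits per sample.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path, bits = 16L) {
  stopifnot(inherits(stack, "voxel_stack"), bits %in% c(8L, 16L))
  maxv <- 2^bits - 1
  dat <- stack$data
  if (min(dat) < 0 || max(dat) > maxv)
    stop(sprintf("gray values must lie in [0, %d] for %d-bit output",
                 maxv, bits))
  pages <- lapply(seq_len(dim(dat)[1L]), function(i) dat[i, , ] / maxv)
  tiff::writeTIFF(pages, path, bits.per.sample = bits)
  jsonlite::write_json(list(voxel_size_um = stack$voxel_size_um,
                            bits = bits),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a voxel stack from a multi-page TIFF
#'
#' Slices are returned in ascending page order. The voxel size must come
#' from the JSON sidecar written by [write_stack()] or be given explicitly;
#' a missing voxel size is a hard error — it is never silently assumed.
#'
#' @param path path to a multi-page TIFF.
#' @param voxel_size_um explicit voxel size, overriding/replacing the sidecar.
#' @return A [voxel_stack()].
#' @export
read_stack <- function(path, voxel_size_um = NULL) {
  if (!file.exists(path)) stop(sprintf("stack file not found: %s", path))
  sidecar <- paste0(path, ".json")
  bits <- 16L
  if (is.null(voxel_size_um)) {
    if (!file.exists(sidecar))
      stop(sprintf(
        "no voxel size: sidecar %s missing and `voxel_size_um` not given",
        sidecar))
    meta <- jsonlite::read_json(sidecar)
    voxel_size_um <- meta$voxel_size_um
    if (!is.null(meta$bits)) bits <- as.integer(meta$bits)
  } else if (file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar)
    if (!is.null(meta$bits)) bits <- as.integer(meta$bits)
  }
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  maxv <- 2^bits - 1
  d2 <- dim(pages[[1L]])
  dat <- array(0, dim = c(length(pages), d2))
  for (i in seq_along(pages)) dat[i, , ] <- round(pages[[i]] * maxv)
  voxel_stack(dat, voxel_size_um)
}

#' Write a segmentation overlay stack
#'
#' Persists the original grayscale with masked voxels brightened towards
#' white, the way an extracted acinus is exported overlaid on its original
#' background. The mask itself is stored losslessly in a paired
#' `<path>_mask.tif` so it can be recovered exactly.
#'
#' @param gray a [voxel_stack()].
#' @param mask logical array, same dimensions as `gray$data`.
#' @param path output TIFF path.
#' @param gain brightening weight in (0, 1]; masked voxels become
#'   `(1-gain)*gray + gain*white`.
#' @return `path`, invisibly.
#' @export
write_overlay <- function(gray, mask, path, gain = 0.4) {
  stopifnot(inherits(gray, "voxel_stack"))
  if (!identical(dim(gray$data), dim(mask)))
    stop(sprintf("shape mismatch: gray %s vs mask %s",
                 paste(dim(gray$data), collapse = "x"),
                 paste(dim(mask), collapse = "x")))
  white <- 65535
  out <- gray$data
  out[mask] <- round((1 - gain) * out[mask] + gain * white)
  write_stack(voxel_stack(out, gray$voxel_size_um), path)
  mstack <- voxel_stack(array(as.integer(mask) * 65535L, dim = dim(mask)),
                        gray$voxel_size_um)
  write_stack(mstack, overlay_mask_path(path))
  invisible(path)
}

overlay_mask_path <- function(path)
  sub("(\\.[^.]+)?$", "_mask.tif", path)

#' Read back the mask paired with an overlay stack
#' @param path the path given to [write_overlay()].
#' @return Logical array.
#' @export
read_overlay_mask <- function(path) {
  m <- read_stack(overlay_mask_path(path))
  m$data > 32767
}

#' Export a systematic set of slices as 2D images
#'
#' Writes one PNG per sampled slice, named by slice index, optionally with a
#' 100 um scale bar burnt into the lower-left corner (bar length
#' `round(100 / voxel_size_um)` pixels).
#'
#' @param stack a [voxel_stack()].
#' @param sample a [surs_slices()] design (or any list with `$indices`).
#' @param path output directory (created if needed).
#' @param burn_scalebar logical.
#' @param bar_um scale bar length in um.
#' @return Character vector of files written (empty for an empty sample).
#' @export
export_slice_set <- function(stack, sample, path, burn_scalebar = FALSE,
                             bar_um = 100) {
  stopifnot(inherits(stack, "voxel_stack"))
  idx <- sample$indices
  if (!length(idx)) return(character(0))
  nz <- dim(stack$data)[1L]
  if (any(idx < 1L) || any(idx > nz))
    stop(sprintf("slice index out of range [1, %d]", nz))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  maxv <- max(stack$data, 1)
  files <- character(length(idx))
  for (j in seq_along(idx)) {
    sl <- stack$data[idx[j], , ] / maxv
    if (burn_scalebar) {
      bar_px <- round(bar_um / stack$voxel_size_um)
      nr <- nrow(sl); nc <- ncol(sl)
      bar_px <- min(bar_px, nc - 4L)
      rows <- max(1L, nr - 6L):max(1L, nr - 4L)
      sl[rows, 3:(2L + bar_px)] <- 1
    }
    f <- file.path(path, sprintf("slice_%04d.png", idx[j]))
    png::writePNG(sl, f)
    files[j] <- f
  }
  files
}

#' Length of the burnt-in scale bar in pixels
#' @param bar_um bar length in um.
#' @param voxel_size_um voxel edge length in um.
#' @return Integer pixel count.
#' @export
scalebar_px <- function(bar_um, voxel_size_um) round(bar_um / voxel_size_um)

counting_table_cols <- c("animal_id", "day", "assessed_acini", "average",
                         "sd", "minimum", "maximum")

#' Read a per-animal counting table
#'
#' Counting tables hold one row per animal for one quantity (alveolar
#' counts, acinar volume in mm^3, or alveolar density per mm^3): number of
#' assessed acini, mean, SD, minimum, maximum. The packaged fixtures
#' reproduce the developmental cohort's published per-animal tables
#' verbatim; see [packaged_table()].
#'
#' @param path CSV file with columns `animal_id, day, assessed_acini,
#'   average, sd, minimum, maximum`.
#' @param quantity optional quantity label attached as an attribute.
#' @return A `counting_table` data frame.
#' @export
read_counting_table <- function(path, quantity = NULL) {
  if (!file.exists(path)) stop(sprintf("counting table not found: %s", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(counting_table_cols %in% names(df)))
    stop(sprintf("counting table must have columns: %s",
                 paste(counting_table_cols, collapse = ", ")))
  validate_counting_table(df)
  structure(df, class = c("counting_table", "data.frame"),
            quantity = quantity)
}

validate_counting_table <- function(df) {
  for (i in seq_len(nrow(df))) {
    r <- df[i, ]
    if (r$assessed_acini < 1 || r$sd < 0 ||
        r$minimum > r$average || r$average > r$maximum)
      stop(sprintf(
        "invalid counting-table row '%s': need n >= 1, sd >= 0, min <= mean <= max",
        r$animal_id))
  }
  invisible(df)
}

#' Write a counting table to CSV (lossless round trip)
#' @param table a `counting_table` or compatible data frame.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_counting_table <- function(table, path) {
  validate_counting_table(table)
  utils::write.csv(table[, counting_table_cols], path, row.names = FALSE)
  invisible(path)
}

#' Packaged per-animal tables of the developmental cohort
#'
#' Per-animal summaries for the three assessed quantities over postnatal
#' days 4/10/21/60 (12 animals, 268 acini): alveolar entrance-ring counts,
#' Cavalieri acinar volumes (mm^3), and alveolar densities (mm^-3).
#'
#' @param which `"counts"`, `"volume_mm3"`, or `"density_per_mm3"`.
#' @return A `counting_table` data frame.
#' @export
packaged_table <- function(which = c("counts", "volume_mm3",
                                     "density_per_mm3")) {
  which <- match.arg(which)
  f <- c(counts = "table1_counts.csv",
         volume_mm3 = "table2_volume_mm3.csv",
         density_per_mm3 = "table3_density_per_mm3.csv")[[which]]
  read_counting_table(
    system.file("extdata", f, package = "acinostereo", mustWork = TRUE),
    quantity = which)
}
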