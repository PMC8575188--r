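#' Define a disk-shaped segmentation stopper
#'
#' A stopper is a solid oriented disk (a short cylinder) placed in the
#' airway lumen at an acinar entrance so that region growing cannot escape
#' into the conducting airways. Thickness is at least 2 voxels so the plug
#' is airtight under 6-connectivity (no diagonal leaks).
#'
#' @param center voxel triple `(z, y, x)` (1-based, may be fractional).
#' @param normal direction vector `(dz, dy, dx)` (normalized internally).
#' @param radius_um disk radius in um; must cover the airway cross-section.
#' @param thickness_vox cylinder thickness along the normal, >= 2 voxels.
#' @return A `segmentation_stopper` list.
#' @export
segmentation_stopper <- function(center, normal, radius_um,
                                 thickness_vox = 3L) {
  stopifnot(length(center) == 3L, length(normal) == 3L, radius_um > 0)
  thickness_vox <- as.integer(thickness_vox)
  if (thickness_vox < 2L) stop("stopper thickness must be >= 2 voxels")
  n <- as.numeric(normal)
  nn <- sqrt(sum(n^2))
  if (nn == 0) stop("stopper normal must be nonzero")
  structure(list(center = as.numeric(center), normal = n / nn,
                 radius_um = radius_um, thickness_vox = thickness_vox),
            class = "segmentation_stopper")
}

#' Rasterize a stopper into a binary plug volume
#'
#' Voxels whose centre lies within `thickness_vox / 2` of the disk plane
#' (along the normal) and within the disk radius (perpendicular) are set.
#' Stoppers extending past the stack boundary are clipped silently.
#'
#' @param stopper a [segmentation_stopper()].
#' @param shape stack dimensions `(nz, ny, nx)`.
#' @param voxel_size_um voxel edge length.
#' @return Logical array of dimension `shape`.
#' @export
rasterize_stopper <- function(stopper, shape, voxel_size_um) {
  stopifnot(inherits(stopper, "segmentation_stopper"), voxel_size_um > 0)
  c0 <- stopper$center
  if (any(c0 < 1) || any(c0 > shape))
    stop("stopper centre lies outside the stack")
  r_vox <- stopper$radius_um / voxel_size_um
  half_t <- stopper$thickness_vox / 2
  reach <- sqrt(r_vox^2 + half_t^2) + 1
  lo <- pmax(1L, floor(c0 - reach))
  hi <- pmin(shape, ceiling(c0 + reach))
  z <- seq.int(lo[1L], hi[1L]); y <- seq.int(lo[2L], hi[2L])
  x <- seq.int(lo[3L], hi[3L])
  g <- as.matrix(expand.grid(z = z, y = y, x = x, KEEP.OUT.ATTRS = FALSE))
  rel <- sweep(g, 2L, c0)
  along <- as.vector(rel %*% stopper$normal)
  perp2 <- rowSums(rel^2) - along^2
  # half-open slab (-t/2, t/2] so an integer thickness covers exactly
  # `thickness_vox` sections when the centre sits on a section
  keep <- along > -half_t & along <= half_t & perp2 <= r_vox^2
  out <- array(FALSE, dim = shape)
  if (any(keep)) out[vox_index(g[keep, , drop = FALSE], shape)] <- TRUE
  out
}

#' Suggest a gray threshold separating air from tissue
#'
#' Otsu's bimodal-separation threshold on the whole stack. A configured
#' override (for per-acinus operator choices) is returned verbatim.
#'
#' @param gray a [voxel_stack()] or numeric array with >= 2 distinct values.
#' @param override optional fixed threshold returned as-is.
#' @return Gray value strictly between the stack minimum and maximum.
#' @export
suggest_threshold <- function(gray, override = NULL) {
  if (!is.null(override)) return(override)
  dat <- if (inherits(gray, "voxel_stack")) gray$data else gray
  rng <- range(dat)
  if (rng[1L] == rng[2L])
    stop("cannot threshold a constant stack")
  x <- (dat - rng[1L]) / (rng[2L] - rng[1L])
  th <- EBImage::otsu(array(x, dim = c(length(x), 1L)), range = c(0, 1))
  rng[1L] + th * (rng[2L] - rng[1L])
}

#' Threshold region growing bounded by segmentation stoppers
#'
#' Computes the 6-connected component of `{gray <= threshold}` (air), minus
#' all rasterized stopper voxels, that contains the seed point. This is the
#' acinus-extraction primitive: the seed sits just distal of the entrance
#' stopper and growth floods the acinar air space without crossing the plug.
#' Deterministic, and idempotent in the sense that growing again from any
#' voxel of the result reproduces the same mask.
#'
#' If the grown mask touches the stack boundary, a warning is issued: on an
#' extracted-acinus stack that usually means an undersized stopper let the
#' growth leak into conducting airways.
#'
#' @param gray a [voxel_stack()].
#' @param seed_point voxel triple `(z, y, x)`; must satisfy
#'   `gray[seed] <= threshold` and lie outside every stopper.
#' @param threshold gray value; air is `<= threshold`.
#' @param stoppers list of [segmentation_stopper()] (possibly empty).
#' @return A `segmentation_result`: `mask`, `seed_point`, `threshold`,
#'   `stoppers`, `voxel_count`, `volume_mm3`, `touches_boundary`.
#' @export
region_grow <- function(gray, seed_point, threshold, stoppers = list()) {
  stopifnot(inherits(gray, "voxel_stack"), length(seed_point) == 3L)
  d <- dim(gray$data)
  seed_point <- as.integer(round(seed_point))
  if (any(seed_point < 1L) || any(seed_point > d))
    stop("seed point outside the stack")
  if (gray$data[seed_point[1L], seed_point[2L], seed_point[3L]] > threshold)
    stop("seed lies in tissue (gray value above threshold)")
  block <- array(FALSE, dim = d)
  for (st in stoppers)
    block <- block | rasterize_stopper(st, d, gray$voxel_size_um)
  if (block[seed_point[1L], seed_point[2L], seed_point[3L]])
    stop("seed lies inside a segmentation stopper")
  air <- (gray$data <= threshold) & !block
  mask <- flood_fill6(air, vox_index(seed_point, d))
  nvox <- sum(mask)
  touches <- any(mask[1L, , ]) || any(mask[d[1L], , ]) ||
    any(mask[, 1L, ]) || any(mask[, d[2L], ]) ||
    any(mask[, , 1L]) || any(mask[, , d[3L]])
  if (touches && length(stoppers))
    warning("segmentation touches the stack boundary: possible stopper leak")
  structure(list(mask = mask, seed_point = seed_point,
                 threshold = threshold, stoppers = stoppers,
                 voxel_count = nvox,
                 volume_mm3 = nvox * voxel_volume_mm3(gray$voxel_size_um),
                 touches_boundary = touches),
            class = "segmentation_result")
}

#' Place a seed point one stopper-thickness distal of a stopper
#'
#' Automatic seeding helper: steps from the stopper centre along its normal
#' by `stopper$thickness_vox` voxels (the distal direction is the normal's
#' positive sense), landing in the airway lumen just past the plug.
#'
#' @param stopper a [segmentation_stopper()].
#' @return Integer voxel triple.
#' @export
seed_from_stopper <- function(stopper) {
  as.integer(round(stopper$center + stopper$normal * stopper$thickness_vox))
}

#' Export an extracted acinus as an overlay stack with provenance
#'
#' Writes the segmented acinus overlaid on its original background via
#' [write_overlay()], plus a JSON manifest recording exactly the inputs
#' used (seed point, threshold, stoppers) and the resulting voxel count.
#' [verify_acinus_export()] re-reads the overlay and fails if the stored
#' mask disagrees with the manifest (tamper check).
#'
#' @param gray a [voxel_stack()].
#' @param result a `segmentation_result` from [region_grow()].
#' @param path output TIFF path.
#' @return `path`, invisibly.
#' @export
extract_acinus <- function(gray, result, path) {
  stopifnot(inherits(result, "segmentation_result"))
  write_overlay(gray, result$mask, path)
  manifest <- list(
    seed_point = result$seed_point,
    threshold = result$threshold,
    stoppers = lapply(result$stoppers, function(s)
      list(center = s$center, normal = s$normal,
           radius_um = s$radius_um, thickness_vox = s$thickness_vox)),
    voxel_count = result$voxel_count,
    voxel_size_um = gray$voxel_size_um)
  jsonlite::write_json(manifest, acinus_manifest_path(path),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

acinus_manifest_path <- function(path)
  sub("(\\.[^.]+)?$", "_manifest.json", path)

#' Validate an exported acinus against its manifest
#' @param path the path given to [extract_acinus()].
#' @return The manifest list, invisibly, or an error if the recovered mask
#'   contradicts the manifest's voxel count.
#' @export
verify_acinus_export <- function(path) {
  manifest <- jsonlite::read_json(acinus_manifest_path(path),
                                  simplifyVector = TRUE,
                                  simplifyDataFrame = FALSE)
  mask <- read_overlay_mask(path)
  if (sum(mask) != manifest$voxel_count)
    stop(sprintf(
      "manifest validation failed: stored mask has %d voxels, manifest says %d",
      sum(mask), manifest$voxel_count))
  invisible(manifest)
}

#' Read a stopper list from JSON or YAML
#'
#' Expected shape: a list of `{center: [z,y,x], normal: [dz,dy,dx],
#' radius_um, thickness_vox}` entries.
#'
#' @param path `.json`, `.yml` or `.yaml` file.
#' @return List of [segmentation_stopper()] objects.
#' @export
read_stoppers <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
  else jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  lapply(raw, function(s)
    segmentation_stopper(unlist(s$center), unlist(s$normal),
                         s$radius_um,
                         if (is.null(s$thickness_vox)) 3L else s$thickness_vox))
}
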