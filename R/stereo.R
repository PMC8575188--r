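#' Systematic uniform random slice design
#'
#' Samples every `interval`-th section of a stack starting at a uniformly
#' random offset (SURS): offsets are drawn from `{1, ..., interval}` and the
#' sampled indices are `seq(offset, depth, by = interval)`. Averaging an
#' estimator over all offsets therefore covers every section exactly once,
#' which is what makes SURS-based estimators unbiased.
#'
#' @param depth total number of sections (>= 1).
#' @param interval sampling period, `1 <= interval <= depth`.
#' @param seed integer seed used to draw the offset.
#' @param offset optional forced offset in `{1, ..., interval}` (bypasses
#'   randomization; used for exhaustive-design verification).
#' @return A `slice_sample`: list with `depth`, `interval`, `offset`,
#'   `indices` (strictly increasing).
#' @export
surs_slices <- function(depth, interval, seed = 1, offset = NULL) {
  depth <- as.integer(depth); interval <- as.integer(interval)
  if (interval < 1L || interval > depth)
    stop(sprintf("interval must lie in [1, depth]; got %d for depth %d",
                 interval, depth))
  if (is.null(offset)) {
    set.seed(as.integer(seed))
    offset <- sample.int(interval, 1L)
  }
  offset <- as.integer(offset)
  stopifnot(offset >= 1L, offset <= interval)
  structure(list(depth = depth, interval = interval, offset = offset,
                 indices = seq.int(offset, depth, by = interval)),
            class = "slice_sample")
}

#' Systematic subsampling of an ordered list of acini
#'
#' Selects a defined fraction (one in `fraction_denominator`) of the acini:
#' every `fraction_denominator`-th id, starting at a uniformly random
#' position among the first `fraction_denominator`. With denominator 3 this
#' is "every third acinus, randomly starting with the first, second, or
#' third one". Over all starts the selections partition the list.
#'
#' @param acinus_ids ordered vector of ids (may be empty).
#' @param fraction_denominator integer >= 1.
#' @param seed integer seed.
#' @param start optional forced start in `{1, ..., fraction_denominator}`.
#' @return Subvector of `acinus_ids` (empty input gives empty output).
#' @export
subsample_acini <- function(acinus_ids, fraction_denominator = 3, seed = 1,
                            start = NULL) {
  k <- as.integer(fraction_denominator)
  if (k < 1L) stop("fraction_denominator must be >= 1")
  if (!length(acinus_ids)) return(acinus_ids[0])
  if (is.null(start)) {
    set.seed(as.integer(seed))
    start <- sample.int(k, 1L)
  }
  stopifnot(start >= 1L, start <= k)
  acinus_ids[seq.int(start, length(acinus_ids), by = k)]
}

#' Construct a counting point grid
#'
#' A square lattice of test points with spacing `spacing_um`, so each point
#' carries an area `a_p = spacing_um^2`. The grid origin offset is in
#' `[0, spacing)^2` (um, `(y, x)` order); drawing it uniformly makes point
#' counting unbiased for any profile shape.
#'
#' @param spacing_um grid constant (> 0).
#' @param origin_offset_um numeric length-2 offset in `[0, spacing)^2`.
#' @param seed seed used to randomize the origin when `origin_offset_um`
#'   is `NULL`.
#' @return A `point_grid` list with `spacing_um`, `origin_offset_um`, `a_p`.
#' @export
point_grid <- function(spacing_um, origin_offset_um = NULL, seed = 1) {
  stopifnot(spacing_um > 0)
  if (is.null(origin_offset_um)) {
    set.seed(as.integer(seed))
    origin_offset_um <- stats::runif(2, 0, spacing_um)
  }
  stopifnot(length(origin_offset_um) == 2L,
            all(origin_offset_um >= 0), all(origin_offset_um < spacing_um))
  structure(list(spacing_um = spacing_um,
                 origin_offset_um = as.numeric(origin_offset_um),
                 a_p = spacing_um^2),
            class = "point_grid")
}

#' Count test points hitting a 2D profile
#'
#' Grid nodes sit at physical positions `origin + k * spacing` (um) in each
#' axis; a node scores when the voxel containing it is inside the mask
#' (voxel `i` covers `[(i-1), i) * voxel_size_um`).
#'
#' @param mask_slice 2D logical matrix (`(y, x)`).
#' @param grid a [point_grid()].
#' @param voxel_size_um voxel edge length of the slice.
#' @return Integer number of hits.
#' @export
count_points <- function(mask_slice, grid, voxel_size_um) {
  stopifnot(is.matrix(mask_slice), voxel_size_um > 0)
  if (grid$spacing_um < voxel_size_um)
    stop("grid spacing must be at least one voxel")
  ny <- nrow(mask_slice); nx <- ncol(mask_slice)
  # node positions in voxel units; half-open membership [0, n) with a
  # relative epsilon so conceptually exact designs stay exact
  sp <- grid$spacing_um / voxel_size_um
  o <- grid$origin_offset_um / voxel_size_um
  ks <- function(o1, n) {
    kmax <- ceiling((n - o1) / sp - 1e-9) - 1
    if (kmax < 0) numeric(0) else o1 + (0:kmax) * sp
  }
  ypos <- ks(o[1], ny); xpos <- ks(o[2], nx)
  if (!length(ypos) || !length(xpos)) return(0L)
  yi <- pmin(ny, floor(ypos + 1e-9) + 1L)
  xi <- pmin(nx, floor(xpos + 1e-9) + 1L)
  sum(mask_slice[yi, xi, drop = FALSE])
}

#' Cavalieri volume estimate from a systematic slice set
#'
#' The Cavalieri principle: `V = t * a_p * sum(P)`, with section separation
#' `t = interval * voxel_size_um` (um), area per point `a_p` (um^2), and
#' total point count over the sampled sections. The result is reported in
#' mm^3 (`1e-9` um^3 per mm^3). With at least three sections the
#' Gundersen-Jensen coefficient of error for smoothness class 0 is attached:
#' `CE = sqrt((3A - 4B + C) / 12) / sum(P)` with `A = sum(P_i^2)`,
#' `B = sum(P_i P_{i+1})`, `C = sum(P_i P_{i+2})`.
#'
#' @param mask 3D logical array, or a numeric vector of per-slice point
#'   counts already taken on the sampled sections.
#' @param sample a [surs_slices()] design.
#' @param grid a [point_grid()] (ignored when `mask` is a count vector,
#'   except for `a_p`).
#' @param voxel_size_um voxel edge length.
#' @return A `cavalieri_estimate`: `sum_points`, `a_p`, `t_um`,
#'   `volume_mm3`, `ce`, `point_counts`.
#' @export
cavalieri_volume <- function(mask, sample, grid, voxel_size_um) {
  stopifnot(inherits(sample, "slice_sample"), inherits(grid, "point_grid"),
            voxel_size_um > 0)
  if (!length(sample$indices)) stop("empty slice sample")
  if (is.array(mask) && length(dim(mask)) == 3L) {
    counts <- vapply(sample$indices, function(i)
      count_points(mask[i, , ], grid, voxel_size_um), integer(1))
  } else if (is.numeric(mask)) {
    if (length(mask) != length(sample$indices))
      stop("per-slice counts must match the number of sampled sections")
    counts <- as.numeric(mask)
  } else stop("`mask` must be a 3D array or a per-slice count vector")
  sp <- sum(counts)
  t_um <- sample$interval * voxel_size_um
  vol <- t_um * grid$a_p * sp * 1e-9
  ce <- NA_real_
  if (length(counts) >= 3L && sp > 0) {
    A <- sum(counts^2)
    B <- sum(counts[-length(counts)] * counts[-1L])
    C <- sum(counts[seq_len(length(counts) - 2L)] *
               counts[-(1:2)])
    ce <- sqrt(max(0, 3 * A - 4 * B + C) / 12) / sp
  }
  structure(list(sum_points = sp, a_p = grid$a_p, t_um = t_um,
                 volume_mm3 = vol, ce = ce, point_counts = counts),
            class = "cavalieri_estimate")
}

#' Physical-disector count of alveoli from entrance-ring events
#'
#' Scans pairs of consecutive sections and counts, per pair, the alveolar
#' profiles present in one section but not the other: `q_appear` (present
#' in the deeper section only) and `q_disappear` (present in the shallower
#' only). Because each alveolus spans one contiguous run of sections, it
#' contributes exactly one appearance and one disappearance over the whole
#' stack, so with exhaustive pairs the bidirectional estimate
#' `(q_appear + q_disappear) / 2` equals the true count exactly. When only
#' a fraction of pairs is examined (systematic pair sampling), the estimate
#' is scaled by `pairs_total / pairs_examined`.
#'
#' @param labels an `acinus_phantom`, a 3D integer label array (alveoli are
#'   labels >= 2), or a list of per-section label/event vectors.
#' @param pair_interval examine every `pair_interval`-th consecutive pair
#'   (1 = exhaustive, the default, spanning the whole volume).
#' @param seed seed for the random pair-sampling start.
#' @param start optional forced start in `{1, ..., pair_interval}`.
#' @return A `disector_result`: `q_appear`, `q_disappear`,
#'   `pairs_examined`, `pairs_total`, `n_estimate`.
#' @export
disector_count <- function(labels, pair_interval = 1L, seed = 1,
                           start = NULL) {
  if (inherits(labels, "acinus_phantom")) labels <- labels$labels
  if (is.array(labels) && length(dim(labels)) == 3L) {
    nz <- dim(labels)[1L]
    per_slice <- lapply(seq_len(nz), function(i) {
      u <- unique(as.vector(labels[i, , ]))
      u[u >= 2L]
    })
  } else if (is.list(labels)) {
    per_slice <- labels
  } else stop("`labels` must be a 3D label array, phantom, or per-slice list")
  nz <- length(per_slice)
  if (nz < 2L) stop("disector needs at least 2 sections")
  pairs_total <- nz - 1L
  pair_interval <- as.integer(pair_interval)
  stopifnot(pair_interval >= 1L)
  if (is.null(start)) {
    if (pair_interval > 1L) set.seed(as.integer(seed))
    start <- if (pair_interval > 1L) sample.int(pair_interval, 1L) else 1L
  }
  pair_ids <- seq.int(start, pairs_total, by = pair_interval)
  qa <- 0L; qd <- 0L
  for (i in pair_ids) {
    a <- per_slice[[i]]; b <- per_slice[[i + 1L]]
    qa <- qa + sum(!(b %in% a))
    qd <- qd + sum(!(a %in% b))
  }
  n_est <- (qa + qd) / 2 * pairs_total / length(pair_ids)
  structure(list(q_appear = qa, q_disappear = qd,
                 pairs_examined = length(pair_ids),
                 pairs_total = pairs_total, n_estimate = n_est),
            class = "disector_result")
}

#' Detect candidate alveolar-mouth openings on a 2D air profile
#'
#' Best-effort heuristic for grayscale stacks where no label volume exists:
#' an alveolar entrance ring crossing a section shows up as a narrow neck
#' connecting an alveolar profile to the duct profile. The neck count is
#' estimated as the increase in the number of connected components after a
#' morphological erosion that severs necks narrower than `2 * neck_radius`
#' pixels. Approximate by design (operator counting is the reference); not
#' used on the exact phantom-label path.
#'
#' @param mask_slice 2D logical air profile.
#' @param neck_radius erosion radius in pixels.
#' @return Integer number of detected openings (>= 0).
#' @export
detect_interruptions <- function(mask_slice, neck_radius = 2L) {
  stopifnot(is.matrix(mask_slice))
  m <- mask_slice * 1
  if (!any(m > 0)) return(0L)
  n0 <- max(EBImage::bwlabel(m))
  brush <- EBImage::makeBrush(2L * neck_radius + 1L, shape = "disc")
  er <- EBImage::erode(m, brush)
  n1 <- max(EBImage::bwlabel(er))
  max(0L, as.integer(n1 - n0))
}

#' Tissue shrinkage factor from paired lobe volumes
#'
#' The fresh lobe volume (fluid displacement) over the processed lobe
#' volume (Cavalieri on sections) gives a single multiplicative factor that
#' undoes processing shrinkage when applied to section-derived volumes.
#'
#' @param v_displacement fresh lobe volume (> 0).
#' @param v_cavalieri processed lobe volume (> 0), same units.
#' @return A `shrinkage_factor` list with both volumes and `factor`.
#' @export
shrinkage_factor <- function(v_displacement, v_cavalieri) {
  if (!is.finite(v_displacement) || v_displacement <= 0 ||
      !is.finite(v_cavalieri) || v_cavalieri <= 0)
    stop("both lobe volumes must be positive")
  structure(list(v_displacement = v_displacement,
                 v_cavalieri = v_cavalieri,
                 factor = v_displacement / v_cavalieri),
            class = "shrinkage_factor")
}

#' Apply (or invert) a shrinkage correction to a volume
#' @param volume volume(s) to correct.
#' @param factor a `shrinkage_factor` or a bare positive number.
#' @param invert undo a previously applied correction.
#' @return Corrected volume(s).
#' @export
apply_correction <- function(volume, factor, invert = FALSE) {
  f <- if (inherits(factor, "shrinkage_factor")) factor$factor else factor
  if (!is.finite(f) || f <= 0) stop("correction factor must be positive")
  if (invert) volume / f else volume * f
}
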