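#' Build a binary-branching duct tree scaffold
#'
#' Generates the geometric skeleton of an acinar airway tree: a connected,
#' acyclic binary tree of tapering cylindrical segments rooted at the acinar
#' entrance (the transition from conducting to gas-exchanging airways, where
#' segmentation stoppers are placed during extraction). Coordinates are in
#' micrometres, `(z, y, x)`, with the root pointing along +z.
#'
#' @param branching_depth integer >= 0; a tree of depth `d` has `2^d` tips
#'   and `2^(d+1) - 1` segments.
#' @param segment_length_um length of the root segment; daughter segments
#'   shrink by `length_taper` per generation.
#' @param radius_um radius of the root segment; daughters taper by
#'   `radius_taper` per generation.
#' @param seed integer; branching azimuths and angle jitter are drawn from
#'   this seed, so equal inputs give identical trees.
#' @param length_taper,radius_taper per-generation multiplicative taper.
#' @param branch_angle_deg mean polar angle between a daughter and its parent.
#' @param max_extent_um optional bound on the tree's spatial extent from the
#'   root; exceeding it is an error naming the offending segment.
#' @return A `duct_tree`: list with `nodes` (data frame `id`, `parent`,
#'   `z`, `y`, `x`, `radius_um`), `entrance` (point + unit normal of the
#'   entrance plane, intersecting the root segment), `depth`, `seed`.
#' @export
build_duct_tree <- function(branching_depth, segment_length_um = 60,
                            radius_um = 8, seed = 1,
                            length_taper = 0.85, radius_taper = 0.9,
                            branch_angle_deg = 38, max_extent_um = Inf) {
  stopifnot(branching_depth >= 0, segment_length_um > 0, radius_um > 0)
  set.seed(as.integer(seed))
  # node 1 is the root base (entrance); every other node ends one segment
  nodes <- data.frame(id = 1L, parent = NA_integer_,
                      z = 0, y = 0, x = 0, radius_um = radius_um)
  dirs <- list(c(1, 0, 0))  # (z,y,x) unit direction of segment ending at node
  tips <- 1L
  len <- segment_length_um
  rad <- radius_um
  next_id <- 2L
  for (gen in 0:branching_depth) {
    new_tips <- integer(0)
    nb <- if (gen == 0L) 1L else 2L  # root is a single segment
    for (tip in tips) {
      d0 <- dirs[[tip]]
      for (b in seq_len(nb)) {
        theta <- if (gen == 0L) 0 else
          (branch_angle_deg + stats::runif(1, -6, 6)) * pi / 180
        phi <- stats::runif(1, 0, 2 * pi) + (b - 1) * pi
        dirn <- rotate_about(d0, theta, phi)
        p0 <- as.numeric(nodes[tip, c("z", "y", "x")])
        p1 <- p0 + dirn * len
        if (max(abs(p1)) > max_extent_um)
          stop(sprintf("segment %d exceeds the allowed extent of %g um",
                       next_id, max_extent_um))
        nodes <- rbind(nodes, data.frame(id = next_id, parent = tip,
                                         z = p1[1], y = p1[2], x = p1[3],
                                         radius_um = rad))
        dirs[[next_id]] <- dirn
        new_tips <- c(new_tips, next_id)
        next_id <- next_id + 1L
      }
    }
    tips <- new_tips
    len <- len * length_taper
    rad <- rad * radius_taper
  }
  structure(list(nodes = nodes,
                 entrance = list(point = c(0, 0, 0), normal = c(1, 0, 0)),
                 depth = as.integer(branching_depth),
                 seed = as.integer(seed)),
            class = "duct_tree")
}

# unit vector at polar angle theta from axis d0, azimuth phi
rotate_about <- function(d0, theta, phi) {
  d0 <- d0 / sqrt(sum(d0^2))
  # orthonormal frame around d0
  helper <- if (abs(d0[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  u <- helper - sum(helper * d0) * d0
  u <- u / sqrt(sum(u^2))
  v <- c(d0[2] * u[3] - d0[3] * u[2],
         d0[3] * u[1] - d0[1] * u[3],
         d0[1] * u[2] - d0[2] * u[1])
  cos(theta) * d0 + sin(theta) * (cos(phi) * u + sin(phi) * v)
}

#' @export
print.duct_tree <- function(x, ...) {
  cat(sprintf("<duct_tree> depth %d, %d segments, %d tips\n",
              x$depth, nrow(x$nodes) - 1L, 2L^x$depth))
  invisible(x)
}

#' Number of tip segments of a duct tree
#' @param tree a `duct_tree`.
#' @return integer count of terminal segments.
#' @export
n_tips <- function(tree) sum(!(tree$nodes$id %in% tree$nodes$parent))

#' Synthesize an acinar phantom with exact voxel ground truth
#'
#' Rasterizes a duct tree into a label volume and attaches spherical alveoli
#' to the duct walls. Each alveolus opens into the duct lumen through a
#' single mouth (the only interruption of its wall), mirroring the counting
#' assumption that wall interruptions occur only at alveolar mouth openings.
#' The whole air space (lumen + alveoli) is a single 6-connected component:
#' one ventilatory unit. The returned manifest is exact by construction:
#' `true_volume_mm3` is the nonzero-label voxel count times the voxel
#' volume, and `n_alveoli` the number of distinct labels >= 2.
#'
#' Labels: 0 background/tissue, 1 duct lumen (including an optional proximal
#' trunk stub upstream of the entrance plane), k >= 2 one per alveolus.
#'
#' @param tree a `duct_tree` (coordinates in um).
#' @param n_alveoli number of alveoli to place (>= 0), exact in the output.
#' @param alveolus_radius_um alveolar radius in um.
#' @param voxel_size_um isotropic voxel edge length.
#' @param seed integer seed; placement is deterministic per seed.
#' @param trunk_length_um length of conducting-airway stub proximal of the
#'   entrance plane (0 = none); used to exercise segmentation stoppers.
#' @param margin_vox empty guard margin around the air space, >= 3 so that
#'   disector pairs exist on both sides of every alveolus.
#' @param max_attempts placement attempt budget; defaults to
#'   `100 * n_alveoli`. Exhausting it is an error reporting how many alveoli
#'   were placed (ground truth is never silently truncated).
#' @return An `acinus_phantom`: `labels` (integer array), `voxel_size_um`,
#'   `entrance` (voxel-space point/normal + proximal air voxel count), and
#'   `truth` manifest (`true_volume_mm3`, `acinar_volume_mm3` distal of the
#'   entrance, `n_alveoli`, `voxel_size_um`, `seed`).
#' @export
synthesize_acinus <- function(tree, n_alveoli, alveolus_radius_um,
                              voxel_size_um, seed = 1,
                              trunk_length_um = 0, margin_vox = 4,
                              max_attempts = NULL) {
  stopifnot(inherits(tree, "duct_tree"), n_alveoli >= 0,
            alveolus_radius_um > 0, voxel_size_um > 0, margin_vox >= 3)
  if (min(tree$nodes$radius_um) <= 2 * voxel_size_um)
    stop("duct radii must exceed 2 voxel lengths at this voxel size")
  if (is.null(max_attempts)) max_attempts <- 100L * max(1L, n_alveoli)
  set.seed(as.integer(seed))

  vs <- voxel_size_um
  nd <- tree$nodes
  r_alv <- alveolus_radius_um / vs
  pad <- (max(nd$radius_um) + 2 * alveolus_radius_um) / vs + margin_vox + 1
  zmin <- min(nd$z) / vs - trunk_length_um / vs
  lo <- c(zmin, min(nd$y) / vs, min(nd$x) / vs) - pad
  hi <- c(max(nd$z), max(nd$y), max(nd$x)) / vs + pad
  dims <- as.integer(ceiling(hi - lo) + 1)
  off <- 1 - lo  # um/vs + off -> 1-based voxel coordinate

  to_vox <- function(p_um) p_um / vs + off
  labels <- array(0L, dim = dims)

  # duct lumen: capsules along each edge, radius of the daughter node
  edges <- nd[!is.na(nd$parent), , drop = FALSE]
  for (i in seq_len(nrow(edges))) {
    a <- to_vox(as.numeric(nd[edges$parent[i], c("z", "y", "x")]))
    b <- to_vox(as.numeric(edges[i, c("z", "y", "x")]))
    labels[capsule_voxels(a, b, edges$radius_um[i] / vs, dims)] <- 1L
  }
  if (nrow(edges) == 0L)  # depth-0 tree has a single segment: synthesise it
    stop("tree must contain at least one segment")
  if (trunk_length_um > 0) {
    a <- to_vox(tree$entrance$point)
    b <- to_vox(tree$entrance$point - tree$entrance$normal * trunk_length_um)
    labels[capsule_voxels(a, b, nd$radius_um[1] / vs, dims)] <- 1L
  }

  # alveolus placement by rejection sampling
  seg_a <- nd[edges$parent, c("z", "y", "x")]
  seg_b <- edges[, c("z", "y", "x")]
  seg_len <- sqrt(rowSums((seg_b - seg_a)^2))
  placed <- 0L
  attempts <- 0L
  excl <- r_alv + 1.8  # >= 1 voxel septum between alveoli
  while (placed < n_alveoli) {
    if (attempts >= max_attempts)
      stop(sprintf("placed only %d of %d alveoli within %d attempts",
                   placed, n_alveoli, attempts))
    attempts <- attempts + 1L
    e <- sample.int(nrow(edges), 1L, prob = seg_len)
    a <- as.numeric(seg_a[e, ]); b <- as.numeric(seg_b[e, ])
    t <- stats::runif(1, 0.12, 0.88)
    p <- a + t * (b - a)
    axis <- (b - a) / seg_len[e]
    u <- rotate_about(axis, pi / 2, stats::runif(1, 0, 2 * pi))
    r_seg <- edges$radius_um[e]
    center <- p + u * (r_seg + 0.55 * alveolus_radius_um)
    cv <- to_vox(center)
    if (any(cv - r_alv < margin_vox) || any(cv + r_alv > dims - margin_vox + 1))
      next
    S <- sphere_voxels(cv, r_alv, dims)
    if (!length(S)) next
    lab_S <- labels[S]
    mouth <- S[lab_S == 1L]
    if (!length(mouth)) next            # no open path into the lumen
    if (any(lab_S >= 2L)) next          # would merge with another alveolus
    # mouth voxels must cluster at this attachment, not a passing branch
    pv <- to_vox(p)
    mz <- (mouth - 1L) %% dims[1L] + 1L
    my <- ((mouth - 1L) %/% dims[1L]) %% dims[2L] + 1L
    mx <- (mouth - 1L) %/% (dims[1L] * dims[2L]) + 1L
    d_att <- sqrt((mz - pv[1])^2 + (my - pv[2])^2 + (mx - pv[3])^2)
    if (max(d_att) > (r_seg + alveolus_radius_um) / vs + 1) next
    if (any(labels[sphere_voxels(cv, excl, dims)] >= 2L)) next
    new <- S[lab_S == 0L]
    if (!length(new)) next
    # alveolar profile must be present on a contiguous run of sections,
    # so the disector sees exactly one appearance and one disappearance
    zs <- sort(unique((new - 1L) %% dims[1L] + 1L))
    if (length(zs) != zs[length(zs)] - zs[1L] + 1L) next
    labels[new] <- placed + 2L
    placed <- placed + 1L
  }

  if (count_components6(labels > 0L) != 1L)
    stop("phantom air space is not a single 6-connected component")

  ent_vox <- to_vox(tree$entrance$point)
  zs_all <- ((which(labels > 0L) - 1L) %% dims[1L]) + 1L
  n_proximal <- sum(zs_all < ent_vox[1L])
  n_air <- length(zs_all)
  truth <- list(
    true_volume_mm3 = n_air * voxel_volume_mm3(vs),
    acinar_volume_mm3 = (n_air - n_proximal) * voxel_volume_mm3(vs),
    n_alveoli = as.integer(n_alveoli),
    voxel_size_um = vs,
    seed = as.integer(seed))
  structure(list(labels = labels, voxel_size_um = vs,
                 entrance = list(point = ent_vox,
                                 normal = tree$entrance$normal,
                                 radius_um = nd$radius_um[1L],
                                 n_proximal_air = n_proximal),
                 truth = truth),
            class = "acinus_phantom")
}

#' @export
print.acinus_phantom <- function(x, ...) {
  d <- dim(x$labels)
  cat(sprintf(
    "<acinus_phantom> %dx%dx%d vox @ %.3g um, %d alveoli, V = %.4g mm3\n",
    d[1], d[2], d[3], x$voxel_size_um, x$truth$n_alveoli,
    x$truth$true_volume_mm3))
  invisible(x)
}

#' Render a label volume as a grayscale stack
#'
#' Emulates tomographic contrast: air (any nonzero label) is dark, tissue
#' septa and background are bright, with optional additive Gaussian noise.
#' If the noise is so strong that an Otsu threshold of the rendered stack no
#' longer falls between the two nominal levels, a warning is issued but the
#' stack is still returned.
#'
#' @param labels an `acinus_phantom` or an integer label array.
#' @param tissue_level,air_level gray values with `tissue_level > air_level`.
#' @param noise_sd standard deviation of additive Gaussian noise (>= 0).
#' @param seed integer seed for the noise; rendering is deterministic per seed.
#' @param voxel_size_um required when `labels` is a bare array.
#' @return A [voxel_stack()].
#' @export
render_grayscale <- function(labels, tissue_level = 200, air_level = 20,
                             noise_sd = 0, seed = 1, voxel_size_um = NULL) {
  if (inherits(labels, "acinus_phantom")) {
    voxel_size_um <- labels$voxel_size_um
    labels <- labels$labels
  }
  if (is.null(voxel_size_um))
    stop("`voxel_size_um` is required when `labels` is a bare array")
  stopifnot(tissue_level > air_level, noise_sd >= 0)
  gray <- array(ifelse(labels > 0L, air_level, tissue_level), dim = dim(labels))
  if (noise_sd > 0) {
    set.seed(as.integer(seed))
    gray <- gray + stats::rnorm(length(gray), 0, noise_sd)
    th <- suggest_threshold(voxel_stack(gray, voxel_size_um))
    if (th <= air_level || th >= tissue_level)
      warning(sprintf(
        "noise_sd = %g: Otsu threshold %.3g does not separate levels %g/%g",
        noise_sd, th, air_level, tissue_level))
  }
  voxel_stack(gray, voxel_size_um)
}

#' Per-day cohort profiles of acinar morphometry
#'
#' Day-level aggregates of the rat developmental cohort (postnatal days 4,
#' 10, 21, 60): mean acinar volume and its coefficient of variation, mean
#' alveoli per acinus, and the number of acini assessed per day. These are
#' the study conditions the phantom cohort generator emulates.
#'
#' @return Named list of `cohort_profile` objects, one per day.
#' @export
day_profiles <- function() {
  list(
    `4`  = cohort_profile(4,  0.03, 0.04 / 0.03, 48,  125, "right"),
    `10` = cohort_profile(10, 0.04, 0.05 / 0.04, 89,  58,  "right"),
    `21` = cohort_profile(21, 0.10, 0.09 / 0.10, 233, 42,  "right"),
    `60` = cohort_profile(60, 0.74, 0.37 / 0.74, 702, 43,  "symmetric"))
}

#' Construct a cohort profile
#'
#' @param day postnatal day, one of 4, 10, 21, 60 (other values allowed for
#'   synthetic experiments).
#' @param mean_volume_mm3 mean acinar volume (> 0).
#' @param cv_volume coefficient of variation of acinar volume (> 0).
#' @param mean_alveoli mean alveoli per acinus (> 0).
#' @param n_acini number of acini in the cohort (>= 1).
#' @param skew_direction `"right"` or `"symmetric"`, descriptive only: the
#'   within-day law is log-normal either way (right-skewed for large CV,
#'   near-symmetric for small).
#' @return A `cohort_profile` list.
#' @export
cohort_profile <- function(day, mean_volume_mm3, cv_volume, mean_alveoli,
                           n_acini, skew_direction = "right") {
  if (!is.finite(cv_volume) || cv_volume <= 0)
    stop("cv_volume must be > 0")
  if (mean_volume_mm3 <= 0 || mean_alveoli <= 0)
    stop("profile means must be > 0")
  if (n_acini < 1) stop("n_acini must be >= 1")
  structure(list(day = day, mean_volume_mm3 = mean_volume_mm3,
                 cv_volume = cv_volume, mean_alveoli = mean_alveoli,
                 n_acini = as.integer(n_acini),
                 skew_direction = skew_direction),
            class = "cohort_profile")
}

#' Draw acinar volumes from a log-normal size law
#'
#' Moment-matched log-normal: for target mean m and coefficient of variation
#' c, `sigma^2 = log(1 + c^2)` and `mu = log(m) - sigma^2/2`, so the drawn
#' volumes have expectation m and CV c with strictly positive support and
#' right skew — matching the early-development volume distributions.
#'
#' @param n number of draws.
#' @param mean_volume_mm3,cv_volume target mean and CV.
#' @param seed integer seed.
#' @return Numeric vector of volumes (mm^3).
#' @export
draw_acinar_volumes <- function(n, mean_volume_mm3, cv_volume, seed = 1) {
  stopifnot(n >= 1, mean_volume_mm3 > 0, cv_volume > 0)
  set.seed(as.integer(seed))
  s2 <- log(1 + cv_volume^2)
  stats::rlnorm(n, meanlog = log(mean_volume_mm3) - s2 / 2,
                sdlog = sqrt(s2))
}

#' Synthesize a cohort of acinar phantoms at a day profile
#'
#' Draws target acinar volumes from the profile's log-normal law and target
#' alveolar counts co-varying with volume, then realizes each acinus as a
#' voxel phantom. Phantom geometry is built in voxel units at desk scale and
#' the voxel edge length is then set so that the realized distal (acinar)
#' air volume equals the drawn target exactly; every estimator downstream is
#' scale-free, so this loses no generality.
#'
#' @param profile a [cohort_profile()].
#' @param seed integer master seed; per-acinus seeds derive from it.
#' @param alveoli_scale divide the profile's mean alveolar count by this
#'   factor when realizing phantoms (1 = the profile's own counts). Counting
#'   estimators are exact at any count, so scaled-down phantoms trade no
#'   validity for speed; the drawn per-acinus count remains exact truth.
#' @param alveolus_radius_vox alveolar radius in voxels.
#' @param trunk_length_vox proximal conducting stub length in voxels.
#' @return List of `acinus_phantom` objects; each `truth` manifest carries
#'   the profile and the realized (= target) acinar volume.
#' @export
synthesize_cohort <- function(profile, seed = 1, alveoli_scale = 1,
                              alveolus_radius_vox = 3,
                              trunk_length_vox = 8) {
  stopifnot(inherits(profile, "cohort_profile"))
  n <- profile$n_acini
  vols <- draw_acinar_volumes(n, profile$mean_volume_mm3,
                              profile$cv_volume, seed = seed)
  set.seed(as.integer(seed) + 1L)
  m_alv <- profile$mean_alveoli / alveoli_scale
  counts <- pmax(1L, as.integer(round(
    m_alv * (vols / profile$mean_volume_mm3)^0.8 *
      exp(stats::rnorm(n, 0, 0.25)))))
  out <- vector("list", n)
  for (i in seq_len(n)) {
    ph <- realize_phantom(counts[i], alveolus_radius_vox, trunk_length_vox,
                          seed = as.integer(seed) * 100L + i)
    # rescale so the distal air volume equals the drawn target exactly
    n_air <- sum(ph$labels > 0L)
    n_distal <- n_air - ph$entrance$n_proximal_air
    vs <- (vols[i] * 1e9 / n_distal)^(1 / 3)
    ph$voxel_size_um <- vs
    # geometry was built at 1 um/voxel: physical lengths scale with vs
    ph$entrance$radius_um <- ph$entrance$radius_um * vs
    ph$truth$voxel_size_um <- vs
    ph$truth$true_volume_mm3 <- n_air * voxel_volume_mm3(vs)
    ph$truth$acinar_volume_mm3 <- n_distal * voxel_volume_mm3(vs)
    ph$truth$profile_day <- profile$day
    out[[i]] <- ph
  }
  out
}

# build one phantom in voxel units, geometry sized to host n alveoli
realize_phantom <- function(n_alveoli, alveolus_radius_vox, trunk_length_vox,
                            seed) {
  r <- alveolus_radius_vox
  need_len <- 6 * n_alveoli * (r / 3)^2 + 80
  # grow the scaffold deterministically until placement succeeds
  for (try in 0:4) {
    len <- need_len * 1.5^try
    depth <- min(5L, max(2L, as.integer(ceiling(log2(n_alveoli / 8 + 2)))))
    repeat {
      L <- len / (2^(depth + 1) - 1)
      if (L <= 18 * r / 3 || depth >= 5L) break
      depth <- depth + 1L
    }
    L <- max(5 * r / 3 + 8, L)
    tree <- build_duct_tree(depth, segment_length_um = L,
                            radius_um = 1.6 * r, seed = seed,
                            radius_taper = 0.93)
    ph <- tryCatch(
      synthesize_acinus(tree, n_alveoli, alveolus_radius_um = r,
                        voxel_size_um = 1, seed = seed + 7L,
                        trunk_length_um = trunk_length_vox),
      error = function(e) e)
    if (!inherits(ph, "error")) return(ph)
  }
  stop(conditionMessage(ph))
}
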