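# Shared fixtures (built in code) and independent brute-force oracles.

# small standard phantom: depth-2 tree, a handful of alveoli
make_phantom <- function(n_alveoli = 8, seed = 1, trunk_um = 0,
                         vox = 2, r_alv = 6) {
  tree <- build_duct_tree(2, segment_length_um = 40, radius_um = 8,
                          seed = seed)
  synthesize_acinus(tree, n_alveoli, alveolus_radius_um = r_alv,
                    voxel_size_um = vox, seed = seed + 100,
                    trunk_length_um = trunk_um)
}

# node-by-node membership count, independent of count_points()
# (same half-open [0, n) voxel-unit convention, walked one node at a time)
brute_count_points <- function(mask_slice, grid, vox) {
  ny <- nrow(mask_slice); nx <- ncol(mask_slice)
  sp <- grid$spacing_um / vox
  hits <- 0L
  y <- grid$origin_offset_um[1] / vox
  while (y < ny - 1e-9) {
    x <- grid$origin_offset_um[2] / vox
    while (x < nx - 1e-9) {
      if (mask_slice[floor(y + 1e-9) + 1L, floor(x + 1e-9) + 1L])
        hits <- hits + 1L
      x <- x + sp
    }
    y <- y + sp
  }
  hits
}

# exhaustive-permutation two-sided Mann-Whitney p-value (tie-aware via
# midranks); enumeration over all choose(n+m, n) group assignments
perm_utest_p <- function(x, y) {
  pooled <- c(x, y)
  n <- length(x); N <- length(pooled)
  r <- rank(pooled)
  u_stat <- function(idx) sum(r[idx]) - n * (n + 1) / 2
  u_obs <- u_stat(seq_len(n))
  center <- n * (N - n) / 2
  combs <- utils::combn(N, n)
  us <- apply(combs, 2, u_stat)
  mean(abs(us - center) >= abs(u_obs - center) - 1e-12)
}

# hand rank-formula Kruskal-Wallis H (no ties)
hand_kruskal_h <- function(groups) {
  pooled <- unlist(groups)
  N <- length(pooled)
  r <- rank(pooled)
  splits <- split(r, rep(seq_along(groups), lengths(groups)))
  12 / (N * (N + 1)) *
    sum(vapply(splits, function(g) length(g) * mean(g)^2, 1)) - 3 * (N + 1)
}
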