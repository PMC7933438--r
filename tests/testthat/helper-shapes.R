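# analytic voxel shapes shared across tests; grids sized so the shape centre
# falls on a voxel centre (odd extents), which keeps voxelization symmetric

sphere_mask <- function(radius_um, spacing_um = 40, margin_vox = 6) {
  n <- 2L * (ceiling(radius_um / spacing_um) + margin_vox) + 1L
  ctr <- (n - 1) / 2 * spacing_um
  ax2 <- ((seq_len(n) - 1) * spacing_um - ctr)^2
  volume_mask(array(outer(outer(ax2, ax2, `+`), ax2, `+`) <= radius_um^2,
                    c(n, n, n)), spacing_um)
}

ellipsoid_mask <- function(semi_um, spacing_um = 40, margin_vox = 6) {
  n <- 2L * (ceiling(semi_um / spacing_um) + margin_vox) + 1L
  ctr <- (n - 1) / 2 * spacing_um
  f <- function(k) (((seq_len(n[k]) - 1) * spacing_um - ctr[k]) / semi_um[k])^2
  q <- outer(outer(f(1), f(2), `+`), f(3), `+`)
  volume_mask(array(q <= 1, n), spacing_um)
}

slab_mask <- function(thickness_um, spacing_um, dims, axis = 1) {
  sp <- rep(spacing_um, length.out = 3)
  nvox <- round(thickness_um / sp[axis])
  m <- array(FALSE, dims)
  i0 <- floor((dims[axis] - nvox) / 2)
  idx <- i0 + seq_len(nvox)
  if (axis == 1) m[idx, , ] <- TRUE
  else if (axis == 2) m[, idx, ] <- TRUE
  else m[, , idx] <- TRUE
  volume_mask(m, sp)
}

dice <- function(a, b) {
  a <- if (is.logical(a)) a else a$data
  b <- if (is.logical(b)) b else b$data
  2 * sum(a & b) / (sum(a) + sum(b))
}

# small seeded blobby mask: union of random balls, for oracle comparisons
random_blob_mask <- function(dims, spacing_um, n_balls = 4, seed = 1) {
  withr::with_seed(seed, {
    sp <- rep(spacing_um, length.out = 3)
    m <- array(FALSE, dims)
    ctr <- lapply(1:3, function(k) (seq_len(dims[k]) - 1) * sp[k])
    for (b in seq_len(n_balls)) {
      c0 <- vapply(1:3, function(k)
        runif(1, 0.25, 0.75) * (dims[k] - 1) * sp[k], numeric(1))
      r <- runif(1, 0.15, 0.3) * min((dims - 1) * sp)
      q <- outer(outer((ctr[[1]] - c0[1])^2, (ctr[[2]] - c0[2])^2, `+`),
                 (ctr[[3]] - c0[3])^2, `+`)
      m <- m | q <= r^2
    }
    volume_mask(m, sp)
  })
}
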