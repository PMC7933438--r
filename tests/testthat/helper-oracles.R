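# Independent brute-force oracles. These re-derive quantities from first
# principles (exhaustive enumeration) and never call the implementation paths
# they check.

# Exhaustive maximal-sphere local thickness under the shared discretization
# rule: r(q) = (centre-to-centre distance to nearest background voxel) minus
# half a voxel along the dominant axis of that displacement (ties broken
# z, then y, then x); sphere at q covers p iff |p - q| <= r(q) + h_min/2.
brute_force_thickness <- function(mask, spacing_um) {
  d <- if (is.logical(mask)) mask else mask$data
  sp <- rep(spacing_um, length.out = 3)
  hmin <- min(sp)
  dims <- dim(d)
  fg <- which(d)
  bg <- which(!d)
  co <- function(idx) sweep(arrayInd(idx, dims) - 1, 2, sp, `*`)
  fg_co <- co(fg)
  bg_co <- co(bg)
  # inscribed radius at every foreground voxel (exhaustive nearest background)
  r <- vapply(seq_along(fg), function(i) {
    dd2 <- colSums((t(bg_co) - fg_co[i, ])^2)
    nb <- which.min(dd2)
    delta <- abs(bg_co[nb, ] - fg_co[i, ])
    dom <- if (delta[1] >= delta[2] && delta[1] >= delta[3]) 1
           else if (delta[2] >= delta[3]) 2 else 3
    max(sqrt(dd2[nb]) - 0.5 * sp[dom], 0.25 * hmin)
  }, numeric(1))
  th <- numeric(length(fg))
  for (i in seq_along(fg)) {
    dd <- sqrt(colSums((t(fg_co) - fg_co[i, ])^2))
    covered <- dd <= r + 0.5 * hmin + 1e-9
    th[i] <- 2 * max(r[covered])
  }
  out <- array(0, dims)
  out[fg] <- th
  out
}

# Pixel-count conicity oracle: the apical area by direct counting and the
# triangle area by an explicit point-in-triangle test over the pixel grid,
# instead of the closed-form base x height formula.
conicity_oracle <- function(sil) {
  m <- sil$mask
  px <- sil$pixel_um
  apical_rows <- which(sil$u > 0)
  apical_px <- sum(m[apical_rows, , drop = FALSE])
  base_row <- apical_rows[which.min(sil$u[apical_rows])]
  cols <- which(m[base_row, ])
  v1 <- c(sil$u[base_row] - 0.5 * px, sil$v[min(cols)] - 0.5 * px)
  v2 <- c(sil$u[base_row] - 0.5 * px, sil$v[max(cols)] + 0.5 * px)
  occ <- apical_rows[rowSums(m[apical_rows, , drop = FALSE]) > 0]
  tip_row <- occ[which.max(sil$u[occ])]
  tip_cols <- which(m[tip_row, ])
  v3 <- c(sil$u[tip_row] + 0.5 * px, mean(sil$v[tip_cols]))
  # count pixel centres inside the triangle (v1, v2, v3)
  grid <- expand.grid(u = sil$u, v = sil$v)
  sign2 <- function(p, a, b) (p[, 1] - b[1]) * (a[2] - b[2]) -
    (a[1] - b[1]) * (p[, 2] - b[2])
  p <- as.matrix(grid)
  d1 <- sign2(p, v1, v2)
  d2 <- sign2(p, v2, v3)
  d3 <- sign2(p, v3, v1)
  inside <- !((d1 < 0 | d2 < 0 | d3 < 0) & (d1 > 0 | d2 > 0 | d3 > 0))
  apical_px / sum(inside)
}

# closed-form one-way ANOVA + Tukey-Kramer from first principles
anova_oracle <- function(values, groups) {
  groups <- factor(groups)
  k <- nlevels(groups)
  n <- length(values)
  means <- tapply(values, groups, mean)
  ns <- tapply(values, groups, length)
  grand <- mean(values)
  ssb <- sum(ns * (means - grand)^2)
  ssw <- sum((values - means[groups])^2)
  df1 <- k - 1
  df2 <- n - k
  f <- (ssb / df1) / (ssw / df2)
  mse <- ssw / df2
  pairs <- utils::combn(levels(groups), 2)
  tukey_p <- apply(pairs, 2, function(pr) {
    se <- sqrt(mse / 2 * (1 / ns[pr[1]] + 1 / ns[pr[2]]))
    q <- abs(means[pr[1]] - means[pr[2]]) / se
    stats::ptukey(q, k, df2, lower.tail = FALSE)
  })
  list(f = f, p = stats::pf(f, df1, df2, lower.tail = FALSE),
       pairs = pairs, tukey_p = tukey_p)
}
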