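# shared fixtures and independent oracles

bundle_map <- function(chains = c("A", "B", "C", "D"), type = "GluK2") {
  subunit_map(c("A", "B", "C", "D"), rep(type, 4), chains)
}

bundle_scheme <- function(n_res = 30L, m3_hi = 20L) {
  domain_scheme(GluK2 = list(M3 = c(1, m3_hi), LBD = c(m3_hi + 1, n_res),
                             analysis_range = c(1, n_res)))
}

random_rigid <- function() {
  rigid_transform(random_rotation(), stats::runif(3, -20, 20))
}

transform_frame <- function(tf, frame) {
  channel_frame(origin = drop(tf$rotation %*% frame$origin) + tf$translation,
                z_axis = drop(tf$rotation %*% frame$z_axis),
                x_axis = drop(tf$rotation %*% frame$x_axis))
}

# exhaustive-grid pore oracle: max-min clearance over an in-plane lattice
pore_grid_oracle <- function(s, frame, z, params, grid_step = 0.05,
                             disc = NULL) {
  if (is.null(disc)) disc <- params$disc_radius
  X <- to_frame(atom_coords(s), frame)
  vdw <- channelgeom:::atom_vdw_radii(s, params)
  slab <- abs(X[, 3] - z) <= params$max_probe + max(vdw)
  X <- X[slab, , drop = FALSE]; vdw <- vdw[slab]
  g <- seq(-disc, disc, by = grid_step)
  cx <- rep(g, times = length(g)); cy <- rep(g, each = length(g))
  keep <- cx^2 + cy^2 <= disc^2
  cx <- cx[keep]; cy <- cy[keep]
  best <- rep(Inf, length(cx))
  for (i in seq_len(nrow(X))) {
    d <- sqrt((cx - X[i, 1])^2 + (cy - X[i, 2])^2 + (z - X[i, 3])^2) - vdw[i]
    best <- pmin(best, d)
  }
  min(max(best), params$max_probe)
}

# brute-force rotation search (seeded quaternions + refinement); never SVD
rotation_search_oracle <- function(moving, fixed, n = 4000L, seed = 99L) {
  set.seed(seed)
  cm <- colMeans(moving); cf <- colMeans(fixed)
  Mc <- sweep(moving, 2, cm); Fc <- sweep(fixed, 2, cf)
  quat_to_rot <- function(q) {
    q <- q / sqrt(sum(q^2))
    w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
    matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
             2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
             2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
           3, 3, byrow = TRUE)
  }
  score <- function(R) sqrt(mean(rowSums((Mc %*% t(R) - Fc)^2)))
  best_q <- NULL; best_v <- Inf
  for (i in seq_len(n)) {
    q <- stats::rnorm(4)
    v <- score(quat_to_rot(q))
    if (v < best_v) { best_v <- v; best_q <- q / sqrt(sum(q^2)) }
  }
  step <- 0.1
  while (step > 1e-6) {
    improved <- FALSE
    for (i in seq_len(200L)) {
      q <- best_q + stats::rnorm(4, sd = step)
      v <- score(quat_to_rot(q))
      if (v < best_v) {
        best_v <- v; best_q <- q / sqrt(sum(q^2)); improved <- TRUE
      }
    }
    if (!improved) step <- step / 2
  }
  list(rmsd = best_v, rotation = quat_to_rot(best_q))
}

# z-rotation grid oracle for pair-symmetry RMSD of z-symmetric fixtures
zrot_rmsd_oracle <- function(moving, fixed, step = 0.02) {
  angles <- seq(0, 360 - step, by = step)
  cm <- colMeans(moving); cf <- colMeans(fixed)
  Mc <- sweep(moving, 2, cm); Fc <- sweep(fixed, 2, cf)
  best <- Inf
  for (a in angles) {
    R <- rotation_about_axis(c(0, 0, 1), a)
    v <- sqrt(mean(rowSums((Mc %*% t(R) - Fc)^2)))
    if (v < best) best <- v
  }
  best
}

# state-pair parameter recovery used by several tests
recover_state_pair <- function(sp) {
  frame <- compute_channel_frame(sp$state_a, sp$map, sp$scheme)
  pos <- c("A", "B", "C", "D")
  rot <- vapply(pos, function(p)
    inplane_rotation_angle(sp$state_a, sp$state_b, p, sp$map, sp$scheme,
                           frame), 0)
  bp <- sp$ground_truth$breakpoint_res
  elev <- vapply(pos, function(p) {
    va <- vertical_position_profile(sp$state_a, p, sp$map, sp$scheme, frame)
    vb <- vertical_position_profile(sp$state_b, p, sp$map, sp$scheme, frame)
    post <- va$res_seq > bp
    mean(vb$value[post] - va$value[post])
  }, 0)
  div <- vapply(pos, function(p) {
    lp <- lateral_deviation_profile(sp$state_a, sp$state_b, p, sp$map,
                                    sp$scheme, frame)
    as.integer(find_divergence_residue(lp))
  }, 1L)
  list(rotations = rot, elevations = elev, divergence = div, frame = frame)
}
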