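test_that("kabsch fit handles identity, pure translation and degeneracy", {
  set.seed(1)
  P <- matrix(rnorm(30, sd = 3), 10, 3)
  f <- kabsch_fit(P, P)
  expect_equal(f$rmsd, 0, tolerance = 1e-12)
  expect_equal(f$transform$rotation, diag(3), tolerance = 1e-9)
  expect_equal(f$transform$translation, c(0, 0, 0), tolerance = 1e-9)
  ft <- kabsch_fit(P, sweep(P, 2, c(5, 0, 0), `+`))
  expect_equal(ft$rmsd, 0, tolerance = 1e-12)
  expect_equal(ft$transform$translation, c(5, 0, 0), tolerance = 1e-9)
  expect_error(kabsch_fit(P[1:2, ], P[1:2, ]), "rank")
  line <- cbind(1:5, 2 * (1:5), -1 * (1:5))
  expect_error(kabsch_fit(line, line), "collinear")
  expect_error(kabsch_fit(P, P[1:5, ]), "counts differ")
})

test_that("kabsch result is proper and never a reflection", {
  # a mirrored target tempts the decomposition into det = -1
  set.seed(2)
  P <- matrix(rnorm(24, sd = 2), 8, 3)
  Q <- P %*% diag(c(-1, 1, 1))
  f <- kabsch_fit(P, Q)
  expect_equal(det(f$transform$rotation), 1, tolerance = 1e-9)
})

test_that("rmsd_fixed matches closed forms and a summation oracle", {
  set.seed(3)
  A <- matrix(rnorm(30), 10, 3)
  expect_equal(rmsd_fixed(A, A), 0)
  expect_equal(rmsd_fixed(A, sweep(A, 2, c(0, 2, 0), `+`)), 2)
  B <- matrix(rnorm(30), 10, 3)
  oracle <- sqrt(sum((A - B)^2) / 10)
  expect_equal(rmsd_fixed(A, B), oracle, tolerance = 1e-12)
})

test_that("kabsch is symmetric in rmsd and invariant under joint moves", {
  set.seed(4)
  A <- matrix(rnorm(36, sd = 2), 12, 3)
  B <- A %*% t(rotation_about_axis(c(2, -1, 1), 25)) +
    matrix(rnorm(36, sd = 0.2), 12, 3)
  expect_equal(kabsch_fit(A, B)$rmsd, kabsch_fit(B, A)$rmsd,
               tolerance = 1e-9)
  for (seed in 1:3) {
    set.seed(seed)
    tf <- random_rigid()
    expect_equal(kabsch_fit(apply_transform(tf, A), apply_transform(tf, B))$rmsd,
                 kabsch_fit(A, B)$rmsd, tolerance = 1e-9)
  }
})

test_that("exact C4 bundle has zero pair-symmetry RMSD", {
  b <- make_cn_bundle(4, 4, bundle_radius = 15, n_res = 30)
  sr <- symmetry_rmsd(b$structure, bundle_map(), bundle_scheme())
  expect_lt(sr$rmsd, 1e-9)
  expect_equal(sr$n_pairs, 40L)
})

test_that("pair-symmetry RMSD of a distorted bundle matches a grid oracle", {
  b <- make_cn_bundle(4, 4, bundle_radius = 15, n_res = 30)
  s <- b$structure
  # push the A/C pair radially outward by d: C2-symmetric distortion,
  # so the optimal alignment is a z-rotation and a fine z-grid is exact
  d <- 0.8
  at <- s$atoms
  at$x[at$chain == "A"] <- at$x[at$chain == "A"] + d
  at$x[at$chain == "C"] <- at$x[at$chain == "C"] - d
  s2 <- struct3d(at)
  sch <- bundle_scheme()
  sr <- symmetry_rmsd(s2, bundle_map(), sch)
  res <- domain_residues(sch, "GluK2", "M3")
  mv <- rbind(atom_coords(select_atoms(s2, "B", range(res), "CA")),
              atom_coords(select_atoms(s2, "D", range(res), "CA")))
  fx <- rbind(atom_coords(select_atoms(s2, "A", range(res), "CA")),
              atom_coords(select_atoms(s2, "C", range(res), "CA")))
  oracle <- zrot_rmsd_oracle(mv, fx)
  expect_equal(sr$rmsd, oracle, tolerance = 1e-3)
  expect_lte(sr$rmsd, oracle + 1e-9)   # never worse than the oracle
  # coordinate noise raises the symmetry RMSD on the noise scale
  set.seed(11)
  atn <- b$structure$atoms
  atn[, c("x", "y", "z")] <- as.matrix(atn[, c("x", "y", "z")]) +
    rnorm(3 * nrow(atn), sd = 0.2)
  srn <- symmetry_rmsd(struct3d(atn), bundle_map(), sch)
  expect_gt(srn$rmsd, 0.05)
  expect_lt(srn$rmsd, 1)
})

test_that("symmetry RMSD reports the orientation minimising the fit", {
  b <- make_cn_bundle(4, 4, bundle_radius = 15, n_res = 30)
  sr <- symmetry_rmsd(b$structure, bundle_map(), bundle_scheme())
  expect_match(sr$orientation, "^B->[AC], D->[CA]$")
})

test_that("channel frame recovers the construction axis and is equivariant", {
  b <- make_cn_bundle(4, 4, bundle_radius = 15, n_res = 30)
  fr <- compute_channel_frame(b$structure, bundle_map(), bundle_scheme())
  expect_equal(fr$z_axis, c(0, 0, 1), tolerance = 1e-6)
  expect_lt(max(abs(fr$origin[1:2])), 1e-9)
  for (seed in 1:3) {
    set.seed(seed)
    tf <- random_rigid()
    fr2 <- compute_channel_frame(apply_transform(tf, b$structure),
                                 bundle_map(), bundle_scheme())
    expect_equal(fr2$z_axis, drop(tf$rotation %*% fr$z_axis),
                 tolerance = 1e-6)
    expect_equal(fr2$origin,
                 drop(tf$rotation %*% fr$origin) + tf$translation,
                 tolerance = 1e-6)
  }
})

test_that("channel frame basis is right-handed and orthonormal", {
  fr <- channel_frame(origin = c(1, 2, 3), z_axis = c(0.1, 0.2, 1),
                      x_axis = c(1, 0.3, 0))
  B <- cbind(fr$x_axis, fr$y_axis, fr$z_axis)
  expect_equal(crossprod(B), diag(3), tolerance = 1e-9, ignore_attr = TRUE)
  expect_equal(det(B), 1, tolerance = 1e-9)
  expect_error(channel_frame(z_axis = c(0, 0, 1), x_axis = c(0, 0, 2)),
               "parallel")
})

test_that("degenerate selections are refused rather than silently framed", {
  # a planar circle has two equal principal directions: no defined axis
  th <- 2 * pi * (0:19) / 20
  circ <- data.frame(chain = rep(c("A", "B", "C", "D"), each = 20),
                     res_seq = rep(1:20, 4), res_name = "ALA",
                     atom_name = "CA", element = "C",
                     x = rep(5 * cos(th), 4) + rep(c(0, 20, 40, 60), each = 20),
                     y = rep(5 * sin(th), 4), z = 0)
  s <- struct3d(circ)
  sch <- domain_scheme(GluK2 = list(M3 = c(1, 20), LBD = c(1, 20)))
  expect_error(compute_channel_frame(s, bundle_map(), sch),
               "degenerate|cancel")
})

test_that("align_states superposes over M3 and reports the M3 RMSD", {
  sp <- make_state_pair()
  set.seed(21)
  tf <- random_rigid()
  b_moved <- apply_transform(tf, sp$state_b)
  al <- align_states(sp$state_a, b_moved, sp$map, sp$scheme)
  expect_lt(al$rmsd, 1e-9)
  expect_equal(atom_coords(al$moving), atom_coords(sp$state_b),
               tolerance = 1e-6)
})
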