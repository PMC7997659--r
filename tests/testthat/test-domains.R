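marker_structure <- function(points, chains, res_seq = NULL) {
  # one CA per row of `points`
  if (is.null(res_seq)) res_seq <- seq_len(nrow(points))
  struct3d(data.frame(chain = chains, res_seq = res_seq, res_name = "ALA",
                      atom_name = "CA", element = "C",
                      x = points[, 1], y = points[, 2], z = points[, 3]))
}

test_that("centre of mass: midpoint, symmetry and a summation oracle", {
  two <- marker_structure(rbind(c(0, 0, 0), c(2, 0, 0)), "A")
  expect_equal(center_of_mass(two), c(1, 0, 0), ignore_attr = TRUE)
  b <- make_cn_bundle(4, 4)$structure
  expect_lt(max(abs(center_of_mass(b)[1:2])), 1e-9)
  set.seed(5)
  cloud <- matrix(rnorm(60), 20, 3)
  s <- marker_structure(cloud, "A")
  expect_equal(center_of_mass(s), colSums(cloud) / 20, ignore_attr = TRUE)
  no_ca <- struct3d(data.frame(chain = "A", res_seq = 1, res_name = "ALA",
                               atom_name = "CB", element = "C",
                               x = 0, y = 0, z = 0))
  expect_error(center_of_mass(no_ca), "no CA")
})

test_that("mass weighting differs from uniform CA on mixed-element atoms", {
  at <- data.frame(chain = "A", res_seq = 1:2, res_name = "ALA",
                   atom_name = c("CA", "SG"), element = c("C", "S"),
                   x = c(0, 10), y = 0, z = 0)
  s <- struct3d(at)
  expect_equal(unname(center_of_mass(s, "uniform_ca")[1]), 0)  # only the CA
  m <- unname(center_of_mass(s, "mass")[1])
  expect_equal(m, 10 * 32.06 / (12.011 + 32.06), tolerance = 1e-9)
})

test_that("COM distance matrix: square arrangement gives the closed form", {
  sft <- 20
  sq <- rbind(A = c(0, 0, 0), B = c(sft, 0, 0),
              C = c(sft, sft, 0), D = c(0, sft, 0))
  s <- marker_structure(sq, rownames(sq), res_seq = rep(1L, 4))
  map <- subunit_map(rownames(sq), rep("X", 4), rownames(sq))
  sch <- domain_scheme(X = list(LBD = c(1, 1)))
  rep_ab <- com_distance_matrix(s, map, sch, dimer_pairing = "AB_CD")
  expect_equal(unname(rep_ab$within_dimer), c(sft, sft))
  expect_equal(rep_ab$between_dimer, sft)
  expect_equal(rep_ab$matrix["A", "C"], sqrt(2) * sft)
  expect_true(isSymmetric(rep_ab$matrix))
  expect_true(all(diag(rep_ab$matrix) == 0))
  # alternative pairing
  rep_ad <- com_distance_matrix(s, map, sch, dimer_pairing = "AD_CB")
  expect_equal(unname(rep_ad$within_dimer), c(sft, sft))
})

test_that("COM distances reproduce known marker placements exactly", {
  set.seed(8)
  pts <- matrix(rnorm(12, sd = 10), 4, 3)
  s <- marker_structure(pts, c("A", "B", "C", "D"), res_seq = rep(1L, 4))
  map <- subunit_map(c("A", "B", "C", "D"), rep("X", 4),
                     c("A", "B", "C", "D"))
  sch <- domain_scheme(X = list(LBD = c(1, 1)))
  rep <- com_distance_matrix(s, map, sch)
  expect_equal(unname(rep$matrix["A", "B"]),
               sqrt(sum((pts[1, ] - pts[2, ])^2)), tolerance = 1e-9)
  # missing LBD coverage is a named error
  s3 <- marker_structure(pts[1:3, ], c("A", "B", "C"), rep(1L, 3))
  expect_error(com_distance_matrix(s3, map, sch), "empty selection")
})

test_that("in-plane rotation: identity is zero, recovery, antisymmetry", {
  sp0 <- make_state_pair(rotations = c(A = 0, B = 0, C = 0, D = 0),
                         elevations = c(A = 0, B = 0, C = 0, D = 0))
  fr <- compute_channel_frame(sp0$state_a, sp0$map, sp0$scheme)
  expect_equal(inplane_rotation_angle(sp0$state_a, sp0$state_b, "A",
                                      sp0$map, sp0$scheme, fr), 0)
  sp <- make_state_pair(rotations = c(A = 25, B = -40, C = 12, D = 179),
                        elevations = c(A = 0, B = 2, C = 0, D = 0))
  fr <- compute_channel_frame(sp$state_a, sp$map, sp$scheme)
  for (p in c("A", "B", "C", "D")) {
    th <- inplane_rotation_angle(sp$state_a, sp$state_b, p, sp$map,
                                 sp$scheme, fr)
    expect_equal(th, unname(sp$ground_truth$rotations[p]),
                 tolerance = 0.1)
    back <- inplane_rotation_angle(sp$state_b, sp$state_a, p, sp$map,
                                   sp$scheme, fr)
    expect_equal(back, -th, tolerance = 0.01)
  }
})

test_that("tilt angle: axial rod reads zero, known tilt is recovered", {
  rod <- function(tilt_deg) {
    R <- rotation_about_axis(c(0, 1, 0), tilt_deg)
    pts <- cbind(0, 0, seq(0, 30, length.out = 21)) %*% t(R)
    # 4 chains so the frame machinery is satisfied; tilt only chain A's LBD
    marker_structure(pts, "A")
  }
  sp <- make_state_pair(rotations = c(A = 0, B = 0, C = 0, D = 0),
                        elevations = c(A = 0, B = 0, C = 0, D = 0))
  fr <- compute_channel_frame(sp$state_a, sp$map, sp$scheme)
  sch <- domain_scheme(X = list(LBD = c(1, 21)))
  map1 <- subunit_map(c("A", "B", "C", "D"), rep("X", 4),
                      c("A", "B", "C", "D"))
  s0 <- rod(0); s15 <- rod(15)
  # direct frame: +z axis
  frz <- channel_frame()
  at <- s0$atoms
  for (cc in c("B", "C", "D")) {
    shift <- ifelse(cc == "B", 40, ifelse(cc == "C", 80, 120))
    extra <- at; extra$chain <- cc; extra$x <- extra$x + shift
    s0$atoms <- rbind(s0$atoms, extra)
    e15 <- extra
    s15$atoms <- rbind(s15$atoms, e15)
  }
  expect_equal(tilt_angle(s0, "A", map1, sch, frz), 0, tolerance = 1e-6)
  expect_equal(tilt_angle(s15, "A", map1, sch, frz), 15, tolerance = 0.1)
})

test_that("cleft closure recovers the clamshell hinge regardless of pose", {
  for (hinge in c(10, 30, 55)) {
    cs <- make_clamshell_pair(hinge, seed = 2)
    got <- cleft_closure_angle(cs$open, cs$closed, "A", map = NULL,
                               scheme = cs$scheme)
    expect_equal(got, hinge, tolerance = 0.1)
    # independent random poses of either state do not change the angle
    set.seed(hinge)
    open2 <- apply_transform(random_rigid(), cs$open)
    closed2 <- apply_transform(random_rigid(), cs$closed)
    expect_equal(cleft_closure_angle(open2, closed2, "A", NULL, cs$scheme),
                 hinge, tolerance = 0.1)
  }
  cs <- make_clamshell_pair(30)
  expect_equal(cleft_closure_angle(cs$open, cs$open, "A", NULL, cs$scheme),
               0, tolerance = 1e-6)
  expect_error(cleft_closure_angle(cs$open, cs$closed, "A", NULL,
                                   domain_scheme(synthetic = list(
                                     LBD_D1 = c(1, 20)))),
               "LBD_D2")
})

test_that("helix pair separation equals the trans centroid distance", {
  pts <- rbind(c(0, 0, 0), c(10, 0, 0), c(3, 4, 0), c(7, -4, 0))
  s <- marker_structure(pts, c("A", "C", "B", "D"), res_seq = rep(1L, 4))
  map <- subunit_map(c("A", "B", "C", "D"), rep("X", 4),
                     c("A", "B", "C", "D"))
  sch <- domain_scheme(X = list(helixG = c(1, 1), LBD = c(1, 1)))
  expect_equal(helix_pair_separation(s, map, sch, "helixG", c("A", "C")),
               10)
  # definitional consistency with the COM distance matrix
  rep <- com_distance_matrix(s, map, sch)
  expect_equal(helix_pair_separation(s, map, sch, "helixG", c("A", "C")),
               unname(rep$matrix["A", "C"]))
  expect_error(helix_pair_separation(s, map, sch, "helixB", c("A", "C")),
               "not defined")
})

test_that("angle estimators are invariant under joint rigid transforms", {
  sp <- make_state_pair()
  base <- recover_state_pair(sp)
  for (seed in 1:3) {
    set.seed(seed)
    tf <- random_rigid()
    sp2 <- sp
    sp2$state_a <- apply_transform(tf, sp$state_a)
    sp2$state_b <- apply_transform(tf, sp$state_b)
    moved <- recover_state_pair(sp2)
    expect_equal(moved$rotations, base$rotations, tolerance = 0.01)
    expect_equal(moved$elevations, base$elevations, tolerance = 0.01)
  }
})
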