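#' Synthetic idealized assemblies with known ground truth
#'
#' These generators build coordinate models whose geometric parameters are
#' known exactly, so every analysis stage in the package can be validated
#' without any external structure: ideal alpha-helices and Cn helical
#' bundles (symmetry RMSD, channel frame), ring lattices with analytically
#' known pore radius (pore profiler), two-lobe clamshell domains with a
#' controllable hinge angle (cleft closure), and paired conformational
#' states related by known per-subunit rotations, elevations and a
#' breakpoint residue (angle decomposition and linker profiles).  All
#' generators are deterministic given their parameters and seed.
#'
#' @name synthetic
NULL

helix_params <- list(rise = 1.5, twist = 100, radius = 2.3)

#' Ideal C-alpha alpha-helix
#'
#' Textbook alpha-helix geometry: 1.5 Angstrom rise and 100 degree twist
#' per residue on a 2.3 Angstrom C-alpha radius, built along `axis` from
#' `origin`.
#'
#' @param n_res Number of residues (>= 4), numbered `res_start` upward.
#' @param origin Length-3 start point of the helix axis.
#' @param axis Helix axis direction (any length, not zero).
#' @param seed_phase Angular phase of the first residue, degrees.
#' @param chain Chain id for the emitted atoms.
#' @param res_start First residue number.
#' @return A C-alpha-only [struct3d] (residue name ALA).
#' @export
make_ideal_helix <- function(n_res, origin = c(0, 0, 0), axis = c(0, 0, 1),
                             seed_phase = 0, chain = "A", res_start = 1L) {
  if (n_res < 4L) stop("n_res must be >= 4")
  if (sqrt(sum(axis^2)) < 1e-12) stop("zero axis vector")
  i <- seq_len(n_res) - 1L
  phi <- (seed_phase + helix_params$twist * i) * pi / 180
  xyz <- cbind(helix_params$radius * cos(phi),
               helix_params$radius * sin(phi),
               helix_params$rise * i)
  u <- axis / sqrt(sum(axis^2))
  z <- c(0, 0, 1)
  if (max(abs(u - z)) > 1e-12) {
    v <- c(z[2] * u[3] - z[3] * u[2], z[3] * u[1] - z[1] * u[3],
           z[1] * u[2] - z[2] * u[1])
    sv <- sqrt(sum(v^2)); cv <- sum(z * u)
    R <- if (sv < 1e-12) diag(c(1, -1, -1))  # axis = -z
         else rotation_about_axis(v, atan2(sv, cv) * 180 / pi)
    xyz <- xyz %*% t(R)
  }
  xyz <- sweep(xyz, 2, origin, `+`)
  struct3d(data.frame(chain = chain, res_seq = res_start + i,
                      res_name = "ALA", atom_name = "CA", element = "C",
                      x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                      stringsAsFactors = FALSE),
           entry_id = "ideal_helix")
}

#' Cn-symmetric helical bundle
#'
#' Places `n_chains / symmetry_order` template helices (distinguished by
#' phase) at `bundle_radius` from the z axis and replicates them by exact
#' rotations of 360/symmetry_order degrees, producing an assembly with
#' exact Cn symmetry about +z.
#'
#' @param n_chains Number of chains, divisible by `symmetry_order`.
#' @param symmetry_order Rotational symmetry order n.
#' @param bundle_radius Distance of each helix axis from the z axis,
#'   Angstrom.
#' @param n_res Residues per chain.
#' @param res_start First residue number of every chain.
#' @return List with `structure` ([struct3d], chains named A, B, ...) and
#'   `ground_truth` (symmetry order and the rotation applied to each chain).
#' @export
make_cn_bundle <- function(n_chains = 4L, symmetry_order = 4L,
                           bundle_radius = 15, n_res = 30L, res_start = 1L) {
  if (n_chains %% symmetry_order != 0L)
    stop("n_chains must be divisible by symmetry_order")
  n_templates <- n_chains %/% symmetry_order
  step <- 360 / n_chains
  chains <- list(); rot_applied <- numeric(0)
  k <- 0L
  for (s in seq_len(symmetry_order) - 1L) {
    for (j in seq_len(n_templates) - 1L) {
      tmpl <- make_ideal_helix(n_res, origin = c(bundle_radius, 0, 0),
                               seed_phase = 37 * j, chain = "T",
                               res_start = res_start)
      place <- j * step                       # template placement angle
      rot <- s * 360 / symmetry_order         # exact symmetry copy
      R <- rotation_about_axis(c(0, 0, 1), place + rot)
      xyz <- atom_coords(tmpl) %*% t(R)
      k <- k + 1L
      at <- tmpl$atoms
      at$chain <- LETTERS[k]
      at$x <- xyz[, 1]; at$y <- xyz[, 2]; at$z <- xyz[, 3]
      chains[[k]] <- at
      rot_applied[LETTERS[k]] <- place + rot
    }
  }
  s3d <- struct3d(do.call(rbind, chains), entry_id = "cn_bundle")
  list(structure = s3d,
       ground_truth = list(symmetry_order = symmetry_order,
                           bundle_radius = bundle_radius,
                           rotation_deg_by_chain = rot_applied,
                           n_res = n_res, noise_sigma = 0))
}

#' Two-lobe clamshell domain pair
#'
#' Builds an "open" two-lobe domain (lobes D1 and D2, each an ideal helix)
#' and a "closed" copy in which lobe D2 is rotated by `hinge_angle` about a
#' hinge axis through the inter-lobe boundary — the clamshell closure an
#' agonist induces in a ligand-binding domain.  Both states share a seeded
#' random global pose so that pose-independence of downstream angle
#' estimators is exercised by construction.
#'
#' @param hinge_angle Closure angle in degrees, in [0, 90].
#' @param seed Integer seed controlling the shared global pose.
#' @param n_res_lobe Residues per lobe.
#' @return List with `open`, `closed` ([struct3d], one chain A), `scheme`
#'   (a [domain_scheme] tagging LBD_D1/LBD_D2) and `ground_truth`.
#' @export
make_clamshell_pair <- function(hinge_angle, seed = 1L, n_res_lobe = 20L) {
  if (hinge_angle < 0 || hinge_angle > 90)
    stop("hinge_angle must be in [0, 90] degrees")
  d1 <- make_ideal_helix(n_res_lobe, origin = c(0, 0, 0), axis = c(-1, 0, 0.3),
                         chain = "A", res_start = 1L)
  d2 <- make_ideal_helix(n_res_lobe, origin = c(2, 0, 0), axis = c(1, 0, 0.3),
                         chain = "A", res_start = n_res_lobe + 1L)
  open_at <- rbind(d1$atoms, d2$atoms)
  closed_at <- open_at
  hinge_point <- c(1, 0, 0)   # inter-lobe boundary
  R <- rotation_about_axis(c(0, 1, 0), hinge_angle)
  idx <- closed_at$res_seq > n_res_lobe
  xyz <- as.matrix(closed_at[idx, c("x", "y", "z")])
  xyz <- sweep(sweep(xyz, 2, hinge_point) %*% t(R), 2, hinge_point, `+`)
  closed_at[idx, c("x", "y", "z")] <- xyz
  # shared seeded pose
  set.seed(seed)
  pose <- rigid_transform(random_rotation(), stats::runif(3, -10, 10))
  open <- apply_transform(pose, struct3d(open_at, entry_id = "clamshell_open"))
  closed <- apply_transform(pose,
                            struct3d(closed_at, entry_id = "clamshell_closed"))
  scheme <- domain_scheme(synthetic = list(
    LBD_D1 = c(1, n_res_lobe),
    LBD_D2 = c(n_res_lobe + 1, 2 * n_res_lobe)))
  list(open = open, closed = closed, scheme = scheme,
       ground_truth = list(hinge_angle = hinge_angle, seed = seed,
                           noise_sigma = 0))
}

#' Ring lattice with analytically known pore radius
#'
#' Stacks rings of atoms on the +z axis.  At each ring plane the largest
#' inscribed probe centred on the axis has radius exactly
#' `ring_radius - atom_vdw`; for a regular ring the on-axis centre is the
#' exact maximiser (moving in any in-plane direction shortens the distance
#' to the nearest atom), so the discretization correction is zero and is
#' recorded as such.
#'
#' @param ring_radius Ring radius in Angstrom; scalar or one per
#'   `z_positions`.
#' @param atom_vdw Van der Waals radius assigned to every lattice atom.
#' @param z_positions Ring plane heights, Angstrom.
#' @param n_atoms_per_ring Atoms per ring (>= 12).
#' @param guard_ring Emit a coplanar outer ring 5 Angstrom beyond each
#'   pore ring (default TRUE).  It stands in for the protein wall that
#'   surrounds a real permeation pathway: without it the largest inscribed
#'   sphere near a bare ring lies in the open space outside it, not in the
#'   pore.  The guard is far enough out not to affect the on-axis radius.
#' @return List with `structure` (one chain per ring, element C),
#'   `params` (a [pore_params] whose vdW table matches `atom_vdw`) and
#'   `ground_truth` with `pore_radii_by_z`.
#' @export
make_pore_lattice <- function(ring_radius = 5, atom_vdw = 1.85,
                              z_positions = c(0), n_atoms_per_ring = 24L,
                              guard_ring = TRUE) {
  if (n_atoms_per_ring < 12L) stop("need >= 12 atoms per ring")
  ring_radius <- rep_len(ring_radius, length(z_positions))
  if (any(ring_radius <= atom_vdw))
    stop("ring_radius must exceed atom_vdw")
  one_ring <- function(radius, z, chain, n, res_offset = 0L) {
    th <- 2 * pi * (seq_len(n) - 1L) / n
    data.frame(chain = chain, res_seq = res_offset + seq_len(n),
               res_name = "RNG", atom_name = "CA", element = "C",
               x = radius * cos(th), y = radius * sin(th), z = z,
               stringsAsFactors = FALSE)
  }
  rows <- list()
  for (j in seq_along(z_positions)) {
    r <- one_ring(ring_radius[j], z_positions[j], LETTERS[j],
                  n_atoms_per_ring)
    if (guard_ring) {
      n_guard <- 3L * n_atoms_per_ring
      r <- rbind(r, one_ring(ring_radius[j] + 5, z_positions[j], LETTERS[j],
                             n_guard, res_offset = n_atoms_per_ring))
    }
    rows[[j]] <- r
  }
  s3d <- struct3d(do.call(rbind, rows), entry_id = "pore_lattice")
  params <- pore_params(vdw_table = c(C = atom_vdw))
  list(structure = s3d, params = params,
       ground_truth = list(
         pore_radii_by_z = data.frame(z = z_positions,
                                      radius = ring_radius - atom_vdw),
         discretization_correction = 0,
         atom_vdw = atom_vdw, noise_sigma = 0))
}

#' Paired conformational states with known per-subunit motions
#'
#' Builds a four-chain assembly (positions A--D at 0/90/180/270 degrees) as
#' "state A": each chain is a pore-lining helix spanning the
#' M3-through-E-helix analysis window topped by a compact LBD domain marker
#' (a 20-residue helix leaning away from the axis, so the domain has a
#' realistic ~30 Angstrom extent for rotation estimation).  "State B" is
#' derived by rigidly rotating each chain's residues beyond
#' `breakpoint_res` (the upper linker segment and the whole LBD) about the
#' channel axis by the per-position angle and translating them vertically
#' by the per-position offset, mimicking the linker-mediated
#' reorganisation between antagonist-bound and desensitized channel
#' states.  Optional isotropic Gaussian coordinate noise (per coordinate,
#' seeded) is added to state B.  The defaults encode the motions reported
#' for the GluK2/K5 receptor: in-plane rotations of 18 degrees at A/C and
#' 110 degrees at B/D, a 12 Angstrom elevation at B/D, and a breakpoint at
#' residue 662.
#'
#' @param rotations Named numeric, degrees about +z per position A--D.
#' @param elevations Named numeric, Angstrom along +z per position A--D.
#' @param breakpoint_res Residue number; residues strictly beyond it move.
#' @param noise_sigma Gaussian sigma per coordinate, Angstrom (state B).
#' @param seed Integer seed for the noise.
#' @param res_start,n_res Residue numbering of the linker helix (defaults
#'   631..676, the M3-through-E-helix analysis window in GluK2 numbering).
#' @param bundle_radius Helix-axis distance from the channel axis.
#' @param lbd_res_start,lbd_n_res Residue numbering of the LBD marker.
#' @return List with `state_a`, `state_b`, `map` (all positions typed
#'   GluK2), `scheme` (M3 = fixed segment below the breakpoint, LBD = the
#'   domain marker, analysis_range = the helix window) and `ground_truth`
#'   echoing every parameter.
#' @export
make_state_pair <- function(rotations = c(A = 18, B = 110, C = 18, D = 110),
                            elevations = c(A = 0, B = 12, C = 0, D = 12),
                            breakpoint_res = 662L, noise_sigma = 0,
                            seed = 1L, res_start = 631L, n_res = 46L,
                            bundle_radius = 9, lbd_res_start = 700L,
                            lbd_n_res = 20L) {
  pos <- c("A", "B", "C", "D")
  if (!all(pos %in% names(rotations)) || !all(pos %in% names(elevations)))
    stop("rotations and elevations must name positions A, B, C, D")
  res_end <- res_start + n_res - 1L
  if (breakpoint_res < res_start + 4L || breakpoint_res > res_end - 4L)
    stop("breakpoint_res outside the modeled range ", res_start, "..",
         res_end - 4L)
  if (lbd_res_start <= res_end) stop("LBD numbering overlaps the helix")
  angles <- c(A = 0, B = 90, C = 180, D = 270)
  top_z <- 1.5 * (n_res - 1)
  rows <- list()
  for (p in pos) {
    h <- make_ideal_helix(n_res, origin = c(bundle_radius, 0, 0),
                          seed_phase = 0, chain = p, res_start = res_start)
    lbd <- make_ideal_helix(lbd_n_res,
                            origin = c(bundle_radius + 4, 0, top_z + 4),
                            axis = c(1, 0, 0.5), chain = p,
                            res_start = lbd_res_start)
    R <- rotation_about_axis(c(0, 0, 1), angles[[p]])
    at <- rbind(h$atoms, lbd$atoms)
    xyz <- as.matrix(at[, c("x", "y", "z")]) %*% t(R)
    at$x <- xyz[, 1]; at$y <- xyz[, 2]; at$z <- xyz[, 3]
    rows[[p]] <- at
  }
  a_at <- do.call(rbind, rows)
  b_at <- a_at
  for (p in pos) {
    idx <- b_at$chain == p & b_at$res_seq > breakpoint_res
    R <- rotation_about_axis(c(0, 0, 1), rotations[[p]])
    xyz <- as.matrix(b_at[idx, c("x", "y", "z")]) %*% t(R)
    xyz[, 3] <- xyz[, 3] + elevations[[p]]
    b_at[idx, c("x", "y", "z")] <- xyz
  }
  if (noise_sigma > 0) {
    set.seed(seed)
    b_at[, c("x", "y", "z")] <- as.matrix(b_at[, c("x", "y", "z")]) +
      stats::rnorm(3L * nrow(b_at), sd = noise_sigma)
  }
  map <- subunit_map(pos, rep("GluK2", 4), pos)
  scheme <- domain_scheme(GluK2 = list(
    M3 = c(res_start, breakpoint_res),
    LBD = c(lbd_res_start, lbd_res_start + lbd_n_res - 1),
    analysis_range = c(res_start, res_end)))
  list(state_a = struct3d(a_at, entry_id = "state_a"),
       state_b = struct3d(b_at, entry_id = "state_b"),
       map = map, scheme = scheme,
       ground_truth = list(rotations = rotations, elevations = elevations,
                           breakpoint_res = breakpoint_res,
                           noise_sigma = noise_sigma, seed = seed,
                           res_start = res_start, n_res = n_res,
                           bundle_radius = bundle_radius,
                           lbd_res_start = lbd_res_start,
                           lbd_n_res = lbd_n_res))
}

#' Uniform random rotation matrix
#'
#' Draws a rotation uniformly (QR of a Gaussian matrix, sign-fixed) from
#' the current RNG state; used by invariance tests and pose randomisation.
#'
#' @return 3x3 proper rotation matrix.
#' @export
random_rotation <- function() {
  q <- qr.Q(qr(matrix(stats::rnorm(9), 3, 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

#' Write ground truth as a sidecar JSON document
#'
#' @param ground_truth Ground-truth list from a generator.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(ground_truth, path) {
  jsonlite::write_json(ground_truth, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns", pretty = TRUE)
  invisible(path)
}
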