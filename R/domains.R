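#' Centre of mass of a selection
#'
#' Default weighting is the unweighted mean of C-alpha positions, the right
#' choice for models built largely as poly-alanine (mass weighting over all
#' atoms would be biased toward the regions with modeled side chains);
#' `"mass"` weighting over all atoms is available for complete models.
#'
#' @param s A [struct3d], usually pre-filtered with [select_atoms()].
#' @param weighting `"uniform_ca"` or `"mass"`.
#' @return Length-3 numeric point.
#' @export
center_of_mass <- function(s, weighting = c("uniform_ca", "mass")) {
  weighting <- match.arg(weighting)
  if (n_atoms(s) == 0L) stop("empty selection")
  if (weighting == "uniform_ca") {
    ca <- s$atoms[s$atoms$atom_name == "CA", , drop = FALSE]
    if (nrow(ca) == 0L) stop("no CA atoms in selection")
    return(colMeans(as.matrix(ca[, c("x", "y", "z")])))
  }
  masses <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999, S = 32.06,
              P = 30.974)
  w <- masses[s$atoms$element]
  w[is.na(w)] <- 12.011
  xyz <- atom_coords(s)
  colSums(xyz * w) / sum(w)
}

lbd_com <- function(s, map, scheme, position, weighting = "uniform_ca") {
  ty <- map_type(map, position)
  if (!has_domain(scheme, ty, "LBD"))
    stop("LBD range not defined for subunit type '", ty,
         "' (position ", position, "); extend the domain scheme")
  sel <- select_atoms(s, chains = map_chain(map, position),
                      res_range = range(domain_residues(scheme, ty, "LBD")))
  center_of_mass(sel, weighting)
}

#' LBD centre-of-mass distance report
#'
#' Computes the LBD centre of mass at each tetramer position, the full 4x4
#' distance matrix, the two within-dimer distances under the stated dimer
#' pairing (default (A,B)+(C,D), the heterodimer arrangement), and the
#' between-dimer distance defined as the distance between the two
#' dimer-COM midpoints.  The within-dimer distances characterise dimer
#' integrity; the between-dimer distance measures the compactness of the
#' LBD layer.
#'
#' @param s A [struct3d].
#' @param map A [subunit_map].
#' @param scheme A [domain_scheme] defining `LBD` per subunit type.
#' @param dimer_pairing `"AB_CD"` (default) or `"AD_CB"`.
#' @param weighting Passed to [center_of_mass()].
#' @return A `com_report` list: `com` (4x3 matrix, rows A--D), `matrix`
#'   (4x4, Angstrom), `within_dimer` (named length-2), `between_dimer`,
#'   `dimer_pairing`.
#' @export
com_distance_matrix <- function(s, map, scheme,
                                dimer_pairing = c("AB_CD", "AD_CB"),
                                weighting = "uniform_ca") {
  dimer_pairing <- match.arg(dimer_pairing)
  pos <- c("A", "B", "C", "D")
  com <- t(vapply(pos, function(p) lbd_com(s, map, scheme, p, weighting),
                  numeric(3)))
  D <- as.matrix(stats::dist(com))
  dimnames(D) <- list(pos, pos)
  pairs <- if (dimer_pairing == "AB_CD") list(c("A", "B"), c("C", "D"))
           else list(c("A", "D"), c("C", "B"))
  within <- vapply(pairs, function(p) D[p[1], p[2]], 0)
  names(within) <- vapply(pairs, paste, "", collapse = "-")
  mid <- lapply(pairs, function(p) (com[p[1], ] + com[p[2], ]) / 2)
  between <- sqrt(sum((mid[[1]] - mid[[2]])^2))
  out <- list(com = com, matrix = D, within_dimer = within,
              between_dimer = between, dimer_pairing = dimer_pairing,
              weighting = weighting)
  class(out) <- "com_report"
  out
}

#' @export
print.com_report <- function(x, ...) {
  cat("<com_report> LBD centre-of-mass geometry\n")
  cat("  within-dimer (A):", paste(sprintf("%s %.1f", names(x$within_dimer),
                                           x$within_dimer), collapse = ", "),
      "\n")
  cat(sprintf("  between-dimer (A): %.1f  [pairing %s]\n", x$between_dimer,
              x$dimer_pairing))
  invisible(x)
}

position_lbd_ca <- function(st, map, scheme, position) {
  ty <- map_type(map, position)
  res <- domain_residues(scheme, ty, "LBD")
  at <- st$atoms
  idx <- match(paste(map_chain(map, position), res, "CA"),
               paste(at$chain, at$res_seq, at$atom_name))
  keep <- !is.na(idx)
  list(res = res[keep], xyz = as.matrix(at[idx[keep], c("x", "y", "z")]))
}

#' In-plane rotation of a domain between two states
#'
#' Projects the position's LBD C-alpha atoms of both states onto the xy
#' plane of the shared channel frame, centres each projection on its own
#' centroid, and solves the two-dimensional orthogonal least-squares
#' rotation carrying state A onto state B.  The sign is right-handed about
#' +z.  Both states must already be expressed in the shared frame (see
#' [align_states()]).
#'
#' @param state_a,state_b [struct3d] states.
#' @param position Tetramer position.
#' @param map,scheme Subunit map and domain scheme.
#' @param frame Shared [channel_frame].
#' @return Signed angle in degrees, in (-180, 180].
#' @export
inplane_rotation_angle <- function(state_a, state_b, position, map, scheme,
                                   frame) {
  pa <- position_lbd_ca(state_a, map, scheme, position)
  pb <- position_lbd_ca(state_b, map, scheme, position)
  common <- intersect(pa$res, pb$res)
  if (length(common) < 3L)
    stop("fewer than 3 common LBD residues at position ", position)
  A <- to_frame(pa$xyz[match(common, pa$res), , drop = FALSE], frame)[, 1:2]
  B <- to_frame(pb$xyz[match(common, pb$res), , drop = FALSE], frame)[, 1:2]
  A <- sweep(A, 2, colMeans(A)); B <- sweep(B, 2, colMeans(B))
  th <- atan2(sum(A[, 1] * B[, 2] - A[, 2] * B[, 1]),
              sum(A[, 1] * B[, 1] + A[, 2] * B[, 2])) * 180 / pi
  if (th <= -180) th <- th + 360
  th
}

#' Out-of-plane tilt of a domain
#'
#' Angle between the first principal direction of the position's LBD
#' C-alpha atoms (oriented away from the membrane, i.e. with positive
#' component along +z) and the channel z axis.  The inter-state tilt change
#' is the difference of the two states' values.
#'
#' @inheritParams inplane_rotation_angle
#' @param state A [struct3d].
#' @return Tilt in degrees, in [0, 180).
#' @export
tilt_angle <- function(state, position, map, scheme, frame) {
  p <- position_lbd_ca(state, map, scheme, position)
  if (nrow(p$xyz) < 3L) stop("fewer than 3 LBD residues at ", position)
  X <- to_frame(p$xyz, frame)
  sv <- svd(sweep(X, 2, colMeans(X)))
  if (sv$d[2] > 0 && (sv$d[1] - sv$d[2]) / sv$d[1] < 0.01)
    stop("degenerate principal direction for LBD at position ", position)
  v <- sv$v[, 1]
  if (v[3] < 0) v <- -v
  acos(max(-1, min(1, v[3]))) * 180 / pi
}

#' Clamshell cleft-closure angle between two states
#'
#' Superposes the two states on the D1 (upper) lobe C-alpha atoms, then
#' measures the residual rigid rotation that maps the D2 (lower) lobe of
#' state A onto that of state B; its rotation angle (from the rotation
#' matrix trace) is the change in cleft closure.  Independent of the global
#' pose of either state.  Lobe boundaries come from the scheme's LBD_D1 and
#' LBD_D2 entries (no defaults are shipped: they are model-specific).
#'
#' @param state_a,state_b [struct3d] states.
#' @param position Tetramer position, resolved through `map`; or set
#'   `map = NULL` and pass the chain id directly as `position`.
#' @param map A [subunit_map] or NULL.
#' @param scheme A [domain_scheme] with LBD_D1 and LBD_D2 for the subunit
#'   type (or, with `map = NULL`, for type `"synthetic"`).
#' @return Closure change in degrees, in [0, 180].
#' @export
cleft_closure_angle <- function(state_a, state_b, position, map, scheme) {
  if (is.null(map)) {
    chain <- position
    ty <- names(unclass(scheme))[1]
  } else {
    chain <- map_chain(map, position)
    ty <- map_type(map, position)
  }
  for (dom in c("LBD_D1", "LBD_D2")) {
    if (!has_domain(scheme, ty, dom))
      stop(dom, " not defined for subunit type '", ty,
           "' in the domain scheme; supply lobe boundaries")
  }
  lobe <- function(st, dom) {
    ca_coords(st, chains = chain,
              res_range = range(domain_residues(scheme, ty, dom)))
  }
  d1 <- kabsch_fit(lobe(state_a, "LBD_D1"), lobe(state_b, "LBD_D1"))
  a_on_b <- apply_transform(d1$transform, state_a)
  d2 <- kabsch_fit(lobe(a_on_b, "LBD_D2"), lobe(state_b, "LBD_D2"))
  rotation_angle(d2$transform$rotation)
}

#' Separation of a helix pair across the symmetry axis
#'
#' Distance between the helix-range C-alpha centroids of the two diagonal
#' (trans) subunits — e.g. the G-helix pair whose approach distinguishes a
#' compact desensitization ring.
#'
#' @param state A [struct3d].
#' @param map,scheme Subunit map and domain scheme.
#' @param helix Domain name, e.g. `"helixG"` or `"helixB"`.
#' @param pair Character pair of positions, `c("A","C")` or `c("B","D")`.
#' @return Distance in Angstrom.
#' @export
helix_pair_separation <- function(state, map, scheme, helix = "helixG",
                                  pair = c("A", "C")) {
  com <- lapply(pair, function(p) {
    ty <- map_type(map, p)
    if (!has_domain(scheme, ty, helix))
      stop("helix range '", helix, "' not defined for subunit type '",
           ty, "'")
    sel <- select_atoms(state, chains = map_chain(map, p),
                        res_range = range(domain_residues(scheme, ty, helix)))
    center_of_mass(sel)
  })
  sqrt(sum((com[[1]] - com[[2]])^2))
}
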