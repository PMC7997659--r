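#' Rigid-body transform
#'
#' A proper rotation (3x3, det = +1) plus translation, mapping points as
#' `R p + t`.
#'
#' @param rotation 3x3 orthonormal matrix with determinant +1.
#' @param translation Length-3 numeric vector (Angstrom).
#' @return A `rigid_transform` object.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- as.matrix(rotation)
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-9)
    stop("rotation is not orthonormal")
  if (abs(det(rotation) - 1) > 1e-9)
    stop("rotation must be proper (det = +1)")
  out <- list(rotation = rotation, translation = as.numeric(translation))
  class(out) <- "rigid_transform"
  out
}

#' Apply a rigid transform to points or a structure
#'
#' @param tf A [rigid_transform].
#' @param x An n x 3 coordinate matrix or a [struct3d].
#' @return Object of the same kind with transformed coordinates.
#' @export
apply_transform <- function(tf, x) {
  if (inherits(x, "struct3d")) {
    xyz <- apply_transform(tf, atom_coords(x))
    x$atoms$x <- xyz[, 1]; x$atoms$y <- xyz[, 2]; x$atoms$z <- xyz[, 3]
    return(x)
  }
  sweep(as.matrix(x) %*% t(tf$rotation), 2, tf$translation, `+`)
}

#' Rotation matrix about an arbitrary axis
#'
#' @param axis Length-3 direction vector (normalized internally).
#' @param angle_deg Rotation angle, degrees, right-handed about `axis`.
#' @return 3x3 rotation matrix.
#' @export
rotation_about_axis <- function(axis, angle_deg) {
  n <- sqrt(sum(axis^2))
  if (n < 1e-12) stop("zero axis vector")
  u <- axis / n
  th <- angle_deg * pi / 180
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

#' Rotation angle of a rotation matrix
#'
#' Magnitude from the trace, `acos((tr R - 1)/2)` clamped to [-1, 1].
#'
#' @param R 3x3 rotation matrix.
#' @return Angle in degrees, in [0, 180].
#' @export
rotation_angle <- function(R) {
  acos(max(-1, min(1, (sum(diag(R)) - 1) / 2))) * 180 / pi
}

#' Least-squares rigid superposition (Kabsch)
#'
#' Finds the proper rotation and translation minimising the RMSD between
#' paired point sets, with the reflection branch of the SVD handled so that
#' the rotation determinant is +1.
#'
#' @param moving n x 3 matrix of points to be transformed.
#' @param fixed n x 3 matrix of target points, row-paired with `moving`.
#' @return List with `transform` (a [rigid_transform] mapping moving onto
#'   fixed) and `rmsd` (the minimised value, Angstrom).
#' @export
kabsch_fit <- function(moving, fixed) {
  moving <- as.matrix(moving); fixed <- as.matrix(fixed)
  if (nrow(moving) != nrow(fixed)) stop("paired point counts differ")
  if (nrow(moving) < 3L)
    stop("rank deficiency: need >= 3 non-collinear point pairs")
  cm <- colMeans(moving); cf <- colMeans(fixed)
  Mc <- sweep(moving, 2, cm); Fc <- sweep(fixed, 2, cf)
  dm <- svd(Mc)$d
  if (dm[2] < 1e-8 * max(dm[1], 1e-12))
    stop("rank deficiency: moving points are collinear or coincident")
  H <- crossprod(Mc, Fc)
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  t <- cf - drop(R %*% cm)
  tf <- rigid_transform(R, t)
  rmsd <- rmsd_fixed(apply_transform(tf, moving), fixed)
  list(transform = tf, rmsd = rmsd)
}

#' RMSD without fitting
#'
#' Root-mean-square of the pairwise distances between two equally sized
#' point sets, with no superposition.
#'
#' @param a,b n x 3 coordinate matrices, row-paired.
#' @return RMSD in Angstrom.
#' @export
rmsd_fixed <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  if (nrow(a) != nrow(b)) stop("paired point counts differ")
  sqrt(mean(rowSums((a - b)^2)))
}

#' Cross-pair symmetry RMSD of a tetramer
#'
#' Measures how closely one diagonal subunit pair reproduces the other
#' under a single rigid-body move: C-alpha atoms of the source pair (default
#' B/D) are paired with the target pair (default A/C) through the residue
#' correspondence, the two-chain rigid body is superposed with one joint
#' Kabsch fit, and the minimised RMSD is returned.  In an exactly fourfold
#' symmetric channel this RMSD is zero; the GluK2/K5 transmembrane domain
#' is near-fourfold despite its mixed composition.  Both pairing
#' orientations (B->A, D->C vs B->C, D->A) are tried and the smaller RMSD
#' kept (reported in `orientation`).
#'
#' @param s A [struct3d].
#' @param map A [subunit_map].
#' @param scheme A [domain_scheme].
#' @param corr A [residue_correspondence] (ignored when both pairs share a
#'   subunit type, where pairing is by identical residue number).
#' @param domain Domain name over which to pair residues (default `"M3"`).
#' @param source_pair,target_pair Character pairs of positions.
#' @return List with `transform`, `rmsd`, `orientation` and `n_pairs`.
#' @export
symmetry_rmsd <- function(s, map, scheme, corr = gluk2_gluk5_correspondence(),
                          domain = "M3",
                          source_pair = c("B", "D"),
                          target_pair = c("A", "C")) {
  src_type <- map_type(map, source_pair[1])
  tgt_type <- map_type(map, target_pair[1])
  src_res <- domain_residues(scheme, src_type, domain)
  pair_res <- function(r) {
    if (identical(src_type, tgt_type)) r
    else if (identical(src_type, corr$from_type)) map_residues(corr, r)
    else map_residues(corr, r, direction = "backward")
  }
  tgt_res <- pair_res(src_res)
  if (anyNA(tgt_res))
    stop("residue correspondence has gaps over ", domain, ": missing ",
         paste(src_res[is.na(tgt_res)], collapse = ", "))
  get_ca <- function(position, res) {
    cc <- map_chain(map, position)
    at <- s$atoms
    idx <- match(paste(cc, res, "CA"),
                 paste(at$chain, at$res_seq, at$atom_name))
    if (anyNA(idx))
      stop("missing CA atoms in chain ", cc, " for residues ",
           paste(res[is.na(idx)], collapse = ", "))
    as.matrix(at[idx, c("x", "y", "z")])
  }
  fit_orientation <- function(tgt_order) {
    mv <- rbind(get_ca(source_pair[1], src_res),
                get_ca(source_pair[2], src_res))
    fx <- rbind(get_ca(tgt_order[1], tgt_res),
                get_ca(tgt_order[2], tgt_res))
    kabsch_fit(mv, fx)
  }
  f1 <- fit_orientation(target_pair)
  f2 <- fit_orientation(rev(target_pair))
  if (f1$rmsd <= f2$rmsd) {
    ori <- sprintf("%s->%s, %s->%s", source_pair[1], target_pair[1],
                   source_pair[2], target_pair[2])
    res <- f1
  } else {
    ori <- sprintf("%s->%s, %s->%s", source_pair[1], target_pair[2],
                   source_pair[2], target_pair[1])
    res <- f2
  }
  list(transform = res$transform, rmsd = res$rmsd, orientation = ori,
       n_pairs = 2L * length(src_res))
}

#' Channel reference frame
#'
#' Origin plus right-handed orthonormal basis with +z along the pore axis
#' toward the extracellular side; "vertical" means z and "lateral" means the
#' xy plane throughout the package.
#'
#' @param origin Length-3 point (Angstrom).
#' @param z_axis Direction of the pore axis (normalized internally).
#' @param x_axis In-plane reference direction; its component along z is
#'   removed before normalization.
#' @return A `channel_frame` object.
#' @export
channel_frame <- function(origin = c(0, 0, 0), z_axis = c(0, 0, 1),
                          x_axis = c(1, 0, 0)) {
  z <- z_axis / sqrt(sum(z_axis^2))
  x <- x_axis - sum(x_axis * z) * z
  nx <- sqrt(sum(x^2))
  if (nx < 1e-9) stop("x_axis is parallel to z_axis")
  x <- x / nx
  y <- c(z[2] * x[3] - z[3] * x[2],
         z[3] * x[1] - z[1] * x[3],
         z[1] * x[2] - z[2] * x[1])
  out <- list(origin = as.numeric(origin), x_axis = x, y_axis = y, z_axis = z)
  class(out) <- "channel_frame"
  out
}

#' Express coordinates in a channel frame
#'
#' @param x An n x 3 matrix or [struct3d].
#' @param frame A [channel_frame].
#' @return Matrix of local (x, y, z) coordinates, or a transformed
#'   [struct3d].
#' @export
to_frame <- function(x, frame) {
  B <- cbind(frame$x_axis, frame$y_axis, frame$z_axis)
  if (inherits(x, "struct3d")) {
    xyz <- sweep(atom_coords(x), 2, frame$origin) %*% B
    x$atoms$x <- xyz[, 1]; x$atoms$y <- xyz[, 2]; x$atoms$z <- xyz[, 3]
    return(x)
  }
  sweep(as.matrix(x), 2, frame$origin) %*% B
}

#' Construct the channel frame from the M3 bundle
#'
#' The pore axis is the average of the per-chain M3 helix axes: for each
#' mapped chain the first principal direction (SVD) of its M3-range
#' C-alpha coordinates, oriented along increasing residue number, then
#' averaged and normalized.  (Per-chain axes are used rather than one
#' pooled principal direction because in a wide bundle the lateral spread
#' across chains can rival the axial extent and silently flip the pooled
#' direction.)  The sign is chosen so the LBD layer lies at positive z
#' (extracellular side up).  The origin is the pooled M3 centroid, so
#' z = 0 sits at the bundle crossing; all "distance from membrane" values
#' in reports are relative to this origin.  The x axis is the in-plane
#' projection of the A-position chain's LBD centroid, making the frame
#' deterministic and equivariant under rigid motion of the assembly.
#'
#' @param s A [struct3d].
#' @param map A [subunit_map].
#' @param scheme A [domain_scheme] defining `M3` and an LBD-like range
#'   (`LBD` if present, else `analysis_range`) per subunit type.
#' @return A [channel_frame].
#' @export
compute_channel_frame <- function(s, map, scheme) {
  pooled <- list(); lbd <- list()
  lbd_dom <- NULL
  for (i in seq_len(nrow(map))) {
    ty <- map$subunit_type[i]
    dom <- if (has_domain(scheme, ty, "LBD")) "LBD"
           else if (has_domain(scheme, ty, "analysis_range")) "analysis_range"
           else NULL
    m3 <- tryCatch(
      ca_coords(s, chains = map$chain[i],
                res_range = range(domain_residues(scheme, ty, "M3"))),
      error = function(e) NULL)
    if (!is.null(m3)) pooled[[map$position[i]]] <- m3
    if (!is.null(dom)) {
      p <- tryCatch(
        ca_coords(s, chains = map$chain[i],
                  res_range = range(domain_residues(scheme, ty, dom))),
        error = function(e) NULL)
      if (!is.null(p)) lbd[[map$position[i]]] <- p
      lbd_dom <- dom
    }
  }
  if (length(pooled) < 3L)
    stop("M3 range resolvable in fewer than 3 chains; cannot build frame")
  if (length(lbd) == 0L)
    stop("no LBD-like range resolvable: cannot orient the axis sign; ",
         "supply an explicit channel_frame()")
  X <- do.call(rbind, pooled)
  origin <- colMeans(X)
  axes <- lapply(pooled, function(p) {
    sv <- svd(sweep(p, 2, colMeans(p)))
    if (sv$d[2] > 0 && (sv$d[1] - sv$d[2]) / sv$d[1] < 0.01)
      stop("degenerate principal directions (top two singular values ",
           "within 1%); supply an explicit channel_frame()")
    v <- sv$v[, 1]
    # orient along increasing residue number (atoms are residue-ordered)
    if (sum((p[nrow(p), ] - p[1, ]) * v) < 0) v <- -v
    v
  })
  z <- colMeans(do.call(rbind, axes))
  nz <- sqrt(sum(z^2))
  if (nz < 1e-6)
    stop("per-chain M3 axes cancel; supply an explicit channel_frame()")
  z <- z / nz
  lbd_com <- colMeans(do.call(rbind, lbd))
  if (sum((lbd_com - origin) * z) < 0) z <- -z
  xa <- if (!is.null(lbd[["A"]])) colMeans(lbd[["A"]]) else lbd_com
  xdir <- (xa - origin) - sum((xa - origin) * z) * z
  if (sqrt(sum(xdir^2)) < 1e-9) {
    # A-chain LBD centroid on the axis: fall back to the first M3 atom
    xdir <- (X[1, ] - origin) - sum((X[1, ] - origin) * z) * z
  }
  channel_frame(origin = origin, z_axis = z, x_axis = xdir)
}

#' Superpose one state onto another over the M3 bundle
#'
#' Inter-state comparisons are expressed in a common frame obtained by one
#' joint Kabsch fit of the four-chain M3-bundle C-alpha sets, justified by
#' the near-invariance of the M3 helices between channel states.
#'
#' @param reference,moving [struct3d] states sharing chain naming.
#' @param map A [subunit_map] (applies to both states).
#' @param scheme A [domain_scheme].
#' @return List: `moving` (transformed [struct3d]), `transform`, `rmsd`
#'   (the M3-bundle inter-state RMSD after fitting), and `frame` (the
#'   [compute_channel_frame] of the reference).
#' @export
align_states <- function(reference, moving, map, scheme) {
  get_pool <- function(st) {
    do.call(rbind, lapply(seq_len(nrow(map)), function(i) {
      ty <- map$subunit_type[i]
      res <- domain_residues(scheme, ty, "M3")
      at <- st$atoms
      idx <- match(paste(map$chain[i], res, "CA"),
                   paste(at$chain, at$res_seq, at$atom_name))
      cbind(res = res, as.matrix(at[idx, c("x", "y", "z")]))
    }))
  }
  a <- get_pool(reference); b <- get_pool(moving)
  ok <- stats::complete.cases(a) & stats::complete.cases(b)
  if (sum(ok) < 3L) stop("fewer than 3 common M3 CA atoms between states")
  fit <- kabsch_fit(b[ok, -1, drop = FALSE], a[ok, -1, drop = FALSE])
  list(moving = apply_transform(fit$transform, moving),
       transform = fit$transform, rmsd = fit$rmsd,
       frame = compute_channel_frame(reference, map, scheme))
}
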