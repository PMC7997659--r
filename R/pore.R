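#' Pore profiling parameters
#'
#' Controls the largest-inscribed-sphere pore profiler.  `closed_cutoff`
#' defaults to 1.15 Angstrom, the radius below which a section of an iGluR
#' permeation pathway is considered closed to water; the vdW table defaults
#' to HOLE-style simple element radii.  Every report echoes the parameter
#' set used.
#'
#' @param z_step Slice spacing along the pore axis, Angstrom.
#' @param max_probe Cap on the reported radius, Angstrom (bulk regions are
#'   capped, not infinite, so profiles stay plottable).
#' @param closed_cutoff Closed-channel radius threshold, Angstrom.
#' @param vdw_table Named element -> radius (Angstrom) vector.
#' @param restarts Seeded random restarts per slice for the centre search.
#' @param disc_radius In-plane search disc about the axis, Angstrom.
#' @param seed Integer seed for the restarts.
#' @return A `pore_params` object.
#' @export
pore_params <- function(z_step = 0.5, max_probe = 10, closed_cutoff = 1.15,
                        vdw_table = c(C = 1.85, N = 1.75, O = 1.65,
                                      S = 2.0, H = 1.0),
                        restarts = 8L, disc_radius = 10, seed = 1L) {
  if (z_step <= 0) stop("z_step must be positive")
  if (closed_cutoff >= max_probe) stop("closed_cutoff must be < max_probe")
  out <- list(z_step = z_step, max_probe = max_probe,
              closed_cutoff = closed_cutoff, vdw_table = vdw_table,
              restarts = as.integer(restarts), disc_radius = disc_radius,
              seed = as.integer(seed))
  class(out) <- "pore_params"
  out
}

atom_vdw_radii <- function(s, params) {
  r <- params$vdw_table[s$atoms$element]
  r[is.na(r)] <- params$vdw_table[["C"]]
  unname(r)
}

# clearance of a probe centre (cx, cy) on slice plane z against slab atoms
slice_clearance <- function(cx, cy, z, slab_xyz, slab_vdw) {
  d <- sqrt((slab_xyz[, 1] - cx)^2 + (slab_xyz[, 2] - cy)^2 +
            (slab_xyz[, 3] - z)^2)
  min(d - slab_vdw)
}

#' Pore-radius profile along the channel axis
#'
#' For each slice plane z the profiler reports the radius of the largest
#' sphere centred in that plane that touches no atom: radius(z) =
#' max over in-plane centres c of min over atoms i of
#' (|c - atom_i| - vdw_i), clamped to [0, max_probe].  The centre search is
#' a derivative-free (Nelder-Mead) maximisation warm-started from the
#' previous slice's centre, from the best point of a deterministic 1
#' Angstrom coarse scan of the disc, and from seeded random restarts
#' within 5 Angstrom, constrained to a disc about the axis (an
#' unconstrained search can escape sideways into lipid-facing cavities).  Atoms considered for a slice are
#' those within max_probe + max(vdW) of its plane.  Slices with no nearby
#' atoms are reported at the cap with a bulk flag.
#'
#' @param s A [struct3d].
#' @param frame A [channel_frame]; slices are perpendicular to its z axis.
#' @param z_range Length-2 numeric, slice range in frame z (Angstrom).
#' @param params A [pore_params].
#' @return A `pore_profile`: data.frame with columns z, x, y (probe centre,
#'   frame coordinates), radius and flag ("ok" or "bulk"), with the
#'   parameter set attached.
#' @export
compute_pore_profile <- function(s, frame, z_range,
                                 params = pore_params()) {
  if (n_atoms(s) == 0L) stop("empty structure")
  X <- to_frame(atom_coords(s), frame)
  vdw <- atom_vdw_radii(s, params)
  zs <- seq(z_range[1], z_range[2], by = params$z_step)
  slab_half <- params$max_probe + max(vdw)
  set.seed(params$seed)
  jitter <- matrix(stats::runif(2L * params$restarts, -5, 5),
                   ncol = 2)   # shared restart offsets, seeded once
  warm <- c(0, 0)
  out <- data.frame(z = zs, x = NA_real_, y = NA_real_,
                    radius = NA_real_, flag = "ok",
                    stringsAsFactors = FALSE)
  disc <- params$disc_radius
  g <- seq(-disc, disc, by = 1)
  coarse <- cbind(rep(g, times = length(g)), rep(g, each = length(g)))
  coarse <- coarse[coarse[, 1]^2 + coarse[, 2]^2 <= disc^2, , drop = FALSE]
  for (k in seq_along(zs)) {
    z <- zs[k]
    sel <- abs(X[, 3] - z) <= slab_half
    if (!any(sel)) {
      out$x[k] <- warm[1]; out$y[k] <- warm[2]
      out$radius[k] <- params$max_probe; out$flag[k] <- "bulk"
      next
    }
    sx <- X[sel, , drop = FALSE]; sv <- vdw[sel]
    obj <- function(c2) {
      r2 <- sqrt(sum(c2^2))
      pen <- if (r2 > disc) 100 * (r2 - disc) else 0
      -(slice_clearance(c2[1], c2[2], z, sx, sv)) + pen
    }
    # deterministic coarse scan of the disc guards against distant basins
    cbest <- rep(Inf, nrow(coarse))
    for (i in seq_len(nrow(sx))) {
      d <- sqrt((coarse[, 1] - sx[i, 1])^2 + (coarse[, 2] - sx[i, 2])^2 +
                (z - sx[i, 3])^2) - sv[i]
      cbest <- pmin(cbest, d)
    }
    starts <- rbind(warm, coarse[which.max(cbest), ],
                    sweep(jitter, 2, warm, `+`), c(0, 0))
    best <- NULL
    for (st in seq_len(nrow(starts))) {
      s0 <- starts[st, ]
      if (sqrt(sum(s0^2)) > disc) s0 <- s0 * disc / sqrt(sum(s0^2))
      o <- stats::optim(s0, obj, method = "Nelder-Mead",
                        control = list(reltol = 1e-12, maxit = 500))
      if (is.null(best) || o$value < best$value) best <- o
    }
    r <- -best$value
    out$x[k] <- best$par[1]; out$y[k] <- best$par[2]
    if (r >= params$max_probe) {
      out$radius[k] <- params$max_probe; out$flag[k] <- "bulk"
    } else {
      out$radius[k] <- max(0, r)
    }
    warm <- best$par
  }
  attr(out, "params") <- params
  class(out) <- c("pore_profile", "data.frame")
  out
}

#' @export
print.pore_profile <- function(x, ...) {
  cat(sprintf("<pore_profile> %d slices, z in [%.2f, %.2f] A, min radius %.3f A\n",
              nrow(x), min(x$z), max(x$z), min(x$radius)))
  invisible(x)
}

#' Locate pore constrictions
#'
#' A constriction is a local minimum of the radius profile below `cutoff`:
#' the smallest sample within a +/- 2 Angstrom window, excluding the first
#' and last samples of the scanned range (a monotone profile therefore has
#' no constriction), with adjacent minima closer than 2 Angstrom merged
#' keeping the smaller.  When a structure and
#' frame are supplied, the residues realising the minimum clearance are
#' attributed to each constriction.
#'
#' @param profile A [compute_pore_profile] result.
#' @param cutoff Radius threshold, Angstrom (e.g. 1.15 for a closed gate;
#'   a wider exploratory cutoff reveals sub-maximal constrictions).
#' @param s,frame Optional [struct3d] and [channel_frame] for residue
#'   attribution.
#' @param k Residues to attribute per constriction.
#' @return data.frame with columns z, radius, x, y and (when attributed) a
#'   `residues` list-column; zero rows when no constriction exists.
#' @export
find_constrictions <- function(profile, cutoff, s = NULL, frame = NULL,
                               k = 4L) {
  n <- nrow(profile)
  is_min <- logical(n)
  for (i in seq_len(n)) {
    if (i == 1L || i == n) next    # boundary samples are not local minima
    win <- abs(profile$z - profile$z[i]) <= 2
    if (profile$radius[i] >= cutoff) next
    m <- min(profile$radius[win])
    first_at_min <- which(win & profile$radius == m)[1]
    is_min[i] <- profile$radius[i] == m && i == first_at_min
  }
  hits <- which(is_min)
  if (length(hits) > 1L) {       # merge minima closer than 2 A, keep smaller
    keep <- logical(length(hits))
    ord <- hits[order(profile$radius[hits])]
    taken_z <- numeric(0)
    for (i in ord) {
      if (!length(taken_z) || min(abs(profile$z[i] - taken_z)) >= 2) {
        keep[match(i, hits)] <- TRUE
        taken_z <- c(taken_z, profile$z[i])
      }
    }
    hits <- sort(hits[keep])
  }
  out <- as.data.frame(profile)[hits, c("z", "radius", "x", "y"),
                                drop = FALSE]
  rownames(out) <- NULL
  if (!is.null(s) && !is.null(frame) && nrow(out)) {
    out$residues <- lapply(seq_len(nrow(out)), function(i)
      attribute_constriction_residues(s, frame, out$z[i],
                                      c(out$x[i], out$y[i]), k = k))
  }
  out
}

#' Residues realising a constriction
#'
#' Ranks residues by their minimum (atom distance - vdW) clearance to the
#' probe centre and returns the `k` tightest; for a four-chain channel the
#' best residue of each chain is reported (one per chain), ties broken by
#' (chain, res_seq).
#'
#' @param s A [struct3d].
#' @param frame The [channel_frame] in which `z` and `center` are given.
#' @param z Slice height, frame coordinates.
#' @param center Length-2 in-plane probe centre, frame coordinates.
#' @param k Number of residues (>= 1).
#' @param params A [pore_params] supplying the vdW table.
#' @return data.frame with chain, res_seq, res_name, clearance (Angstrom).
#' @export
attribute_constriction_residues <- function(s, frame, z, center, k = 4L,
                                            params = pore_params()) {
  if (k < 1L) stop("k must be >= 1")
  X <- to_frame(atom_coords(s), frame)
  vdw <- atom_vdw_radii(s, params)
  cl <- sqrt((X[, 1] - center[1])^2 + (X[, 2] - center[2])^2 +
             (X[, 3] - z)^2) - vdw
  at <- s$atoms
  key <- paste(at$chain, at$res_seq)
  agg <- tapply(cl, key, min)
  info <- at[!duplicated(key), c("chain", "res_seq", "res_name")]
  info$clearance <- as.numeric(agg[paste(info$chain, info$res_seq)])
  nch <- length(unique(info$chain))
  if (nch == 4L && k == 4L) {
    picked <- do.call(rbind, lapply(split(info, info$chain), function(d)
      d[order(d$clearance, d$res_seq), ][1, ]))
  } else {
    eps <- 1e-9
    info <- info[order(info$clearance, info$chain, info$res_seq), ]
    kth <- info$clearance[min(k, nrow(info))]
    picked <- info[info$clearance <= kth + eps, ]
    picked <- picked[order(picked$chain, picked$res_seq), ]
  }
  rownames(picked) <- NULL
  picked[order(picked$chain, picked$res_seq), ]
}

#' Export a pore profile as TSV
#'
#' One row per slice: z, x, y, radius, flag.
#'
#' @param profile A [compute_pore_profile] result.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_pore_profile <- function(profile, path) {
  utils::write.table(as.data.frame(profile)[, c("z", "x", "y", "radius",
                                                "flag")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
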