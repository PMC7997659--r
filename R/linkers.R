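#' Per-residue deviation profiles over the M3-to-E-helix window
#'
#' The M3-S2 linkers transmit gating motions from the ligand-binding layer
#' to the pore.  These profiles decompose each residue's inter-state motion
#' into a lateral (in-plane, xy) and a vertical (z) component in the shared
#' channel frame, over the analysis window running from the intracellular
#' end of M3 through the E helix (defaults: GluK2 631--676, GluK5
#' 615--660).  Unmodeled residues produce explicit holes in the profile,
#' never interpolation.
#'
#' @name linker_profiles
NULL

position_range_ca <- function(st, map, scheme, position) {
  ty <- map_type(map, position)
  res <- domain_residues(scheme, ty, "analysis_range")
  at <- st$atoms
  idx <- match(paste(map_chain(map, position), res, "CA"),
               paste(at$chain, at$res_seq, at$atom_name))
  keep <- !is.na(idx)
  list(res = res[keep], xyz = as.matrix(at[idx[keep], c("x", "y", "z")]),
       gaps = res[!keep])
}

new_deviation_profile <- function(res_seq, value, kind, position, reference) {
  out <- data.frame(res_seq = res_seq, value = value,
                    stringsAsFactors = FALSE)
  attr(out, "kind") <- kind
  attr(out, "position") <- position
  attr(out, "reference") <- reference
  class(out) <- c("deviation_profile", "data.frame")
  out
}

#' @export
print.deviation_profile <- function(x, ...) {
  cat(sprintf("<deviation_profile> %s, position %s, %d residues [%d..%d]\n",
              attr(x, "kind"), attr(x, "position"), nrow(x),
              min(x$res_seq), max(x$res_seq)))
  invisible(x)
}

#' Lateral deviation profile between two states
#'
#' For each residue in the analysis range, the in-plane (xy) distance in
#' the shared channel frame between its C-alpha position in the two states;
#' with `full3d = TRUE`, the full three-dimensional displacement instead.
#' Residues missing from either state are omitted and listed in the `gaps`
#' attribute.
#'
#' @param state_a,state_b [struct3d] states in the shared frame (see
#'   [align_states()]).
#' @param position Tetramer position.
#' @param map,scheme Subunit map and domain scheme.
#' @param frame Shared [channel_frame].
#' @param full3d Use the full 3-D displacement rather than its in-plane
#'   component.
#' @return A `deviation_profile` (columns res_seq, value).
#' @export
lateral_deviation_profile <- function(state_a, state_b, position, map,
                                      scheme, frame, full3d = FALSE) {
  pa <- position_range_ca(state_a, map, scheme, position)
  pb <- position_range_ca(state_b, map, scheme, position)
  common <- intersect(pa$res, pb$res)
  if (!length(common)) stop("no common residues at position ", position)
  A <- to_frame(pa$xyz[match(common, pa$res), , drop = FALSE], frame)
  B <- to_frame(pb$xyz[match(common, pb$res), , drop = FALSE], frame)
  d <- B - A
  v <- if (full3d) sqrt(rowSums(d^2)) else sqrt(d[, 1]^2 + d[, 2]^2)
  out <- new_deviation_profile(common, v,
                               if (full3d) "displacement_3d"
                               else "lateral_deviation",
                               position,
                               "state_b relative to state_a, shared frame")
  attr(out, "gaps") <- sort(union(pa$gaps, pb$gaps))
  out
}

#' Vertical position profile of one state
#'
#' The z coordinate (channel frame; z = 0 at the M3-bundle centroid, +z
#' extracellular) of each C-alpha in the analysis range.  The inter-state
#' elevation change of a segment is the difference of the two states'
#' profiles.
#'
#' @param state A [struct3d].
#' @inheritParams lateral_deviation_profile
#' @return A `deviation_profile` with kind `"vertical_position"`.
#' @export
vertical_position_profile <- function(state, position, map, scheme, frame) {
  p <- position_range_ca(state, map, scheme, position)
  if (!length(p$res)) stop("no analysis-range residues at ", position)
  z <- to_frame(p$xyz, frame)[, 3]
  out <- new_deviation_profile(p$res, z, "vertical_position", position,
                               "z = 0 at M3-bundle centroid")
  attr(out, "gaps") <- p$gaps
  out
}

#' Detect the divergence residue of a deviation profile
#'
#' Finds the first residue at which two conformational states part ways:
#' the baseline is the median of the first `baseline_window` profile
#' values, and the divergence residue is the first whose value exceeds
#' max(threshold_mult x baseline, 2 Angstrom) and is followed by at least
#' `persistence` further samples that stay above the threshold (a
#' non-returning stretch, so isolated spikes do not qualify).  Returns NA
#' when no residue qualifies.
#'
#' @param profile A `deviation_profile`.
#' @param baseline_window Number of leading samples forming the baseline.
#' @param threshold_mult Multiple of the baseline required.
#' @param floor_ang Absolute threshold floor, Angstrom.
#' @param persistence Samples that must remain above threshold.
#' @return Residue number (integer) or NA.
#' @export
find_divergence_residue <- function(profile, baseline_window = 10L,
                                    threshold_mult = 3, floor_ang = 2.0,
                                    persistence = 3L) {
  v <- profile$value
  if (length(v) < baseline_window + 2L)
    stop("profile shorter than baseline_window + 2")
  thr <- max(threshold_mult * stats::median(v[seq_len(baseline_window)]),
             floor_ang)
  above <- v > thr
  for (i in seq_along(v)) {
    if (!above[i]) next
    tail_idx <- seq(i + 1L, length.out = persistence)
    if (max(tail_idx) > length(v)) next
    if (all(above[tail_idx])) return(profile$res_seq[i])
  }
  NA_integer_
}

#' Export deviation profiles as TSV
#'
#' One row per residue: position, res_seq, value, kind.
#'
#' @param profiles A `deviation_profile` or list of them.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_deviation_profiles <- function(profiles, path) {
  if (inherits(profiles, "deviation_profile")) profiles <- list(profiles)
  rows <- do.call(rbind, lapply(profiles, function(p)
    data.frame(position = attr(p, "position"), res_seq = p$res_seq,
               value = p$value, kind = attr(p, "kind"),
               stringsAsFactors = FALSE)))
  utils::write.table(rows, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
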