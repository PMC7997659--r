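#' Subunit map: chains to tetramer positions
#'
#' Binds the four chains of a tetramer to positions A--D and subunit types.
#' In GluK2/K5 kainate receptors the pore-proximal A/C positions are GluK5
#' and the pore-distal B/D positions are GluK2; the diagonal (trans) pairs
#' are A--C and B--D.  Invariants enforced: each position used exactly once,
#' A and C share a subunit type, B and D share a subunit type.
#'
#' @param positions Character vector, a permutation of `c("A","B","C","D")`.
#' @param subunit_types Character vector of subunit type per position.
#' @param chains Character vector of chain ids per position.
#' @return A `subunit_map` data.frame with columns position, subunit_type,
#'   chain, ordered A, B, C, D.
#' @export
subunit_map <- function(positions, subunit_types, chains) {
  m <- data.frame(position = as.character(positions),
                  subunit_type = as.character(subunit_types),
                  chain = as.character(chains), stringsAsFactors = FALSE)
  if (!setequal(m$position, c("A", "B", "C", "D")) || nrow(m) != 4L)
    stop("positions must be A, B, C, D each exactly once")
  if (anyDuplicated(m$chain)) stop("duplicate chain ids in subunit map")
  m <- m[order(m$position), , drop = FALSE]
  rownames(m) <- NULL
  typ <- function(p) m$subunit_type[m$position == p]
  if (!identical(typ("A"), typ("C")))
    stop("positions A and C must have the same subunit type")
  if (!identical(typ("B"), typ("D")))
    stop("positions B and D must have the same subunit type")
  class(m) <- c("subunit_map", "data.frame")
  m
}

map_chain <- function(map, position) {
  map$chain[map$position == position]
}

map_type <- function(map, position) {
  map$subunit_type[map$position == position]
}

#' Domain residue-range scheme
#'
#' Per subunit type, named domains mapped to one or more closed residue
#' intervals (author numbering).  Recognised domain names include ATD, LBD,
#' LBD_D1, LBD_D2, helixB, helixE, helixG, M1, M3, M3S2_linker and
#' analysis_range.  Validates lo <= hi and, when both are given, that M3 is
#' contained in analysis_range.
#'
#' @param ... Named lists, one per subunit type; each element is a domain
#'   name mapped to `c(lo, hi)` or a list of such intervals.
#' @return A `domain_scheme` object.
#' @export
domain_scheme <- function(...) {
  sch <- list(...)
  if (is.null(names(sch)) || any(!nzchar(names(sch))))
    stop("each subunit type must be named")
  for (ty in names(sch)) {
    for (dom in names(sch[[ty]])) {
      iv <- sch[[ty]][[dom]]
      if (!is.list(iv)) iv <- list(iv)
      for (r in iv) {
        if (length(r) != 2L || any(r <= 0) || r[1] > r[2])
          stop("invalid interval for ", ty, "/", dom,
               ": need positive c(lo, hi) with lo <= hi")
      }
      sch[[ty]][[dom]] <- iv
    }
    m3 <- sch[[ty]][["M3"]]
    ar <- sch[[ty]][["analysis_range"]]
    if (!is.null(m3) && !is.null(ar)) {
      lo <- min(vapply(ar, `[`, 0, 1)); hi <- max(vapply(ar, `[`, 0, 2))
      ok <- all(vapply(m3, function(r) r[1] >= lo && r[2] <= hi, TRUE))
      if (!ok) stop("M3 must be contained in analysis_range for ", ty)
    }
  }
  class(sch) <- "domain_scheme"
  sch
}

#' Default GluK2/GluK5 domain scheme
#'
#' Ships the published residue conventions for the pore-lining M3 helix and
#' the M3-through-E-helix analysis window: GluK2 M3 = 631--664 and analysis
#' range 631--676; GluK5 M3 = 615--648 and analysis range 615--660.
#' LBD and lobe (D1/D2) boundaries are deliberately not defaulted: they are
#' model-dependent and must be supplied per entry.
#'
#' @return A [domain_scheme].
#' @export
default_domain_scheme <- function() {
  domain_scheme(
    GluK2 = list(M3 = c(631, 664), analysis_range = c(631, 676)),
    GluK5 = list(M3 = c(615, 648), analysis_range = c(615, 660)))
}

#' Residues of a named domain for one subunit type
#'
#' @param scheme A [domain_scheme].
#' @param subunit_type Subunit type name.
#' @param domain Domain name.
#' @return Integer vector of residue numbers.
#' @export
domain_residues <- function(scheme, subunit_type, domain) {
  ty <- scheme[[subunit_type]]
  if (is.null(ty) || is.null(ty[[domain]]))
    stop("domain '", domain, "' not defined for subunit type '",
         subunit_type, "' in the scheme")
  sort(unique(unlist(lapply(ty[[domain]], function(r) r[1]:r[2]))))
}

has_domain <- function(scheme, subunit_type, domain) {
  !is.null(scheme[[subunit_type]]) && !is.null(scheme[[subunit_type]][[domain]])
}

#' Cross-subunit residue correspondence
#'
#' Injective mapping from residue numbers of one subunit type to another,
#' used to pair equivalent residues across GluK2/GluK5 chains.  The shipped
#' default covers the M3/E-helix region where the alignment is a constant
#' offset: GluK5 = GluK2 - 16 (631<->615, 652<->636, 664<->648, 676<->660).
#'
#' @param from Integer vector of source (GluK2) residue numbers.
#' @param to Integer vector of target (GluK5) residue numbers, same length.
#' @param from_type,to_type Subunit type labels.
#' @return A `residue_correspondence` object.
#' @export
residue_correspondence <- function(from, to, from_type = "GluK2",
                                   to_type = "GluK5") {
  from <- as.integer(from); to <- as.integer(to)
  if (length(from) != length(to)) stop("from/to length mismatch")
  if (anyDuplicated(from) || anyDuplicated(to))
    stop("correspondence must be injective")
  out <- list(from = from, to = to, from_type = from_type, to_type = to_type)
  class(out) <- "residue_correspondence"
  out
}

#' @rdname residue_correspondence
#' @export
gluk2_gluk5_correspondence <- function() {
  residue_correspondence(631:676, 631:676 - 16L)
}

#' Map residues through a correspondence
#'
#' @param corr A [residue_correspondence].
#' @param res Integer residues in the `from_type` numbering.
#' @param direction `"forward"` (from -> to) or `"backward"`.
#' @return Integer vector; NA where unmapped.
#' @export
map_residues <- function(corr, res, direction = c("forward", "backward")) {
  direction <- match.arg(direction)
  if (direction == "forward") corr$to[match(res, corr$from)]
  else corr$from[match(res, corr$to)]
}

#' Assign chains to tetramer positions
#'
#' With an explicit mapping, validates and returns it.  Without one, infers
#' positions geometrically: the channel axis is taken as the normalized mean
#' of the per-chain first principal directions (each oriented along
#' increasing residue number), and the two chains whose LBD-range
#' (or, failing that, all) C-alpha atoms sit at smaller mean in-plane radial
#' distance from the axis are labelled pore-proximal (A/C); the other two
#' are B/D.  Diagonal partners are forced: A--C and B--D are the trans
#' pairs.  Subunit types cannot be inferred from geometry, so the proximal
#' and distal types default to GluK5 and GluK2 respectively and can be
#' overridden.
#'
#' @param s A [struct3d] with at least four chains (unless `mapping` given).
#' @param mapping Optional explicit [subunit_map] (validated, returned).
#' @param scheme Optional [domain_scheme] supplying an LBD range for the
#'   radial measurement.
#' @param proximal_type,distal_type Subunit types assigned to A/C and B/D
#'   when inferring.
#' @return A [subunit_map].
#' @export
assign_subunits <- function(s, mapping = NULL, scheme = NULL,
                            proximal_type = "GluK5",
                            distal_type = "GluK2") {
  if (!is.null(mapping)) {
    m <- subunit_map(mapping$position, mapping$subunit_type, mapping$chain)
    missing <- setdiff(m$chain, chain_ids(s))
    if (length(missing))
      stop("mapped chain(s) absent from structure: ",
           paste(missing, collapse = ", "))
    return(m)
  }
  ch <- chain_ids(s)
  if (length(ch) < 4L)
    stop("geometric inference needs >= 4 chains; pass an explicit mapping")
  ch <- ch[seq_len(4L)]
  all_ca <- ca_coords(s, chains = ch)
  ctr <- colMeans(all_ca)
  # axis = mean of per-chain principal directions, oriented by residue order
  axes <- t(vapply(ch, function(cc) {
    p <- ca_coords(s, chains = cc)
    v <- svd(sweep(p, 2, colMeans(p)))$v[, 1]
    if (sum((p[nrow(p), ] - p[1, ]) * v) < 0) v <- -v
    v
  }, numeric(3)))
  ax <- colMeans(axes)
  ax <- ax / sqrt(sum(ax^2))
  radial <- function(p) {
    rel <- sweep(p, 2, ctr)
    inplane <- rel - outer(drop(rel %*% ax), ax)
    mean(sqrt(rowSums(inplane^2)))
  }
  lbd_rng <- if (!is.null(scheme) && has_domain(scheme, proximal_type, "LBD"))
    range(domain_residues(scheme, proximal_type, "LBD")) else NULL
  r <- vapply(ch, function(cc) {
    p <- tryCatch(ca_coords(s, chains = cc, res_range = lbd_rng),
                  error = function(e) ca_coords(s, chains = cc))
    radial(p)
  }, 0)
  ord <- ch[order(r)]
  prox <- ord[1:2]; dist <- ord[3:4]
  if (abs(sort(r)[2] - sort(r)[3]) < 1)
    stop("radial separation between candidate proximal and distal chains ",
         "< 1 A: geometric inference is ambiguous; pass an explicit mapping")
  prox <- sort(prox); dist <- sort(dist)
  subunit_map(positions = c("A", "C", "B", "D"),
              subunit_types = c(proximal_type, proximal_type,
                                distal_type, distal_type),
              chains = c(prox, dist))
}
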