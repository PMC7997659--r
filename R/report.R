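#' Full two-state structural comparison
#'
#' Runs the comparison battery between two conformational states of a
#' tetrameric channel: M3-bundle superposition into a shared channel frame,
#' inter-state M3 RMSD, cross-pair symmetry RMSD of each state, LBD
#' centre-of-mass geometry, per-position in-plane rotation and tilt change,
#' cleft-closure change (when lobe boundaries are defined), and lateral and
#' vertical linker-deviation profiles with divergence-residue detection.
#' Stages whose inputs are not resolvable (e.g. no LBD_D1/D2 lobes in the
#' scheme) are skipped and recorded by name in `$skipped` rather than
#' aborting the rest of the battery.
#'
#' @param state_a Reference state (e.g. antagonist-bound), a [struct3d].
#' @param state_b Comparison state (e.g. desensitized), a [struct3d].
#' @param map A [subunit_map] valid for both states.
#' @param scheme A [domain_scheme].
#' @param corr A [residue_correspondence] for cross-type pairing.
#' @param align Superpose state_b onto state_a over the M3 bundle first
#'   (default TRUE; set FALSE when the states are already co-framed).
#' @return A `state_comparison` object: list with `frame`, `m3_rmsd`,
#'   `symmetry` (per state), `com` (per state), `angles` (per-position
#'   data.frame), `lateral`, `vertical_a`, `vertical_b` (profile lists),
#'   `divergence` (named residues), `skipped`, `conventions`.
#' @export
compare_states <- function(state_a, state_b, map, scheme,
                           corr = gluk2_gluk5_correspondence(),
                           align = TRUE) {
  skipped <- character(0)
  note_skip <- function(stage, e) {
    skipped[[stage]] <<- conditionMessage(e)
    NULL
  }
  al <- align_states(state_a, state_b, map, scheme)
  if (align) state_b <- al$moving
  frame <- al$frame
  pos <- c("A", "B", "C", "D")

  symmetry <- lapply(list(state_a = state_a, state_b = state_b), function(st)
    tryCatch(symmetry_rmsd(st, map, scheme, corr),
             error = function(e) note_skip("symmetry_rmsd", e)))
  com <- lapply(list(state_a = state_a, state_b = state_b), function(st)
    tryCatch(com_distance_matrix(st, map, scheme),
             error = function(e) note_skip("com_distance_matrix", e)))

  angles <- do.call(rbind, lapply(pos, function(p) {
    rot <- tryCatch(inplane_rotation_angle(state_a, state_b, p, map,
                                           scheme, frame),
                    error = function(e) note_skip(paste0("rotation_", p), e))
    tl <- tryCatch(tilt_angle(state_b, p, map, scheme, frame) -
                     tilt_angle(state_a, p, map, scheme, frame),
                   error = function(e) note_skip(paste0("tilt_", p), e))
    cc <- tryCatch(cleft_closure_angle(state_a, state_b, p, map, scheme),
                   error = function(e) note_skip(paste0("closure_", p), e))
    data.frame(position = p,
               in_plane_rotation = if (is.null(rot)) NA_real_ else rot,
               tilt_change = if (is.null(tl)) NA_real_ else tl,
               cleft_closure_change = if (is.null(cc)) NA_real_ else cc,
               stringsAsFactors = FALSE)
  }))

  lateral <- list(); vertical_a <- list(); vertical_b <- list()
  divergence <- stats::setNames(rep(NA_integer_, 4), pos)
  for (p in pos) {
    lp <- tryCatch(lateral_deviation_profile(state_a, state_b, p, map,
                                             scheme, frame),
                   error = function(e) note_skip(paste0("lateral_", p), e))
    if (!is.null(lp)) {
      lateral[[p]] <- lp
      divergence[p] <- tryCatch(find_divergence_residue(lp),
                                error = function(e) NA_integer_)
    }
    vertical_a[[p]] <- tryCatch(
      vertical_position_profile(state_a, p, map, scheme, frame),
      error = function(e) note_skip(paste0("vertical_a_", p), e))
    vertical_b[[p]] <- tryCatch(
      vertical_position_profile(state_b, p, map, scheme, frame),
      error = function(e) note_skip(paste0("vertical_b_", p), e))
  }

  out <- list(frame = frame, m3_rmsd = al$rmsd, transform = al$transform,
              symmetry = symmetry, com = com, angles = angles,
              lateral = lateral, vertical_a = vertical_a,
              vertical_b = vertical_b, divergence = divergence,
              skipped = skipped,
              conventions = report_conventions(frame))
  class(out) <- "state_comparison"
  out
}

report_conventions <- function(frame = NULL) {
  list(frame = paste("+z extracellular; z = 0 at the pooled M3-bundle",
                     "C-alpha centroid; lateral = xy plane"),
       com_weighting = "unweighted mean over C-alpha atoms",
       between_dimer = "distance between dimer-COM midpoints",
       angles = paste("in-plane rotation signed right-handed about +z;",
                      "tilt and closure reported as magnitudes"),
       origin = if (!is.null(frame)) frame$origin else NULL)
}

#' @export
print.state_comparison <- function(x, ...) {
  cat("<state_comparison>\n")
  cat(sprintf("  M3 inter-state RMSD: %.2f A\n", x$m3_rmsd))
  for (nm in names(x$symmetry))
    if (!is.null(x$symmetry[[nm]]))
      cat(sprintf("  symmetry RMSD (%s): %.2f A [%s]\n", nm,
                  x$symmetry[[nm]]$rmsd, x$symmetry[[nm]]$orientation))
  cat("  per-position angles (deg):\n")
  print(x$angles, row.names = FALSE, digits = 4)
  dv <- x$divergence[!is.na(x$divergence)]
  if (length(dv))
    cat("  divergence residues:",
        paste(sprintf("%s:%d", names(dv), dv), collapse = "  "), "\n")
  if (length(x$skipped))
    cat("  skipped stages:", paste(names(x$skipped), collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.state_comparison <- function(object, ...) {
  print(object)
  for (nm in names(object$com))
    if (!is.null(object$com[[nm]])) {
      cat(sprintf("-- LBD COM geometry, %s --\n", nm))
      print(object$com[[nm]])
    }
  invisible(object)
}

config_fingerprint <- function(txt) {
  # rolling 31-bit hash: provenance fingerprint, not cryptographic
  h <- 5381
  for (b in utf8ToInt(txt)) h <- (h * 33 + b) %% 2147483647
  sprintf("%08x", h)
}

report_meta <- function(config, seed) {
  list(tool = "channelgeom",
       version = as.character(utils::packageVersion("channelgeom")),
       config_hash = config_fingerprint(
         as.character(jsonlite::toJSON(config, auto_unbox = TRUE,
                                       digits = NA))),
       seed = seed,
       conventions = report_conventions())
}

read_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) stop("config must be a list or a YAML file path")
  config
}

resolve_map <- function(s, config, scheme) {
  if (!is.null(config$mapping) && !identical(config$mapping, "infer")) {
    m <- config$mapping
    assign_subunits(s, mapping = data.frame(
      position = vapply(m, `[[`, "", "position"),
      subunit_type = vapply(m, `[[`, "", "subunit_type"),
      chain = vapply(m, `[[`, "", "chain"), stringsAsFactors = FALSE))
  } else assign_subunits(s, scheme = scheme)
}

resolve_scheme <- function(config) {
  if (is.null(config$scheme)) default_domain_scheme()
  else do.call(domain_scheme, lapply(config$scheme, function(ty)
    lapply(ty, function(iv) as.numeric(iv))))
}

#' Pore-profile report from a config
#'
#' Reads one structure, builds (or accepts) the channel frame, profiles the
#' pore and calls constrictions, and writes the profile TSV, a constriction
#' JSON and a conventions/metadata JSON to the output directory.
#'
#' @param config List or YAML path with fields `input` (structure path),
#'   `out_dir`, optional `mapping`, `scheme`, `z_range`, `pore`
#'   (pore_params overrides), `cutoff`, `seed`.
#' @return Invisibly, a list with the profile, constrictions and the paths
#'   written.
#' @export
run_pore_report <- function(config) {
  config <- read_config(config)
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  out_dir <- if (is.null(config$out_dir)) "." else config$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  s <- read_structure(config$input)
  scheme <- resolve_scheme(config)
  map <- resolve_map(s, config, scheme)
  frame <- compute_channel_frame(s, map, scheme)
  pp <- do.call(pore_params, c(config$pore, list(seed = seed)))
  zr <- if (!is.null(config$z_range)) as.numeric(config$z_range)
        else range(to_frame(atom_coords(s), frame)[, 3])
  prof <- compute_pore_profile(s, frame, zr, pp)
  cutoff <- if (is.null(config$cutoff)) pp$closed_cutoff
            else as.numeric(config$cutoff)
  cons <- find_constrictions(prof, cutoff, s = s, frame = frame)
  paths <- list(profile = file.path(out_dir, "pore_profile.tsv"),
                constrictions = file.path(out_dir, "constrictions.json"),
                meta = file.path(out_dir, "pore_meta.json"))
  write_pore_profile(prof, paths$profile)
  jsonlite::write_json(
    list(cutoff = cutoff,
         constrictions = cons[, c("z", "radius", "x", "y")],
         residues = if (!is.null(cons$residues)) cons$residues else list()),
    paths$constrictions, auto_unbox = TRUE, digits = NA,
    dataframe = "rows", pretty = TRUE)
  jsonlite::write_json(c(report_meta(config, seed),
                         list(pore_params = unclass(pp))),
                       paths$meta, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(list(profile = prof, constrictions = cons, paths = paths))
}

#' Two-state comparison report from a config
#'
#' Reads two structures, runs [compare_states()] and writes one JSON report
#' plus profile TSVs to the output directory.
#'
#' @param config List or YAML path with fields `input_a`, `input_b`,
#'   `out_dir`, optional `mapping`, `scheme`, `seed`.
#' @return Invisibly, the `state_comparison` plus written paths.
#' @export
run_state_comparison <- function(config) {
  config <- read_config(config)
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  out_dir <- if (is.null(config$out_dir)) "." else config$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  a <- read_structure(config$input_a)
  b <- read_structure(config$input_b)
  scheme <- resolve_scheme(config)
  map <- resolve_map(a, config, scheme)
  cmp <- compare_states(a, b, map, scheme)
  paths <- list(report = file.path(out_dir, "comparison.json"),
                lateral = file.path(out_dir, "lateral_profiles.tsv"),
                vertical = file.path(out_dir, "vertical_profiles.tsv"))
  if (length(cmp$lateral)) write_deviation_profiles(cmp$lateral,
                                                    paths$lateral)
  vp <- c(cmp$vertical_a, cmp$vertical_b)
  vp <- vp[!vapply(vp, is.null, TRUE)]
  if (length(vp)) write_deviation_profiles(vp, paths$vertical)
  rep <- c(report_meta(config, seed), list(
    m3_rmsd = cmp$m3_rmsd,
    symmetry_rmsd = lapply(cmp$symmetry, function(x)
      if (is.null(x)) NULL else list(rmsd = x$rmsd,
                                     orientation = x$orientation)),
    transform = cbind(cmp$transform$rotation, cmp$transform$translation),
    angles = cmp$angles,
    com = lapply(cmp$com, function(x) if (is.null(x)) NULL else
      list(within_dimer = x$within_dimer, between_dimer = x$between_dimer,
           dimer_pairing = x$dimer_pairing)),
    divergence_residues = as.list(cmp$divergence),
    skipped = as.list(cmp$skipped)))
  jsonlite::write_json(rep, paths$report, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", matrix = "rowmajor",
                       pretty = TRUE)
  invisible(list(comparison = cmp, paths = paths))
}

#' Generate synthetic fixtures from a config
#'
#' Writes PDB fixtures plus a ground-truth JSON sidecar for the requested
#' generator; deterministic per seed.
#'
#' @param config List or YAML path with `generator` (one of
#'   `"state_pair"`, `"cn_bundle"`, `"pore_lattice"`, `"clamshell"`),
#'   `out_dir`, `seed` and generator-specific parameters under `params`.
#' @return Invisibly, the written paths.
#' @export
run_simulation <- function(config) {
  config <- read_config(config)
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  out_dir <- if (is.null(config$out_dir)) "." else config$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  gen <- match.arg(config$generator,
                   c("state_pair", "cn_bundle", "pore_lattice", "clamshell"))
  pars <- if (is.null(config$params)) list() else config$params
  paths <- list(meta = file.path(out_dir, "ground_truth.json"))
  obj <- switch(gen,
    state_pair = do.call(make_state_pair, c(pars, list(seed = seed))),
    cn_bundle = do.call(make_cn_bundle, pars),
    pore_lattice = do.call(make_pore_lattice, pars),
    clamshell = do.call(make_clamshell_pair, c(pars, list(seed = seed))))
  emit <- function(s, name) {
    p <- file.path(out_dir, paste0(name, ".pdb"))
    write_structure(s, p)
    paths[[name]] <<- p
  }
  if (gen == "state_pair") {
    emit(obj$state_a, "state_a"); emit(obj$state_b, "state_b")
  } else if (gen == "clamshell") {
    emit(obj$open, "open"); emit(obj$closed, "closed")
  } else emit(obj$structure, gen)
  write_ground_truth(c(obj$ground_truth, report_meta(config, seed)),
                     paths$meta)
  invisible(paths)
}
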