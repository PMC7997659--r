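#' Atomic structure container
#'
#' A `struct3d` holds the ordered atom records of one coordinate model:
#' one row per atom with chain id, author residue number, residue and atom
#' names, element, Cartesian coordinates in Angstrom, occupancy, alt-loc id
#' and a heteroatom flag.  Author residue numbering is used everywhere and
#' never renumbered, so residue labels match those printed in structural
#' work on these receptors (e.g. T652 on GluK2).
#'
#' @param atoms data.frame with columns `chain`, `res_seq`, `res_name`,
#'   `atom_name`, `element`, `x`, `y`, `z` and optionally `occ`, `alt_loc`,
#'   `het`.
#' @param entry_id character identifier for the model.
#' @param source_format `"pdb"`, `"mmcif"` or `"synthetic"`.
#' @return An object of class `struct3d`.
#' @export
struct3d <- function(atoms, entry_id = "", source_format = "synthetic") {
  need <- c("chain", "res_seq", "res_name", "atom_name", "element",
            "x", "y", "z")
  miss <- setdiff(need, names(atoms))
  if (length(miss))
    stop("atoms is missing column(s): ", paste(miss, collapse = ", "))
  if (is.null(atoms$occ)) atoms$occ <- 1
  if (is.null(atoms$alt_loc)) atoms$alt_loc <- ""
  if (is.null(atoms$het)) atoms$het <- FALSE
  atoms$res_seq <- as.integer(atoms$res_seq)
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  if (!all(is.finite(xyz))) stop("non-finite coordinates in atom records")
  if (nrow(atoms) == 0L) stop("structure has no atoms")
  key <- paste(atoms$chain, atoms$res_seq, atoms$atom_name, atoms$alt_loc)
  if (anyDuplicated(key))
    stop("duplicate (chain, res_seq, atom_name, alt_loc) atom keys")
  rownames(atoms) <- NULL
  out <- list(entry_id = entry_id, atoms = atoms,
              source_format = source_format)
  class(out) <- "struct3d"
  out
}

#' @export
print.struct3d <- function(x, ...) {
  ch <- unique(x$atoms$chain)
  cat(sprintf("<struct3d> %s: %d atoms, %d chain(s) [%s], source=%s\n",
              if (nzchar(x$entry_id)) x$entry_id else "(unnamed)",
              nrow(x$atoms), length(ch), paste(ch, collapse = ","),
              x$source_format))
  invisible(x)
}

#' Coordinate matrix of a structure
#'
#' @param s A [struct3d] object.
#' @return Numeric n x 3 matrix of x, y, z in Angstrom.
#' @export
atom_coords <- function(s) {
  as.matrix(s$atoms[, c("x", "y", "z")])
}

n_atoms <- function(s) nrow(s$atoms)

chain_ids <- function(s) unique(s$atoms$chain)

#' Read a coordinate model from PDB or mmCIF
#'
#' Parses the first model of a PDB v3.3 or mmCIF file (via bio3d) into a
#' [struct3d].  Alternate locations are resolved to the highest-occupancy
#' conformer, ties broken by the alphabetically first alt-loc id; missing
#' occupancies are treated as 1.0.  Heteroatoms are retained but flagged in
#' the `het` column.  Insertion codes are rejected with an error.
#'
#' @param path Path to the coordinate file.
#' @param format `"pdb"` or `"mmcif"`; inferred from the file extension
#'   when omitted (`.pdb`/`.ent` vs `.cif`/`.mmcif`).
#' @return A [struct3d] with all polymer atoms of the first model.
#' @export
read_structure <- function(path, format = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(format)) {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext,
                     pdb = , ent = "pdb",
                     cif = , mmcif = "mmcif",
                     stop("cannot infer format from extension '.", ext,
                          "'; pass format = \"pdb\" or \"mmcif\""))
  }
  format <- match.arg(format, c("pdb", "mmcif"))
  raw <- tryCatch(
    if (format == "pdb")
      suppressWarnings(bio3d::read.pdb(path, multi = FALSE, rm.alt = FALSE,
                                       verbose = FALSE))
    else suppressWarnings(bio3d::read.cif(path, rm.alt = FALSE,
                                          verbose = FALSE)),
    error = function(e) stop("failed to parse ", format, " file '", path,
                             "': ", conditionMessage(e), call. = FALSE))
  at <- raw$atom
  if (!is.null(at$insert) && any(!is.na(at$insert) & nzchar(at$insert)))
    stop("insertion codes present in '", path,
         "'; renumber the model before analysis")
  occ <- at$o
  occ[is.na(occ)] <- 1
  alt <- at$alt
  alt[is.na(alt)] <- ""
  elem <- at$elesy
  if (is.null(elem)) elem <- NA_character_
  guess <- toupper(substr(gsub("[^A-Za-z].*", "", at$elety), 1, 1))
  elem <- ifelse(is.na(elem) | !nzchar(elem), guess, trimws(elem))
  atoms <- data.frame(chain = at$chain, res_seq = at$resno,
                      res_name = at$resid, atom_name = at$elety,
                      element = toupper(elem),
                      x = at$x, y = at$y, z = at$z,
                      occ = occ, alt_loc = alt,
                      het = at$type == "HETATM",
                      stringsAsFactors = FALSE)
  # alt-loc resolution: keep highest occupancy, ties -> first alt id
  ord <- order(atoms$chain, atoms$res_seq, atoms$atom_name,
               -atoms$occ, atoms$alt_loc)
  atoms <- atoms[ord, , drop = FALSE]
  key <- paste(atoms$chain, atoms$res_seq, atoms$atom_name)
  atoms <- atoms[!duplicated(key), , drop = FALSE]
  atoms$alt_loc <- ""
  atoms <- atoms[order(match(atoms$chain, unique(at$chain)),
                       atoms$res_seq, atoms$atom_name), , drop = FALSE]
  if (!any(!atoms$het))
    stop("no polymer atoms in '", path, "'")
  struct3d(atoms, entry_id = tools::file_path_sans_ext(basename(path)),
           source_format = format)
}

#' Write a structure as fixed-width PDB
#'
#' @param s A [struct3d].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_structure <- function(s, path) {
  at <- s$atoms
  bio3d::write.pdb(file = path,
                   xyz = as.numeric(t(as.matrix(at[, c("x", "y", "z")]))),
                   resno = at$res_seq, resid = at$res_name,
                   eleno = seq_len(nrow(at)), elety = at$atom_name,
                   chain = at$chain, o = at$occ,
                   b = rep(0, nrow(at)), elesy = at$element)
  invisible(path)
}

#' Select atoms by chain, residue range and atom name
#'
#' Filters combine with AND; `res_range` is a closed interval in author
#' numbering.  Selecting with no filters returns the structure unchanged.
#'
#' @param s A [struct3d].
#' @param chains Optional character vector of chain ids.
#' @param res_range Optional length-2 numeric `c(lo, hi)`.
#' @param atom_names Optional character vector (e.g. `"CA"`).
#' @param include_het Keep heteroatoms (default TRUE).
#' @return The filtered [struct3d]; error if the selection is empty.
#' @export
select_atoms <- function(s, chains = NULL, res_range = NULL,
                         atom_names = NULL, include_het = TRUE) {
  at <- s$atoms
  keep <- rep(TRUE, nrow(at))
  if (!is.null(chains)) keep <- keep & at$chain %in% chains
  if (!is.null(res_range)) {
    stopifnot(length(res_range) == 2L)
    keep <- keep & at$res_seq >= res_range[1] & at$res_seq <= res_range[2]
  }
  if (!is.null(atom_names)) keep <- keep & at$atom_name %in% atom_names
  if (!include_het) keep <- keep & !at$het
  if (!any(keep))
    stop("empty selection (chains=", paste(chains, collapse = ","),
         " res_range=", paste(res_range, collapse = ".."),
         " atom_names=", paste(atom_names, collapse = ","), ")")
  out <- s
  out$atoms <- at[keep, , drop = FALSE]
  rownames(out$atoms) <- NULL
  out
}

ca_coords <- function(s, chains = NULL, res_range = NULL) {
  atom_coords(select_atoms(s, chains = chains, res_range = res_range,
                           atom_names = "CA"))
}
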