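minimal_pdb <- function() {
  c("ATOM      1  CA  ALA A   1       1.000   2.000   3.000  1.00  0.00           C",
    "ATOM      2  CA  ALA A   2       2.500   2.000   3.000  1.00  0.00           C",
    "ATOM      3  CA  ALA A   3       4.000   2.000   3.000  1.00  0.00           C",
    "END")
}

minimal_cif <- function() {
  c("data_test", "loop_",
    "_atom_site.group_PDB", "_atom_site.id", "_atom_site.type_symbol",
    "_atom_site.label_atom_id", "_atom_site.label_alt_id",
    "_atom_site.label_comp_id", "_atom_site.label_asym_id",
    "_atom_site.label_entity_id", "_atom_site.label_seq_id",
    "_atom_site.pdbx_PDB_ins_code", "_atom_site.Cartn_x",
    "_atom_site.Cartn_y", "_atom_site.Cartn_z", "_atom_site.occupancy",
    "_atom_site.B_iso_or_equiv", "_atom_site.pdbx_formal_charge",
    "_atom_site.auth_seq_id", "_atom_site.auth_comp_id",
    "_atom_site.auth_asym_id", "_atom_site.auth_atom_id",
    "_atom_site.pdbx_PDB_model_num",
    "ATOM 1 C CA . ALA A 1 1 ? 1.000 2.000 3.000 1.00 0.00 ? 1 ALA A CA 1",
    "ATOM 2 C CA . ALA A 2 2 ? 2.500 2.000 3.000 1.00 0.00 ? 2 ALA A CA 1",
    "ATOM 3 C CA . ALA A 3 3 ? 4.000 2.000 3.000 1.00 0.00 ? 3 ALA A CA 1")
}

test_that("PDB parsing echoes a minimal hand-written file exactly", {
  fp <- withr::local_tempfile(fileext = ".pdb")
  writeLines(minimal_pdb(), fp)
  s <- read_structure(fp)
  expect_s3_class(s, "struct3d")
  expect_equal(nrow(s$atoms), 3L)
  expect_identical(atom_coords(s),
                   matrix(c(1, 2.5, 4, 2, 2, 2, 3, 3, 3), 3, 3,
                          dimnames = list(NULL, c("x", "y", "z"))))
  expect_identical(s$atoms$res_seq, 1:3)
  expect_false(any(s$atoms$het))
})

test_that("mmCIF parsing is field-by-field equal to the PDB dialect", {
  fp <- withr::local_tempfile(fileext = ".pdb")
  fc <- withr::local_tempfile(fileext = ".cif")
  writeLines(minimal_pdb(), fp); writeLines(minimal_cif(), fc)
  sp <- read_structure(fp); sc <- read_structure(fc)
  cols <- c("chain", "res_seq", "res_name", "atom_name", "element",
            "x", "y", "z", "occ", "het")
  expect_identical(sp$atoms[, cols], sc$atoms[, cols])
})

test_that("write-read round trip agrees within fixed-width rounding", {
  b <- make_cn_bundle(4, 4, bundle_radius = 15, n_res = 30)
  fp <- withr::local_tempfile(fileext = ".pdb")
  write_structure(b$structure, fp)
  s2 <- read_structure(fp)
  expect_equal(nrow(s2$atoms), nrow(b$structure$atoms))
  expect_lt(max(abs(atom_coords(s2) - atom_coords(b$structure))), 1e-3)
  expect_identical(s2$atoms$chain, b$structure$atoms$chain)
  expect_identical(s2$atoms$res_seq, b$structure$atoms$res_seq)
})

test_that("alt-locs resolve to highest occupancy, ties alphabetically", {
  fp <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  CA AALA A   1       1.000   0.000   0.000  0.40  0.00           C",
    "ATOM      2  CA BALA A   1       9.000   0.000   0.000  0.60  0.00           C",
    "ATOM      3  CA AALA A   2       2.000   0.000   0.000  0.50  0.00           C",
    "ATOM      4  CA BALA A   2       8.000   0.000   0.000  0.50  0.00           C",
    "ATOM      5  CA  ALA A   3       3.000   0.000   0.000  1.00  0.00           C",
    "END"), fp)
  s <- read_structure(fp)
  expect_equal(nrow(s$atoms), 3L)
  # res 1: occupancy 0.6 wins (x = 9); res 2: tie, alt A wins (x = 2)
  expect_equal(s$atoms$x, c(9, 2, 3))
})

test_that("insertion codes and empty-polymer files are rejected", {
  fp <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  CA  ALA A   1A      1.000   0.000   0.000  1.00  0.00           C",
    "ATOM      2  CA  ALA A   2       1.000   2.000   0.000  1.00  0.00           C",
    "END"), fp)
  expect_error(read_structure(fp), "insertion")
  fh <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "HETATM    1  O   HOH A   1       0.000   0.000   0.000  1.00  0.00           O",
    "END"), fh)
  expect_error(read_structure(fh), "no polymer")
  expect_error(read_structure("no/such/file.pdb"), "not found")
})

test_that("select filters compose as intersection and reject empty results", {
  b <- make_cn_bundle(4, 4, n_res = 30)$structure
  expect_equal(nrow(select_atoms(b, chains = "A", atom_names = "CA")$atoms),
               30L)
  r <- select_atoms(b, res_range = c(5, 10))
  expect_true(all(r$atoms$res_seq >= 5 & r$atoms$res_seq <= 10))
  # no filters: identity
  expect_identical(select_atoms(b)$atoms, b$atoms)
  # composition == conjunction
  s1 <- select_atoms(select_atoms(b, chains = c("A", "B")),
                     res_range = c(3, 7))
  s2 <- select_atoms(b, chains = c("A", "B"), res_range = c(3, 7))
  expect_identical(s1$atoms, s2$atoms)
  expect_error(select_atoms(b, chains = "Z"), "empty selection")
})

test_that("explicit subunit mappings validate and pass through", {
  b <- make_cn_bundle(4, 4)$structure
  m <- data.frame(position = c("A", "B", "C", "D"),
                  subunit_type = c("GluK5", "GluK2", "GluK5", "GluK2"),
                  chain = c("A", "B", "C", "D"))
  out <- assign_subunits(b, mapping = m)
  expect_s3_class(out, "subunit_map")
  expect_identical(out$chain, c("A", "B", "C", "D"))
  # A and C must share a type
  bad <- m; bad$subunit_type <- c("GluK2", "GluK2", "GluK5", "GluK2")
  expect_error(assign_subunits(b, mapping = bad), "same subunit type")
  # mapped chain absent
  m2 <- m; m2$chain <- c("A", "B", "C", "Z")
  expect_error(assign_subunits(b, mapping = m2), "absent")
})

test_that("geometric inference labels the inner chains A/C", {
  # two proximal chains at 15 A, two distal at 25 A
  inner <- make_cn_bundle(2, 2, bundle_radius = 15, n_res = 20)$structure
  outer <- make_cn_bundle(2, 2, bundle_radius = 25, n_res = 20)$structure
  at_o <- outer$atoms
  at_o$chain <- ifelse(at_o$chain == "A", "C", "D")
  at_i <- inner$atoms
  at_i$chain <- ifelse(at_i$chain == "A", "A", "B")
  s <- struct3d(rbind(at_i, at_o))
  m <- assign_subunits(s)
  expect_setequal(m$chain[m$position %in% c("A", "C")], c("A", "B"))
  expect_setequal(m$chain[m$position %in% c("B", "D")], c("C", "D"))
  expect_identical(unique(m$subunit_type[m$position %in% c("A", "C")]),
                   "GluK5")
  # invariant under a global rigid move
  for (seed in 1:3) {
    set.seed(seed)
    s2 <- apply_transform(random_rigid(), s)
    expect_identical(assign_subunits(s2), m)
  }
  # ambiguous radii -> explicit mapping requested
  same <- make_cn_bundle(4, 4, bundle_radius = 15)$structure
  expect_error(assign_subunits(same), "ambiguous")
})

test_that("residue correspondence reproduces the printed GluK2/GluK5 pairs", {
  corr <- gluk2_gluk5_correspondence()
  expect_equal(map_residues(corr, c(631L, 652L, 664L, 676L)),
               c(615L, 636L, 648L, 660L))
  expect_equal(map_residues(corr, c(615L, 648L), direction = "backward"),
               c(631L, 664L))
  expect_error(residue_correspondence(c(1, 2), c(5, 5)), "injective")
})

test_that("the shipped domain scheme keeps M3 inside the analysis range", {
  sch <- default_domain_scheme()
  for (ty in c("GluK2", "GluK5")) {
    m3 <- domain_residues(sch, ty, "M3")
    ar <- domain_residues(sch, ty, "analysis_range")
    expect_true(all(m3 %in% ar))
  }
  expect_equal(range(domain_residues(sch, "GluK2", "M3")), c(631, 664))
  expect_equal(range(domain_residues(sch, "GluK5", "M3")), c(615, 648))
  expect_error(domain_scheme(GluK2 = list(M3 = c(10, 5))), "lo <= hi")
  expect_error(domain_scheme(GluK2 = list(M3 = c(1, 50),
                                          analysis_range = c(10, 40))),
               "contained")
})
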