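# structures_io: reading, writing, radii, selection

test_that("minimal 3-atom glycine PDB reads as one residue", {
  s <- read_structure(gly_3atom_pdb())
  expect_s3_class(s, "Structure")
  expect_equal(nrow(s$atoms), 3)
  rt <- residue_table(s)
  expect_equal(nrow(rt), 1)
  expect_equal(rt$resname, "GLY")
  expect_equal(sort(s$atoms$name), sort(c("N", "CA", "C")))
})

test_that("two-model PDB with model_policy=all returns a 2-frame Ensemble", {
  lines <- c(
    "MODEL        1",
    pdb_atom_line(1, "N", "GLY", "A", 1, 0, 0, 0),
    pdb_atom_line(2, "CA", "GLY", "A", 1, 1.46, 0, 0),
    pdb_atom_line(3, "C", "GLY", "A", 1, 2.0, 1.4, 0),
    "ENDMDL",
    "MODEL        2",
    pdb_atom_line(1, "N", "GLY", "A", 1, 0.5, 0, 0),
    pdb_atom_line(2, "CA", "GLY", "A", 1, 1.96, 0, 0),
    pdb_atom_line(3, "C", "GLY", "A", 1, 2.5, 1.4, 0),
    "ENDMDL"
  )
  e <- read_structure(write_pdb_fixture(lines), model_policy = "all")
  expect_s3_class(e, "Ensemble")
  expect_length(e$frames, 2)
  expect_identical(e$frames[[1]]$atoms$name, e$frames[[2]]$atoms$name)
  # model_policy = "first" returns a single Structure
  s <- read_structure(write_pdb_fixture(lines), model_policy = "first")
  expect_s3_class(s, "Structure")
})

test_that("HOH records are flagged as water", {
  lines <- c(
    pdb_atom_line(1, "CA", "GLY", "A", 1, 0, 0, 0),
    pdb_atom_line(2, "O", "HOH", "W", 1, 10, 0, 0, record = "HETATM")
  )
  s <- read_structure(write_pdb_fixture(lines))
  expect_identical(s$atoms$is_water, c(FALSE, TRUE))
})

test_that("unparseable ATOM record raises a format error naming the line", {
  lines <- c(
    pdb_atom_line(1, "CA", "GLY", "A", 1, 0, 0, 0),
    "ATOM      2  CA  GLY A   2      bad_coord   0.000   0.000  1.00  0.00           C"
  )
  expect_error(read_structure(write_pdb_fixture(lines)), "line 2")
})

test_that("mmCIF input is read with author numbering and coordinates intact", {
  p <- tempfile(fileext = ".cif")
  writeLines(c(
    "data_fixture",
    "loop_",
    "_atom_site.group_PDB",
    "_atom_site.id",
    "_atom_site.type_symbol",
    "_atom_site.label_atom_id",
    "_atom_site.label_alt_id",
    "_atom_site.label_comp_id",
    "_atom_site.label_asym_id",
    "_atom_site.label_entity_id",
    "_atom_site.label_seq_id",
    "_atom_site.pdbx_PDB_ins_code",
    "_atom_site.Cartn_x",
    "_atom_site.Cartn_y",
    "_atom_site.Cartn_z",
    "_atom_site.occupancy",
    "_atom_site.B_iso_or_equiv",
    "_atom_site.pdbx_formal_charge",
    "_atom_site.auth_seq_id",
    "_atom_site.auth_comp_id",
    "_atom_site.auth_asym_id",
    "_atom_site.auth_atom_id",
    "_atom_site.pdbx_PDB_model_num",
    "ATOM 1 N N . GLY A 1 1 ? 1.000 2.000 3.000 1.00 0.00 ? 42 GLY A N 1",
    "ATOM 2 C CA . GLY A 1 1 ? 2.400 2.000 3.000 1.00 0.00 ? 42 GLY A CA 1"
  ), p)
  s <- read_structure(p)
  expect_equal(nrow(s$atoms), 2)
  expect_equal(s$atoms$resno, c(42, 42)) # author numbering is canonical
  expect_equal(s$atoms$x, c(1, 2.4))
  expect_setequal(s$atoms$name, c("N", "CA"))
})

test_that("missing element column is inferred from the atom name", {
  line <- pdb_atom_line(1, "CA", "GLY", "A", 1, 0, 0, 0)
  line <- substr(line, 1, 66) # strip the element columns
  s <- read_structure(write_pdb_fixture(line))
  expect_equal(toupper(s$atoms$element), "C")
})

test_that("altloc resolution keeps the highest occupancy, ties by letter", {
  lines <- c(
    pdb_atom_line(1, "CA", "SER", "A", 1, 0, 0, 0, altloc = "A", occ = 0.4),
    pdb_atom_line(2, "CA", "SER", "A", 1, 1, 0, 0, altloc = "B", occ = 0.6),
    pdb_atom_line(3, "CB", "SER", "A", 1, 2, 0, 0, altloc = "A", occ = 0.5),
    pdb_atom_line(4, "CB", "SER", "A", 1, 3, 0, 0, altloc = "B", occ = 0.5)
  )
  s <- read_structure(write_pdb_fixture(lines))
  expect_equal(nrow(s$atoms), 2)
  expect_equal(s$atoms$x[s$atoms$name == "CA"], 1) # occupancy 0.6 wins
  expect_equal(s$atoms$x[s$atoms$name == "CB"], 2) # tie -> altloc A
})

test_that("round-trip preserves counts, names, keys and coordinates to 3 decimals", {
  s <- gate62()$structure
  p <- tempfile(fileext = ".pdb")
  write_structure(s, p)
  s2 <- read_structure(p)
  expect_equal(nrow(s2$atoms), nrow(s$atoms))
  expect_identical(s2$atoms$name, s$atoms$name)
  expect_identical(s2$atoms$resno, s$atoms$resno)
  expect_identical(s2$atoms$chain, s$atoms$chain)
  expect_equal(s2$atoms$x, s$atoms$x, tolerance = 1e-3)
  expect_equal(s2$atoms$z, s$atoms$z, tolerance = 1e-3)
})

test_that("ensemble construction rejects topology mismatches as a hard error", {
  s1 <- gate62()$structure
  s2 <- s1
  s2$atoms <- s2$atoms[-1, ]
  expect_error(new_ensemble(list(s1, s2)), "topolog")
})

test_that("non-finite coordinates are rejected on construction", {
  expect_error(
    new_structure(data.frame(
      name = "CA", resname = "GLY", chain = "A", resno = 1,
      x = NaN, y = 0, z = 0
    )),
    "finite"
  )
})

test_that("assign_radii matches the published Bondi values", {
  s <- read_structure(gly_3atom_pdb())
  s <- assign_radii(s, "bondi")
  expect_equal(s$atoms$vdw[s$atoms$name == "CA"], 1.70)
  bondi <- vdw_radius_table("bondi")
  chothia <- vdw_radius_table("chothia")
  expect_equal(bondi$radius[bondi$element == "O"], 1.52)
  expect_equal(chothia$radius[chothia$element == "C"], 1.87)
  # sodium's symbol "NA" must survive CSV parsing as a string
  expect_true("NA" %in% bondi$element)
})

test_that("unknown element falls back to the default radius with a warning", {
  s <- new_structure(data.frame(
    name = "XX", resname = "UNK", chain = "A", resno = 1,
    x = 0, y = 0, z = 0, element = "X"
  ))
  expect_warning(s2 <- assign_radii(s, "bondi"), "default")
  expect_true(s2$atoms$vdw > 0)
})

test_that("selection grammar covers the documented clauses", {
  s <- gate62()$structure
  sel <- select_atoms(s, "chain A and resi 199-203 and name CA")
  expect_equal(nrow(sel), 5)
  expect_equal(sort(sel$resno), 199:203)

  expect_equal(nrow(select_atoms(s, "water within structure")), 0)

  ser <- select_atoms(s, "sidechain of resi 228")
  expect_setequal(ser$name, c("CB", "OG"))

  expect_error(select_atoms(s, "chain A and gibberish 4"), "position|clause")
})

test_that("selections come back in file order and empty selections are legal", {
  s <- gate62()$structure
  sel <- select_atoms(s, "name CA")
  expect_false(is.unsorted(attr(sel, "idx")))
  expect_equal(nrow(select_atoms(s, "resi 9999")), 0)
})
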