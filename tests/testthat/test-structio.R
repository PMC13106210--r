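test_that("PDB parsing preserves atoms, residues and HETATM flags", {
  f <- write_toy_pdb(tempfile(fileext = ".pdb"))
  s <- read_pdb(f)
  expect_s3_class(s, "md_structure")
  expect_equal(nrow(s$atoms), 13)
  expect_equal(nrow(s$residues), 4)  # 3 amino acids + ligand
  expect_equal(s$atoms$name[1:4], c("N", "CA", "C", "O"))
  expect_true(s$atoms$het[13])
  expect_false(any(s$atoms$het[1:12]))
  expect_equal(s$atoms$chain[9], "B")
  # Bondi radii / masses assigned from the element
  expect_equal(s$atoms$vdw_radius[1], 1.55)
  expect_equal(s$atoms$mass[2], 12.011)
})

test_that("write_pdb / read_pdb round-trips coordinates to PDB precision", {
  s <- make_ideal_helix(8)
  f <- tempfile(fileext = ".pdb")
  write_pdb(s, f)
  s2 <- read_pdb(f)
  expect_equal(nrow(s2$atoms), nrow(s$atoms))
  expect_equal(s2$atoms$name, s$atoms$name)
  expect_equal(s2$atoms$res_id, s$atoms$res_id)
  expect_lt(max(abs(coords(s2) - coords(s))), 1e-3)
  # fixed-column layout: coordinates at columns 31-54, element at 77-78
  ln <- readLines(f)[1]
  expect_equal(substr(ln, 1, 4), "ATOM")
  expect_equal(trimws(substr(ln, 77, 78)), "N")
  expect_equal(as.numeric(substr(ln, 31, 38)), unname(coords(s)[1, 1]),
               tolerance = 1e-3)
})

test_that("malformed records and insertion codes are rejected with context", {
  f <- tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00  0.00           N",
    "ATOM      2  CA  ALA A   1       1.45x   0.000   0.000  1.00  0.00           C"),
    f)
  expect_error(read_pdb(f), "line 2")
  writeLines(c(
    "ATOM      1  N   ALA A   1A      0.000   0.000   0.000  1.00  0.00           N"),
    f)
  expect_error(read_pdb(f), "insertion")
  writeLines("REMARK nothing here", f)
  expect_error(read_pdb(f), "ATOM")
})

test_that("multi-model PDB trajectories round-trip", {
  base <- make_ideal_helix(6)
  tr <- simulate_trajectory(base, covariance_spec(sigma = 0.3, seed = 2), 5)
  f <- tempfile(fileext = ".pdb")
  write_trajectory(tr, f)
  tr2 <- read_trajectory(f)
  expect_equal(n_frames(tr2), 5)
  expect_lt(max(abs(tr2$coords - tr$coords)), 1e-3)
  # single-model file gives a one-frame trajectory
  f1 <- tempfile(fileext = ".pdb")
  write_pdb(base, f1)
  expect_equal(n_frames(read_trajectory(f1)), 1)
})

test_that("atom selections are ordered, typed and complain when required", {
  s <- make_ideal_helix(50)
  ca <- select_atoms(s, "calpha")
  expect_length(ca, 50)
  expect_true(all(diff(ca) > 0))
  bb <- select_atoms(s, "backbone")
  expect_length(bb, 200)  # N, CA, C, O per residue
  f <- write_toy_pdb(tempfile(fileext = ".pdb"))
  two <- read_pdb(f)
  chb <- select_atoms(two, list(chain = "B"))
  expect_true(all(two$atoms$chain[chb] == "B"))
  expect_identical(select_atoms(s, "hetero"), integer(0))
  expect_error(select_atoms(s, "hetero", require_nonempty = TRUE), "no atoms")
  expect_error(select_atoms(s, "sidechain"), "unknown")
})

test_that("interaction and energy tables read with schema checks", {
  rows <- data.frame(
    ligand_id = c("L1", "L1", "L2", "L3", "L3"),
    chain = "A", res_id = c(363, 280, 363, 363, 363),
    res_name = c("HIS", "TYR", "HIS", "HIS", "HIS"),
    interaction_class = c("hbond", "pi", "vdw", "hbond", "hbond"))
  f <- write_toy_interactions(tempfile(fileext = ".csv"), rows)
  expect_warning(tab <- read_interaction_table(f), "duplicate")
  expect_equal(sort(unique(tab$ligand_id)), c("L1", "L2", "L3"))
  expect_equal(attr(tab, "n_ligands"), 3)
  expect_equal(nrow(tab), 4)  # duplicate (L3, His363, hbond) dropped

  f2 <- tempfile(fileext = ".csv")
  write.csv(rows[, -5], f2, row.names = FALSE)
  expect_error(read_interaction_table(f2), "interaction_class")

  ed <- data.frame(complex_id = "c1", chain = "A", res_id = 1:20,
                   res_name = "ALA", energy_kcal_mol = -seq(0.1, 2, by = 0.1))
  f3 <- tempfile(fileext = ".csv")
  write.csv(ed, f3, row.names = FALSE)
  et <- read_energy_table(f3)
  expect_equal(nrow(et), 20)
  ed$energy_kcal_mol <- as.character(ed$energy_kcal_mol)
  ed$energy_kcal_mol[3] <- "oops"
  write.csv(ed, f3, row.names = FALSE)
  expect_error(read_energy_table(f3), "row 3")
})
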