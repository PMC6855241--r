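test_that("a single-model file reads as a one-frame ensemble", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  N   ALA A   1       1.000   2.000   3.000  1.00  0.00           N",
    "ATOM      2  CA  ALA A   1       2.000   2.000   3.000  1.00  0.00           C",
    "ATOM      3  C   ALA A   1       3.000   2.000   3.000  1.00  0.00           C",
    "ATOM      4  O   ALA A   1       3.500   3.000   3.000  1.00  0.00           O",
    "ATOM      5  CB  ALA A   1       2.000   0.500   3.000  1.00  0.00           C",
    "END"), f)
  e <- read_multimodel_pdb(f)
  expect_equal(n_frames(e), 1L)
  expect_equal(n_atoms(e), 5L)
  expect_equal(get_frame(e, 1)[2, ], c(2, 2, 3))
  expect_equal(e$topology$residue_name[1], "ALA")
})

test_that("write/read round-trips coordinates to format precision", {
  e <- make_gnm_ensemble(10, n_frames = 4, seed = 7)
  f <- withr::local_tempfile(fileext = ".pdb")
  write_multimodel_pdb(e, f)
  expect_equal(sum(grepl("^MODEL", readLines(f))), 4L)
  e2 <- read_multimodel_pdb(f)
  expect_equal(n_frames(e2), 4L)
  for (i in 1:4)
    expect_equal(get_frame(e2, i), get_frame(e, i), tolerance = 2e-3)
  # second pass is exact: 3-decimal values survive unchanged
  f2 <- withr::local_tempfile(fileext = ".pdb")
  write_multimodel_pdb(e2, f2)
  e3 <- read_multimodel_pdb(f2)
  expect_identical(e3$frames, e2$frames)
  expect_identical(e3$topology$atom_name, e2$topology$atom_name)
})

test_that("round-trip output agrees with an independent PDB reader", {
  skip_if_not_installed("bio3d")
  e <- make_gnm_ensemble(6, n_frames = 2, seed = 1)
  f <- withr::local_tempfile(fileext = ".pdb")
  write_multimodel_pdb(e, f)
  p <- bio3d::read.pdb(f, multi = TRUE, verbose = FALSE)
  expect_equal(nrow(p$xyz), 2L)
  ours <- read_multimodel_pdb(f)
  expect_equal(matrix(p$xyz[2, ], ncol = 3, byrow = TRUE),
               get_frame(ours, 2), ignore_attr = TRUE)
})

test_that("inconsistent MODELs raise a topology-mismatch error", {
  e <- make_gnm_ensemble(5, n_frames = 2, seed = 1)
  f <- withr::local_tempfile(fileext = ".pdb")
  write_multimodel_pdb(e, f)
  ln <- readLines(f)
  atom_lines <- which(startsWith(ln, "ATOM"))
  writeLines(ln[-atom_lines[7]], f)  # drop one atom from MODEL 2
  expect_error(read_multimodel_pdb(f), "topology mismatch.*MODEL 2")
})

test_that("malformed coordinate fields are reported with a line number", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  CA  ALA A   1       1.000   2.000   3.000  1.00  0.00           C",
    "ATOM      2  CA  ALA A   2       xx.xxx   2.000   3.000  1.00  0.00           C"),
    f)
  expect_error(read_multimodel_pdb(f), "line 2")
})

test_that("altloc resolution keeps the highest-occupancy conformer", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  CA AALA A   1       1.000   0.000   0.000  0.40  0.00           C",
    "ATOM      2  CA BALA A   1       2.000   0.000   0.000  0.60  0.00           C",
    "ATOM      3  CB AALA A   1       3.000   0.000   0.000  0.50  0.00           C",
    "ATOM      4  CB BALA A   1       4.000   0.000   0.000  0.50  0.00           C",
    "END"), f)
  e <- read_multimodel_pdb(f)
  expect_equal(n_atoms(e), 2L)
  expect_equal(get_frame(e, 1)[, 1], c(2, 3))  # B wins on occupancy, A on tie
})

test_that("residue numbers beyond the fixed-width field refuse to write", {
  e <- make_gnm_ensemble(3, n_frames = 2, seed = 1)
  e$topology$residue_number[3] <- 10000L
  expect_error(write_multimodel_pdb(e, withr::local_tempfile()), "9999")
})

test_that("energy and score tables round-trip and validate their schema", {
  tab <- make_energy_table(10, means = c(E_vdw = -40, G_psolv = 7),
                           sds = c(E_vdw = 2, G_psolv = 1), seed = 3)
  f <- withr::local_tempfile(fileext = ".tsv")
  write.table(tab, f, sep = "\t", quote = FALSE, row.names = FALSE)
  back <- read_energy_table(f)
  expect_equal(as.data.frame(back), as.data.frame(tab), tolerance = 1e-12)

  # header-only file is a degenerate input, not an empty table
  writeLines("E_vdw\tE_ele\tE_int\tG_psolv\tG_npsolv", f)
  expect_error(read_energy_table(f), "no rows")

  writeLines(c("E_vdw\tE_ele\tE_int\tG_psolv", "-1\t0\t0\t2"), f)
  expect_error(read_energy_table(f), "G_npsolv")

  s <- make_screening_scores(5, 7, d = 1, seed = 2)
  g <- withr::local_tempfile(fileext = ".csv")
  write.csv(s, g, row.names = FALSE, quote = FALSE)
  s2 <- read_score_table(g)
  expect_equal(s2$score, s$score, tolerance = 1e-12)

  # one-class tables pass ingestion; ROC construction rejects them later
  one <- s[s$label == "decoy", ]
  write.csv(one, g, row.names = FALSE, quote = FALSE)
  expect_s3_class(read_score_table(g), "score_table")
  expect_error(roc_points(read_score_table(g)), "at least one")

  dup <- s; dup$ligand_id[2] <- dup$ligand_id[1]
  write.csv(dup, g, row.names = FALSE, quote = FALSE)
  expect_error(read_score_table(g), "duplicate ligand_id")
})

test_that("residue selections resolve by chain/number and atom class", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  N   GLY A  10       0.000   0.000   0.000  1.00  0.00           N",
    "ATOM      2  CA  GLY A  10       1.000   0.000   0.000  1.00  0.00           C",
    "ATOM      3  C   GLY A  10       2.000   0.000   0.000  1.00  0.00           C",
    "ATOM      4  O   GLY A  10       3.000   0.000   0.000  1.00  0.00           O",
    "ATOM      5  N   ALA A  11       4.000   0.000   0.000  1.00  0.00           N",
    "ATOM      6  CA  ALA A  11       5.000   0.000   0.000  1.00  0.00           C",
    "ATOM      7  CB  ALA A  11       6.000   0.000   0.000  1.00  0.00           C",
    "END"), f)
  e <- read_multimodel_pdb(f)
  sel <- select_residues(e, residue_selection("A", 10), atoms = "backbone")
  expect_length(sel[["A:10"]], 4L)
  expect_equal(selection_atoms(select_residues(e, residue_selection("A", 11),
                                               atoms = "sidechain")), 7L)
  # empty selection, missing residue, name mismatch
  expect_length(select_residues(e, residue_selection(character(0), integer(0))), 0L)
  expect_error(select_residues(e, residue_selection("B", 10)), "B:10")
  expect_error(select_residues(e, residue_selection("A", 10, resname = "TRP")),
               "mismatch")
  # disjoint selections give disjoint atom sets
  a <- selection_atoms(select_residues(e, residue_selection("A", 10)))
  b <- selection_atoms(select_residues(e, residue_selection("A", 11)))
  expect_length(intersect(a, b), 0L)
})

test_that("selection files and numbering maps load from TSV", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("chain\tresnum", "A\t195", "B\t28"), f)
  sel <- read_selection_tsv(f, label = "PPI_pocket")
  expect_equal(selection_keys(sel), c("A:195", "B:28"))
  g <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("key\tgeneric", "A:195\t5.34", "A:28\tN-term"), g)
  bw <- read_generic_numbering(g)
  expect_equal(unname(bw["A:195"]), "5.34")
})
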