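# System construction, PDB and TRJF I/O, atom selection

test_that("PDB parsing sets solute/mainchain flags and survives a round trip", {
  sys <- gen_peptide_system(5, "helix")
  lines <- write_structure(sys)
  re <- parse_structure(lines)
  expect_equal(n_atoms(re), n_atoms(sys))
  expect_equal(re$atoms$name, sys$atoms$name)
  expect_equal(re$atoms$resid, sys$atoms$resid)
  expect_equal(re$reference, round(sys$reference, 3), ignore_attr = TRUE)
  expect_true(all(re$atoms$is_solute))
  expect_true(all(re$atoms$is_mainchain[re$atoms$name %in% c("N", "CA", "C", "O")]))
  # second round trip is exact
  re2 <- parse_structure(write_structure(re))
  expect_equal(re2$reference, re$reference, ignore_attr = TRUE)
  expect_equal(re2$atoms$donor, re$atoms$donor)
})

test_that("minimal PDB text parses; ions and waters are flagged non-solute", {
  pdb <- c(
    "ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00  0.00           N",
    "ATOM      2  CA  ALA A   1       1.460   0.000   0.000  1.00  0.00           C",
    "ATOM      3  C   ALA A   1       2.000   1.400   0.000  1.00  0.00           C",
    "HETATM    4 CA    CA A 301       8.000   8.000   8.000  1.00  0.00          CA",
    "HETATM    5 CA    CA A 302      12.000   8.000   8.000  1.00  0.00          CA",
    "HETATM    6  OW  HOH A 401      20.000  20.000  20.000  1.00  0.00           O",
    "END")
  sys <- parse_structure(pdb)
  expect_equal(n_atoms(sys), 6)
  expect_equal(sys$atoms$is_solute, c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE))
  expect_true(all(sys$atoms$is_mainchain[1:3]))
  expect_equal(length(unique(sys$atoms$resid)), 4)
})

test_that("malformed and empty PDB input raise informative errors", {
  bad <- "ATOM      1  N   ALA A   1       0.000   xxx.000   0.000"
  expect_error(parse_structure(bad), "line 1")
  expect_error(parse_structure("REMARK nothing here"), "empty input")
})

test_that("TRJF round trip is lossless at the declared precision", {
  toy <- gen_toy_protein_solvent(n_residues = 6, n_waters = 2,
                                 schedule = "none", n_frames = 5, seed = 1)
  path <- withr::local_tempfile()
  write_trjf(toy$trajectory, path)
  back <- read_trjf(path, toy$system)
  expect_equal(n_frames(back), 5)
  expect_equal(back$xyz, round(toy$trajectory$xyz, 6), ignore_attr = TRUE)
  expect_equal(back$times, toy$trajectory$times)
})

test_that("TRJF readers reject malformed files", {
  toy <- gen_toy_protein_solvent(n_residues = 6, n_waters = 0,
                                 schedule = "none", n_frames = 3, seed = 1)
  path <- withr::local_tempfile()
  write_trjf(toy$trajectory, path)
  lines <- readLines(path)
  # drop one coordinate line from the second frame block
  at2 <- grep("^frame 2", lines)
  truncated <- lines[-(at2 + 1L)]
  p2 <- withr::local_tempfile(lines = truncated)
  expect_error(read_trjf(p2, toy$system), "frame 2 has")
  # non-monotone times
  lines2 <- sub("^frame 3 time .*$", "frame 3 time 0.000001", lines)
  p3 <- withr::local_tempfile(lines = lines2)
  expect_error(read_trjf(p3, toy$system), "strictly increasing")
  # atom-count mismatch against the system
  other <- gen_peptide_system(3, "helix")
  expect_error(read_trjf(path, other), "does not match")
})

test_that("multi-model PDB reads as a trajectory", {
  toy <- gen_toy_protein_solvent(n_residues = 5, n_waters = 0,
                                 schedule = "none", n_frames = 3, seed = 2)
  path <- withr::local_tempfile(fileext = ".pdb")
  con <- file(path, "w")
  for (k in 1:3) {
    writeLines(sprintf("MODEL     %4d", k), con)
    writeLines(write_structure(toy$system,
                               coords = frame_coords(toy$trajectory, k)),
               con)
    writeLines("ENDMDL", con)
  }
  close(con)
  tr <- read_trajectory_pdb(path)
  expect_equal(n_frames(tr), 3)
})

test_that("trajectory constructor validates times and coordinates", {
  sys <- gen_peptide_system(3, "helix")
  n3 <- 3 * n_atoms(sys)
  good <- matrix(0, 2, n3)
  expect_error(sd_trajectory(sys, good, times = c(2, 1)),
               "strictly increasing")
  bad <- good; bad[1, 1] <- NaN
  expect_error(sd_trajectory(sys, bad), "non-finite")
  expect_error(sd_trajectory(sys, matrix(0, 2, n3 - 1)), "columns")
})

test_that("selection grammar matches the documented keywords", {
  toy <- gen_toy_protein_solvent(n_residues = 10, n_waters = 3,
                                 schedule = "none", n_frames = 2, seed = 1)
  sys <- toy$system
  ca <- select_atoms(sys, "name CA and solute")
  expect_equal(length(ca), 10)
  expect_equal(sys$atoms$name[ca], rep("CA", 10))
  mc <- select_atoms(sys, "mainchain")
  expect_true(all(sys$atoms$is_mainchain[mc]))
  expect_equal(sort(c(select_atoms(sys, "solute"),
                      select_atoms(sys, "not solute"))),
               seq_len(n_atoms(sys)))
  expect_equal(select_atoms(sys, "resid 2:4 and name CA"),
               select_atoms(sys, "(resid 2 or resid 3 or resid 4) and name CA"))
  prot <- gen_peptide_system(4, "helix")
  expect_warning(empty <- select_atoms(prot, "not solute"), "no atoms")
  expect_length(empty, 0)
  expect_error(select_atoms(prot, "nonsense keyword"), "syntax error")
})

test_that("selection algebra: |A and B| + |A or B| = |A| + |B|", {
  toy <- gen_toy_protein_solvent(n_residues = 12, n_waters = 4,
                                 schedule = "none", n_frames = 2, seed = 3)
  sys <- toy$system
  pairs <- list(c("name CA", "resid 3:9"),
                c("mainchain", "heavy"),
                c("solvent", "name OW"),
                c("hydrogen", "resid 1:6"))
  for (p in pairs) {
    a <- length(select_atoms(sys, p[1]))
    b <- length(select_atoms(sys, p[2]))
    ab <- length(select_atoms(sys, paste(p[1], "and", p[2])))
    aob <- length(select_atoms(sys, paste(p[1], "or", p[2])))
    expect_equal(ab + aob, a + b, info = paste(p, collapse = " / "))
  }
})

test_that("analysis_config validates its cutoffs", {
  cfg <- analysis_config()
  expect_equal(cfg$hb_distance_cutoff, 3.5)
  expect_equal(cfg$hb_angle_cutoff, 120)
  expect_equal(cfg$native_contact_cutoff, 6.0)
  expect_error(analysis_config(hb_distance_cutoff = -1))
  expect_error(analysis_config(hb_angle_cutoff = 200))
})
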