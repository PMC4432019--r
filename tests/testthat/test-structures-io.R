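test_that("read_pdb parses minimal ATOM records with coordinates and B-factors", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  CA  GLY A   1       1.000   2.000   3.000  1.00 10.00           C",
    "ATOM      2  CA  ALA A   2       4.500  -1.250   0.000  1.00 20.50           C"),
    f)
  st <- read_pdb(f)
  expect_equal(nrow(st$atoms), 2)
  expect_equal(st$atoms$x, c(1, 4.5))
  expect_equal(st$atoms$y, c(2, -1.25))
  expect_equal(st$atoms$b, c(10, 20.5))
  expect_equal(st$atoms$resno, c(1, 2))
})

test_that("read_pdb errors on missing files and empty structures", {
  expect_error(read_pdb(tempfile()), "no such file")
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines("REMARK nothing here", f)
  expect_error(read_pdb(f))
})

test_that("alternate locations resolve to highest occupancy, ties alphabetical", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  CA AGLY A   1       0.000   0.000   0.000  0.60 10.00           C",
    "ATOM      2  CA BGLY A   1       9.000   9.000   9.000  0.40 10.00           C",
    "ATOM      3  CA CALA A   2       1.000   1.000   1.000  0.50 10.00           C",
    "ATOM      4  CA DALA A   2       2.000   2.000   2.000  0.50 10.00           C"),
    f)
  st <- read_pdb(f)
  expect_equal(nrow(st$atoms), 2)
  expect_equal(st$atoms$altloc, c("A", "C"))
  expect_equal(st$atoms$x, c(0, 1))
})

test_that("fixture bead sets round-trip through PDB text at column precision", {
  for (ns in list(fixture_linear_chain(5, 3.8),
                  fixture_random_connected(15, 25, seed = 3))) {
    f <- withr::local_tempfile(fileext = ".pdb")
    write_pdb(ns, f)
    st <- read_pdb(f)
    back <- assemble_state(st, "apo")
    expect_equal(back$xyz, ns$xyz, tolerance = 1e-3, ignore_attr = TRUE)
    expect_equal(back$labels$resno, ns$labels$resno)
  }
})

test_that("apo assembly keeps protein beads only, independent of ligand model", {
  st <- synthetic_structure_cached()
  apo_c <- assemble_state(st, "apo", ligand_model = "centroid")
  apo_h <- assemble_state(st, "apo", ligand_model = "heavy_atoms")
  expect_equal(length(apo_c), 420)
  expect_true(all(apo_c$labels$kind == "protein"))
  expect_identical(apo_c$xyz, apo_h$xyz)
})

test_that("holo assembly appends ligand beads after protein beads", {
  st <- synthetic_structure_cached()
  h1 <- assemble_state(st, "holo1")
  h2 <- assemble_state(st, "holo2")
  expect_equal(length(h1), 421)
  expect_equal(length(h2), 422)
  expect_equal(sum(h2$labels$kind == "ligand"), 2)
  # holo2 contains holo1's beads as a prefix-consistent subset
  expect_identical(h2$xyz[seq_len(421), ], h1$xyz)
  # ligand beads come last
  expect_equal(which(h2$labels$kind == "ligand"), c(421L, 422L))
})

test_that("centroid ligand bead sits at the heavy-atom centroid", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  CA  GLY A   1       0.000   0.000   5.000  1.00 10.00           C",
    "ATOM      2  CA  GLY A   2       3.800   0.000   5.000  1.00 10.00           C",
    "ATOM      3  CA  GLY A   3       7.600   0.000   5.000  1.00 10.00           C",
    "ATOM      4  CA  GLY A   4      11.400   0.000   5.000  1.00 10.00           C",
    "HETATM    5  C1  CMP A 301       0.000   0.000   0.000  1.00 30.00           C",
    "HETATM    6  C2  CMP A 301       3.000   0.000   0.000  1.00 30.00           C",
    "HETATM    7  O1  CMP A 301       0.000   3.000   0.000  1.00 30.00           O"),
    f)
  st <- read_pdb(f)
  apo <- assemble_state(st, "apo")
  expect_equal(length(apo), 4)
  h1 <- assemble_state(st, "holo1")
  expect_equal(unname(h1$xyz[5, ]), c(1, 1, 0))
  expect_error(assemble_state(st, "holo2"), "ligand group")
})

test_that("residues lacking a CA atom are skipped with a warning", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  CA  GLY A   1       0.000   0.000   0.000  1.00 10.00           C",
    "ATOM      2  CB  ALA A   2       3.000   0.000   0.000  1.00 10.00           C",
    "ATOM      3  CA  GLY A   3       6.000   0.000   0.000  1.00 10.00           C"),
    f)
  st <- read_pdb(f)
  expect_warning(ns <- assemble_state(st, "apo"), "lack a CA")
  expect_equal(ns$labels$resno, c(1L, 3L))
})

test_that("fixtures are deterministic and geometrically correct", {
  tb <- fixture_two_bead(1)
  expect_equal(unname(tb$xyz), rbind(c(0, 0, 0), c(1, 0, 0)))
  lc <- fixture_linear_chain(3, 5)
  expect_equal(unname(lc$xyz[, 1]), c(0, 5, 10))
  expect_true(all(lc$xyz[, 2:3] == 0))
  a <- fixture_random_connected(20, 30, seed = 7)
  b <- fixture_random_connected(20, 30, seed = 7)
  expect_identical(a$xyz, b$xyz)
  expect_false(identical(a$xyz, fixture_random_connected(20, 30, seed = 8)$xyz))
})

test_that("node_set enforces its invariants", {
  lab <- data.frame(chain = "A", resno = 1:2, kind = "protein", name = "GLY")
  expect_error(node_set(lab, matrix(0, 2, 2)), "3 columns")
  expect_error(node_set(lab, rbind(c(0, 0, 0), c(NA, 0, 0))), "finite")
  expect_error(node_set(lab[1, ], matrix(0, 1, 3)), "at least 2")
  expect_error(node_set(rbind(lab[1, ], lab[1, ]), matrix(0:5, 2, 3)),
               "duplicate")
  expect_error(node_set(lab, matrix(0:5, 2, 3), masses = c(1, -1)), "positive")
})

test_that("the synthetic homodimer has the documented architecture", {
  st <- synthetic_structure_cached()
  a <- st$atoms
  expect_equal(sum(a$record == "ATOM" & a$chain == "A"), 210)
  expect_equal(sum(a$record == "ATOM" & a$chain == "B"), 210)
  expect_equal(sort(unique(a$resname[a$record == "HETATM"])), "CMP")
  # C2 symmetry: chain B is chain A rotated by pi about z
  xa <- as.matrix(a[a$record == "ATOM" & a$chain == "A", c("x", "y", "z")])
  xb <- as.matrix(a[a$record == "ATOM" & a$chain == "B", c("x", "y", "z")])
  expect_equal(unname(xb), unname(xa %*% diag(c(-1, -1, 1))))
  # consecutive C-alphas at virtual bond length 3.8
  bonds <- sqrt(rowSums((xa[-1, ] - xa[-210, ])^2))
  expect_true(all(abs(bonds - 3.8) < 0.2))
  # generation is deterministic given the seed
  st2 <- synthetic_cap_structure(seed = 1L)
  expect_identical(st$atoms, st2$atoms)
})
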