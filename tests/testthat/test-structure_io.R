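# Parsing, residue normalization, altloc resolution and loop finding.

test_that("residue names normalize to canonical bases", {
  expect_identical(normalize_residue("DT"), list(code = "T", is_modified = FALSE))
  expect_identical(normalize_residue("U"), list(code = "U", is_modified = FALSE))
  # brominated uridine (HETATM-encoded in the native DNA/RNA structures)
  expect_identical(normalize_residue("BRU"), list(code = "U", is_modified = TRUE))
  expect_warning(res <- normalize_residue("XYZ"), "unknown residue")
  expect_true(is.na(res$code))
})

test_that("altloc resolution keeps the highest occupancy, tie goes to A", {
  mk <- function(occs, alts) {
    residue_record("A", 1L, "T", data.frame(
      name = rep("C1'", length(occs)), element = "C",
      x = seq_along(occs), y = 0, z = 0,
      occupancy = occs, altloc = alts, b_factor = 0))
  }
  r <- resolve_altlocs(mk(c(0.6, 0.4), c("A", "B")))
  expect_equal(nrow(r$atoms), 1)
  expect_equal(r$atoms$altloc, "A")
  r <- resolve_altlocs(mk(c(0.5, 0.5), c("B", "A")))
  expect_equal(r$atoms$altloc, "A")
  r <- resolve_altlocs(mk(c(0.3, 0.7), c("A", "B")))
  expect_equal(r$atoms$altloc, "B")
  single <- mk(1, "")
  expect_identical(resolve_altlocs(single), single)
})

test_that("multi-model files yield one structure model per MODEL block", {
  lines <- c(
    "MODEL        1",
    pdb_line("ATOM", 1, "C1'", " ", "DT", "A", 1, 1, 2, 3),
    pdb_line("ATOM", 2, "N1", " ", "DT", "A", 1, 2, 2, 3),
    "ENDMDL",
    "MODEL        2",
    pdb_line("ATOM", 1, "C1'", " ", "DT", "A", 1, 1.5, 2, 3),
    pdb_line("ATOM", 2, "N1", " ", "DT", "A", 1, 2.5, 2, 3),
    "ENDMDL", "END")
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(lines, f)
  models <- read_structure(f)
  expect_length(models, 2)
  for (m in models) {
    expect_length(m$chains, 1)
    expect_length(m$chains$A, 1)
  }
  expect_equal(models[[1]]$chains$A[[1]]$atoms$x[1], 1)
  expect_equal(models[[2]]$chains$A[[1]]$atoms$x[1], 1.5)
})

test_that("water-only files give a zero-chain model with a warning", {
  lines <- c(pdb_line("HETATM", 1, "O", " ", "HOH", "A", 1, 0, 0, 0),
             pdb_line("HETATM", 2, "O", " ", "HOH", "A", 2, 3, 0, 0),
             "END")
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(lines, f)
  models <- read_structure(f)
  expect_length(models[[1]]$chains, 0)
})

test_that("HETATM-encoded modified nucleotides join the chain", {
  lines <- c(pdb_line("HETATM", 1, "C1'", " ", "BRU", "A", 1, 0, 0, 0),
             pdb_line("HETATM", 2, "N1", " ", "BRU", "A", 1, 1.4, 0, 0),
             pdb_line("ATOM", 3, "C1'", " ", "DA", "A", 2, 5, 0, 0),
             "END")
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(lines, f)
  m <- read_structure(f)[[1]]
  expect_equal(vapply(m$chains$A, `[[`, "", "code"), c("U", "A"))
  expect_true(m$chains$A[[1]]$is_modified)
  expect_false(m$chains$A[[2]]$is_modified)
})

test_that("ligand residues are excluded from chains with a warning", {
  lines <- c(pdb_line("ATOM", 1, "C1'", " ", "DT", "A", 1, 0, 0, 0),
             pdb_line("HETATM", 2, "C1", " ", "LIG", "A", 2, 8, 0, 0),
             "END")
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(lines, f)
  expect_warning(m <- read_structure(f)[[1]], "LIG")
  expect_length(m$chains$A, 1)
})

test_that("unparseable files raise a fatal parse error", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines("this is not a coordinate file", f)
  expect_error(read_structure(f), "cannot parse")
  expect_error(read_structure(file.path(tempdir(), "no_such_file.pdb")),
               "not found")
})

test_that("loops are found between G-tracts on the telomeric layouts", {
  # unimolecular 22-mer: three loops at positions 5-7, 11-13, 17-19
  m <- build_chain("AGGGTTAGGGTTAGGGTTAGGG")
  loops <- find_loops(m)
  expect_length(loops, 3)
  expect_equal(lapply(loops, `[[`, "positions"),
               list(5:7, 11:13, 17:19))
  expect_true(all(vapply(loops, `[[`, TRUE, "resolved")))

  # bimolecular half: one loop per chain, flanking residues never loop
  half <- build_chain("TAGGGTTAGGGT")
  bim <- structure_model("bimol", list(A = half$chains$A,
                                       B = half$chains$A))
  loops <- find_loops(bim)
  expect_length(loops, 2)
  expect_equal(vapply(loops, `[[`, "", "chain_id"), c("A", "B"))
  expect_equal(loops[[1]]$positions, 6:8)

  # no inter-tract segment, no loop
  expect_length(find_loops(build_chain("GGGG")), 0)
})

test_that("non-matching inter-tract segments warn and are not typed", {
  m <- build_chain("GGGTAGGG")
  expect_warning(loops <- find_loops(m), "does not match")
  expect_length(loops, 0)
})

test_that("loops with missing core atoms are flagged unresolved", {
  m <- build_toy_quadruplex(drop_atoms = list(list(seq = 12, atom = "O4'")))
  loops <- find_loops(m)
  expect_length(loops, 3)
  expect_equal(vapply(loops, `[[`, TRUE, "resolved"),
               c(TRUE, FALSE, TRUE))
})

test_that("PDB write/read round trip preserves names, codes, coordinates", {
  f <- withr::local_tempfile(fileext = ".pdb")
  m <- build_toy_quadruplex(c(1, 9, 4), path = f)
  m2 <- read_structure(f)[[1]]
  expect_equal(length(m2$chains$A), length(m$chains$A))
  for (i in seq_along(m$chains$A)) {
    a <- m$chains$A[[i]]$atoms
    b <- m2$chains$A[[i]]$atoms
    expect_identical(m2$chains$A[[i]]$code, m$chains$A[[i]]$code)
    expect_setequal(b$name, a$name)
    j <- match(a$name, b$name)
    # PDB columns carry three decimals
    expect_equal(as.matrix(b[j, c("x", "y", "z")]),
                 as.matrix(a[, c("x", "y", "z")]),
                 tolerance = 1e-3, ignore_attr = TRUE)
  }
})

test_that("loop finding is invariant to chain order and rigid motion", {
  half <- build_chain("TAGGGTTAGGGT")
  ab <- structure_model("x", list(A = half$chains$A, B = half$chains$A))
  ba <- structure_model("x", list(B = half$chains$A, A = half$chains$A))
  seqs <- function(loops) {
    sort(vapply(loops, function(l) {
      paste(l$chain_id, paste(l$positions, collapse = ","))
    }, ""))
  }
  expect_identical(seqs(find_loops(ab)), seqs(find_loops(ba)))

  set.seed(11)
  m <- build_toy_quadruplex(c(1, 9, 4))
  mt <- transform_model(m, random_rotation(), rnorm(3, sd = 20))
  expect_identical(lapply(find_loops(mt), `[[`, "positions"),
                   lapply(find_loops(m), `[[`, "positions"))
})
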