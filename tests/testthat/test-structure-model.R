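test_that("a generated hairpin survives a write/parse round trip", {
  hp <- hairpin_g()
  s <- hp$struct
  f <- withr::local_tempfile(fileext = ".pdb")
  write_structure(s, f)
  s2 <- parse_structure(f)
  expect_equal(s2$atom$name, s$atom$name)
  expect_equal(s2$atom$resno, s$atom$resno)
  expect_equal(s2$atom$resid, s$atom$resid)
  expect_equal(s2$xyz, s$xyz, tolerance = 1e-3)

  # a second round trip is byte-identical: coordinates are already on
  # the fixed 8.3 grid
  f2 <- withr::local_tempfile(fileext = ".pdb")
  write_structure(s2, f2)
  expect_identical(readLines(f), readLines(f2))
})

test_that("parsing rejects unusable input", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines("REMARK nothing here", f)
  expect_error(parse_structure(f), "no protein ATOM")
  expect_error(parse_structure(tempfile()), "not found")
})

test_that("multi-model files with mismatched atoms name the model", {
  hp <- hairpin_g()
  f <- withr::local_tempfile(fileext = ".pdb")
  at <- hp$struct$atom
  lines <- readLines({write_structure(hp$struct, f); f})
  atom_lines <- grep("^ATOM", lines, value = TRUE)
  con <- c("MODEL        1", atom_lines, "ENDMDL",
           "MODEL        2", atom_lines[-5], "ENDMDL", "END")
  writeLines(con, f)
  expect_error(parse_structure(f), "model 2")
})

test_that("HETATM and waters are excluded from the atom table", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  N   GLY A 107      11.104   6.134  -6.504  1.00  0.00           N",
    "ATOM      2  CA  GLY A 107      12.560   6.071  -6.342  1.00  0.00           C",
    "ATOM      3  C   GLY A 107      13.075   7.244  -5.514  1.00  0.00           C",
    "HETATM    4  O   HOH A 201      20.000  20.000  20.000  1.00  0.00           O",
    "END"), f)
  s <- parse_structure(f)
  expect_equal(nrow(s$atom), 3)
  expect_false(any(s$atom$resid == "HOH"))
})

test_that("IMGT anchoring finds 104/107 from the CDR3 sequence", {
  hp <- hairpin_g()
  a <- anchor_of(hp)
  expect_equal(a$residues$aa[a$pos104], "C")
  expect_equal(a$residues$aa[a$pos107], "G")
  expect_equal(a$pos107, a$pos104 + 3L)
  expect_equal(length(a$loop_idx), 14)  # full CDR3, chain ends at 117

  hs <- hairpin_s()
  as_ <- anchor_of(hs)
  expect_equal(as_$residues$aa[as_$pos107], "S")
})

test_that("anchoring validates its inputs", {
  hp <- hairpin_g()
  expect_error(anchor_imgt(hp$struct, "A", "ASSDAGG"),
               "must start with the conserved C")
  expect_error(anchor_imgt(hp$struct, "A", "CWWWWDAG"), "not found")
  expect_error(anchor_imgt(hp$struct, "Z", "CASGDAGGGYEQYF"), "no chain")
})

test_that("ambiguous CDR3 matches are rejected", {
  hp <- hairpin_g()
  at <- structure_atoms(hp$struct)
  shifted <- at[at$resno >= 104, ]
  shifted$resno <- shifted$resno + 100L
  shifted$x <- shifted$x + 50
  dup <- structure_from_atoms(rbind(at, shifted), pdb_id = "dup")
  expect_error(anchor_imgt(dup, "A", "CASGDAGGGYEQYF"), "ambiguous")
})

test_that("pos107 is the 4th CDR3 residue for assorted loop sequences", {
  for (seq in c("CASGDAGGGYEQYF", "CASSDWVSYEQYF", "CAWSVGNTFREG")) {
    hp <- make_hairpin(hairpin_spec(loop_sequence = seq,
                                    include_y40 = FALSE),
                       name = "tmp")
    a <- anchor_imgt(hp$struct, "A", seq)
    expect_equal(a$residues$aa[a$pos107], substr(seq, 4, 4))
  }
})

test_that("Y40 is located by author number or unique-Tyr window", {
  hp <- hairpin_g()
  a_num <- anchor_imgt(hp$struct, "A", "CASGDAGGGYEQYF",
                       y40_author_number = 40)
  a_win <- anchor_imgt(hp$struct, "A", "CASGDAGGGYEQYF")
  expect_equal(a_num$pos40, a_win$pos40)
  expect_equal(a_num$residues$resno[a_num$pos40], 40)
  expect_equal(a_num$residues$resno[a_num$pos42], 42)

  # alanine at 40 means no tyrosine to anchor
  ha <- hairpin_ala40()
  a40 <- anchor_of(ha)
  expect_null(a40$pos40)
  expect_null(a40$pos42)
})
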