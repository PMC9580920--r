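# coordinate model, heavy-atom typing and file round trips

test_that("the heavy-atom type scheme has 85 entries with the right per-base counts", {
  tab <- atomTypeTable()
  expect_equal(nrow(tab), 85L)
  expect_equal(as.integer(table(tab$base)[c("A", "C", "G", "U")]),
               c(22L, 20L, 23L, 20L))
  expect_false(anyDuplicated(paste(tab$base, tab$name)) > 0)
})

test_that("atomTypeOf is total: members typed, non-members NA", {
  expect_equal(atomTypeOf("G", "N2"), "G.N2")
  expect_true(is.na(atomTypeOf("U", "N2")))
  expect_true(is.na(atomTypeOf("A", "OP3")))   # terminal phosphate untyped
  expect_true(is.na(atomTypeOf("G", "H1")))
  # vectorised
  expect_equal(atomTypeOf(c("A", "U"), c("N6", "O4")), c("A.N6", "U.O4"))
})

test_that("mmCIF write -> read round trip preserves the model to file precision", {
  dx <- makeDuplex("GGCAUGC")
  f <- withr::local_tempfile(fileext = ".cif")
  writeMmCIF(dx$structure, f)
  s <- readRNAStructure(f)
  a0 <- atomTable(dx$structure); a1 <- atomTable(s)
  expect_identical(a1$name, a0$name)
  expect_identical(a1$base, a0$base)
  expect_identical(a1$residx, a0$residx)
  expect_lt(max(abs(as.matrix(a1[, c("x", "y", "z")]) -
                    as.matrix(a0[, c("x", "y", "z")]))), 1e-3)
  # idempotence: writing the re-read structure gives identical bytes
  f2 <- withr::local_tempfile(fileext = ".cif")
  f3 <- withr::local_tempfile(fileext = ".cif")
  writeMmCIF(s, f2)
  writeMmCIF(readRNAStructure(f2), f3)
  expect_identical(readLines(f2)[-1], readLines(f3)[-1])
})

test_that("reading is deterministic: identical bytes give identical models", {
  dx <- makeHairpin(3, 4, seed = 7)
  f <- withr::local_tempfile(fileext = ".cif")
  writeMmCIF(dx$structure, f)
  expect_identical(atomTable(readRNAStructure(f)),
                   atomTable(readRNAStructure(f)))
})

.gResidueCif <- function(extraLines = character()) {
  # minimal mmCIF: one full G residue (23 heavy atoms) built from the
  # package's own template, plus optional extra atom_site rows
  dx <- makeDuplex("G")
  a <- atomTable(dx$structure)
  g1 <- new("RNAStructure", id = "g1",
            atoms = a[a$chain == "A", , drop = FALSE], log = character())
  f <- tempfile(fileext = ".cif")
  writeMmCIF(g1, f)
  if (length(extraLines)) {
    lines <- readLines(f)
    writeLines(c(lines[-length(lines)], extraLines, "#"), f)
  }
  f
}

test_that("a single-G mmCIF yields one residue with 23 heavy atoms", {
  f <- .gResidueCif()
  s <- readRNAStructure(f)
  expect_equal(structureLength(s), 1L)
  expect_equal(nAtoms(s), 23L)
  expect_equal(residueTable(s)$base, "G")
  unlink(f)
})

test_that("protein chains, waters and hydrogens are filtered with a log", {
  extras <- c(
    "ATOM 900 C CA . ALA P 1 1 ? 0.0 0.0 0.0 1.00 0.00 1 P 1",
    "ATOM 901 N N . ALA P 1 1 ? 1.0 0.0 0.0 1.00 0.00 1 P 1",
    "HETATM 902 O O . HOH W 1 1 ? 9.0 9.0 9.0 1.00 0.00 1 W 1",
    "ATOM 903 H H21 . G A 1 1 ? 0.5 0.5 0.5 1.00 0.00 1 A 1")
  f <- .gResidueCif(extras)
  s <- readRNAStructure(f)
  a <- atomTable(s)
  expect_true(all(a$base %in% c("A", "C", "G", "U")))
  expect_true(all(a$element %in% c("C", "N", "O", "P")))
  expect_false("P" %in% a$chain)
  expect_true(any(grepl("non-standard", processingLog(s))))
  expect_true(any(grepl("non-heavy", processingLog(s))))
  unlink(f)
})

test_that("altloc atoms resolve to the highest-occupancy conformer", {
  f <- .gResidueCif()
  lines <- readLines(f)
  # duplicate the first G atom as altlocs A (occ .4) and B (occ .6)
  row <- grep("^ATOM 1 ", lines, value = TRUE)
  a <- sub(" \\. G", " A G", sub("1\\.00", "0.40", row))
  b <- sub(" \\. G", " B G", sub("1\\.00", "0.60", row))
  b <- sub("\\? (-?[0-9.]+) ", "? 99.000 ", b)   # move B somewhere else
  lines <- lines[!grepl("^ATOM 1 ", lines)]
  writeLines(c(lines[-length(lines)], a, b, "#"), f)
  s <- readRNAStructure(f)
  at <- atomTable(s)
  expect_true(any(abs(at$x - 99) < 1e-6))   # B conformer won
  expect_true(any(grepl("alternate-location", processingLog(s))))
  unlink(f)
})

test_that("multi-model files keep model 1 only", {
  dx <- makeDuplex("GC")
  f <- withr::local_tempfile(fileext = ".cif")
  writeMmCIF(dx$structure, f)
  lines <- readLines(f)
  body <- grep("^ATOM", lines, value = TRUE)
  shifted <- sub(" 1$", " 2", body)
  writeLines(c(lines[-length(lines)], shifted, "#"), f)
  s <- readRNAStructure(f)
  expect_equal(nAtoms(s), length(body))
  expect_true(any(grepl("multi-model", processingLog(s))))
})

test_that("PDB-format files are read through the same contract", {
  dx <- makeDuplex("GGC")
  a <- atomTable(dx$structure)
  f <- withr::local_tempfile(fileext = ".pdb")
  fmt <- "ATOM  %5d %-4s %3s %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s"
  lines <- sprintf(fmt, seq_len(nrow(a)),
                   ifelse(nchar(a$name) < 4, paste0(" ", a$name), a$name),
                   a$base, a$chain, a$resno, a$x, a$y, a$z, a$element)
  writeLines(c(lines, "END"), f)
  s <- readRNAStructure(f)
  expect_equal(structureLength(s), 6L)
  expect_equal(nAtoms(s), nrow(a))
  expect_lt(max(abs(as.matrix(atomTable(s)[, c("x", "y", "z")]) -
                    as.matrix(a[, c("x", "y", "z")]))), 1e-3)
})

test_that("unparseable input and RNA-free input raise the contracted errors", {
  f <- withr::local_tempfile(fileext = ".cif")
  writeLines("this is not a structure file", f)
  expect_error(readRNAStructure(f), "atom_site")
  writeLines(c("data_x", "loop_", "_atom_site.group_PDB",
               "_atom_site.type_symbol", "_atom_site.label_atom_id",
               "_atom_site.label_comp_id", "_atom_site.label_asym_id",
               "_atom_site.auth_seq_id", "_atom_site.Cartn_x",
               "_atom_site.Cartn_y", "_atom_site.Cartn_z",
               "ATOM C CA ALA P 1 0.0 0.0 0.0"), f)
  expect_error(readRNAStructure(f), "no standard RNA residues")
  expect_error(readRNAStructure(tempfile()), "not found")
})

test_that("chain breaks are detected from O3'-P connectivity", {
  dx <- makeDuplex("GGGG")
  links <- chainLinks(dx$structure)
  # residues 1..4 are chain A (linked), 5..8 chain B (linked), no A-B link
  expect_identical(links, c(TRUE, TRUE, TRUE, FALSE, TRUE, TRUE, TRUE))
})
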