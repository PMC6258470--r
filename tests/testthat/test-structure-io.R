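test_that("PDB round trip preserves names, numbering and coordinates", {
  s <- makeToyRna(decoyGenConfig(nNucleotides = 3))
  f <- withr::local_tempfile(fileext = ".pdb")
  writeRnaPdb(s, f)
  r <- readRnaPdb(f)
  expect_equal(nNucleotides(r), 3L)
  a0 <- atomData(s); a1 <- atomData(r)
  expect_equal(a1$elety, a0$elety)
  expect_equal(a1$resno, a0$resno)
  expect_equal(a1$resname, a0$resname)
  expect_equal(as.matrix(a1[, c("x", "y", "z")]),
               as.matrix(a0[, c("x", "y", "z")]),
               tolerance = 1e-3, ignore_attr = TRUE)
})

.pdbLine <- function(serial, name, res, chain, resno, x, y, z, occ = 1,
                     element = substr(name, 1, 1)) {
  sprintf("ATOM  %5d %-4s %3s %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          serial, name, res, chain, resno, x, y, z, occ, 0, element)
}

test_that("model selection picks the requested MODEL and errors when absent", {
  lines <- c("MODEL        1",
             .pdbLine(1, "C1'", "A", "A", 1, 1, 0, 0),
             .pdbLine(2, "N9", "A", "A", 1, 2, 0, 0),
             "ENDMDL",
             "MODEL        2",
             .pdbLine(1, "C1'", "A", "A", 1, 9, 9, 9),
             .pdbLine(2, "N9", "A", "A", 1, 10, 9, 9),
             "ENDMDL", "END")
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(lines, f)
  m1 <- readRnaPdb(f, model = 1)
  m2 <- readRnaPdb(f, model = 2)
  expect_equal(atomData(m1)$x[1], 1)
  expect_equal(atomData(m2)$x[1], 9)
  expect_error(readRnaPdb(f, model = 3), "available models")
})

test_that("non-RNA residues are skipped with a count, RNA retained", {
  lines <- c(.pdbLine(1, "N", "ALA", "B", 1, 0, 0, 0, element = "N"),
             .pdbLine(2, "CA", "ALA", "B", 1, 1, 0, 0, element = "C"),
             .pdbLine(3, "O", "HOH", "B", 2, 5, 5, 5, element = "O"),
             .pdbLine(4, "C1'", "A", "A", 1, 0, 0, 0),
             .pdbLine(5, "N9", "A", "A", 1, 1.5, 0, 0),
             .pdbLine(6, "C1'", "U", "A", 2, 3, 0, 0),
             .pdbLine(7, "N1", "U", "A", 2, 4.5, 0, 0),
             .pdbLine(8, "C1'", "PSU", "A", 3, 6, 0, 0),
             "END")
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(lines, f)
  # independent oracle: scan the raw text for RNA residues
  resInText <- unique(vapply(lines[startsWith(lines, "ATOM")], function(l)
    paste(substr(l, 18, 20), substr(l, 22, 26)), ""))
  rnaCount <- sum(trimws(substr(resInText, 1, 3)) %in%
                    c("A", "U", "G", "C", "PSU"))
  expect_message(s <- readRnaPdb(f), "skipped 2 non-RNA")
  expect_equal(nNucleotides(s), rnaCount)
  # the pseudouridine alias maps to its parent
  expect_equal(nucleotideKeys(s)$resname, c("A", "U", "U"))
})

test_that("alternate locations resolve to highest occupancy, first seen", {
  lines <- c(.pdbLine(1, "C1'", "A", "A", 1, 1, 0, 0, occ = 0.4),
             .pdbLine(2, "C1'", "A", "A", 1, 2, 0, 0, occ = 0.6),
             .pdbLine(3, "N9", "A", "A", 1, 3, 0, 0, occ = 0.5),
             .pdbLine(4, "N9", "A", "A", 1, 4, 0, 0, occ = 0.5),
             "END")
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(lines, f)
  a <- atomData(readRnaPdb(f))
  expect_equal(nrow(a), 2L)
  expect_equal(a$x[a$elety == "C1'"], 2)  # higher occupancy wins
  expect_equal(a$x[a$elety == "N9"], 3)   # tie: first appearance
})

test_that("property assignment covers table, fallback and hydrogen rules", {
  s <- makeToyRna(decoyGenConfig(nNucleotides = 2))
  tab <- atomPropertyTable()
  withProps <- assignAtomProperties(s)
  a <- atomData(withProps)
  # every canonical heavy atom present in the shipped table
  expect_true(all(!is.na(a$mass)) && all(!is.na(a$charge)))
  # total nucleotide mass equals an independent sum over the table
  nuc <- a[a$resno == 2, ]
  expected <- sum(vapply(nuc$elety, function(at)
    tab$mass[tab$resname == "U" & tab$elety == at], numeric(1)))
  expect_equal(sum(nuc$mass), expected, tolerance = 1e-12)
  # idempotence
  twice <- assignAtomProperties(withProps)
  expect_equal(atomData(twice), atomData(withProps))
  # unknown-but-carbon atom falls back to element mass with charge 0
  s2 <- s
  s2@atoms$elety[1] <- "CX9"
  expect_message(p2 <- assignAtomProperties(s2), "fallback")
  expect_equal(atomData(p2)$mass[1], 12.01)
  expect_equal(atomData(p2)$charge[1], 0)
  # hydrogens dropped under the heavy-only default
  s3 <- s
  extra <- s3@atoms[1, ]
  extra$elety <- "H5'"; extra$element <- "H"
  s3@atoms <- rbind(s3@atoms, extra)
  s3@atoms <- s3@atoms[order(s3@atoms$chain, s3@atoms$resno), ]
  p3 <- assignAtomProperties(s3)
  expect_false(any(grepl("^H", atomData(p3)$elety)))
})

test_that("score report has one row per nucleotide plus a matching global", {
  scores <- data.frame(chain = "A", resno = 1:14, resname = "A",
                       score = seq(0.01, 0.14, by = 0.01))
  assess <- new("StructureAssessment", structureId = "fix",
                perNucleotide = scores, globalScore = sum(scores$score),
                skipped = data.frame())
  f <- withr::local_tempfile(fileext = ".tsv")
  jf <- withr::local_tempfile(fileext = ".json")
  writeScoreReport(assess, f, jf)
  tab <- read.delim(f)
  expect_equal(nrow(tab), 15L)              # 14 data rows + global row
  gl <- tab$unfitness_score[tab$chain == "global"]
  expect_equal(gl, sum(scores$score), tolerance = 1e-9)
  js <- jsonlite::read_json(jf)
  expect_equal(js$n_nucleotides, 14L)
  expect_equal(js$global_score, sum(scores$score), tolerance = 1e-9)
  empty <- new("StructureAssessment", structureId = "x",
               perNucleotide = scores[0, ], globalScore = 0,
               skipped = data.frame())
  expect_error(writeScoreReport(empty, f), "no per-nucleotide")
})
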