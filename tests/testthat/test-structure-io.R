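write_mini_pdb <- function(lines, path = tempfile(fileext = ".pdb")) {
  writeLines(c(lines, "END"), path)
  path
}

pdb_line <- function(serial, atom, alt, res, chain, resno, x, y, z,
                     occ = 1, b = 20, el = "C", rec = "ATOM  ") {
  nm <- if (nchar(atom) >= 4) substr(atom, 1, 4) else sprintf(" %-3s", atom)
  sprintf("%s%5d %s%s%-3s %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          rec, serial, nm, alt, res, chain, resno, x, y, z, occ, b, el)
}

test_that("parsing maps records to atom sites, keeps waters/hydrogens flagged", {
  path <- write_mini_pdb(c(
    pdb_line(1, "N", " ", "ALA", "A", 1, 0, 0, 0, el = "N"),
    pdb_line(2, "CA", "A", "ALA", "A", 1, 1.458, 0, 0, occ = 0.5),
    pdb_line(3, "CA", "B", "ALA", "A", 1, 1.458, 0.6, 0, occ = 0.5),
    pdb_line(4, "C", " ", "ALA", "A", 1, 2.0, 1.4, 0),
    pdb_line(5, "H", " ", "ALA", "A", 1, 0, 0, 1, el = "H"),
    pdb_line(6, "O", " ", "HOH", "A", 101, 9, 9, 9, el = "O",
             rec = "HETATM")))
  ch <- parse_structure(path)[["A"]]
  expect_equal(nrow(ch$atoms), 6)
  ca <- ch$atoms[ch$atoms$atom_name == "CA", ]
  expect_setequal(ca$altloc, c("A", "B"))
  expect_true(all(ch$atoms$altloc[ch$atoms$atom_name %in% c("N", "C")] == ""))
  expect_true(ch$atoms$is_hydrogen[ch$atoms$atom_name == "H"])
  expect_true(ch$atoms$is_water[ch$atoms$res_name == "HOH"])
  # waters are not residues
  expect_equal(nrow(ch$residues), 1)
})

test_that("single-conformer files yield all-blank altlocs", {
  path <- write_mini_pdb(c(
    pdb_line(1, "N", " ", "GLY", "A", 1, 0, 0, 0, el = "N"),
    pdb_line(2, "CA", " ", "GLY", "A", 1, 1.4, 0, 0),
    pdb_line(3, "C", " ", "GLY", "A", 1, 2.4, 1, 0)))
  ch <- parse_structure(path)[["A"]]
  expect_true(all(ch$atoms$altloc == ""))
})

test_that("generated fixture has exactly the atom count a line scan finds", {
  spec <- fixture_spec(8, altloc_segments = data.frame(
    start = 3, end = 5, dx = 0.6, dy = 0, dz = 0), seed = 7)
  fx <- make_structure(spec)
  lines <- readLines(fx$path)
  n_records <- sum(grepl("^(ATOM|HETATM)", lines))
  ch <- parse_structure(fx$path)[[1]]
  expect_equal(nrow(ch$atoms), n_records)
  # 5 single residues x 3 atoms + 3 altloc residues x 3 atoms x 2 locations
  expect_equal(n_records, 5 * 3 + 3 * 3 * 2)
})

test_that("requesting an absent chain names the available ones", {
  path <- write_mini_pdb(pdb_line(1, "CA", " ", "ALA", "A", 1, 0, 0, 0))
  expect_error(parse_structure(path, chains = "Q"), "available chains: A")
  expect_error(parse_structure(tempfile()), "does not exist")
})

test_that("relabeling canonicalizes non-standard labels lexicographically", {
  mk <- function(labels) {
    tiny_chain(data.frame(resno = 1, atom = "CA", altloc = labels,
                          x = seq_along(labels), y = 0, z = 0))
  }
  # {A,B} untouched, empty map
  ch <- relabel_altlocs(mk(c("A", "B")))
  expect_equal(ch$atoms$altloc, c("A", "B"))
  expect_length(ch$relabel_map, 0)
  # {Z} -> {A}, map records A -> Z
  ch <- relabel_altlocs(mk("Z"))
  expect_equal(ch$atoms$altloc, "A")
  expect_equal(ch$relabel_map[["1|"]], c(A = "Z"))
  # {Y,Z} -> {A,B} by lexicographic sort
  ch <- relabel_altlocs(mk(c("Z", "Y")))
  expect_equal(sort(ch$atoms$altloc), c("A", "B"))
  expect_equal(ch$atoms$altloc[ch$atoms$original_altloc == "Y"], "A")
  expect_equal(ch$atoms$altloc[ch$atoms$original_altloc == "Z"], "B")
})

test_that("relabeling is idempotent and only ever touches labels", {
  ch0 <- tiny_chain(data.frame(
    resno = c(1, 1, 1, 2, 2), atom = c("CA", "CA", "N", "CA", "CA"),
    altloc = c("P", "Q", "", "A", "B"),
    x = 1:5, y = 0, z = 0, b = c(10, 20, 30, 40, 50)))
  ch1 <- relabel_altlocs(ch0)
  ch2 <- relabel_altlocs(ch1)
  expect_equal(ch1$atoms$altloc, ch2$atoms$altloc)
  expect_equal(ch1$atoms[c("x", "y", "z", "occupancy", "b_factor")],
               ch0$atoms[c("x", "y", "z", "occupancy", "b_factor")])
  expect_equal(ch1$atoms$altloc[1:2], c("A", "B"))
  expect_length(relabel_altlocs(ch1)$relabel_map, 1)
})

test_that("round trip through the PDB writer preserves the structure", {
  spec <- fixture_spec(6, altloc_segments = data.frame(
    start = 2, end = 4, dx = 0.4, dy = 0.2, dz = 0), b_factor = 17.31)
  fx <- make_structure(spec)
  ch <- parse_structure(fx$path)[[1]]
  path2 <- tempfile(fileext = ".pdb")
  write_structure_pdb(ch, path2)
  ch2 <- parse_structure(path2)[[1]]
  expect_equal(nrow(ch2$atoms), nrow(ch$atoms))
  expect_equal(ch2$atoms$x, ch$atoms$x, tolerance = 1e-8)
  expect_equal(ch2$atoms$b_factor, ch$atoms$b_factor, tolerance = 1e-8)
  expect_equal(ch2$atoms$altloc, ch$atoms$altloc)
})

test_that("altloc presence counts the union of backbone labels", {
  # all single -> 1; N,CA,C each {A,B,C} -> 3; CA-only {A,B} -> 2
  ch <- tiny_chain(data.frame(
    resno = c(1, 1, 1,
              rep(2, 9),
              3, 3, 3, 3),
    atom = c("N", "CA", "C",
             rep(c("N", "CA", "C"), each = 3),
             "N", "CA", "CA", "C"),
    altloc = c("", "", "",
               rep(c("A", "B", "C"), 3),
               "", "A", "B", ""),
    x = 1:16, y = 0, z = 0))
  pres <- altloc_presence(ch)
  expect_equal(pres$num_altlocs, c(1, 3, 2))
  expect_equal(pres$altlocs_CA[[3]], c("A", "B"))
  expect_equal(pres$altlocs_N[[3]], character(0))
})
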