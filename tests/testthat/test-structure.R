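pdb_lines <- function(df) {
  strsplit(write_pdb(tibble::as_tibble(df)), "\n")[[1]]
}

two_atom_pdb <- paste(
  "ATOM      1  N   GLY A   1       0.000   0.000   0.000  1.00  0.00           N",
  "ATOM      2  CA  GLY A   1       1.450   0.000   0.000  1.00  0.00           C",
  sep = "\n"
)

test_that("parse_pdb reads ATOM records into residues and atoms", {
  s <- parse_pdb(two_atom_pdb)
  expect_s3_class(s, "protein_structure")
  expect_equal(nrow(s), 2)
  expect_equal(unique(s$resno), 1L)
  expect_equal(s$atom, c("N", "CA"))
  expect_equal(s$element, c("N", "C"))
  expect_equal(s$x, c(0, 1.45))
})

test_that("parse_pdb rejects text without ATOM records and bad coordinates", {
  expect_error(parse_pdb("HELLO"), class = "phorescreen_parse_error")
  bad <- sub("1.450", "x.xxx", two_atom_pdb, fixed = TRUE)
  expect_error(parse_pdb(bad), regexp = "line 2", class = "phorescreen_parse_error")
})

test_that("toy pocket residue count matches a line-scanning oracle", {
  pock <- fx_pocket()
  s <- fx_structure()
  lines <- strsplit(pock$pdb, "\n")[[1]]
  atom_lines <- lines[startsWith(lines, "ATOM")]
  keys <- unique(paste(substr(atom_lines, 22, 22), trimws(substr(atom_lines, 23, 26))))
  expect_equal(
    nrow(dplyr::distinct(tibble::as_tibble(s), chain, resno)),
    length(keys)
  )
})

test_that("write_pdb / parse_pdb round-trips names, keys and coordinates", {
  s <- fx_structure()
  s2 <- parse_pdb(write_pdb(s))
  expect_equal(s2$atom, s$atom)
  expect_equal(s2$resname, s$resname)
  expect_equal(s2$chain, s$chain)
  expect_equal(s2$resno, s$resno)
  expect_equal(round(s2$x, 3), round(s$x, 3))
  expect_equal(round(s2$y, 3), round(s$y, 3))
  expect_equal(round(s2$z, 3), round(s$z, 3))
})

test_that("select_pocket boundary is inclusive and radius is monotone", {
  s <- fx_structure()
  # sphere of radius 0 centered exactly on one atom
  a1 <- tibble::as_tibble(s)[5, ]
  sel <- select_pocket(s, pocket_sphere(c(a1$x, a1$y, a1$z), 0))
  expect_equal(unique(sel$resno), a1$resno)
  # radius beyond the structure diameter keeps every residue
  all_sel <- select_pocket(s, pocket_sphere(c(0, 0, 0), 100))
  expect_equal(nrow(all_sel), nrow(s))
  # monotonicity in radius
  r1 <- select_pocket(s, pocket_sphere(c(0, 0, 0), 7))
  r2 <- select_pocket(s, pocket_sphere(c(0, 0, 0), 9))
  k1 <- unique(paste(r1$chain, r1$resno))
  k2 <- unique(paste(r2$chain, r2$resno))
  expect_true(all(k1 %in% k2))
})

test_that("select_pocket at 6 A equals the brute-force distance oracle", {
  s <- fx_structure()
  sel <- select_pocket(s, pocket_sphere(c(0, 0, 0), 6))
  df <- tibble::as_tibble(s)
  df <- df[!df$element %in% c("H", "D"), ]
  df$d <- sqrt(df$x^2 + df$y^2 + df$z^2)
  oracle <- sort(unique(df$resno[df$d <= 6]))
  expect_equal(sort(unique(sel$resno)), oracle)
})

test_that("interface_residues matches brute force and handles extremes", {
  s <- fx_structure()
  expect_equal(nrow(interface_residues(s, s, 0.1)), nrow(s))
  far <- tibble::as_tibble(s)
  far$x <- far$x + 100
  far <- structure_from_atoms(far)
  expect_equal(nrow(interface_residues(s, far, 5)), 0)
  expect_error(interface_residues(s, s, 0))
  # two 3-residue fixtures vs all-pairs oracle
  mk <- function(xoff) {
    structure_from_atoms(tibble::tibble(
      atom = rep("CA", 3), resname = "GLY", chain = "A", resno = 1:3,
      x = xoff + c(0, 2, 8), y = 0, z = 0
    ))
  }
  a <- mk(0)
  b <- mk(4.2)
  got <- sort(unique(interface_residues(a, b, 4.5)$resno))
  da <- tibble::as_tibble(a)
  db <- tibble::as_tibble(b)
  oracle <- sort(unique(da$resno[vapply(seq_len(nrow(da)), function(i) {
    any(sqrt((db$x - da$x[i])^2 + (db$y - da$y[i])^2 + (db$z - da$z[i])^2) <= 4.5)
  }, logical(1))]))
  expect_equal(got, oracle)
})

test_that("sphere_from_residues covers the selection with padding", {
  one <- structure_from_atoms(tibble::tibble(
    atom = "CA", resname = "GLY", chain = "A", resno = 1, x = 2, y = 3, z = 4
  ))
  sph <- sphere_from_residues(one, tibble::tibble(chain = "A", resno = 1), padding = 0)
  expect_equal(sph$center, c(2, 3, 4))
  expect_equal(sph$radius, 0)
  two <- structure_from_atoms(tibble::tibble(
    atom = c("CA", "CA"), resname = "GLY", chain = "A", resno = 1:2,
    x = c(0, 10), y = 0, z = 0
  ))
  sph2 <- sphere_from_residues(two, tibble::tibble(chain = "A", resno = 1:2), padding = 1)
  expect_equal(sph2$radius, 6)
  expect_error(
    sphere_from_residues(two, tibble::tibble(chain = "A", resno = 9), padding = 0),
    regexp = "not found"
  )
  # toy pocket: sphere over the two glutamates contains all their heavy atoms
  s <- fx_structure()
  key <- fx_pocket()$key_residues
  sph3 <- sphere_from_residues(s, key, padding = 3)
  glu <- dplyr::semi_join(tibble::as_tibble(s), key, by = c("chain", "resno"))
  d <- sqrt((glu$x - sph3$center[1])^2 + (glu$y - sph3$center[2])^2 +
    (glu$z - sph3$center[3])^2)
  expect_true(all(d <= sph3$radius))
})

test_that("pocket_report lists residues with distances, sorted", {
  rep <- pocket_report(fx_structure(), fx_sphere())
  expect_true(all(c("chain", "resno", "resname", "min_dist") %in% names(rep)))
  expect_equal(rep$resno, sort(rep$resno))
  expect_true(all(rep$min_dist <= fx_sphere()$radius))
})
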