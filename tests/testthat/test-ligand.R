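test_that("parse_smiles resolves implicit hydrogens and formulas", {
  eth <- parse_smiles("CCO")
  expect_equal(length(phorescreen:::heavy_idx(eth)), 3)
  expect_equal(ligand_formula(eth), "C2H6O")
  ac73 <- parse_smiles(ac73_smiles(), id = "AC-73")
  expect_equal(length(phorescreen:::heavy_idx(ac73)), 24)
  expect_equal(ligand_formula(ac73), "C21H21NO2")
})

test_that("parse_smiles reports syntax errors with an offset", {
  expect_error(parse_smiles("C("), regexp = "offset", class = "phorescreen_parse_error")
  expect_error(parse_smiles("C)O"), class = "phorescreen_parse_error")
  expect_error(parse_smiles("c1ccccc"), regexp = "ring", class = "phorescreen_parse_error")
  expect_error(parse_smiles(""), class = "phorescreen_parse_error")
})

test_that("mol_weight sums standard atomic weights including implicit H", {
  expect_equal(mol_weight(parse_smiles("O")), 18.015, tolerance = 1e-6)
  expect_equal(mol_weight(parse_smiles("CCO")), 46.069, tolerance = 1e-6)
})

test_that("mol_weight agrees with the ChemmineR reference on assorted molecules", {
  smiles <- c(
    "CCO", "c1ccccc1", "CC(=O)O", "CCN", "c1ccncc1", "CC(C)C",
    "COC", "CS", "CCCl", "OC(=O)c1ccccc1", "CC(N)C(=O)O", ac73_smiles()
  )
  for (s in smiles) {
    lig <- parse_smiles(s)
    sdfset <- suppressWarnings(ChemmineR::read.SDFset(ChemmineR::read.SDFstr(
      strsplit(write_sdf(lig), "\n")[[1]]
    )))
    expect_equal(mol_weight(lig), unname(ChemmineR::MW(sdfset))[1], tolerance = 5e-4)
  }
})

test_that("mol_weight is invariant under atom reordering", {
  lig <- parse_smiles("CC(=O)O")
  n <- nrow(lig$atoms)
  perm <- rev(seq_len(n))
  inv <- order(perm)
  relig <- new_ligand(
    "perm",
    lig$atoms[perm, c("element", "charge")],
    tibble::tibble(
      i = inv[lig$bonds$i], j = inv[lig$bonds$j], order = lig$bonds$order
    ),
    conformers = list(lig$conformers[[1]][perm, ])
  )
  expect_equal(mol_weight(relig), mol_weight(lig))
  f1 <- perceive_ligand_features(lig)
  f2 <- perceive_ligand_features(relig)
  expect_equal(table(f1$kind), table(f2$kind))
})

test_that("SDF round trip preserves atom, bond and coordinate tables", {
  lib <- fx_library()
  txt <- write_sdf(lib$ligands[1:3])
  back <- parse_sdf(txt)
  expect_length(back, 3)
  for (k in 1:3) {
    a <- lib$ligands[[k]]
    b <- back[[k]]
    expect_equal(b$id, a$id)
    expect_equal(b$atoms$element, a$atoms$element)
    expect_equal(b$atoms$charge, a$atoms$charge)
    expect_equal(b$bonds, a$bonds)
    expect_equal(
      round(b$conformers[[1]], 4),
      round(a$conformers[[1]], 4),
      ignore_attr = TRUE
    )
  }
})

test_that("parse_sdf rejects malformed blocks by name", {
  lig <- parse_smiles("CCO")
  txt <- strsplit(write_sdf(lig), "\n")[[1]]
  # claim more atoms than present
  txt[4] <- sub("  9", " 12", txt[4])
  expect_error(parse_sdf(txt), class = "phorescreen_parse_error")
  expect_error(parse_sdf("just\ntwo lines"), class = "phorescreen_parse_error")
})

test_that("logP is table-driven and strictly additive over fragments", {
  methane <- parse_smiles("C")
  # one aliphatic carbon + 4 hydrogens on carbon
  expect_equal(logp_estimate(methane), 0.14 + 4 * 0.10, tolerance = 1e-9)
  etoh <- parse_smiles("CCO")
  expect_equal(
    logp_estimate(etoh),
    2 * 0.14 + (-0.64) + 5 * 0.10 + 1 * (-0.23),
    tolerance = 1e-9
  )
  # disconnected union: logp(A.B) = logp(A) + logp(B)
  ab <- parse_sdf(write_sdf(list(parse_smiles("CC"), parse_smiles("O"))))
  combined <- new_ligand(
    "union",
    dplyr::bind_rows(ab[[1]]$atoms[, 1:2], ab[[2]]$atoms[, 1:2]),
    dplyr::bind_rows(
      ab[[1]]$bonds,
      dplyr::mutate(ab[[2]]$bonds,
        i = i + nrow(ab[[1]]$atoms), j = j + nrow(ab[[1]]$atoms)
      )
    ),
    conformers = list(rbind(ab[[1]]$conformers[[1]], ab[[2]]$conformers[[1]] + 50)),
    multi_fragment = TRUE
  )
  expect_equal(
    logp_estimate(combined),
    logp_estimate(ab[[1]]) + logp_estimate(ab[[2]]),
    tolerance = 1e-9
  )
})

test_that("logS model evaluates its linear form with stated coefficients", {
  expect_equal(logs_from_predictors(0, 0, 0, 0), 0.16)
  # negative MW coefficient: heavier molecule, lower predicted solubility
  expect_lt(
    logs_from_predictors(1, 300, 2, 0.5),
    logs_from_predictors(1, 200, 2, 0.5)
  )
  etoh <- parse_smiles("CCO")
  expect_equal(
    logs_estimate(etoh),
    logs_from_predictors(logp_estimate(etoh), mol_weight(etoh), 0, 0),
    tolerance = 1e-9
  )
})

test_that("ligand feature perception follows the rule table", {
  benzene <- parse_smiles("c1ccccc1", gen3d = TRUE)
  f <- perceive_ligand_features(benzene)
  expect_equal(sum(f$kind == "donor"), 0)
  expect_equal(sum(f$kind == "acceptor"), 0)
  expect_equal(sum(f$kind == "hydrophobic"), 1)
  methane <- parse_smiles("C", gen3d = TRUE)
  expect_equal(nrow(perceive_ligand_features(methane)), 0)
  ac73 <- parse_smiles(ac73_smiles(), id = "AC-73", gen3d = TRUE)
  fa <- perceive_ligand_features(ac73)
  expect_equal(sum(fa$kind == "donor"), 3) # phenol OH, alcohol OH, amine NH
  expect_equal(sum(fa$kind == "acceptor"), 3) # two oxygens plus the amine N
  expect_equal(sum(fa$kind == "hydrophobic"), 3) # three ring centroids
  # donors live on O or N atoms only
  don <- fa[fa$kind == "donor", ]
  idx <- unlist(don$atom_indices)
  expect_true(all(toupper(ac73$atoms$element[idx]) %in% c("O", "N")))
  # amide N is not an acceptor
  amide <- parse_smiles("CC(=O)NC", gen3d = TRUE)
  fam <- perceive_ligand_features(amide)
  acc_atoms <- unlist(fam$atom_indices[fam$kind == "acceptor"])
  expect_false(any(toupper(amide$atoms$element[acc_atoms]) == "N"))
  # feature perception without a conformer is a state error
  noconf <- new_ligand("x", tibble::tibble(element = "C", charge = 0L),
    tibble::tibble(i = integer(), j = integer(), order = integer())
  )
  expect_error(perceive_ligand_features(noconf), regexp = "conformer")
})

test_that("rotatable-bond counting skips rings, multiples and terminals", {
  # all ethanol bonds touch a terminal heavy atom
  expect_equal(ligand_properties(parse_smiles("CCO"))$n_rotatable, 0L)
  expect_equal(ligand_properties(parse_smiles("CCCC"))$n_rotatable, 1L)
  expect_equal(ligand_properties(parse_smiles("c1ccccc1"))$n_rotatable, 0L)
  expect_equal(ligand_properties(parse_smiles("C=C"))$n_rotatable, 0L)
  # biphenyl: one rotatable inter-ring bond
  expect_equal(ligand_properties(parse_smiles("c1ccccc1-c1ccccc1"))$n_rotatable, 1L)
})
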