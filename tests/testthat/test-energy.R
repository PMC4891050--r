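atoms_at <- function(element, xyz, charge = 0) {
  tibble::tibble(
    element = element, charge = charge,
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3]
  )
}

prot_at <- function(element, xyz, charge = 0, resno = 1) {
  tibble::tibble(
    chain = "A", resno = resno, resname = "XXX", atom = "X",
    element = element, charge = charge,
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3]
  )
}

test_that("a neutral pair at the LJ minimum scores exactly -epsilon", {
  p <- energy_params()
  sig <- p$sigma[["C"]]
  r0 <- 2^(1 / 6) * sig
  e <- interaction_energy(
    atoms_at("C", matrix(c(0, 0, 0), 1, 3)),
    prot_at("C", matrix(c(r0, 0, 0), 1, 3)),
    p
  )
  expect_equal(e, -p$eps[["C"]], tolerance = 1e-12)
})

test_that("the Coulomb term with dielectric 4r matches hand arithmetic", {
  # disable vdW by zeroing epsilon; two unit charges at 3 A
  p <- energy_params(eps = c(C = 0), default_eps = 0)
  e <- interaction_energy(
    atoms_at("C", matrix(c(0, 0, 0), 1, 3), charge = 1),
    prot_at("C", matrix(c(3, 0, 0), 1, 3), charge = 1),
    p
  )
  expect_equal(e, 332.0636 / (4 * 3 * 3), tolerance = 1e-12)
})

test_that("pairs beyond the cutoff contribute nothing and near-overlap errors", {
  p <- energy_params(pair_cutoff = 10)
  e <- interaction_energy(
    atoms_at("C", matrix(c(0, 0, 0), 1, 3), charge = 1),
    prot_at("C", matrix(c(11, 0, 0), 1, 3), charge = 1),
    p
  )
  expect_equal(e, 0)
  expect_error(
    interaction_energy(
      atoms_at("C", matrix(c(0, 0, 0), 1, 3)),
      prot_at("C", matrix(c(1e-5, 0, 0), 1, 3)),
      p
    ),
    regexp = "singular"
  )
})

test_that("energy decays to zero as separation grows (neutral tail)", {
  p <- energy_params(pair_cutoff = 100)
  lig <- atoms_at("C", matrix(c(0, 0, 0), 1, 3))
  sig <- p$sigma[["C"]]
  rs <- seq(2 * sig, 8 * sig, length.out = 12)
  es <- vapply(rs, function(r) {
    interaction_energy(lig, prot_at("C", matrix(c(r, 0, 0), 1, 3)), p)
  }, numeric(1))
  expect_true(all(diff(abs(es)) < 0)) # magnitude decreasing beyond 2 sigma
  expect_lt(abs(es[length(es)]), 1e-3)
})

test_that("per-residue decomposition conserves the shell total", {
  # single residue: one entry equal to the total
  lig <- atoms_at("N", matrix(c(0, 0, 0), 1, 3), charge = -0.3)
  prot <- prot_at("O", matrix(c(3, 0, 0), 1, 3), charge = -0.4)
  ps <- per_residue_decomposition(lig, prot)
  expect_equal(nrow(ps$per_residue), 1)
  expect_equal(ps$per_residue$energy, ps$total)
  # two residues: hand-computed pair sums
  prot2 <- dplyr::bind_rows(
    prot_at("O", matrix(c(3, 0, 0), 1, 3), charge = -0.4, resno = 1),
    prot_at("C", matrix(c(0, 4, 0), 1, 3), charge = 0.1, resno = 2)
  )
  p <- energy_params()
  ps2 <- per_residue_decomposition(lig, prot2, p)
  hand <- function(le, pe, r, q1, q2) {
    sij <- (p$sigma[[le]] + p$sigma[[pe]]) / 2
    eij <- sqrt(p$eps[[le]] * p$eps[[pe]])
    4 * eij * ((sij / r)^12 - (sij / r)^6) + 332.0636 * q1 * q2 / (4 * r^2)
  }
  expect_equal(
    ps2$per_residue$energy[ps2$per_residue$resno == 1],
    hand("N", "O", 3, -0.3, -0.4),
    tolerance = 1e-10
  )
  expect_equal(
    ps2$per_residue$energy[ps2$per_residue$resno == 2],
    hand("N", "C", 4, -0.3, 0.1),
    tolerance = 1e-10
  )
  expect_equal(sum(ps2$per_residue$energy), ps2$total, tolerance = 1e-9)
  # a residue outside the shell is absent even if the ligand is charged
  prot3 <- dplyr::bind_rows(
    prot2,
    prot_at("O", matrix(c(20, 0, 0), 1, 3), charge = -0.4, resno = 3)
  )
  ps3 <- per_residue_decomposition(lig, prot3, p, shell = 10)
  expect_false(3 %in% ps3$per_residue$resno)
})

test_that("decomposition conservation and rigid-motion invariance hold on random fixtures", {
  withr::with_seed(77, {
    for (rep in 1:20) {
      prot <- random_protein_atoms()
      lig <- random_ligand_atoms()
      ps <- per_residue_decomposition(lig, prot)
      expect_lt(abs(sum(ps$per_residue$energy) - ps$total), 1e-6)
      # joint rigid motion leaves the energy unchanged
      rot <- random_rotation()
      shift <- runif(3, -5, 5)
      e1 <- interaction_energy(lig, prot)
      e2 <- interaction_energy(
        apply_rigid_df(lig, rot, shift),
        apply_rigid_df(prot, rot, shift)
      )
      expect_lt(abs(e1 - e2), 1e-8)
    }
  })
})

test_that("rigid minimization finds the LJ optimum and never increases energy", {
  p <- energy_params()
  sig <- (p$sigma[["C"]] + p$sigma[["C"]]) / 2
  r0 <- 2^(1 / 6) * sig
  lig <- atoms_at("C", matrix(c(r0 - 0.5, 0, 0), 1, 3))
  prot <- prot_at("C", matrix(c(0, 0, 0), 1, 3))
  mn <- minimize_pose(lig, prot, p, max_iter = 200)
  sep <- sqrt(mn$atoms$x^2 + mn$atoms$y^2 + mn$atoms$z^2)
  expect_lt(abs(sep - r0), 0.05)
  expect_true(all(diff(mn$trace$energy) <= 1e-12))
  # determinism: identical trace on rerun
  mn2 <- minimize_pose(lig, prot, p, max_iter = 200)
  expect_identical(mn$trace, mn2$trace)
  # a pose already at the discrete minimum is returned unchanged
  mn3 <- minimize_pose(mn$atoms, prot, p, max_iter = 50)
  expect_lte(mn3$energy, mn$energy + 1e-12)
  expect_lt(abs(mn3$energy - mn$energy), 1e-6)
})

test_that("minimization is monotone across random seeded fixtures", {
  withr::with_seed(99, {
    for (rep in 1:10) {
      prot <- random_protein_atoms()
      lig <- random_ligand_atoms()
      mn <- minimize_pose(lig, prot, max_iter = 40)
      expect_true(all(diff(mn$trace$energy) <= 1e-12))
      expect_lte(mn$energy, mn$trace$energy[1])
    }
  })
})

test_that("non-finite starting energies are rejected with advice", {
  lig <- atoms_at("C", matrix(c(0, 0, 0), 1, 3))
  prot <- prot_at("C", matrix(c(1e-5, 0, 0), 1, 3))
  expect_error(minimize_pose(lig, prot), regexp = "exclusion_check|singular")
})

hb_protein <- function(acc_x = 2.9) {
  # a glycine whose backbone O sits on the x axis as the acceptor
  structure_from_atoms(tibble::tibble(
    atom = c("N", "CA", "C", "O"), resname = "GLY", chain = "A", resno = 1,
    x = c(8, 6.5, 5, acc_x), y = c(4, 3, 0.9, 0), z = 0
  ))
}

hb_ligand <- function(hpos) {
  new_ligand(
    "wat",
    tibble::tibble(element = c("O", "H"), charge = 0L),
    tibble::tibble(i = 1L, j = 2L, order = 1L),
    conformers = list(rbind(c(0, 0, 0), hpos))
  )
}

test_that("hydrogen bonds require distance and, with explicit H, angle", {
  # O-H...O at 2.9 A and 180 degrees: one ligand-donor bond
  lig <- hb_ligand(c(1, 0, 0))
  hb <- detect_hbonds(lig, hb_protein(2.9))
  ldon <- hb[hb$donor_side == "ligand", ]
  expect_equal(nrow(ldon), 1)
  expect_equal(ldon$distance, 2.9, tolerance = 0.01)
  expect_gt(ldon$angle, 179)
  # 3.6 A: out of range
  hb2 <- detect_hbonds(lig, hb_protein(3.6))
  expect_equal(nrow(hb2[hb2$donor_side == "ligand", ]), 0)
  # 2.9 A but a ~100 degree D-H...A angle: rejected
  lig3 <- hb_ligand(c(0.5, 0.87, 0))
  hb3 <- detect_hbonds(lig3, hb_protein(2.9))
  expect_equal(nrow(hb3[hb3$donor_side == "ligand", ]), 0)
})

test_that("an acceptor residue placed to H-bond the ligand dominates the decomposition", {
  # ligand donor N-H pointing at a glutamate carboxylate 2.9 A away;
  # two apolar residues sit farther out
  prot <- structure_from_atoms(tibble::tibble(
    atom = c("N", "CA", "C", "O", "CB", "CG", "CD", "OE1", "OE2",
             "N", "CA", "C", "O", "CB",
             "N", "CA", "C", "O", "CB"),
    resname = c(rep("GLU", 9), rep("ALA", 5), rep("ALA", 5)),
    chain = "A",
    resno = c(rep(64L, 9), rep(1L, 5), rep(2L, 5)),
    x = c(9.2, 8.2, 8.9, 10.1, 6.9, 5.6, 4.3, 2.9, 4.0,
          0, 1.5, 2.2, 3.4, 1.0,
          -6, -5, -4.5, -3.4, -5.5),
    y = c(-1.2, -0.4, 0.9, 1.2, -0.7, 0.1, -0.4, 0.1, -1.5,
          6, 6.5, 7.7, 7.8, 5.2,
          -3, -3.5, -4.7, -4.8, -2.2),
    z = 0
  ))
  lig <- new_ligand(
    "amine",
    tibble::tibble(element = c("N", "H", "C"), charge = 0L),
    tibble::tibble(i = c(1L, 1L), j = c(2L, 3L), order = 1L),
    conformers = list(rbind(c(0, 0.1, 0), c(1, 0.07, 0), c(-1.4, 0.2, 0)))
  )
  la <- phorescreen:::ligand_pose_atoms(lig)
  ps <- per_residue_decomposition(la, prot)
  expect_equal(ps$per_residue$resname[1], "GLU") # most negative first
  expect_lt(ps$per_residue$energy[1], min(0, ps$per_residue$energy[-1]))
})
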