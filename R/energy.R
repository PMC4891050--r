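# Transparent pose-energy model: Lennard-Jones 12-6 plus Coulomb with a
# distance-dependent dielectric eps(r) = 4r, Lorentz-Berthelot combining,
# per-residue decomposition over a distance shell, rigid-body minimization
# and geometric hydrogen-bond detection. This is an open analog of the
# proprietary scoring used in commercial docking suites; its absolute values
# are not comparable with theirs.

# generic per-element vdW parameters (sigma in Angstrom, epsilon kcal/mol);
# hydrogen uses a polar-hydrogen-like radius so hydrogen-bond geometry
# (donor H ~1.9 A from the acceptor) is not penalized sterically
VDW_SIGMA <- c(
  H = 1.20, C = 3.40, N = 3.25, O = 2.96, S = 3.50, P = 3.74,
  F = 2.94, CL = 3.52, BR = 3.73, I = 3.96
)
VDW_EPS <- c(
  H = 0.015, C = 0.086, N = 0.170, O = 0.210, S = 0.250, P = 0.200,
  F = 0.060, CL = 0.270, BR = 0.390, I = 0.550
)

#' Energy model parameters
#'
#' @param pair_cutoff Pairwise interaction cutoff in Angstroms (default 10).
#' @param coulomb_k Coulomb constant, 332.0636 kcal A / (mol e^2).
#' @param sigma,eps Named per-element vdW parameter vectors; unknown elements
#'   fall back to `default_sigma`/`default_eps`.
#' @param default_sigma,default_eps Fallback vdW parameters.
#' @return An `energy_params` list.
#' @export
energy_params <- function(pair_cutoff = 10, coulomb_k = 332.0636,
                          sigma = VDW_SIGMA, eps = VDW_EPS,
                          default_sigma = 3.5, default_eps = 0.1) {
  if (pair_cutoff <= 0) abort("pair_cutoff must be positive.")
  if (any(eps < 0)) abort("epsilon values must be non-negative.")
  structure(
    list(
      pair_cutoff = pair_cutoff, coulomb_k = coulomb_k,
      sigma = sigma, eps = eps,
      default_sigma = default_sigma, default_eps = default_eps
    ),
    class = "energy_params"
  )
}

param_lookup <- function(tbl, key, default) {
  v <- tbl[key]
  v[is.na(v)] <- default
  unname(v)
}

# ---- partial charges --------------------------------------------------------

#' Assign partial charges to ligand atoms
#'
#' A simple documented scheme (version pq-0.1): fixed polar-group increments
#' (hydroxyl O -0.35, other O -0.40, N -0.30, S -0.10, H on N/O +0.35,
#' C bonded to N/O +0.15), plus each formal charge spread half onto its atom
#' and half equally over bonded neighbours.
#'
#' @param ligand A `ligand` object.
#' @return Numeric vector of partial charges (e) per atom.
#' @export
assign_ligand_charges <- function(ligand) {
  key <- elem_key(ligand$atoms$element)
  hc <- h_count(ligand)
  adj <- lig_adj(ligand)
  q <- numeric(nrow(ligand$atoms))
  for (i in seq_along(q)) {
    nb_keys <- key[adj[[i]]]
    q[i] <- switch(key[i],
      O = if (hc[i] >= 1) -0.35 else -0.40,
      N = -0.30,
      S = -0.10,
      H = ,
      D = if (any(nb_keys %in% c("N", "O"))) 0.35 else 0.0,
      C = if (any(nb_keys %in% c("N", "O"))) 0.15 else 0.0,
      0.0
    )
  }
  for (i in which(ligand$atoms$charge != 0)) {
    fc <- ligand$atoms$charge[i]
    nb <- adj[[i]]
    q[i] <- q[i] + fc * 0.5
    if (length(nb) > 0) q[nb] <- q[nb] + fc * 0.5 / length(nb)
  }
  q
}

# resname-aware protein atom charge increments (version pq-0.1)
protein_atom_charge <- function(atom, resname, element) {
  if (toupper(element) %in% c("H", "D")) {
    return(if (atom %in% c("H", "HN")) 0.30 else 0.0)
  }
  if (atom == "N") return(-0.30)
  if (atom %in% c("O", "OXT")) return(-0.40)
  if (atom == "C") return(0.30)
  if (resname == "ASP" && atom %in% c("OD1", "OD2")) return(-0.50)
  if (resname == "GLU" && atom %in% c("OE1", "OE2")) return(-0.50)
  if (resname == "ASP" && atom == "CG") return(0.40)
  if (resname == "GLU" && atom == "CD") return(0.40)
  if (atom %in% c("OG", "OG1", "OH")) return(-0.35)
  if (resname == "ASN" && atom == "OD1") return(-0.40)
  if (resname == "GLN" && atom == "OE1") return(-0.40)
  if (resname == "ASN" && atom == "ND2") return(-0.20)
  if (resname == "GLN" && atom == "NE2") return(-0.20)
  if (atom == "NZ") return(0.35)
  if (atom %in% c("NE", "NH1", "NH2")) return(0.25)
  if (resname == "HIS" && atom %in% c("ND1", "NE2")) return(-0.10)
  if (atom == "NE1") return(-0.15)
  if (atom %in% c("SD", "SG")) return(-0.10)
  0.0
}

#' Assign partial charges to protein atoms
#'
#' Adds a `charge` column to a structure tibble using fixed polar-group
#' increments keyed on residue and atom name (backbone N/O, carboxylates,
#' hydroxyls, side-chain amines; version pq-0.1). Apolar atoms get 0.
#'
#' @param structure A `protein_structure` tibble.
#' @return The structure with a `charge` column.
#' @export
assign_protein_charges <- function(structure) {
  df <- as_tibble(structure)
  df$charge <- map_dbl(
    seq_len(nrow(df)),
    function(i) protein_atom_charge(df$atom[i], df$resname[i], df$element[i])
  )
  new_structure(df, attr(structure, "structure_id") %||% "structure")
}

# build the ligand-side atom table (element, charge, x, y, z) for a pose
ligand_pose_atoms <- function(ligand, pose = NULL, conformer = 1) {
  xyz <- pose %||% ligand$conformers[[conformer]]
  tibble(
    element = ligand$atoms$element,
    charge = assign_ligand_charges(ligand),
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3]
  )
}

# ---- interaction energy -----------------------------------------------------

#' Protein-ligand interaction energy
#'
#' Sum over ligand-atom / protein-atom pairs within `pair_cutoff` of
#' `4 eps_ij ((sigma_ij/r)^12 - (sigma_ij/r)^6) + k q_i q_j / (4 r^2)`
#' (Lennard-Jones 12-6 plus Coulomb with distance-dependent dielectric
#' `eps(r) = 4r`). `sigma_ij` is the arithmetic and `eps_ij` the geometric
#' combination of the per-element parameters.
#'
#' @param lig_atoms Tibble with `element`, `charge`, `x`, `y`, `z` (e.g. from
#'   a superposed pose).
#' @param prot_atoms Tibble with the same columns (see
#'   [assign_protein_charges()]).
#' @param params An [energy_params()] object.
#' @return Interaction energy in kcal/mol.
#' @export
interaction_energy <- function(lig_atoms, prot_atoms, params = energy_params()) {
  if (nrow(lig_atoms) == 0 || nrow(prot_atoms) == 0) return(0)
  ls <- param_lookup(params$sigma, toupper(lig_atoms$element), params$default_sigma)
  le <- param_lookup(params$eps, toupper(lig_atoms$element), params$default_eps)
  ps <- param_lookup(params$sigma, toupper(prot_atoms$element), params$default_sigma)
  pe <- param_lookup(params$eps, toupper(prot_atoms$element), params$default_eps)
  lq <- lig_atoms$charge %||% numeric(nrow(lig_atoms))
  pq <- prot_atoms$charge %||% numeric(nrow(prot_atoms))
  d2 <- outer(lig_atoms$x, prot_atoms$x, "-")^2 +
    outer(lig_atoms$y, prot_atoms$y, "-")^2 +
    outer(lig_atoms$z, prot_atoms$z, "-")^2
  r <- sqrt(d2)
  if (any(r < 1e-3)) {
    abort("Atom pair closer than 1e-3 A; energy is singular. Run exclusion_check first.")
  }
  mask <- r <= params$pair_cutoff
  if (!any(mask)) return(0)
  sij <- outer(ls, ps, "+") / 2
  eij <- sqrt(outer(le, pe))
  qq <- outer(lq, pq)
  sr6 <- (sij / r)^6
  e <- 4 * eij * (sr6^2 - sr6) + params$coulomb_k * qq / (4 * r * r)
  sum(e[mask])
}

structure_atom_table <- function(structure) {
  df <- as_tibble(structure)
  if (!"charge" %in% names(df)) df <- assign_protein_charges(df)
  df
}

#' Per-residue interaction-energy decomposition
#'
#' Restricts the protein to residues having at least one heavy atom within
#' `shell` Angstroms of any ligand heavy atom, computes the total interaction
#' energy over that shell, and attributes each pair term to the residue of
#' its protein atom. The per-residue energies sum to the shell total by
#' construction.
#'
#' @param lig_atoms Ligand pose atom tibble (`element`, `charge`,
#'   `x`,`y`,`z`).
#' @param structure A `protein_structure` tibble (charges are assigned if
#'   absent).
#' @param params An [energy_params()].
#' @param shell Shell radius in Angstroms (default 10).
#' @return A `pose_score`: list with `total` (kcal/mol), `per_residue`
#'   (tibble `chain`, `resno`, `resname`, `residue` label, `energy`, sorted
#'   ascending), and `shell`.
#' @export
per_residue_decomposition <- function(lig_atoms, structure,
                                      params = energy_params(), shell = 10) {
  prot <- structure_atom_table(structure)
  lig_heavy <- lig_atoms[!toupper(lig_atoms$element) %in% c("H", "D"), ]
  prot_heavy <- prot[!prot$element %in% c("H", "D"), ]
  mind <- map_dbl(seq_len(nrow(prot_heavy)), function(i) {
    min(sqrt((lig_heavy$x - prot_heavy$x[i])^2 +
      (lig_heavy$y - prot_heavy$y[i])^2 +
      (lig_heavy$z - prot_heavy$z[i])^2))
  })
  shell_keys <- prot_heavy[mind <= shell, c("chain", "resno")] |> distinct()
  shell_atoms <- semi_join(prot, shell_keys, by = c("chain", "resno"))
  groups <- shell_atoms |> group_by(.data$chain, .data$resno, .data$resname) |> group_split()
  per <- bind_rows(map(groups, function(g) {
    tibble(
      chain = g$chain[1], resno = g$resno[1], resname = g$resname[1],
      residue = residue_label(g$resname[1], g$resno[1]),
      energy = interaction_energy(lig_atoms, g, params)
    )
  }))
  if (nrow(per) == 0) {
    per <- tibble(
      chain = character(), resno = integer(), resname = character(),
      residue = character(), energy = double()
    )
  }
  per <- arrange(per, .data$energy)
  structure(
    list(total = sum(per$energy), per_residue = per, shell = shell),
    class = "pose_score"
  )
}

residue_label <- function(resname, resno) {
  nm <- paste0(
    toupper(substr(resname, 1, 1)),
    tolower(substr(resname, 2, nchar(resname)))
  )
  paste0(nm, resno)
}

#' @export
print.pose_score <- function(x, ...) {
  cat(sprintf(
    "<pose_score> total %.3f kcal/mol over %d residues within %.1f A\n",
    x$total, nrow(x$per_residue), x$shell
  ))
  print(head(x$per_residue, 5))
  invisible(x)
}

# ---- rigid-body minimization ------------------------------------------------

rotation_about_axis <- function(axis, angle) {
  u <- axis / vnorm(axis)
  c_ <- cos(angle); s <- sin(angle)
  ux <- u[1]; uy <- u[2]; uz <- u[3]
  matrix(c(
    c_ + ux^2 * (1 - c_), ux * uy * (1 - c_) - uz * s, ux * uz * (1 - c_) + uy * s,
    uy * ux * (1 - c_) + uz * s, c_ + uy^2 * (1 - c_), uy * uz * (1 - c_) - ux * s,
    uz * ux * (1 - c_) - uy * s, uz * uy * (1 - c_) + ux * s, c_ + uz^2 * (1 - c_)
  ), 3, 3, byrow = TRUE)
}

#' Rigid-body pose minimization
#'
#' Greedy coordinate descent over the six rigid degrees of freedom
#' (translations along and rotations about the ligand-centroid axes) with a
#' shrinking step schedule: at each iteration the best energy-improving move
#' is taken; when no move improves, both steps are halved. Stops when the
#' translation step falls below `min_step` or after `max_iter` iterations.
#' The search is deterministic; energy never increases along the trace.
#'
#' @param lig_atoms Ligand pose atom tibble (`element`, `charge`,
#'   `x`,`y`,`z`).
#' @param prot_atoms Protein atom tibble (or `protein_structure`; charges
#'   assigned if absent).
#' @param params An [energy_params()].
#' @param max_iter Maximum iterations (default 100).
#' @param step Initial translation step in Angstroms (default 0.5).
#' @param rot_step Initial rotation step in radians (default 0.2).
#' @param min_step Terminal translation step (default 0.01).
#' @return List: `atoms` (minimized pose tibble), `energy`, `trace` (tibble
#'   `iter`, `energy`), `start_energy`.
#' @export
minimize_pose <- function(lig_atoms, prot_atoms, params = energy_params(),
                          max_iter = 100, step = 0.5, rot_step = 0.2,
                          min_step = 0.01) {
  prot <- structure_atom_table(prot_atoms)
  cur <- as.matrix(lig_atoms[, c("x", "y", "z")])
  energy_of <- function(xyz) {
    la <- lig_atoms
    la$x <- xyz[, 1]; la$y <- xyz[, 2]; la$z <- xyz[, 3]
    interaction_energy(la, prot, params)
  }
  e <- energy_of(cur)
  if (!is.finite(e)) {
    abort("Starting energy is not finite; run exclusion_check before minimizing.")
  }
  start_e <- e
  trace <- list(tibble(iter = 0L, energy = e))
  axes <- rbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  for (it in seq_len(max_iter)) {
    if (step < min_step) break
    best_e <- e
    best_xyz <- NULL
    for (a in 1:3) {
      for (s in c(-1, 1)) {
        xyz <- sweep(cur, 2, s * step * axes[a, ], "+")
        et <- tryCatch(energy_of(xyz), error = function(err) Inf)
        if (et < best_e - 1e-12) {
          best_e <- et
          best_xyz <- xyz
        }
        cen <- colMeans(cur)
        rot <- rotation_about_axis(axes[a, ], s * rot_step)
        xyz <- sweep(sweep(cur, 2, cen) %*% t(rot), 2, cen, "+")
        et <- tryCatch(energy_of(xyz), error = function(err) Inf)
        if (et < best_e - 1e-12) {
          best_e <- et
          best_xyz <- xyz
        }
      }
    }
    if (is.null(best_xyz)) {
      step <- step / 2
      rot_step <- rot_step / 2
    } else {
      cur <- best_xyz
      e <- best_e
    }
    trace <- c(trace, list(tibble(iter = it, energy = e)))
  }
  out <- lig_atoms
  out$x <- cur[, 1]; out$y <- cur[, 2]; out$z <- cur[, 3]
  list(atoms = out, energy = e, trace = bind_rows(trace), start_energy = start_e)
}

# ---- hydrogen-bond detection ------------------------------------------------

#' Detect protein-ligand hydrogen bonds
#'
#' Geometric criterion on heavy atoms: every (donor heavy atom, acceptor)
#' pair across the interface with distance at most `dmax` is reported, in
#' both directions (ligand donor to protein acceptor and protein donor to
#' ligand acceptor). When the ligand donor carries an explicit hydrogen the
#' D-H...A angle must also be at least `amin` degrees (the best hydrogen is
#' used); donors without explicit hydrogens are assessed on distance only.
#'
#' @param ligand A `ligand` object.
#' @param structure A `protein_structure` tibble.
#' @param pose Optional pose coordinate matrix (default conformer 1).
#' @param dmax Maximum donor-acceptor distance (default 3.5 A).
#' @param amin Minimum D-H...A angle in degrees (default 120).
#' @return A tibble: `donor_side`, `donor`, `acceptor_side`, `acceptor`,
#'   `distance`, `angle` (`NA` without explicit hydrogen).
#' @export
detect_hbonds <- function(ligand, structure, pose = NULL, dmax = 3.5, amin = 120) {
  xyz <- pose %||% ligand$conformers[[1]]
  rings <- ligand_rings(ligand)
  da <- ligand_da_atoms(ligand, rings)
  key <- elem_key(ligand$atoms$element)
  adj <- lig_adj(ligand)
  sites <- perceive_sites(structure)
  psite <- function(kind) sites[sites$kind == kind & sites$atom != "", ]
  pdon <- psite("donor")
  pacc <- psite("acceptor")
  out <- list()
  hb_row <- function(ds, d, as_, a, dist, ang) {
    tibble(
      donor_side = ds, donor = d, acceptor_side = as_, acceptor = a,
      distance = dist, angle = ang
    )
  }
  lig_label <- function(i) sprintf("%s%d", key[i], i)
  # ligand donor -> protein acceptor
  for (i in da$donors) {
    hs <- adj[[i]][key[adj[[i]]] %in% c("H", "D")]
    for (r in seq_len(nrow(pacc))) {
      apos <- c(pacc$x[r], pacc$y[r], pacc$z[r])
      dist <- vnorm(xyz[i, ] - apos)
      if (dist > dmax) next
      ang <- NA_real_
      if (length(hs) > 0) {
        angs <- map_dbl(hs, function(h) {
          v1 <- xyz[i, ] - xyz[h, ]
          v2 <- apos - xyz[h, ]
          acos(pmin(1, pmax(-1, sum(v1 * v2) / (vnorm(v1) * vnorm(v2))))) * 180 / pi
        })
        ang <- max(angs)
        if (ang < amin) next
      }
      out <- c(out, list(hb_row(
        "ligand", lig_label(i), "protein",
        paste0(residue_label(pacc$resname[r], pacc$resno[r]), ":", pacc$atom[r]),
        dist, ang
      )))
    }
  }
  # protein donor -> ligand acceptor (protein usually unprotonated:
  # distance-only)
  for (i in da$acceptors) {
    for (r in seq_len(nrow(pdon))) {
      dpos <- c(pdon$x[r], pdon$y[r], pdon$z[r])
      dist <- vnorm(xyz[i, ] - dpos)
      if (dist > dmax) next
      out <- c(out, list(hb_row(
        "protein",
        paste0(residue_label(pdon$resname[r], pdon$resno[r]), ":", pdon$atom[r]),
        "ligand", lig_label(i), dist, NA_real_
      )))
    }
  }
  empty <- hb_row(character(), character(), character(), character(), double(), double())
  bind_rows(empty, out)
}
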