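# Deterministic synthetic-data generators: a toy binding pocket in PDB
# format, ligand libraries with actives planted onto a hypothesis plus
# kind-deficient and geometry-violating decoys, screen readout tables with
# planted hit counts, and 4PL dose-response data with known parameters.
# Every generator is a pure function of its seed and size parameters.

# idealized residue templates in a local frame: CA at the origin, side chain
# extending along +x (bond geometry is approximate; these are synthetic
# pockets for testing, not physical folds)
RES_TEMPLATES <- list(
  GLY = rbind(
    N = c(-0.7, -1.2, 0), CA = c(0, 0, 0), C = c(-0.7, 1.2, 0), O = c(-1.9, 1.4, 0.1)
  ),
  ALA = rbind(
    N = c(-0.7, -1.2, 0), CA = c(0, 0, 0), C = c(-0.7, 1.2, 0), O = c(-1.9, 1.4, 0.1),
    CB = c(1.5, 0, 0)
  ),
  VAL = rbind(
    N = c(-0.7, -1.2, 0), CA = c(0, 0, 0), C = c(-0.7, 1.2, 0), O = c(-1.9, 1.4, 0.1),
    CB = c(1.5, 0, 0), CG1 = c(2.3, 1.1, 0.3), CG2 = c(2.3, -1.0, -0.3)
  ),
  LEU = rbind(
    N = c(-0.7, -1.2, 0), CA = c(0, 0, 0), C = c(-0.7, 1.2, 0), O = c(-1.9, 1.4, 0.1),
    CB = c(1.5, 0, 0), CG = c(2.8, 0.2, 0), CD1 = c(3.6, 1.2, 0.4), CD2 = c(3.6, -0.9, -0.4)
  ),
  MET = rbind(
    N = c(-0.7, -1.2, 0), CA = c(0, 0, 0), C = c(-0.7, 1.2, 0), O = c(-1.9, 1.4, 0.1),
    CB = c(1.5, 0, 0), CG = c(2.8, 0, 0.2), SD = c(4.0, 0, 0.3), CE = c(5.2, 0.4, 0)
  ),
  PHE = rbind(
    N = c(-0.7, -1.2, 0), CA = c(0, 0, 0), C = c(-0.7, 1.2, 0), O = c(-1.9, 1.4, 0.1),
    CB = c(1.5, 0, 0), CG = c(2.9, 0, 0), CD1 = c(3.6, 1.15, 0.1), CD2 = c(3.6, -1.15, -0.1),
    CE1 = c(5.0, 1.2, 0.1), CE2 = c(5.0, -1.2, -0.1), CZ = c(5.7, 0, 0)
  ),
  SER = rbind(
    N = c(-0.7, -1.2, 0), CA = c(0, 0, 0), C = c(-0.7, 1.2, 0), O = c(-1.9, 1.4, 0.1),
    CB = c(1.5, 0, 0), OG = c(2.4, 0.3, 0.2)
  ),
  THR = rbind(
    N = c(-0.7, -1.2, 0), CA = c(0, 0, 0), C = c(-0.7, 1.2, 0), O = c(-1.9, 1.4, 0.1),
    CB = c(1.5, 0, 0), OG1 = c(2.4, 0.4, 0.2), CG2 = c(2.0, -1.2, 0)
  ),
  ASN = rbind(
    N = c(-0.7, -1.2, 0), CA = c(0, 0, 0), C = c(-0.7, 1.2, 0), O = c(-1.9, 1.4, 0.1),
    CB = c(1.5, 0, 0), CG = c(2.9, 0, 0), OD1 = c(3.5, 1.05, 0.1), ND2 = c(3.6, -1.1, -0.1)
  ),
  GLU = rbind(
    N = c(-0.7, -1.2, 0), CA = c(0, 0, 0), C = c(-0.7, 1.2, 0), O = c(-1.9, 1.4, 0.1),
    CB = c(1.5, 0, 0), CG = c(2.9, 0.2, 0), CD = c(4.2, 0, 0), OE1 = c(4.9, 1.0, 0.1),
    OE2 = c(4.7, -1.1, -0.1)
  ),
  LYS = rbind(
    N = c(-0.7, -1.2, 0), CA = c(0, 0, 0), C = c(-0.7, 1.2, 0), O = c(-1.9, 1.4, 0.1),
    CB = c(1.5, 0, 0), CG = c(2.8, 0, 0.2), CD = c(4.1, 0.2, 0), CE = c(5.4, 0, 0),
    NZ = c(6.3, 0.9, 0.1)
  )
)

# pocket residue layout: residue identity, file number, backbone (CA) radius.
# Radii are chosen so side-chain tips line a cleft of radius ~6.5 A around
# the origin; numbering echoes the CD147 dimer-interface region (the two
# glutamates are 64 and 73).
TOY_POCKET_LAYOUT <- tibble::tribble(
  ~resname, ~resno, ~radius,
  "VAL", 61L, 8.8,
  "LEU", 62L, 10.1,
  "GLY", 63L, 6.6,
  "GLU", 64L, 11.4,
  "SER", 65L, 8.9,
  "ALA", 66L, 8.0,
  "MET", 67L, 11.7,
  "ASN", 70L, 10.1,
  "THR", 71L, 8.9,
  "GLU", 73L, 11.4,
  "PHE", 74L, 12.2,
  "LYS", 75L, 12.9
)

# expected side-chain interaction sites per pocket residue (the generator's
# ground-truth manifest; backbone donor/acceptor sites exist in addition)
TOY_POCKET_MANIFEST <- tibble::tribble(
  ~resno, ~resname, ~kind, ~atom,
  61L, "VAL", "hydrophobic", "CB+CG1+CG2",
  62L, "LEU", "hydrophobic", "CB+CG+CD1+CD2",
  64L, "GLU", "acceptor", "OE1",
  64L, "GLU", "acceptor", "OE2",
  65L, "SER", "donor", "OG",
  65L, "SER", "acceptor", "OG",
  66L, "ALA", "hydrophobic", "CB",
  67L, "MET", "hydrophobic", "CB+CG+CE",
  70L, "ASN", "donor", "ND2",
  70L, "ASN", "acceptor", "OD1",
  71L, "THR", "donor", "OG1",
  71L, "THR", "acceptor", "OG1",
  73L, "GLU", "acceptor", "OE1",
  73L, "GLU", "acceptor", "OE2",
  74L, "PHE", "hydrophobic", "CB+CG+CD1+CD2+CE1+CE2+CZ",
  75L, "LYS", "donor", "NZ"
)

#' Generate a toy binding pocket
#'
#' Builds a 12-residue synthetic cleft in PDB format: residues are placed on
#' a ring with their idealized side chains pointing inward, so their tips
#' line a concave pocket about the origin. The pocket contains two glutamate
#' acceptor residues (numbered 64 and 73, echoing the CD147 dimer-interface
#' glutamates), several donor residues and several hydrophobic residues. A
#' ground-truth manifest lists the intended side-chain interaction site of
#' every residue. Output is byte-identical for a given seed.
#'
#' @param seed Integer seed for the coordinate jitter.
#' @param jitter Uniform coordinate jitter amplitude in Angstroms
#'   (default 0.15).
#' @return A list: `pdb` (PDB text), `manifest` (tibble `chain`, `resno`,
#'   `resname`, `kind`, `atom`), `center` (origin), `radius` (8 A pocket
#'   sphere radius), `key_residues` (tibble with the two glutamates).
#' @export
make_toy_pocket <- function(seed = 1, jitter = 0.15) {
  local_seed(seed, {
    layout <- TOY_POCKET_LAYOUT
    nres <- nrow(layout)
    rows <- list()
    serial <- 0L
    for (i in seq_len(nres)) {
      theta <- 2 * pi * (i - 1) / nres
      zoff <- 0.8 * (-1)^i
      tmpl <- RES_TEMPLATES[[layout$resname[i]]]
      # rotate local +x onto the inward (-radial) direction
      ang <- theta + pi
      rot <- matrix(c(cos(ang), sin(ang), 0, -sin(ang), cos(ang), 0, 0, 0, 1), 3, 3)
      ca_pos <- c(layout$radius[i] * cos(theta), layout$radius[i] * sin(theta), zoff)
      xyz <- t(rot %*% t(tmpl)) + matrix(ca_pos, nrow(tmpl), 3, byrow = TRUE)
      xyz <- xyz + matrix(runif(length(xyz), -jitter, jitter), nrow(tmpl), 3)
      for (a in seq_len(nrow(tmpl))) {
        serial <- serial + 1L
        nm <- rownames(tmpl)[a]
        rows <- c(rows, list(tibble(
          serial = serial, atom = nm, element = substr(nm, 1, 1),
          resname = layout$resname[i], chain = "A", resno = layout$resno[i],
          x = xyz[a, 1], y = xyz[a, 2], z = xyz[a, 3]
        )))
      }
    }
    atoms <- bind_rows(rows)
    manifest <- TOY_POCKET_MANIFEST
    manifest$chain <- "A"
    list(
      pdb = write_pdb(atoms),
      manifest = manifest[, c("chain", "resno", "resname", "kind", "atom")],
      center = c(0, 0, 0),
      radius = 8,
      key_residues = tibble(chain = "A", resno = c(64L, 73L))
    )
  })
}

# orthonormal basis perpendicular to u
perp_basis <- function(u) {
  ref <- if (abs(u[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  e1 <- unitv(c(
    u[2] * ref[3] - u[3] * ref[2],
    u[3] * ref[1] - u[1] * ref[3],
    u[1] * ref[2] - u[2] * ref[1]
  ))
  e2 <- c(
    u[2] * e1[3] - u[3] * e1[2],
    u[3] * e1[1] - u[1] * e1[3],
    u[1] * e1[2] - u[2] * e1[1]
  )
  list(e1 = e1, e2 = e2)
}

# choose a position for an auxiliary atom near `pos`, preferring clearance
# from exclusion spheres when `avoid` is given
place_clear <- function(pos, toward, avoid, clearance = 1.5) {
  if (is.null(avoid) || nrow(avoid) == 0) return(pos)
  clear <- function(p) {
    min(sqrt((avoid$x - p[1])^2 + (avoid$y - p[2])^2 + (avoid$z - p[3])^2))
  }
  if (clear(pos) >= clearance) return(pos)
  dirv <- unitv(toward - pos)
  if (is.null(dirv)) return(pos)
  cands <- map(seq_len(4), function(k) pos + 0.5 * k * dirv)
  scores <- map_dbl(cands, clear)
  if (any(scores >= clearance)) {
    cands[[which(scores >= clearance)[1]]]
  } else {
    cands[[which.max(scores)]]
  }
}

# append a feature-expressing group; `mode` controls chemistry:
#   donor        N with explicit H (also an amine acceptor)
#   donor_plus   protonated amine N-H (donor, never an acceptor)
#   acceptor     carbonyl C=O (O is the feature atom; no hydrogens, so it
#                never expresses a donor)
#   hydrophobic  cyclopropane ring centred on the target
#   subst_C      bare C placeholder (no donor/acceptor; used when dropping
#                acceptors -- a placeholder O would itself be an acceptor)
add_group <- function(mol, mode, p, u, avoid, interior, dir = NULL) {
  idx <- function() nrow(mol$atoms)
  push <- function(element, pos, charge = 0L) {
    mol$atoms <<- bind_rows(mol$atoms, tibble(element = element, charge = charge))
    mol$xyz <<- rbind(mol$xyz, pos)
    idx()
  }
  bond <- function(i, j, order = 1L) {
    mol$bonds <<- bind_rows(mol$bonds, tibble(i = i, j = j, order = order))
  }
  anchor <- switch(mode,
    donor = ,
    donor_plus = {
      n <- push("N", p, charge = if (mode == "donor_plus") 1L else 0L)
      # the hydrogen points along the feature direction (at the protein
      # acceptor site) when one is known, giving near-linear H-bond geometry
      hpos <- if (is.null(dir)) place_clear(p + 1.0 * u, interior, avoid) else p + 1.0 * dir
      h <- push("H", hpos)
      bond(n, h)
      n
    },
    acceptor = {
      o <- push("O", p)
      cdir <- if (is.null(dir)) u else -dir
      c_ <- push("C", place_clear(p + 1.23 * cdir, interior, avoid))
      bond(c_, o, 2L)
      c_
    },
    hydrophobic = {
      b <- perp_basis(u)
      ids <- map_int(0:2, function(t) {
        ang <- 2 * pi * t / 3
        push("C", p + 0.87 * (cos(ang) * b$e1 + sin(ang) * b$e2))
      })
      bond(ids[1], ids[2]); bond(ids[2], ids[3]); bond(ids[3], ids[1])
      ids[1]
    },
    subst_C = push("C", p)
  )
  mol$anchors <- c(mol$anchors, anchor)
  mol
}

# assemble one synthetic ligand expressing the given targets
build_planted_ligand <- function(id, targets, modes, n_link, decoration,
                                 avoid = NULL) {
  interior <- c(mean(targets$x), mean(targets$y), mean(targets$z))
  mol <- list(
    atoms = tibble(element = character(), charge = integer()),
    bonds = tibble(i = integer(), j = integer(), order = integer()),
    xyz = matrix(0, 0, 3), anchors = integer()
  )
  for (g in seq_len(nrow(targets))) {
    p <- c(targets$x[g], targets$y[g], targets$z[g])
    u <- unitv(interior - p) %||% c(0, 0, 1)
    dir <- NULL
    if (all(c("dx", "dy", "dz") %in% names(targets)) && !is.na(targets$dx[g])) {
      dir <- c(targets$dx[g], targets$dy[g], targets$dz[g])
    }
    mol <- add_group(mol, modes[g], p, u, avoid, interior, dir = dir)
  }
  # chain the group anchors with optional carbon linkers
  for (g in seq_len(nrow(targets))[-1]) {
    a <- mol$anchors[g - 1]
    b <- mol$anchors[g]
    if (n_link == 0) {
      mol$bonds <- bind_rows(mol$bonds, tibble(i = a, j = b, order = 1L))
    } else {
      prev <- a
      pa <- mol$xyz[a, ]; pb <- mol$xyz[b, ]
      for (t in seq_len(n_link)) {
        pos <- pa + (pb - pa) * t / (n_link + 1)
        pos <- place_clear(pos, interior, avoid)
        mol$atoms <- bind_rows(mol$atoms, tibble(element = "C", charge = 0L))
        mol$xyz <- rbind(mol$xyz, pos)
        cur <- nrow(mol$atoms)
        mol$bonds <- bind_rows(mol$bonds, tibble(i = prev, j = cur, order = 1L))
        prev <- cur
      }
      mol$bonds <- bind_rows(mol$bonds, tibble(i = prev, j = b, order = 1L))
    }
  }
  if (!is.null(decoration)) {
    a <- mol$anchors[1]
    pos <- place_clear(mol$xyz[a, ] + c(0, 0, 1.4), interior, avoid)
    mol$atoms <- bind_rows(mol$atoms, tibble(element = decoration, charge = 0L))
    mol$xyz <- rbind(mol$xyz, pos)
    mol$bonds <- bind_rows(mol$bonds, tibble(
      i = a, j = nrow(mol$atoms), order = 1L
    ))
  }
  new_ligand(id, mol$atoms, mol$bonds, conformers = list(unname(mol$xyz)))
}

#' Generate a planted ligand library for a hypothesis
#'
#' Actives are synthetic molecules whose perceived pharmacophore features
#' cover every hypothesis feature: donor features become amine N-H groups,
#' acceptor features carbonyl oxygens, hydrophobic features cyclopropane
#' rings centred on the feature. One feature per active is displaced by
#' exactly `displacement`; the others sit on the hypothesis. Actives differ
#' in linker length and a decorating substituent so they are structurally
#' distinguishable by fingerprints. Decoys either omit every group of one
#' feature kind present in the hypothesis (kind-deficient: they can never
#' match) or scale the feature geometry up until every pairwise distance
#' violates the match tolerance (distance-violating).
#'
#' @param hypothesis A feature tibble (`kind`, `x`, `y`, `z`, `tolerance`),
#'   or one row of an [enumerate_hypotheses()] result.
#' @param n_active,n_decoy Library composition (defaults 5 and 45).
#' @param displacement Planting displacement in Angstroms; must be smaller
#'   than the smallest feature tolerance (default 0.5).
#' @param seed Integer seed.
#' @param avoid Optional exclusion tibble; auxiliary atoms are nudged toward
#'   the pocket interior to keep clear of the spheres.
#' @return A list: `ligands` (list of `ligand`), `labels` (tibble `id`,
#'   `role`, `defect`), `sdf` (the library as SDF text).
#' @export
make_planted_library <- function(hypothesis, n_active = 5, n_decoy = 45,
                                 displacement = 0.5, seed = 1, avoid = NULL) {
  if (is.data.frame(hypothesis) && "features" %in% names(hypothesis)) {
    stopifnot(nrow(hypothesis) == 1)
    hypothesis <- hypothesis$features[[1]]
  }
  hyp <- as_tibble(hypothesis)
  stopifnot(all(c("kind", "x", "y", "z", "tolerance") %in% names(hyp)))
  if (displacement >= min(hyp$tolerance)) {
    abort("displacement must be smaller than the smallest feature tolerance.")
  }
  k <- nrow(hyp)
  kinds <- unique(hyp$kind)
  decorations <- c("F", "CL", "BR", "S", "I")
  pos <- as.matrix(hyp[, c("x", "y", "z")])
  pd <- as.matrix(dist(pos))
  min_d <- min(pd[upper.tri(pd)])
  max_d <- max(pd[upper.tri(pd)])
  scale_factor <- (max_d + 2 * max(hyp$tolerance) + 1) / max(min_d, 0.1)
  local_seed(seed, {
    ligs <- list()
    labels <- list()
    for (a in seq_len(n_active)) {
      targets <- hyp[, intersect(c("kind", "x", "y", "z", "dx", "dy", "dz"), names(hyp))]
      if (displacement > 0) {
        di <- ((a - 1) %% k) + 1
        dirv <- unitv(runif(3, -1, 1)) %||% c(1, 0, 0)
        targets$x[di] <- targets$x[di] + displacement * dirv[1]
        targets$y[di] <- targets$y[di] + displacement * dirv[2]
        targets$z[di] <- targets$z[di] + displacement * dirv[3]
      }
      id <- sprintf("ACT-%03d", a)
      ligs <- c(ligs, list(build_planted_ligand(
        id, targets,
        modes = targets$kind,
        n_link = (a - 1) %% 4,
        decoration = decorations[((a - 1) %% length(decorations)) + 1],
        avoid = avoid
      )))
      labels <- c(labels, list(tibble(id = id, role = "active", defect = NA_character_)))
    }
    for (d in seq_len(n_decoy)) {
      id <- sprintf("DEC-%03d", d)
      if (d %% 2 == 1) {
        drop_kind <- kinds[((d - 1) %/% 2) %% length(kinds) + 1]
        modes <- map_chr(hyp$kind, function(kk) {
          if (kk != drop_kind) {
            # kind-deficient decoys must not express the dropped kind through
            # side effects: amines are protonated when acceptors are dropped,
            # and no oxygen is used when dropping donors would add acceptors
            switch(kk,
              donor = if (drop_kind == "acceptor") "donor_plus" else "donor",
              acceptor = "acceptor",
              hydrophobic = "hydrophobic"
            )
          } else {
            # the substitute itself must not express the dropped kind: a
            # carbonyl carries no hydrogens (never a donor) and no ring or
            # apolar run (never hydrophobic); a bare carbon is never an
            # acceptor
            switch(drop_kind,
              donor = "acceptor",
              acceptor = "subst_C",
              hydrophobic = "acceptor"
            )
          }
        })
        n_link <- if (drop_kind == "hydrophobic") min((d - 1) %% 4, 2) else (d - 1) %% 4
        ligs <- c(ligs, list(build_planted_ligand(
          id, hyp[, intersect(c("kind", "x", "y", "z", "dx", "dy", "dz"), names(hyp))],
          modes = modes, n_link = n_link, decoration = NULL, avoid = avoid
        )))
        labels <- c(labels, list(tibble(
          id = id, role = "decoy", defect = paste0("missing_", drop_kind)
        )))
      } else {
        cen <- colMeans(pos)
        scaled <- sweep(sweep(pos, 2, cen), 1, rep(scale_factor, k), "*") +
          matrix(cen, k, 3, byrow = TRUE)
        targets <- tibble(
          kind = hyp$kind, x = scaled[, 1], y = scaled[, 2], z = scaled[, 3]
        )
        modes <- map_chr(hyp$kind, function(kk) {
          switch(kk, donor = "donor_plus", acceptor = "acceptor", hydrophobic = "hydrophobic")
        })
        ligs <- c(ligs, list(build_planted_ligand(
          id, targets, modes = modes, n_link = 0, decoration = NULL, avoid = NULL
        )))
        labels <- c(labels, list(tibble(id = id, role = "decoy", defect = "distance")))
      }
    }
    list(ligands = ligs, labels = bind_rows(labels), sdf = write_sdf(ligs))
  })
}

#' Generate a screen readout table with planted hit counts
#'
#' Emulates a primary-screen readout over `n` compounds: exactly
#' `n_ru_hits` compounds exceed the RU threshold, exactly `n_inh_hits`
#' exceed the inhibition threshold, and exactly `n_overlap` exceed both.
#' Values are drawn with a margin of 2 RU / 3 percentage points from the
#' thresholds so strict-inequality triage recovers the planted counts
#' exactly.
#'
#' @param n Number of compounds (default 100).
#' @param n_ru_hits,n_inh_hits,n_overlap Planted counts (defaults 5, 7, 1).
#' @param ru_min,inh_min Thresholds the counts refer to (defaults 20, 30).
#' @param seed Integer seed.
#' @return A tibble `compound_id`, `ru`, `inhibition`, with the planted
#'   truth in attribute `"truth"`.
#' @export
make_screen_table <- function(n = 100, n_ru_hits = 5, n_inh_hits = 7,
                              n_overlap = 1, ru_min = 20, inh_min = 30,
                              seed = 1) {
  if (n_overlap > min(n_ru_hits, n_inh_hits)) {
    abort("n_overlap cannot exceed min(n_ru_hits, n_inh_hits).")
  }
  if (n_ru_hits + n_inh_hits - n_overlap > n) {
    abort("Requested hit counts exceed n.")
  }
  local_seed(seed, {
    ids <- sprintf("CMP-%03d", seq_len(n))
    shuffled <- sample(n)
    both <- shuffled[seq_len(n_overlap)]
    ru_only <- shuffled[n_overlap + seq_len(n_ru_hits - n_overlap)]
    inh_only <- shuffled[n_ru_hits + seq_len(n_inh_hits - n_overlap)]
    ru <- runif(n, 0, ru_min - 2)
    inh <- runif(n, -10, inh_min - 3)
    ru[c(both, ru_only)] <- runif(n_ru_hits, ru_min + 2, ru_min + 50)
    inh[c(both, inh_only)] <- runif(n_inh_hits, inh_min + 3, 95)
    out <- tibble(compound_id = ids, ru = round(ru, 3), inhibition = round(inh, 3))
    attr(out, "truth") <- list(
      ru_hits = sort(ids[c(both, ru_only)]),
      inh_hits = sort(ids[c(both, inh_only)]),
      intersection = sort(ids[both])
    )
    out
  })
}

#' Generate 4PL dose-response data with known parameters
#'
#' `response = bottom + (top - bottom) / (1 + (dose/ic50)^hill) + e`,
#' with `e ~ Normal(0, noise_sd)` under the given seed.
#'
#' @param bottom,top,hill,ic50 True curve parameters (defaults 0, 100, 1,
#'   10).
#' @param doses Dose grid (> 0); the default is the standard half-log
#'   serial-dilution design, 8 doses bracketing the ic50 (about 0.018x to
#'   56x), anchoring both asymptotes while sampling the transition.
#' @param replicates Independent replicate responses per dose (default 1;
#'   dose-response assays are typically run as triplicate measurements of
#'   several independent experiments).
#' @param noise_sd Gaussian noise standard deviation (default 0).
#' @param seed Integer seed.
#' @return A tibble `dose`, `response` with the true parameters in attribute
#'   `"truth"`.
#' @export
make_dose_response <- function(bottom = 0, top = 100, hill = 1, ic50 = 10,
                               doses = NULL, replicates = 1, noise_sd = 0,
                               seed = 1) {
  doses <- doses %||% (10^seq(-1.75, 1.75, by = 0.5) * ic50)
  doses <- rep(doses, replicates)
  if (any(doses <= 0)) abort("Doses must be positive.")
  local_seed(seed, {
    y <- fourpl(doses, bottom, top, hill, ic50) + rnorm(length(doses), 0, noise_sd)
    out <- tibble(dose = doses, response = y)
    attr(out, "truth") <- list(bottom = bottom, top = top, hill = hill, ic50 = ic50)
    out
  })
}
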