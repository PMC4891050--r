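# Ligand molecular model: a small-molecule graph with optional 3D conformers.
# SMILES and SDF input are parsed with OpenBabel (ChemmineOB) and ChemmineR;
# property estimation and feature perception are rule-based and deterministic.

# IUPAC standard average atomic weights, 4 decimals (table version paw-2021).
ATOMIC_WEIGHTS <- c(
  H = 1.008, D = 2.0141, B = 10.81, C = 12.011, N = 14.007, O = 15.999,
  F = 18.9984, "NA" = 22.9898, MG = 24.305, SI = 28.085, P = 30.974, S = 32.06,
  CL = 35.45, K = 39.0983, CA = 40.078, BR = 79.904, I = 126.9045
)

# default valences for implicit-hydrogen inference
DEFAULT_VALENCE <- c(
  C = 4, N = 3, O = 2, S = 2, P = 3, B = 3,
  F = 1, CL = 1, BR = 1, I = 1, H = 1, D = 1
)

#' Construct a ligand object
#'
#' A ligand is a molecular graph (atoms with formal charges, bonds with
#' integer orders) plus zero or more 3D conformers. Implicit hydrogen counts
#' are inferred from default valences (adjusted by formal charge), so graphs
#' built with explicit hydrogens get zero inferred hydrogens on those
#' positions automatically.
#'
#' @param id Ligand identifier.
#' @param atoms Data frame with columns `element` and optionally `charge`
#'   (formal charge, default 0).
#' @param bonds Data frame with columns `i`, `j`, `order` (1, 2, 3; 4 is
#'   treated as aromatic order 1.5 for valence purposes). May have zero rows.
#' @param conformers List of numeric matrices (n_atoms x 3, Angstroms).
#' @param multi_fragment Allow a disconnected graph? Default `FALSE`.
#' @return An object of class `ligand`.
#' @export
new_ligand <- function(id, atoms, bonds, conformers = list(), multi_fragment = FALSE) {
  atoms <- as_tibble(atoms)
  if (!"charge" %in% names(atoms)) atoms$charge <- 0L
  bonds <- as_tibble(bonds)
  if (nrow(bonds) == 0) bonds <- tibble(i = integer(), j = integer(), order = integer())
  n <- nrow(atoms)
  if (n == 0) abort("Ligand must have at least one atom.")
  if (nrow(bonds) > 0 && (max(bonds$i, bonds$j) > n || min(bonds$i, bonds$j) < 1)) {
    abort("Bond endpoints outside atom range.")
  }
  for (cf in conformers) {
    if (!is.matrix(cf) || nrow(cf) != n || ncol(cf) != 3) {
      abort("Each conformer must be an n_atoms x 3 coordinate matrix.")
    }
  }
  lig <- structure(
    list(id = id, atoms = atoms, bonds = bonds, conformers = conformers),
    class = "ligand"
  )
  lig$atoms$nh <- infer_implicit_h(lig)
  if (!multi_fragment && n > 1 && length(connected_components(lig)) > 1) {
    abort(sprintf("Ligand '%s' graph is disconnected; set multi_fragment = TRUE to allow.", id))
  }
  lig
}

#' @export
print.ligand <- function(x, ...) {
  cat(sprintf(
    "<ligand '%s'> %s, %d atoms (%d heavy), %d bonds, %d conformer(s)\n",
    x$id, ligand_formula(x), nrow(x$atoms), length(heavy_idx(x)),
    nrow(x$bonds), length(x$conformers)
  ))
  invisible(x)
}

elem_key <- function(e) toupper(e)

heavy_idx <- function(lig) which(!elem_key(lig$atoms$element) %in% c("H", "D"))

# adjacency list over all atoms
lig_adj <- function(lig) {
  adj <- vector("list", nrow(lig$atoms))
  for (r in seq_len(nrow(lig$bonds))) {
    i <- lig$bonds$i[r]; j <- lig$bonds$j[r]
    adj[[i]] <- c(adj[[i]], j)
    adj[[j]] <- c(adj[[j]], i)
  }
  adj
}

connected_components <- function(lig) {
  n <- nrow(lig$atoms)
  adj <- lig_adj(lig)
  comp <- integer(n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (comp[s] != 0L) next
    cur <- cur + 1L
    queue <- s
    comp[s] <- cur
    while (length(queue) > 0) {
      v <- queue[1]; queue <- queue[-1]
      for (w in adj[[v]]) {
        if (comp[w] == 0L) {
          comp[w] <- cur
          queue <- c(queue, w)
        }
      }
    }
  }
  split(seq_len(n), comp)
}

# sum of bond orders per atom (aromatic order 4 counted as 1.5)
bond_order_sum <- function(lig) {
  n <- nrow(lig$atoms)
  s <- numeric(n)
  ord <- ifelse(lig$bonds$order == 4, 1.5, lig$bonds$order)
  for (r in seq_len(nrow(lig$bonds))) {
    s[lig$bonds$i[r]] <- s[lig$bonds$i[r]] + ord[r]
    s[lig$bonds$j[r]] <- s[lig$bonds$j[r]] + ord[r]
  }
  s
}

infer_implicit_h <- function(lig) {
  key <- elem_key(lig$atoms$element)
  val <- DEFAULT_VALENCE[key]
  chg <- lig$atoms$charge
  # charge raises N/P valence, lowers O/S; carbon valence drops either way
  eff <- ifelse(key %in% c("N", "P"), val + chg,
    ifelse(key %in% c("O", "S"), val + chg, val - abs(chg))
  )
  eff[is.na(eff)] <- 0
  pmax(0L, as.integer(round(eff - bond_order_sum(lig))))
}

# total hydrogens on each atom: inferred implicit + explicit H neighbours
h_count <- function(lig) {
  nh <- lig$atoms$nh
  is_h <- elem_key(lig$atoms$element) %in% c("H", "D")
  for (r in seq_len(nrow(lig$bonds))) {
    i <- lig$bonds$i[r]; j <- lig$bonds$j[r]
    if (is_h[j]) nh[i] <- nh[i] + 1L
    if (is_h[i]) nh[j] <- nh[j] + 1L
  }
  nh
}

#' Molecular formula in Hill order
#'
#' @param ligand A [new_ligand()] object.
#' @return A string such as `"C21H21NO2"` (explicit plus implicit hydrogens).
#' @export
ligand_formula <- function(ligand) {
  key <- elem_key(ligand$atoms$element)
  counts <- table(key)
  nH <- sum(ligand$atoms$nh) + sum(counts[names(counts) %in% c("H", "D")])
  counts <- counts[!names(counts) %in% c("H", "D")]
  std <- c(C = "C", N = "N", O = "O", S = "S", P = "P", F = "F",
    CL = "Cl", BR = "Br", I = "I", B = "B")
  show <- function(sym, n) if (n == 1) sym else paste0(sym, n)
  parts <- character()
  if ("C" %in% names(counts)) parts <- c(parts, show("C", counts[["C"]]))
  if (nH > 0) parts <- c(parts, show("H", nH))
  rest <- sort(setdiff(names(counts), "C"))
  for (k in rest) parts <- c(parts, show(std[k] %||% k, counts[[k]]))
  paste(parts, collapse = "")
}

#' Molecular weight from standard atomic weights
#'
#' Sum of IUPAC standard average atomic weights over all atoms, including
#' implicit hydrogens.
#'
#' @param ligand A `ligand` object.
#' @return Molecular weight in Daltons.
#' @export
#' @examples
#' mol_weight(parse_smiles("CCO")) # ethanol, 46.069
mol_weight <- function(ligand) {
  key <- elem_key(ligand$atoms$element)
  w <- ATOMIC_WEIGHTS[key]
  if (anyNA(w)) {
    abort(sprintf(
      "Unknown element(s): %s", paste(unique(key[is.na(w)]), collapse = ", ")
    ))
  }
  sum(w) + sum(ligand$atoms$nh) * ATOMIC_WEIGHTS[["H"]]
}

# ---- SMILES / SDF I/O -------------------------------------------------------

# light syntactic validation so gross SMILES errors are reported with an
# offset (the OpenBabel reader is lenient and silently recovers)
validate_smiles <- function(s) {
  if (!nzchar(s)) return(list(offset = 0L, msg = "empty SMILES"))
  chars <- strsplit(s, "")[[1]]
  allowed <- c(
    LETTERS, letters, as.character(0:9),
    "(", ")", "[", "]", "=", "#", "+", "-", "/", "\\", "@", "%", ".", ":", "*"
  )
  ok <- chars %in% allowed
  if (any(!ok)) {
    i <- which(!ok)[1]
    return(list(offset = i, msg = sprintf("invalid character '%s'", chars[i])))
  }
  depth_p <- 0L; depth_b <- 0L
  ring <- integer()
  i <- 1L
  n <- length(chars)
  while (i <= n) {
    ch <- chars[i]
    if (ch == "(") depth_p <- depth_p + 1L
    if (ch == ")") {
      depth_p <- depth_p - 1L
      if (depth_p < 0) return(list(offset = i, msg = "unmatched ')'"))
    }
    if (ch == "[") depth_b <- depth_b + 1L
    if (ch == "]") {
      depth_b <- depth_b - 1L
      if (depth_b < 0) return(list(offset = i, msg = "unmatched ']'"))
    }
    if (depth_b == 0 && grepl("[0-9]", ch)) {
      lab <- as.integer(ch)
      ring <- c(ring, lab)
    }
    if (depth_b == 0 && ch == "%") {
      if (i + 2 > n || !grepl("^[0-9]{2}$", paste0(chars[i + 1], chars[i + 2]))) {
        return(list(offset = i, msg = "bad %nn ring closure"))
      }
      ring <- c(ring, as.integer(paste0(chars[i + 1], chars[i + 2])))
      i <- i + 2L
    }
    i <- i + 1L
  }
  if (depth_p != 0) return(list(offset = n, msg = "unclosed '('"))
  if (depth_b != 0) return(list(offset = n, msg = "unclosed '['"))
  odd <- names(which(table(ring) %% 2 == 1))
  if (length(odd) > 0) {
    return(list(offset = n, msg = sprintf("unpaired ring closure %s", odd[1])))
  }
  NULL
}

#' Parse a SMILES string
#'
#' Validates the string syntactically (reporting the offset of the first
#' problem), then parses it with OpenBabel. Implicit hydrogens are
#' materialized as explicit atoms, so formula and weight are complete.
#'
#' @param smiles A single SMILES string.
#' @param id Ligand id (default the SMILES itself).
#' @param gen3d Generate a 3D conformer with OpenBabel? Default `FALSE`
#'   (a flat layout conformer is still attached).
#' @return A `ligand` object.
#' @export
#' @examples
#' lig <- parse_smiles("CCO")
#' ligand_formula(lig)
parse_smiles <- function(smiles, id = smiles, gen3d = FALSE) {
  stopifnot(is.character(smiles), length(smiles) == 1)
  bad <- validate_smiles(smiles)
  if (!is.null(bad)) {
    abort(
      sprintf("SMILES parse error at offset %d: %s", bad$offset, bad$msg),
      class = "phorescreen_parse_error"
    )
  }
  opts <- if (gen3d) {
    data.frame(names = c("gen3D", "h"), args = c("", ""))
  } else {
    data.frame(names = c("gen2D", "h"), args = c("", ""))
  }
  sdf <- ChemmineOB::convertFormat("SMI", "SDF", paste0(smiles, " mol"), options = opts)
  if (!nzchar(sdf)) {
    abort("SMILES parse error: OpenBabel returned no molecule.",
      class = "phorescreen_parse_error"
    )
  }
  ligs <- parse_sdf(sdf)
  lig <- ligs[[1]]
  lig$id <- id
  lig
}

#' Read a SMILES file (one molecule per line, optional id)
#'
#' @param text Character: file text or vector of lines (`SMILES[ <id>]`).
#' @return A list of `ligand` objects.
#' @export
read_smiles <- function(text) {
  lines <- if (length(text) == 1L) strsplit(text, "\n", fixed = TRUE)[[1]] else text
  lines <- lines[nzchar(str_trim(lines))]
  map(seq_along(lines), function(i) {
    parts <- strsplit(str_trim(lines[i]), "[ \t]+")[[1]]
    parse_smiles(parts[1], id = if (length(parts) > 1) parts[2] else parts[1])
  })
}

#' Parse an SDF (V2000) file into ligands
#'
#' Uses the ChemmineR reader for atom and bond blocks; `M  CHG` lines are
#' applied as formal charges. Coordinates become conformer 1.
#'
#' @param text SDF text (single string or vector of lines).
#' @return A list of `ligand` objects.
#' @export
parse_sdf <- function(text) {
  lines <- if (length(text) == 1L) strsplit(text, "\n", fixed = TRUE)[[1]] else text
  # split into molecule blocks
  ends <- which(startsWith(lines, "$$$$"))
  if (length(ends) == 0) ends <- length(lines) + 1L
  starts <- c(1L, head(ends, -1) + 1L)
  blocks <- map2(starts, ends, function(s, e) lines[s:min(e - 1L, length(lines))])
  blocks <- keep(blocks, function(b) any(nzchar(str_trim(b))))
  map(seq_along(blocks), function(bi) parse_sdf_block(blocks[[bi]], bi))
}

parse_sdf_block <- function(block, block_index) {
  name <- str_trim(block[1])
  if (!nzchar(name)) name <- sprintf("mol%d", block_index)
  if (length(block) < 4) {
    abort(sprintf("SDF block %d ('%s'): truncated header.", block_index, name),
      class = "phorescreen_parse_error"
    )
  }
  counts <- block[4]
  natoms <- suppressWarnings(as.integer(substr(counts, 1, 3)))
  nbonds <- suppressWarnings(as.integer(substr(counts, 4, 6)))
  if (is.na(natoms) || is.na(nbonds) || natoms < 1 ||
    length(block) < 4 + natoms + nbonds) {
    abort(
      sprintf("SDF block %d ('%s'): bad counts line '%s'.", block_index, name, counts),
      class = "phorescreen_parse_error"
    )
  }
  sdfset <- tryCatch(
    suppressWarnings(ChemmineR::read.SDFset(ChemmineR::read.SDFstr(c(block, "$$$$")))),
    error = function(e) {
      abort(
        sprintf("SDF block %d ('%s'): %s", block_index, name, conditionMessage(e)),
        class = "phorescreen_parse_error"
      )
    }
  )
  sdf <- sdfset[[1]]
  ab <- ChemmineR::atomblock(sdf)
  bb <- ChemmineR::bondblock(sdf)
  if (nrow(ab) != natoms) {
    abort(
      sprintf(
        "SDF block %d ('%s'): atom block has %d atoms but counts line says %d.",
        block_index, name, nrow(ab), natoms
      ),
      class = "phorescreen_parse_error"
    )
  }
  element <- sub("_.*$", "", rownames(ab))
  charge <- integer(natoms)
  chg_lines <- block[startsWith(block, "M  CHG")]
  for (ln in chg_lines) {
    flds <- as.integer(strsplit(str_trim(substr(ln, 7, nchar(ln))), "[ ]+")[[1]])
    npairs <- flds[1]
    for (p in seq_len(npairs)) {
      charge[flds[2 * p]] <- flds[2 * p + 1]
    }
  }
  bonds <- if (nrow(bb) == 0) {
    tibble(i = integer(), j = integer(), order = integer())
  } else {
    tibble(
      i = as.integer(bb[, 1]), j = as.integer(bb[, 2]),
      order = as.integer(bb[, 3])
    )
  }
  coords <- unname(as.matrix(ab[, 1:3, drop = FALSE]))
  new_ligand(
    id = name,
    atoms = tibble(element = element, charge = charge),
    bonds = bonds,
    conformers = list(coords),
    multi_fragment = TRUE
  )
}

#' Write ligands as SDF (V2000) text
#'
#' Coordinates are written to 4 decimals; nonzero formal charges are emitted
#' as `M  CHG` lines. Round-trips through [parse_sdf()] preserve atom, bond
#' and coordinate tables.
#'
#' @param ligands A `ligand` or list of ligands.
#' @param conformer Conformer index to write (default 1; zero coordinates are
#'   written for ligands without conformers).
#' @return A single SDF string.
#' @export
write_sdf <- function(ligands, conformer = 1) {
  if (inherits(ligands, "ligand")) ligands <- list(ligands)
  blocks <- map_chr(ligands, function(lig) {
    n <- nrow(lig$atoms)
    nb <- nrow(lig$bonds)
    xyz <- if (length(lig$conformers) >= conformer) {
      lig$conformers[[conformer]]
    } else {
      matrix(0, n, 3)
    }
    atom_lines <- sprintf(
      "%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
      xyz[, 1], xyz[, 2], xyz[, 3], lig$atoms$element
    )
    bond_lines <- if (nb > 0) {
      sprintf("%3d%3d%3d  0  0  0  0", lig$bonds$i, lig$bonds$j, lig$bonds$order)
    } else {
      character()
    }
    chg <- which(lig$atoms$charge != 0)
    chg_lines <- if (length(chg) > 0) {
      sprintf(
        "M  CHG%3d%s", length(chg),
        paste(sprintf("%4d%4d", chg, lig$atoms$charge[chg]), collapse = "")
      )
    } else {
      character()
    }
    paste(c(
      lig$id, "  phorescreen", "",
      sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", n, nb),
      atom_lines, bond_lines, chg_lines, "M  END", "$$$$"
    ), collapse = "\n")
  })
  paste0(paste(blocks, collapse = "\n"), "\n")
}

# ---- ring perception and derived sets --------------------------------------

# rings via ChemmineR on the ligand's own V2000 serialization;
# returns list(rings = list of integer index vectors, aromatic = logical)
ligand_rings <- function(ligand) {
  hv <- heavy_idx(ligand)
  if (nrow(ligand$bonds) < 3 || length(hv) < 3) {
    return(list(rings = list(), aromatic = logical()))
  }
  sdfset <- suppressWarnings(
    ChemmineR::read.SDFset(ChemmineR::read.SDFstr(
      strsplit(write_sdf(ligand), "\n", fixed = TRUE)[[1]]
    ))
  )
  r <- tryCatch(
    suppressWarnings(ChemmineR::rings(sdfset[[1]], upper = 10, type = "all", arom = TRUE)),
    error = function(e) list(RINGS = list(), AROMATIC = logical())
  )
  idx <- map(r$RINGS, function(ring) as.integer(sub("^.*_", "", ring)))
  list(rings = idx, aromatic = as.logical(r$AROMATIC))
}

ring_atom_set <- function(rings) sort(unique(unlist(rings$rings)))

aromatic_atom_set <- function(rings) {
  if (length(rings$rings) == 0) return(integer())
  sort(unique(unlist(rings$rings[rings$aromatic])))
}

ring_bond_pairs <- function(rings) {
  prs <- list()
  for (ring in rings$rings) {
    k <- length(ring)
    for (t in seq_len(k)) {
      a <- ring[t]; b <- ring[if (t == k) 1 else t + 1]
      prs <- c(prs, list(sort(c(a, b))))
    }
  }
  unique(prs)
}

#' Count rotatable bonds
#'
#' Single, acyclic bonds between two heavy atoms that each have at least one
#' further heavy neighbour.
#'
#' @param ligand A `ligand` object.
#' @param rings Optional precomputed [ligand_rings] result.
#' @return Integer count.
#' @export
n_rotatable <- function(ligand, rings = ligand_rings(ligand)) {
  if (nrow(ligand$bonds) == 0) return(0L)
  is_h <- elem_key(ligand$atoms$element) %in% c("H", "D")
  hdeg <- integer(nrow(ligand$atoms))
  for (r in seq_len(nrow(ligand$bonds))) {
    i <- ligand$bonds$i[r]; j <- ligand$bonds$j[r]
    if (!is_h[j]) hdeg[i] <- hdeg[i] + 1L
    if (!is_h[i]) hdeg[j] <- hdeg[j] + 1L
  }
  ringb <- ring_bond_pairs(rings)
  cnt <- 0L
  for (r in seq_len(nrow(ligand$bonds))) {
    i <- ligand$bonds$i[r]; j <- ligand$bonds$j[r]
    if (ligand$bonds$order[r] != 1 || is_h[i] || is_h[j]) next
    if (hdeg[i] < 2 || hdeg[j] < 2) next
    if (list(sort(c(i, j))) %in% ringb) next
    cnt <- cnt + 1L
  }
  cnt
}

# ---- logP / logS ------------------------------------------------------------

# Atom-additive logP contributions (table version plogp-0.1). Strictly
# additive over atoms, hence over disconnected fragments. Hydrogens
# (explicit or implicit) contribute by the polarity of the atom they sit on.
LOGP_CONTRIB <- c(
  C_AROMATIC = 0.23, C_ALIPHATIC = 0.14, N = -0.60, O = -0.64,
  S = 0.25, P = -0.50, F = 0.22, CL = 0.65, BR = 0.86, I = 1.12,
  H_ON_C = 0.10, H_ON_HET = -0.23
)

#' Estimate logP by an additive atom-contribution scheme
#'
#' Each heavy atom contributes a fixed value by element (aromatic and
#' aliphatic carbon differ); each hydrogen contributes by the polarity of its
#' parent atom. Atom types missing from the table contribute 0 with a
#' warning. The scheme is strictly additive over disconnected fragments.
#' Table version: plogp-0.1.
#'
#' @param ligand A `ligand` object.
#' @param rings Optional precomputed [ligand_rings] result.
#' @return Estimated logP (octanol/water partition, unitless).
#' @export
logp_estimate <- function(ligand, rings = ligand_rings(ligand)) {
  key <- elem_key(ligand$atoms$element)
  arom <- aromatic_atom_set(rings)
  hc <- h_count(ligand)
  total <- 0
  missing <- character()
  for (i in seq_len(nrow(ligand$atoms))) {
    k <- key[i]
    if (k %in% c("H", "D")) next # counted with the parent atom
    contrib <- if (k == "C") {
      if (i %in% arom) LOGP_CONTRIB[["C_AROMATIC"]] else LOGP_CONTRIB[["C_ALIPHATIC"]]
    } else if (k %in% names(LOGP_CONTRIB)) {
      LOGP_CONTRIB[[k]]
    } else {
      missing <- c(missing, k)
      0
    }
    h_contrib <- if (k == "C") LOGP_CONTRIB[["H_ON_C"]] else LOGP_CONTRIB[["H_ON_HET"]]
    total <- total + contrib + hc[i] * h_contrib
  }
  if (length(missing) > 0) {
    warn(sprintf(
      "logP table has no entry for element(s) %s; contribution 0 used.",
      paste(unique(missing), collapse = ", ")
    ))
  }
  total
}

# logS linear-model coefficients: ESOL-style aqueous solubility estimate
# (Delaney 2004 coefficients): intercept, logP, MW, rotatable bonds,
# aromatic proportion.
LOGS_COEFS <- c(
  intercept = 0.16, logp = -0.63, mw = -0.0062,
  n_rotatable = 0.066, aromatic_proportion = -0.74
)

#' Evaluate the logS linear model from its predictors
#'
#' `logS = 0.16 - 0.63 logP - 0.0062 MW + 0.066 RB - 0.74 AP`, the
#' ESOL-style aqueous-solubility model with published coefficients (AP is
#' the aromatic proportion of heavy atoms).
#'
#' @param logp,mw,n_rotatable,aromatic_proportion Model predictors.
#' @return Estimated logS (log10 mol/L).
#' @export
logs_from_predictors <- function(logp, mw, n_rotatable, aromatic_proportion) {
  unname(
    LOGS_COEFS["intercept"] + LOGS_COEFS["logp"] * logp + LOGS_COEFS["mw"] * mw +
      LOGS_COEFS["n_rotatable"] * n_rotatable +
      LOGS_COEFS["aromatic_proportion"] * aromatic_proportion
  )
}

#' Estimate aqueous solubility (logS)
#'
#' @param ligand A `ligand` object.
#' @param rings Optional precomputed [ligand_rings] result.
#' @return Estimated logS; see [logs_from_predictors()] for the model.
#' @export
logs_estimate <- function(ligand, rings = ligand_rings(ligand)) {
  hv <- heavy_idx(ligand)
  ap <- if (length(hv) == 0) 0 else length(intersect(aromatic_atom_set(rings), hv)) / length(hv)
  logs_from_predictors(
    logp = logp_estimate(ligand, rings),
    mw = mol_weight(ligand),
    n_rotatable = n_rotatable(ligand, rings),
    aromatic_proportion = ap
  )
}

#' Compute the ligand property table
#'
#' @param ligands A `ligand` or list of ligands.
#' @return A tibble: `id`, `mw`, `logp`, `logs`, `n_rotatable`.
#' @export
ligand_properties <- function(ligands) {
  if (inherits(ligands, "ligand")) ligands <- list(ligands)
  bind_rows(map(ligands, function(lig) {
    rings <- ligand_rings(lig)
    tibble(
      id = lig$id,
      mw = mol_weight(lig),
      logp = logp_estimate(lig, rings),
      logs = logs_estimate(lig, rings),
      n_rotatable = n_rotatable(lig, rings)
    )
  }))
}

# ---- ligand pharmacophore features -----------------------------------------

# atom-level donor/acceptor assignment used by feature perception and H-bond
# detection; returns list(donors, acceptors) of atom indices
ligand_da_atoms <- function(ligand, rings = ligand_rings(ligand)) {
  key <- elem_key(ligand$atoms$element)
  hc <- h_count(ligand)
  adj <- lig_adj(ligand)
  arom <- aromatic_atom_set(rings)
  is_h <- key %in% c("H", "D")
  hdeg <- map_int(adj, function(nb) sum(!is_h[nb]))
  # amide N: single-bonded to a carbon that is double-bonded to an O
  dbl_co <- logical(nrow(ligand$atoms)) # carbons with C=O
  for (r in seq_len(nrow(ligand$bonds))) {
    i <- ligand$bonds$i[r]; j <- ligand$bonds$j[r]
    if (ligand$bonds$order[r] == 2) {
      if (key[i] == "C" && key[j] == "O") dbl_co[i] <- TRUE
      if (key[j] == "C" && key[i] == "O") dbl_co[j] <- TRUE
    }
  }
  amide_n <- map_lgl(seq_along(adj), function(i) {
    key[i] == "N" && any(dbl_co[adj[[i]]])
  })
  donors <- which(key %in% c("N", "O") & hc >= 1)
  acceptors <- which(
    key == "O" |
      (key == "N" & !amide_n & ligand$atoms$charge <= 0 &
        (hdeg + hc) < 4 &
        # aromatic N is an acceptor only without H
        (!(seq_along(key) %in% arom) | hc == 0))
  )
  list(donors = donors, acceptors = acceptors)
}

#' Perceive ligand pharmacophore features on a conformer
#'
#' Donors are O/N atoms bearing at least one hydrogen; acceptors are any O
#' plus N with a free lone pair (not quaternary, not amide; aromatic N only
#' without H); hydrophobic features are the centroids of carbocyclic rings
#' and of connected runs of three or more acyclic apolar carbons (carbons
#' bonded only to carbon or hydrogen).
#'
#' @param ligand A `ligand` object.
#' @param conformer Conformer index (default 1).
#' @return A tibble: `kind`, `x`, `y`, `z`, `atom_indices` (list column).
#' @export
perceive_ligand_features <- function(ligand, conformer = 1) {
  if (length(ligand$conformers) < conformer) {
    abort(sprintf("Ligand '%s' has no conformer %d.", ligand$id, conformer))
  }
  xyz <- ligand$conformers[[conformer]]
  rings <- ligand_rings(ligand)
  da <- ligand_da_atoms(ligand, rings)
  key <- elem_key(ligand$atoms$element)
  rows <- list()
  frow <- function(kind, idx) {
    cen <- colMeans(xyz[idx, , drop = FALSE])
    tibble(kind = kind, x = cen[1], y = cen[2], z = cen[3], atom_indices = list(idx))
  }
  for (i in da$donors) rows <- c(rows, list(frow("donor", i)))
  for (i in da$acceptors) rows <- c(rows, list(frow("acceptor", i)))
  # carbocyclic ring centroids
  for (ring in rings$rings) {
    if (all(key[ring] == "C")) rows <- c(rows, list(frow("hydrophobic", sort(ring))))
  }
  # acyclic apolar carbon runs
  in_ring <- ring_atom_set(rings)
  adj <- lig_adj(ligand)
  apolar <- which(map_lgl(seq_along(key), function(i) {
    key[i] == "C" && !(i %in% in_ring) &&
      all(key[adj[[i]]] %in% c("C", "H", "D"))
  }))
  if (length(apolar) >= 3) {
    comp <- components_of_subset(adj, apolar)
    for (cmp in comp) {
      if (length(cmp) >= 3) rows <- c(rows, list(frow("hydrophobic", sort(cmp))))
    }
  }
  empty <- tibble(
    kind = character(), x = double(), y = double(), z = double(),
    atom_indices = list()
  )
  bind_rows(empty, rows)
}

# connected components of the induced subgraph on `subset`
components_of_subset <- function(adj, subset) {
  inset <- logical(length(adj))
  inset[subset] <- TRUE
  seen <- logical(length(adj))
  comps <- list()
  for (s in subset) {
    if (seen[s]) next
    queue <- s
    seen[s] <- TRUE
    cmp <- integer()
    while (length(queue) > 0) {
      v <- queue[1]; queue <- queue[-1]
      cmp <- c(cmp, v)
      for (w in adj[[v]]) {
        if (inset[w] && !seen[w]) {
          seen[w] <- TRUE
          queue <- c(queue, w)
        }
      }
    }
    comps <- c(comps, list(cmp))
  }
  comps
}

#' The AC-73 structure as SMILES
#'
#' The CD147 dimerization inhibitor
#' 3-(2-(((1,1'-biphenyl)-4-ylmethyl)amino)-1-hydroxyethyl)phenol
#' (Specs id AN-465/42834501), written as SMILES from its IUPAC name.
#'
#' @return A SMILES string.
#' @export
ac73_smiles <- function() {
  "OC(c1cccc(O)c1)CNCc1ccc(-c2ccccc2)cc1"
}
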