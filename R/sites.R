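# Protein interaction-site perception: a fixed, deterministic rule table
# mapping residue chemistry to H-bond donor/acceptor and hydrophobic sites.
# Works on unprotonated structures: donor directions use idealized heavy-atom
# geometry, never explicit hydrogens.

# side-chain donor/acceptor atoms per residue: atom, kind, root atoms used
# for the direction (root -> atom)
SIDECHAIN_SITES <- list(
  SER = list(list(atom = "OG", kind = c("donor", "acceptor"), root = "CB")),
  THR = list(list(atom = "OG1", kind = c("donor", "acceptor"), root = "CB")),
  TYR = list(list(atom = "OH", kind = c("donor", "acceptor"), root = "CZ")),
  LYS = list(list(atom = "NZ", kind = "donor", root = "CE")),
  ARG = list(
    list(atom = "NE", kind = "donor", root = "CD"),
    list(atom = "NH1", kind = "donor", root = "CZ"),
    list(atom = "NH2", kind = "donor", root = "CZ")
  ),
  ASP = list(
    list(atom = "OD1", kind = "acceptor", root = "CG"),
    list(atom = "OD2", kind = "acceptor", root = "CG")
  ),
  GLU = list(
    list(atom = "OE1", kind = "acceptor", root = "CD"),
    list(atom = "OE2", kind = "acceptor", root = "CD")
  ),
  ASN = list(
    list(atom = "ND2", kind = "donor", root = "CG"),
    list(atom = "OD1", kind = "acceptor", root = "CG")
  ),
  GLN = list(
    list(atom = "NE2", kind = "donor", root = "CD"),
    list(atom = "OE1", kind = "acceptor", root = "CD")
  ),
  HIS = list(
    list(atom = "ND1", kind = c("donor", "acceptor"), root = "CG"),
    list(atom = "NE2", kind = c("donor", "acceptor"), root = "CE1")
  ),
  TRP = list(list(atom = "NE1", kind = "donor", root = "CD1"))
)

# apolar side-chain carbons whose centroid defines the hydrophobic site
HYDROPHOBIC_ATOMS <- list(
  ALA = "CB",
  VAL = c("CB", "CG1", "CG2"),
  LEU = c("CB", "CG", "CD1", "CD2"),
  ILE = c("CB", "CG1", "CG2", "CD1"),
  PHE = c("CB", "CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
  MET = c("CB", "CG", "CE"),
  PRO = c("CB", "CG", "CD"),
  TRP = c("CB", "CG", "CD1", "CD2", "CE2", "CE3", "CZ2", "CZ3", "CH2")
)

site_row <- function(kind, pos, dir, chain, resno, resname, atom) {
  tibble(
    kind = kind,
    x = pos[1], y = pos[2], z = pos[3],
    dx = if (is.null(dir)) NA_real_ else dir[1],
    dy = if (is.null(dir)) NA_real_ else dir[2],
    dz = if (is.null(dir)) NA_real_ else dir[3],
    chain = chain, resno = resno, resname = resname, atom = atom
  )
}

#' Perceive protein interaction sites
#'
#' Applies a fixed rule table to each residue: backbone N is a donor
#' (direction estimated from N, CA and C when no amide hydrogen is present),
#' backbone O an acceptor (direction C to O); side-chain donors/acceptors
#' follow standard hydrogen-bond chemistry (hydroxyls of Ser/Thr/Tyr both
#' roles, Lys/Arg/Trp side-chain N donors, Asp/Glu carboxylate O acceptors,
#' Asn/Gln amide N donor and O acceptor, His ring N both roles); apolar
#' side chains of Ala/Val/Leu/Ile/Phe/Met/Pro/Trp contribute one hydrophobic
#' site at the centroid of their apolar carbons. Unknown residue names
#' contribute backbone sites only.
#'
#' @param residues A `protein_structure` tibble (typically a pocket selection
#'   from [select_pocket()]).
#' @return A tibble of sites: `kind` (donor/acceptor/hydrophobic), position
#'   `x`,`y`,`z`, unit direction `dx`,`dy`,`dz` (`NA` for hydrophobic),
#'   `chain`, `resno`, `resname`, `atom`.
#' @export
perceive_sites <- function(residues) {
  df <- as_tibble(residues)
  empty <- site_row("donor", c(0, 0, 0), NULL, "", 0L, "", "")[0, ]
  if (nrow(df) == 0) return(empty)
  groups <- df |> group_by(.data$chain, .data$resno) |> group_split()
  out <- map(groups, perceive_residue_sites)
  bind_rows(empty, out)
}

perceive_residue_sites <- function(res) {
  resname <- res$resname[1]
  chain <- res$chain[1]
  resno <- res$resno[1]
  pos_of <- function(name) {
    i <- which(res$atom == name)
    if (length(i) == 0) return(NULL)
    c(res$x[i[1]], res$y[i[1]], res$z[i[1]])
  }
  rows <- list()
  # backbone donor N: direction N -> H, idealized as N -> (2*CA - C) - N when
  # no amide hydrogen is present (points away from the CA/C frame)
  n <- pos_of("N"); ca <- pos_of("CA"); cc <- pos_of("C"); o <- pos_of("O")
  if (!is.null(n)) {
    hpos <- pos_of("H")
    dir <- if (!is.null(hpos)) {
      unitv(hpos - n)
    } else if (!is.null(ca) && !is.null(cc)) {
      unitv((2 * ca - cc) - n)
    } else {
      NULL
    }
    rows <- c(rows, list(site_row("donor", n, dir, chain, resno, resname, "N")))
  }
  if (!is.null(o) && !is.null(cc)) {
    rows <- c(rows, list(site_row("acceptor", o, unitv(o - cc), chain, resno, resname, "O")))
  }
  for (rule in SIDECHAIN_SITES[[resname]] %||% list()) {
    p <- pos_of(rule$atom)
    root <- pos_of(rule$root)
    if (is.null(p)) next
    dir <- if (!is.null(root)) unitv(p - root) else NULL
    for (k in rule$kind) {
      rows <- c(rows, list(site_row(k, p, dir, chain, resno, resname, rule$atom)))
    }
  }
  hyd <- HYDROPHOBIC_ATOMS[[resname]]
  if (!is.null(hyd)) {
    at <- res[res$atom %in% hyd, ]
    if (nrow(at) > 0) {
      cen <- c(mean(at$x), mean(at$y), mean(at$z))
      rows <- c(rows, list(site_row(
        "hydrophobic", cen, NULL, chain, resno, resname,
        paste(at$atom, collapse = "+")
      )))
    }
  }
  bind_rows(rows)
}

feature_row <- function(kind, pos, dir, tolerance, weight, provenance) {
  tibble(
    kind = kind,
    x = pos[1], y = pos[2], z = pos[3],
    dx = if (is.null(dir)) NA_real_ else dir[1],
    dy = if (is.null(dir)) NA_real_ else dir[2],
    dz = if (is.null(dir)) NA_real_ else dir[3],
    tolerance = tolerance, weight = weight,
    provenance = list(provenance)
  )
}

empty_features <- function() {
  feature_row("donor", c(0, 0, 0), NULL, 1, 1, character())[0, ]
}

#' Project complementary pharmacophore features into the pocket
#'
#' Builds the ligand-side interaction map: each protein donor projects a
#' ligand *acceptor* feature `d_hb` Angstroms along the donor direction, each
#' protein acceptor a ligand *donor* feature likewise, and each hydrophobic
#' site a hydrophobic feature `d_hp` along the outward (site to pocket
#' center) direction. Features falling outside the pocket sphere or within
#' `clash_dist` of any protein heavy atom are discarded. Feature directions
#' point back toward the generating protein site.
#'
#' @param sites Site tibble from [perceive_sites()].
#' @param structure The full `protein_structure` (for clash checks).
#' @param pocket A [pocket_sphere()].
#' @param d_hb Donor/acceptor projection distance (default 2.9 A, canonical
#'   heavy-atom H-bond length).
#' @param d_hp Hydrophobic projection distance (default 4.0 A).
#' @param clash_dist Minimum allowed feature-to-protein-atom distance
#'   (default 1.5 A).
#' @param tolerance Feature match tolerance assigned to every feature
#'   (default 1.5 A).
#' @return A feature tibble: `kind`, `x`,`y`,`z`, `dx`,`dy`,`dz`,
#'   `tolerance`, `weight` (1 pre-clustering), `provenance` (list of
#'   "chain:resno" keys).
#' @export
complement_features <- function(sites, structure, pocket,
                                d_hb = 2.9, d_hp = 4.0,
                                clash_dist = 1.5, tolerance = 1.5) {
  hv <- heavy_atoms(structure)
  cen <- pocket$center
  rows <- list()
  for (i in seq_len(nrow(sites))) {
    s <- sites[i, ]
    p <- c(s$x, s$y, s$z)
    if (s$kind == "hydrophobic") {
      u <- unitv(cen - p)
      if (is.null(u)) next
      fpos <- p + d_hp * u
      fkind <- "hydrophobic"
    } else {
      if (is.na(s$dx)) {
        u <- unitv(cen - p)
      } else {
        u <- c(s$dx, s$dy, s$dz)
      }
      if (is.null(u)) next
      fpos <- p + d_hb * u
      fkind <- if (s$kind == "donor") "acceptor" else "donor"
    }
    if (vnorm(fpos - cen) > pocket$radius) next
    if (min(dist_to_point(hv, fpos)) < clash_dist) next
    dir <- unitv(p - fpos)
    rows <- c(rows, list(feature_row(
      fkind, fpos, dir, tolerance, 1, paste0(s$chain, ":", s$resno)
    )))
  }
  bind_rows(empty_features(), rows)
}

#' Exclusion volumes from protein-occupied space
#'
#' Places one forbidden sphere of radius `r_excl` at every protein heavy atom
#' within `pocket$radius + margin` of the pocket center. A valid pose may not
#' place any heavy atom strictly inside an exclusion sphere.
#'
#' @param structure A `protein_structure` tibble.
#' @param pocket A [pocket_sphere()].
#' @param margin Extra shell beyond the pocket radius (default 2 A).
#' @param r_excl Exclusion sphere radius (default 1.4 A).
#' @return A tibble: `x`,`y`,`z`, `radius`, `chain`, `resno`, `atom`.
#' @export
exclusion_volumes <- function(structure, pocket, margin = 2, r_excl = 1.4) {
  if (margin < 0) abort("margin must be >= 0.")
  hv <- heavy_atoms(structure)
  hv$d <- dist_to_point(hv, pocket$center)
  hv |>
    filter(.data$d <= pocket$radius + margin) |>
    transmute(
      .data$x, .data$y, .data$z, radius = r_excl,
      .data$chain, .data$resno, .data$atom
    )
}

#' Cluster interaction-map features
#'
#' Complete-linkage agglomerative clustering of feature positions at distance
#' cutoff `cutoff`, performed separately per feature kind (kinds never
#' merge). Each cluster is replaced by one feature at the arithmetic-mean
#' position; the direction is the renormalized mean (absent when members lack
#' directions or the mean degenerates); the weight is the sum of member
#' weights (so total weight is conserved); tolerance is the member mean;
#' provenance is the union. Because averaging can bring replacement centers
#' within the cutoff of each other, passes are repeated until no further
#' merge occurs, which makes the operation idempotent.
#'
#' @param features Feature tibble from [complement_features()].
#' @param cutoff Positive clustering height in Angstroms (default 1.5).
#' @return A feature tibble with at most as many rows as the input.
#' @export
cluster_features <- function(features, cutoff = 1.5) {
  if (!is.numeric(cutoff) || length(cutoff) != 1 || cutoff <= 0) {
    abort("cutoff must be a single positive number.")
  }
  repeat {
    merged <- cluster_features_once(features, cutoff)
    if (nrow(merged) == nrow(features)) return(merged)
    features <- merged
  }
}

cluster_features_once <- function(features, cutoff) {
  if (nrow(features) == 0) return(features)
  out <- list()
  for (k in c("donor", "acceptor", "hydrophobic")) {
    fk <- features[features$kind == k, ]
    if (nrow(fk) == 0) next
    cl <- if (nrow(fk) == 1) {
      1L
    } else {
      hc <- hclust(dist(as.matrix(fk[, c("x", "y", "z")])), method = "complete")
      cutree(hc, h = cutoff)
    }
    for (g in sort(unique(cl))) {
      m <- fk[cl == g, ]
      pos <- c(mean(m$x), mean(m$y), mean(m$z))
      dir <- NULL
      if (!anyNA(m$dx)) {
        dm <- c(mean(m$dx), mean(m$dy), mean(m$dz))
        if (vnorm(dm) >= 1e-6) dir <- dm / vnorm(dm)
      }
      out <- c(out, list(feature_row(
        k, pos, dir,
        tolerance = mean(m$tolerance),
        weight = sum(m$weight),
        provenance = sort(unique(unlist(m$provenance)))
      )))
    }
  }
  bind_rows(empty_features(), out)
}

#' Enumerate pharmacophore hypotheses
#'
#' All subsets of the (clustered) feature list with between `kmin` and `kmax`
#' members whose pairwise distances are all at least `min_pair_dist`. Subset
#' ids are the sorted 1-based feature indices joined by "-"; output is in
#' lexicographic id order (sizes ascending, indices ascending within size).
#'
#' @param features Clustered feature tibble.
#' @param kmin,kmax Hypothesis size range (defaults 3 and 7). `kmin` below 3
#'   or `kmax` above the feature count are clamped with a warning.
#' @param min_pair_dist Minimum allowed pairwise feature distance
#'   (default 2 A), preventing degenerate near-duplicate hypotheses.
#' @return A tibble: `id`, `size`, `idx` (list of integer indices),
#'   `features` (list of feature tibbles).
#' @export
enumerate_hypotheses <- function(features, kmin = 3, kmax = 7, min_pair_dist = 2) {
  n <- nrow(features)
  if (kmin < 3) {
    warn("kmin below 3; clamped to 3.")
    kmin <- 3
  }
  if (kmax > n) {
    warn(sprintf("kmax (%d) exceeds feature count (%d); clamped.", kmax, n))
    kmax <- n
  }
  empty <- tibble(
    id = character(), size = integer(),
    idx = list(), features = list()
  )
  if (kmin > kmax || n < kmin) return(empty)
  pos <- as.matrix(features[, c("x", "y", "z")])
  dmat <- as.matrix(dist(pos))
  rows <- list()
  for (k in kmin:kmax) {
    sets <- combn(n, k)
    for (j in seq_len(ncol(sets))) {
      s <- sets[, j]
      sub <- dmat[s, s, drop = FALSE]
      if (all(sub[upper.tri(sub)] >= min_pair_dist)) {
        rows <- c(rows, list(tibble(
          id = paste(s, collapse = "-"), size = k,
          idx = list(s), features = list(features[s, ])
        )))
      }
    }
  }
  if (length(rows) == 0) return(empty)
  bind_rows(rows)
}
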