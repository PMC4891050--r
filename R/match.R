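# Hypothesis matching: injective kind-compatible assignment of ligand
# features onto hypothesis features with pairwise distance pruning, followed
# by Kabsch rigid superposition and a quadratic-falloff fit score.

#' Match ligand features onto a hypothesis
#'
#' Finds every injective assignment of ligand features to the hypothesis
#' features such that kinds agree and, for every matched pair (i, j),
#' `|d_ligand(i, j) - d_hypothesis(i, j)| <= t_i + t_j` where `t` are the
#' feature tolerances. Assignments are enumerated by backtracking in
#' deterministic order (hypothesis features in order, ligand candidates by
#' ascending index).
#'
#' @param ligand_features Tibble from [perceive_ligand_features()].
#' @param hypothesis Feature tibble (columns `kind`, `x`, `y`, `z`,
#'   `tolerance`).
#' @param max_matches Stop after this many assignments (default `Inf`).
#' @return A list of integer vectors; element `k` of a vector is the row of
#'   `ligand_features` matched to hypothesis feature `k`. Empty list if no
#'   complete match exists.
#' @export
match_features <- function(ligand_features, hypothesis, max_matches = Inf) {
  nh <- nrow(hypothesis)
  nl <- nrow(ligand_features)
  if (nh == 0 || nl < nh) return(list())
  lpos <- as.matrix(ligand_features[, c("x", "y", "z")])
  hpos <- as.matrix(hypothesis[, c("x", "y", "z")])
  ld <- as.matrix(dist(lpos))
  hd <- as.matrix(dist(hpos))
  tol <- hypothesis$tolerance
  cand <- map(seq_len(nh), function(i) which(ligand_features$kind == hypothesis$kind[i]))
  if (any(map_int(cand, length) == 0)) return(list())
  out <- list()
  assign_next <- function(i, sel) {
    if (length(out) >= max_matches) return(invisible())
    if (i > nh) {
      out[[length(out) + 1]] <<- sel
      return(invisible())
    }
    for (c in cand[[i]]) {
      if (c %in% sel) next
      ok <- TRUE
      for (p in seq_len(i - 1)) {
        if (abs(ld[sel[p], c] - hd[p, i]) > tol[p] + tol[i]) {
          ok <- FALSE
          break
        }
      }
      if (ok) assign_next(i + 1, c(sel, c))
    }
  }
  assign_next(1L, integer())
  out
}

#' Kabsch least-squares rigid superposition
#'
#' Computes the proper rotation (determinant +1) and translation minimizing
#' the RMSD of `p` onto `q`.
#'
#' @param p,q Matrices (n x 3) of paired points; `p` is moved onto `q`.
#' @return List with `rotation` (3 x 3), `translation` (length 3; the
#'   transform is `x %*% t(rotation) + translation`), and the point `rmsd`.
#' @export
kabsch <- function(p, q) {
  stopifnot(nrow(p) == nrow(q), ncol(p) == 3, ncol(q) == 3)
  if (nrow(p) < 3) {
    abort("At least 3 paired points are required for a rigid superposition.")
  }
  cp <- colMeans(p)
  cq <- colMeans(q)
  pc <- sweep(p, 2, cp)
  qc <- sweep(q, 2, cq)
  h <- t(pc) %*% qc
  sv <- svd(h)
  d <- sign(det(sv$v %*% t(sv$u)))
  rot <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  moved <- pc %*% t(rot)
  rmsd <- sqrt(mean(rowSums((moved - qc)^2)))
  list(rotation = rot, translation = as.numeric(cq - rot %*% cp), rmsd = rmsd)
}

apply_rigid <- function(xyz, transform) {
  sweep(xyz %*% t(transform$rotation), 2, transform$translation, "+")
}

#' Superpose a conformer onto a hypothesis via a feature mapping
#'
#' Rigidly transforms the whole conformer with the Kabsch superposition of
#' the matched ligand feature points onto the hypothesis feature points.
#'
#' @param conformer Coordinate matrix (n_atoms x 3).
#' @param mapping Integer vector from [match_features()].
#' @param hypothesis Hypothesis feature tibble.
#' @param ligand_features Ligand feature tibble (same conformer frame).
#' @return List: `pose` (transformed conformer), `pose_features`
#'   (transformed matched feature positions, rows ordered as the
#'   hypothesis), `rmsd`, `transform`.
#' @export
align_pose <- function(conformer, mapping, hypothesis, ligand_features) {
  if (length(mapping) < 3) {
    abort("Mapping has fewer than 3 matched points; superposition is degenerate.")
  }
  lp <- as.matrix(ligand_features[mapping, c("x", "y", "z")])
  hp <- as.matrix(hypothesis[, c("x", "y", "z")])
  tr <- kabsch(lp, hp)
  list(
    pose = apply_rigid(conformer, tr),
    pose_features = apply_rigid(lp, tr),
    rmsd = tr$rmsd,
    transform = tr
  )
}

#' Pharmacophore fit score
#'
#' `fit = sum_i w_i * max(0, 1 - (d_i / t_i)^2)` over hypothesis features,
#' where `d_i` is the distance from hypothesis feature i to its matched
#' (superposed) ligand feature, `t_i` the tolerance and `w_i` the weight.
#' A perfectly superposed ligand scores the sum of weights; a feature
#' displaced to its tolerance contributes zero.
#'
#' @param pose_features Matrix (k x 3) of superposed ligand feature
#'   positions, row i matched to hypothesis feature i.
#' @param hypothesis Hypothesis feature tibble (`x`,`y`,`z`, `tolerance`,
#'   `weight`).
#' @return Non-negative fit value.
#' @export
fit_score <- function(pose_features, hypothesis) {
  hp <- as.matrix(hypothesis[, c("x", "y", "z")])
  d <- sqrt(rowSums((pose_features - hp)^2))
  sum(hypothesis$weight * pmax(0, 1 - (d / hypothesis$tolerance)^2))
}

#' Check a pose against exclusion volumes
#'
#' A pose fails if any ligand heavy-atom center lies strictly inside any
#' exclusion sphere (a point exactly on the surface passes).
#'
#' @param pose Coordinate matrix (n_atoms x 3) in the pocket frame.
#' @param exclusions Exclusion tibble from [exclusion_volumes()].
#' @param elements Optional element vector; hydrogens are ignored when given.
#' @return List: `pass` (logical) and `violating` (index of the first
#'   violating atom, or `NA`).
#' @export
exclusion_check <- function(pose, exclusions, elements = NULL) {
  idx <- seq_len(nrow(pose))
  if (!is.null(elements)) idx <- idx[!toupper(elements) %in% c("H", "D")]
  if (nrow(exclusions) == 0 || length(idx) == 0) {
    return(list(pass = TRUE, violating = NA_integer_))
  }
  for (i in idx) {
    d <- sqrt((exclusions$x - pose[i, 1])^2 +
      (exclusions$y - pose[i, 2])^2 +
      (exclusions$z - pose[i, 3])^2)
    if (any(d < exclusions$radius)) {
      return(list(pass = FALSE, violating = i))
    }
  }
  list(pass = TRUE, violating = NA_integer_)
}
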