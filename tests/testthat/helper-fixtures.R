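# Shared fixtures (built once per test run) and independent oracles.

.fx <- new.env()

fx_pocket <- function() {
  if (is.null(.fx$pocket)) .fx$pocket <- make_toy_pocket(seed = 1)
  .fx$pocket
}

fx_structure <- function() {
  if (is.null(.fx$structure)) .fx$structure <- parse_pdb(fx_pocket()$pdb, id = "toy")
  .fx$structure
}

fx_sphere <- function() pocket_sphere(fx_pocket()$center, fx_pocket()$radius)

fx_map <- function() {
  if (is.null(.fx$map)) {
    .fx$map <- interaction_map(fx_structure(), fx_sphere())
  }
  .fx$map
}

# a 3-feature hypothesis with one feature of each kind, from the toy map
fx_hypothesis <- function() {
  if (is.null(.fx$hyp)) {
    hyps <- enumerate_hypotheses(fx_map()$features,
      kmin = 3, kmax = 3, min_pair_dist = 3.5
    )
    mixed <- which(purrr::map_lgl(
      hyps$features,
      function(ft) length(unique(ft$kind)) == 3
    ))
    .fx$hyp <- hyps$features[[mixed[1]]]
  }
  .fx$hyp
}

fx_library <- function() {
  if (is.null(.fx$lib)) {
    .fx$lib <- make_planted_library(
      fx_hypothesis(),
      n_active = 5, n_decoy = 45,
      displacement = 0.5, seed = 1, avoid = fx_map()$exclusions
    )
  }
  .fx$lib
}

# build a protein_structure from a plain atom table (via the PDB dialect)
structure_from_atoms <- function(df, id = "fixture") {
  df <- tibble::as_tibble(df)
  if (!"serial" %in% names(df)) df$serial <- seq_len(nrow(df))
  if (!"element" %in% names(df)) df$element <- substr(df$atom, 1, 1)
  parse_pdb(write_pdb(df), id = id)
}

# random pharmacophore feature set (tibble like cluster_features input)
random_features <- function(n, kinds = c("donor", "acceptor", "hydrophobic"),
                            span = 8, tolerance = 1.5) {
  tibble::tibble(
    kind = sample(kinds, n, replace = TRUE),
    x = runif(n, -span, span), y = runif(n, -span, span), z = runif(n, -span, span),
    dx = NA_real_, dy = NA_real_, dz = NA_real_,
    tolerance = tolerance, weight = 1,
    provenance = lapply(seq_len(n), function(i) sprintf("A:%d", i))
  )
}

# ---- independent oracles ----------------------------------------------------

# brute-force complete-linkage agglomeration at cutoff h, per kind;
# returns the partition as a list of sorted index vectors
oracle_complete_linkage <- function(pos, cutoff) {
  n <- nrow(pos)
  clusters <- as.list(seq_len(n))
  d <- as.matrix(dist(pos))
  repeat {
    if (length(clusters) == 1) break
    best <- c(NA, NA)
    best_d <- Inf
    for (a in seq_along(clusters)) {
      for (b in seq_along(clusters)) {
        if (a >= b) next
        dd <- max(d[clusters[[a]], clusters[[b]]])
        if (dd < best_d) {
          best_d <- dd
          best <- c(a, b)
        }
      }
    }
    if (best_d > cutoff) break
    merged <- sort(c(clusters[[best[1]]], clusters[[best[2]]]))
    clusters <- c(clusters[-best], list(merged))
  }
  clusters <- lapply(clusters, sort)
  clusters[order(purrr::map_int(clusters, 1))]
}

# iterated complete-linkage: re-run single passes on the replacement
# centers (unweighted means of current points) until no merge occurs,
# tracking which original points each cluster contains
oracle_iterated_linkage <- function(pos, cutoff) {
  parts <- as.list(seq_len(nrow(pos)))
  pts <- pos
  repeat {
    partition <- oracle_complete_linkage(pts, cutoff)
    if (length(partition) == nrow(pts)) break
    parts <- lapply(partition, function(g) sort(unlist(parts[g])))
    pts <- do.call(rbind, lapply(partition, function(g) {
      colMeans(pts[g, , drop = FALSE])
    }))
  }
  parts[order(purrr::map_int(parts, 1))]
}

# partition induced by cluster_features provenance (inputs get unique
# provenance tags 1..n as strings)
partition_from_clusters <- function(clustered, n) {
  parts <- lapply(clustered$provenance, function(p) sort(as.integer(p)))
  parts[order(purrr::map_int(parts, 1))]
}

# exhaustive injective kind-compatible assignment enumeration with the
# pairwise distance criterion (oracle for match_features)
oracle_match <- function(lig, hyp) {
  nh <- nrow(hyp)
  ld <- as.matrix(dist(as.matrix(lig[, c("x", "y", "z")])))
  hd <- as.matrix(dist(as.matrix(hyp[, c("x", "y", "z")])))
  tol <- hyp$tolerance
  res <- list()
  idx <- seq_len(nrow(lig))
  recurse <- function(i, sel) {
    if (i > nh) {
      res[[length(res) + 1]] <<- sel
      return(invisible())
    }
    for (c in idx) {
      if (c %in% sel) next
      if (lig$kind[c] != hyp$kind[i]) next
      recurse(i + 1, c(sel, c))
    }
  }
  recurse(1, integer())
  Filter(function(sel) {
    all(vapply(seq_len(nh), function(i) {
      all(vapply(seq_len(nh)[-i], function(j) {
        abs(ld[sel[i], sel[j]] - hd[i, j]) <= tol[i] + tol[j]
      }, logical(1)))
    }, logical(1)))
  }, res)
}

# leader-algorithm diversity selection oracle over a precomputed similarity
# matrix, in rank order
oracle_leader <- function(sim, n, threshold) {
  accepted <- integer()
  for (i in seq_len(nrow(sim))) {
    if (length(accepted) >= n) break
    if (all(sim[i, accepted] < threshold)) accepted <- c(accepted, i)
  }
  accepted
}

# random small protein-like atom table (with charges, so no residue-name
# charge assignment is involved) for energy fixtures
random_protein_atoms <- function(n_res = 3, atoms_per_res = 3, rmin = 3, rmax = 7) {
  rows <- list()
  for (r in seq_len(n_res)) {
    for (a in seq_len(atoms_per_res)) {
      u <- stats::rnorm(3)
      u <- u / sqrt(sum(u^2))
      rad <- runif(1, rmin, rmax)
      rows[[length(rows) + 1]] <- tibble::tibble(
        chain = "A", resno = r, resname = "XXX", atom = "X",
        element = sample(c("C", "N", "O"), 1),
        charge = runif(1, -0.3, 0.3),
        x = rad * u[1], y = rad * u[2], z = rad * u[3]
      )
    }
  }
  dplyr::bind_rows(rows)
}

random_ligand_atoms <- function(n = 4) {
  tibble::tibble(
    element = sample(c("C", "N", "O"), n, replace = TRUE),
    charge = runif(n, -0.3, 0.3),
    x = runif(n, -1, 1), y = runif(n, -1, 1), z = runif(n, -1, 1)
  )
}

random_rotation <- function() {
  q <- stats::rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), 3, 3, byrow = TRUE)
}

apply_rigid_df <- function(df, rot, shift) {
  xyz <- as.matrix(df[, c("x", "y", "z")]) %*% t(rot)
  df$x <- xyz[, 1] + shift[1]
  df$y <- xyz[, 2] + shift[2]
  df$z <- xyz[, 3] + shift[3]
  df
}
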