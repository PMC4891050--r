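# The screening funnel: property filters, library matching against
# hypotheses, ranking, top-N cuts and leader-style diversity selection.

#' Filter a library on computed properties
#'
#' Keeps ligands with `mw <= mw_max`, `logp <= logp_max` and
#' `logs >= logs_min` (all boundaries inclusive); input order is preserved.
#'
#' @param ligands List of `ligand` objects.
#' @param mw_max Maximum molecular weight in Da (default 500).
#' @param logp_max Maximum estimated logP (default 5).
#' @param logs_min Minimum estimated logS (default -6).
#' @param properties Optional precomputed [ligand_properties()] tibble (rows
#'   aligned with `ligands`).
#' @return The filtered list of ligands, with the matching property rows in
#'   attribute `"properties"`.
#' @export
property_filter <- function(ligands, mw_max = 500, logp_max = 5, logs_min = -6,
                            properties = NULL) {
  if (length(ligands) == 0) return(ligands)
  props <- properties %||% ligand_properties(ligands)
  keep <- props$mw <= mw_max & props$logp <= logp_max & props$logs >= logs_min
  out <- ligands[keep]
  attr(out, "properties") <- props[keep, ]
  out
}

#' Screen a ligand library against pharmacophore hypotheses
#'
#' For every ligand, enumerates feature matches against every hypothesis and
#' conformer, superposes each match, discards poses violating the exclusion
#' volumes, and keeps the ligand's best (maximum-fit) passing result. The
#' ranking is by fit descending with ties broken by ligand id ascending, so
#' reruns are byte-identical.
#'
#' @param ligands List of `ligand` objects.
#' @param hypotheses Hypothesis tibble from [enumerate_hypotheses()] (columns
#'   `id`, `features`), or a single feature tibble (treated as one hypothesis
#'   with id `"H1"`).
#' @param exclusions Exclusion tibble (from [exclusion_volumes()] or an
#'   `interaction_map`); `NULL` skips the check.
#' @param max_matches Per ligand/hypothesis cap on enumerated mappings
#'   (default 200).
#' @return A tibble ranked by fit: `ligand_id`, `hypothesis_id`, `conformer`,
#'   `fit`, `rmsd`, `mapping` (list), `pose` (list of coordinate matrices).
#' @export
screen_library <- function(ligands, hypotheses, exclusions = NULL,
                           max_matches = 200) {
  if (inherits(hypotheses, "interaction_map")) {
    abort("Pass a hypothesis tibble, not the interaction map; see enumerate_hypotheses().")
  }
  if (is.data.frame(hypotheses) && "kind" %in% names(hypotheses)) {
    hypotheses <- tibble(id = "H1", size = nrow(hypotheses), features = list(hypotheses))
  }
  empty <- tibble(
    ligand_id = character(), hypothesis_id = character(),
    conformer = integer(), fit = double(), rmsd = double(),
    mapping = list(), pose = list()
  )
  if (length(ligands) == 0 || nrow(hypotheses) == 0) return(empty)
  rows <- list()
  for (lig in ligands) {
    best <- NULL
    for (ci in seq_along(lig$conformers)) {
      lf <- perceive_ligand_features(lig, ci)
      if (nrow(lf) == 0) next
      for (hi in seq_len(nrow(hypotheses))) {
        hyp <- hypotheses$features[[hi]]
        maps <- match_features(lf, hyp, max_matches = max_matches)
        for (m in maps) {
          al <- align_pose(lig$conformers[[ci]], m, hyp, lf)
          if (!is.null(exclusions)) {
            chk <- exclusion_check(al$pose, exclusions, elements = lig$atoms$element)
            if (!chk$pass) next
          }
          fit <- fit_score(al$pose_features, hyp)
          if (is.null(best) || fit > best$fit) {
            best <- tibble(
              ligand_id = lig$id, hypothesis_id = hypotheses$id[hi],
              conformer = ci, fit = fit, rmsd = al$rmsd,
              mapping = list(m), pose = list(al$pose)
            )
          }
        }
      }
    }
    if (!is.null(best)) rows <- c(rows, list(best))
  }
  if (length(rows) == 0) return(empty)
  bind_rows(rows) |> arrange(desc(.data$fit), .data$ligand_id)
}

#' Take the top of a ranked table
#'
#' @param ranked A ranked tibble (e.g. from [screen_library()]).
#' @param n Number of rows to keep (`n >= 0`; more than available returns
#'   all).
#' @return The first `min(n, nrow)` rows.
#' @export
select_top <- function(ranked, n) {
  stopifnot(n >= 0)
  ranked[seq_len(min(n, nrow(ranked))), , drop = FALSE]
}

#' Diversity selection by the leader algorithm
#'
#' Walks the ranked results in order and accepts a candidate iff its Tanimoto
#' similarity to every already-accepted leader is strictly below
#' `sim_threshold`, stopping after `n` acceptances. Deterministic.
#'
#' @param ranked Ranked tibble with a `ligand_id` column.
#' @param ligands List of `ligand` objects covering the ranked ids.
#' @param n Maximum number selected.
#' @param sim_threshold Tanimoto threshold (default 0.9).
#' @param max_len,nbits Fingerprint parameters (see [path_fingerprint()]).
#' @return The accepted subset of `ranked`, in rank order.
#' @export
diversity_select <- function(ranked, ligands, n, sim_threshold = 0.9,
                             max_len = 5, nbits = 1024) {
  if (nrow(ranked) == 0 || n == 0) return(ranked[0, , drop = FALSE])
  by_id <- setNames(ligands, map_chr(ligands, "id"))
  leaders <- list()
  keep <- integer()
  for (r in seq_len(nrow(ranked))) {
    if (length(keep) >= n) break
    id <- ranked$ligand_id[r]
    lig <- by_id[[id]]
    if (is.null(lig)) abort(sprintf("Ligand '%s' not found in library.", id))
    fp <- path_fingerprint(lig, max_len = max_len, nbits = nbits)
    if (all(map_dbl(leaders, tanimoto, b = fp) < sim_threshold)) {
      leaders <- c(leaders, list(fp))
      keep <- c(keep, r)
    }
  }
  ranked[keep, , drop = FALSE]
}
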