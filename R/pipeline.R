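# End-to-end orchestration of the screening funnel:
# pocket -> interaction map -> hypotheses -> property filter -> matching ->
# top-by-fit -> minimization + energy -> top-by-energy -> diversity -> final.

#' Screening pipeline configuration
#'
#' Defaults are desk-scale: the published funnel kept the top 5000 ligands
#' by fit, the top 1000 by minimized binding energy and 100 diverse finalists
#' from a 300k library; synthetic desk-scale runs default to 20 / 10 / 5.
#'
#' @param cluster_cutoff Feature clustering height (A).
#' @param kmin,kmax,min_pair_dist Hypothesis enumeration controls.
#' @param mw_max,logp_max,logs_min Property-filter thresholds.
#' @param top_fit,top_energy,n_final Funnel sizes (must be non-increasing).
#' @param sim_threshold Diversity Tanimoto threshold.
#' @param max_hypotheses Cap on enumerated hypotheses (deterministic prefix).
#' @param max_matches Per ligand/hypothesis mapping cap.
#' @param d_hb,d_hp,clash_dist,tolerance,margin Interaction-map parameters
#'   (see [complement_features()] and [exclusion_volumes()]).
#' @param energy An [energy_params()] object.
#' @param minimize List of [minimize_pose()] controls.
#' @param shell Per-residue decomposition shell (A).
#' @param verbose Log stage counts with [message()]?
#' @return A `screen_config` list.
#' @export
screen_config <- function(cluster_cutoff = 1.5, kmin = 3, kmax = 5,
                          min_pair_dist = 2,
                          mw_max = 500, logp_max = 5, logs_min = -6,
                          top_fit = 20, top_energy = 10, n_final = 5,
                          sim_threshold = 0.9,
                          max_hypotheses = 200, max_matches = 200,
                          d_hb = 2.9, d_hp = 4.0, clash_dist = 1.5,
                          tolerance = 1.5, margin = 2,
                          energy = energy_params(),
                          minimize = list(max_iter = 60, step = 0.25,
                                          rot_step = 0.1, min_step = 0.01),
                          shell = 10, verbose = FALSE) {
  if (!(top_fit >= top_energy && top_energy >= n_final && n_final > 0)) {
    abort("Funnel sizes must be positive and non-increasing: top_fit >= top_energy >= n_final.")
  }
  structure(as.list(environment()), class = "screen_config")
}

log_stage <- function(verbose, stage, n) {
  if (verbose) message(sprintf("[phorescreen] %-16s %d", stage, n))
}

#' Run the virtual-screening funnel
#'
#' Executes the full cascade on a ligand library against a pocket: builds the
#' interaction map (sites, complementary features, exclusion volumes,
#' clustering), enumerates hypotheses unless given, filters the library on
#' computed properties, matches and superposes every ligand, keeps the top
#' `top_fit` by fit, minimizes each pose rigidly and re-ranks by interaction
#' energy, keeps the top `top_energy`, applies leader diversity selection to
#' `n_final`, and computes the per-residue energy decomposition and hydrogen
#' bonds of the best final pose. Deterministic given its inputs.
#'
#' @param ligands List of `ligand` objects.
#' @param structure A `protein_structure` tibble.
#' @param pocket A [pocket_sphere()].
#' @param hypotheses Optional hypothesis tibble (or single feature tibble);
#'   enumerated from the map when `NULL`.
#' @param config A [screen_config()].
#' @param out_prefix Optional path prefix; writes `<prefix>_hits.tsv`,
#'   `<prefix>_funnel.tsv`, `<prefix>_residues.tsv`, `<prefix>_hbonds.tsv`.
#' @return A `screen_run`: list with `funnel` (stage counts), `results`
#'   (final ranked tibble), `ranked_fit`, `map`, `hypotheses`, `top_hit`
#'   (list with `pose_score` and `hbonds`), `config`.
#' @export
run_screen <- function(ligands, structure, pocket, hypotheses = NULL,
                       config = screen_config(), out_prefix = NULL) {
  cfg <- config
  map <- interaction_map(
    structure, pocket,
    cluster_cutoff = cfg$cluster_cutoff, margin = cfg$margin,
    d_hb = cfg$d_hb, d_hp = cfg$d_hp, clash_dist = cfg$clash_dist,
    tolerance = cfg$tolerance
  )
  if (is.null(hypotheses)) {
    hypotheses <- enumerate_hypotheses(
      map$features,
      kmin = cfg$kmin, kmax = cfg$kmax, min_pair_dist = cfg$min_pair_dist
    )
    if (nrow(hypotheses) > cfg$max_hypotheses) {
      warn(sprintf(
        "%d hypotheses enumerated; keeping the first %d.",
        nrow(hypotheses), cfg$max_hypotheses
      ))
      hypotheses <- hypotheses[seq_len(cfg$max_hypotheses), ]
    }
  } else if (is.data.frame(hypotheses) && "kind" %in% names(hypotheses)) {
    hypotheses <- tibble(
      id = "H1", size = nrow(hypotheses), features = list(hypotheses)
    )
  }
  funnel <- list()
  stage <- function(name, n) {
    log_stage(cfg$verbose, name, n)
    funnel[[length(funnel) + 1]] <<- tibble(stage = name, n = as.integer(n))
  }
  stage("library", length(ligands))
  filtered <- property_filter(
    ligands,
    mw_max = cfg$mw_max, logp_max = cfg$logp_max, logs_min = cfg$logs_min
  )
  stage("property_filter", length(filtered))
  ranked <- screen_library(
    filtered, hypotheses, map$exclusions,
    max_matches = cfg$max_matches
  )
  stage("matched", nrow(ranked))
  topf <- select_top(ranked, cfg$top_fit)
  stage("top_fit", nrow(topf))
  # rigid in-situ minimization and energy re-ranking
  prot <- assign_protein_charges(structure)
  by_id <- setNames(ligands, map_chr(ligands, "id"))
  if (nrow(topf) > 0) {
    scored <- map(seq_len(nrow(topf)), function(r) {
      lig <- by_id[[topf$ligand_id[r]]]
      la <- ligand_pose_atoms(lig, pose = topf$pose[[r]])
      mn <- minimize_pose(
        la, prot, cfg$energy,
        max_iter = cfg$minimize$max_iter, step = cfg$minimize$step,
        rot_step = cfg$minimize$rot_step, min_step = cfg$minimize$min_step
      )
      row <- topf[r, ]
      row$energy <- mn$energy
      row$min_pose <- list(as.matrix(mn$atoms[, c("x", "y", "z")]))
      row
    })
    topf <- bind_rows(scored) |> arrange(.data$energy, .data$ligand_id)
  } else {
    topf$energy <- double()
    topf$min_pose <- list()
  }
  tope <- select_top(topf, cfg$top_energy)
  stage("top_energy", nrow(tope))
  final <- diversity_select(tope, ligands, cfg$n_final,
    sim_threshold = cfg$sim_threshold
  )
  if (nrow(final) < cfg$n_final && nrow(tope) >= cfg$n_final && cfg$verbose) {
    message("[phorescreen] diversity selection returned fewer than n_final hits")
  }
  stage("diverse", nrow(final))
  top_hit <- NULL
  if (nrow(final) > 0) {
    lig <- by_id[[final$ligand_id[1]]]
    la <- ligand_pose_atoms(lig, pose = final$min_pose[[1]])
    top_hit <- list(
      ligand_id = final$ligand_id[1],
      pose_score = per_residue_decomposition(la, prot, cfg$energy, shell = cfg$shell),
      hbonds = detect_hbonds(lig, structure, pose = final$min_pose[[1]])
    )
  }
  run <- structure(
    list(
      funnel = bind_rows(funnel),
      results = final, ranked_fit = ranked, map = map,
      hypotheses = hypotheses, top_hit = top_hit, config = cfg
    ),
    class = "screen_run"
  )
  if (!is.null(out_prefix)) write_screen_run(run, out_prefix)
  run
}

#' @export
print.screen_run <- function(x, ...) {
  cat("<screen_run>\n")
  for (r in seq_len(nrow(x$funnel))) {
    cat(sprintf("  %-16s %d\n", x$funnel$stage[r], x$funnel$n[r]))
  }
  if (!is.null(x$top_hit)) {
    cat(sprintf(
      "  top hit: %s (energy %.3f kcal/mol, %d H-bond(s))\n",
      x$top_hit$ligand_id, x$top_hit$pose_score$total, nrow(x$top_hit$hbonds)
    ))
  }
  invisible(x)
}

write_screen_run <- function(run, prefix) {
  hits <- run$results |>
    select(dplyr::any_of(c("ligand_id", "hypothesis_id", "conformer", "fit", "energy")))
  readr::write_tsv(hits, paste0(prefix, "_hits.tsv"))
  readr::write_tsv(run$funnel, paste0(prefix, "_funnel.tsv"))
  if (!is.null(run$top_hit)) {
    readr::write_tsv(
      run$top_hit$pose_score$per_residue[, c("residue", "energy")],
      paste0(prefix, "_residues.tsv")
    )
    readr::write_tsv(run$top_hit$hbonds, paste0(prefix, "_hbonds.tsv"))
  }
  invisible(prefix)
}

#' Plot the screening funnel
#'
#' @param object A `screen_run` (or its `funnel` tibble).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot screen_run
#' @export
autoplot.screen_run <- function(object, ...) {
  fun <- object$funnel
  fun$stage <- factor(fun$stage, levels = fun$stage)
  ggplot(fun, aes(x = .data$stage, y = .data$n)) +
    geom_col() +
    labs(x = NULL, y = "compounds", title = "Screening funnel") +
    theme_minimal()
}

#' Triage a screen readout table
#'
#' Reads (or takes) a table of compound readouts and applies [triage_hits()],
#' validating the rows first; malformed rows are reported by number.
#'
#' @param records A data frame with columns `compound_id`, `ru`,
#'   `inhibition`, or a path to a CSV file with those columns.
#' @param ru_min,inh_min Strict thresholds (defaults 20 and 30).
#' @param out_prefix Optional prefix: writes `<prefix>_triage.tsv` with one
#'   row per compound and hit flags.
#' @return A `triage_result` (see [triage_hits()]).
#' @export
run_triage <- function(records, ru_min = 20, inh_min = 30, out_prefix = NULL) {
  if (is.character(records)) {
    records <- readr::read_csv(records, show_col_types = FALSE)
  }
  records <- as_tibble(records)
  need <- c("compound_id", "ru", "inhibition")
  if (!all(need %in% names(records)) || nrow(records) == 0) {
    abort(sprintf(
      "records must be a non-empty table with columns %s.",
      paste(need, collapse = ", ")
    ))
  }
  bad <- which(!is.finite(records$ru) | !is.finite(records$inhibition) |
    is.na(records$compound_id))
  if (length(bad) > 0) {
    abort(sprintf("Malformed record in row %d.", bad[1]))
  }
  res <- triage_hits(records, ru_min = ru_min, inh_min = inh_min)
  if (!is.null(out_prefix)) {
    out <- records
    out$ru_hit <- out$ru > ru_min
    out$inh_hit <- out$inhibition > inh_min
    out$dual_hit <- out$ru_hit & out$inh_hit
    readr::write_tsv(out, paste0(out_prefix, "_triage.tsv"))
  }
  res
}
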