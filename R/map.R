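#' Build a complete interaction map for a pocket
#'
#' Convenience wrapper running site perception, feature projection, exclusion
#' volume placement and feature clustering for a pocket sphere on a
#' structure.
#'
#' @param structure A `protein_structure` tibble.
#' @param pocket A [pocket_sphere()].
#' @param cluster_cutoff Complete-linkage clustering height (default 1.5 A);
#'   `NULL` skips clustering.
#' @param margin Exclusion-volume shell margin (default 2 A).
#' @param ... Passed to [complement_features()].
#' @return An `interaction_map`: list with `features` (clustered feature
#'   tibble), `exclusions` (exclusion tibble) and `pocket`.
#' @export
interaction_map <- function(structure, pocket, cluster_cutoff = 1.5,
                            margin = 2, ...) {
  pock_res <- select_pocket(structure, pocket)
  sites <- perceive_sites(pock_res)
  feats <- complement_features(sites, structure, pocket, ...)
  if (!is.null(cluster_cutoff)) feats <- cluster_features(feats, cluster_cutoff)
  excl <- exclusion_volumes(structure, pocket, margin = margin)
  structure(
    list(features = feats, exclusions = excl, pocket = pocket),
    class = "interaction_map"
  )
}

#' @export
print.interaction_map <- function(x, ...) {
  cat(sprintf(
    "<interaction_map> %d features (%s), %d exclusion spheres\n",
    nrow(x$features),
    paste(sprintf("%d %s", table(x$features$kind), names(table(x$features$kind))),
      collapse = ", "
    ),
    nrow(x$exclusions)
  ))
  invisible(x)
}

round6 <- function(x) round(x, 6)

#' Serialize / read an interaction map
#'
#' Writes the map as JSON: one record per feature (kind, position, direction,
#' tolerance, weight, provenance) and per exclusion sphere, plus the pocket
#' sphere. Numeric fields are written at 6-decimal precision and round-trip
#' exactly at that precision.
#'
#' @param map An `interaction_map`.
#' @param path Output file path.
#' @return `write_map` returns `path` invisibly; `read_map` returns the
#'   reconstructed `interaction_map`.
#' @export
write_map <- function(map, path) {
  feats <- as_tibble(map$features)
  payload <- list(
    pocket = list(center = round6(map$pocket$center), radius = round6(map$pocket$radius)),
    features = map(seq_len(nrow(feats)), function(i) {
      f <- feats[i, ]
      list(
        kind = f$kind,
        position = round6(c(f$x, f$y, f$z)),
        direction = if (is.na(f$dx)) NULL else round6(c(f$dx, f$dy, f$dz)),
        tolerance = round6(f$tolerance),
        weight = round6(f$weight),
        provenance = unlist(f$provenance)
      )
    }),
    exclusions = map(seq_len(nrow(map$exclusions)), function(i) {
      e <- map$exclusions[i, ]
      list(
        center = round6(c(e$x, e$y, e$z)), radius = round6(e$radius),
        chain = e$chain, resno = e$resno, atom = e$atom
      )
    })
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_map
#' @export
read_map <- function(path) {
  p <- jsonlite::read_json(path)
  feats <- bind_rows(empty_features(), map(p$features, function(f) {
    feature_row(
      f$kind, unlist(f$position),
      if (is.null(f$direction)) NULL else unlist(f$direction),
      f$tolerance, f$weight, unlist(f$provenance) %||% character()
    )
  }))
  excl <- bind_rows(
    tibble(
      x = double(), y = double(), z = double(), radius = double(),
      chain = character(), resno = integer(), atom = character()
    ),
    map(p$exclusions, function(e) {
      cen <- unlist(e$center)
      tibble(
        x = cen[1], y = cen[2], z = cen[3], radius = e$radius,
        chain = e$chain, resno = as.integer(e$resno), atom = e$atom
      )
    })
  )
  structure(
    list(
      features = feats, exclusions = excl,
      pocket = pocket_sphere(unlist(p$pocket$center), p$pocket$radius)
    ),
    class = "interaction_map"
  )
}
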