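#' Parse a protein structure from PDB text
#'
#' Reads fixed-column `ATOM` (and optionally `HETATM`) records of the first
#' model of a PDB file into an atom-level tibble. Only alternate location
#' indicator `'A'` or blank is kept; waters (`HOH`, `WAT`, `DOD`) are skipped
#' with `HETATM` records by default. The element symbol is taken from columns
#' 77-78, falling back to inference from the atom name.
#'
#' @param text PDB-format text: a single string or a character vector of lines.
#' @param id Structure identifier stored in the `structure_id` attribute.
#' @param keep_hetatm Keep non-water `HETATM` records? Default `FALSE`.
#'
#' @return A tibble of class `protein_structure` with one row per atom:
#'   `serial`, `atom` (PDB atom name), `element`, `resname`, `chain`,
#'   `resno`, `x`, `y`, `z`. Residue (file) order is preserved.
#' @export
#' @examples
#' pock <- make_toy_pocket(seed = 1)
#' s <- parse_pdb(pock$pdb)
#' dplyr::count(s, chain, resno, resname)
parse_pdb <- function(text, id = "structure", keep_hetatm = FALSE) {
  lines <- if (length(text) == 1L) strsplit(text, "\n", fixed = TRUE)[[1]] else text
  # first model only
  endmdl <- which(startsWith(lines, "ENDMDL"))
  if (length(endmdl) > 0) lines <- lines[seq_len(endmdl[1] - 1L)]
  rec <- substr(lines, 1, 6)
  is_atom <- startsWith(rec, "ATOM")
  is_het <- startsWith(rec, "HETATM")
  if (!any(is_atom)) {
    abort("No ATOM records found in PDB text.", class = "phorescreen_parse_error")
  }
  keep <- is_atom | (keep_hetatm & is_het)
  idx <- which(keep)
  # validate coordinate fields before handing to the reader, so bad fields
  # are reported with their line number
  for (i in idx) {
    ln <- lines[i]
    for (cols in list(c(31, 38), c(39, 46), c(47, 54))) {
      fld <- str_trim(substr(ln, cols[1], cols[2]))
      if (is.na(suppressWarnings(as.numeric(fld)))) {
        abort(
          sprintf("Unparseable coordinate field '%s' on line %d: %s", fld, i, ln),
          class = "phorescreen_parse_error"
        )
      }
    }
  }
  tf <- tempfile(fileext = ".pdb")
  on.exit(unlink(tf))
  writeLines(lines, tf)
  pdb <- bio3d::read.pdb(tf, multi = FALSE, rm.alt = TRUE, verbose = FALSE)
  at <- pdb$atom
  keep_row <- at$type == "ATOM" | (keep_hetatm & at$type == "HETATM")
  keep_row <- keep_row & !(at$resid %in% c("HOH", "WAT", "DOD"))
  at <- at[keep_row, , drop = FALSE]
  elem <- ifelse(
    !is.na(at$elesy) & nzchar(str_trim(at$elesy)),
    str_trim(at$elesy),
    infer_element(at$elety)
  )
  out <- tibble(
    serial = as.integer(at$eleno),
    atom = str_trim(at$elety),
    element = toupper(elem),
    resname = str_trim(at$resid),
    chain = ifelse(is.na(at$chain), " ", at$chain),
    resno = as.integer(at$resno),
    x = at$x, y = at$y, z = at$z
  )
  if (any(!is.finite(out$x) | !is.finite(out$y) | !is.finite(out$z))) {
    abort("Non-finite coordinates in PDB text.", class = "phorescreen_parse_error")
  }
  new_structure(out, id)
}

new_structure <- function(atoms, id = "structure") {
  out <- as_tibble(atoms)
  attr(out, "structure_id") <- id
  class(out) <- c("protein_structure", class(out))
  out
}

# element from PDB atom name: first alphabetic character, with the usual
# two-letter cases handled by the columns-77/78 path upstream
infer_element <- function(name) {
  nm <- gsub("[^A-Za-z].*$", "", gsub("^[0-9 ]+", "", name))
  toupper(substr(nm, 1, 1))
}

#' @export
print.protein_structure <- function(x, ...) {
  nres <- nrow(distinct(as_tibble(x), .data$chain, .data$resno))
  cat(sprintf(
    "<protein_structure '%s'> %d atoms, %d residues\n",
    attr(x, "structure_id") %||% "?", nrow(x), nres
  ))
  NextMethod()
}

#' Write a structure to PDB text
#'
#' Serializes an atom tibble back to fixed-column `ATOM` records (one line
#' per atom, coordinates to 3 decimals), the dialect read by [parse_pdb()].
#'
#' @param structure A `protein_structure` tibble.
#' @return A single string of PDB text ending in `END`.
#' @export
write_pdb <- function(structure) {
  lines <- sprintf(
    "ATOM  %5d %-4s %3s %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
    structure$serial,
    ifelse(nchar(structure$atom) < 4, paste0(" ", structure$atom), structure$atom),
    structure$resname, structure$chain, structure$resno,
    structure$x, structure$y, structure$z, structure$element
  )
  paste(c(lines, "END", ""), collapse = "\n")
}

#' Define a pocket sphere
#'
#' @param center Numeric 3-vector, sphere center in Angstroms.
#' @param radius Positive radius in Angstroms.
#' @return A `pocket_sphere` object.
#' @export
pocket_sphere <- function(center, radius) {
  stopifnot(length(center) == 3, all(is.finite(center)))
  if (!is.numeric(radius) || length(radius) != 1 || radius < 0) {
    abort("radius must be a single non-negative number.")
  }
  structure(list(center = as.numeric(center), radius = as.numeric(radius)),
    class = "pocket_sphere"
  )
}

#' @export
print.pocket_sphere <- function(x, ...) {
  cat(sprintf(
    "<pocket_sphere> center (%.2f, %.2f, %.2f), radius %.2f A\n",
    x$center[1], x$center[2], x$center[3], x$radius
  ))
  invisible(x)
}

heavy_atoms <- function(structure) {
  filter(as_tibble(structure), !.data$element %in% c("H", "D"))
}

dist_to_point <- function(df, p) {
  sqrt((df$x - p[1])^2 + (df$y - p[2])^2 + (df$z - p[3])^2)
}

#' Select residues inside a pocket sphere
#'
#' Keeps every residue having at least one heavy atom within `sphere$radius`
#' (inclusive) of the sphere center. All atoms of selected residues are
#' returned; file order is preserved.
#'
#' @param structure A `protein_structure` tibble from [parse_pdb()].
#' @param sphere A [pocket_sphere()].
#' @return A `protein_structure` tibble restricted to the selected residues.
#' @export
select_pocket <- function(structure, sphere) {
  stopifnot(inherits(sphere, "pocket_sphere"))
  hv <- heavy_atoms(structure)
  hv$d <- dist_to_point(hv, sphere$center)
  keys <- hv |>
    filter(.data$d <= sphere$radius) |>
    distinct(.data$chain, .data$resno)
  out <- semi_join(as_tibble(structure), keys, by = c("chain", "resno"))
  new_structure(out, attr(structure, "structure_id") %||% "structure")
}

#' Residues of one structure in contact with another
#'
#' Returns the residues of `a` having at least one heavy atom within `cutoff`
#' Angstroms of any heavy atom of `b` -- e.g. the dimer-interface residues
#' when `a` and `b` are the two protomers.
#'
#' @param a,b `protein_structure` tibbles.
#' @param cutoff Positive contact distance in Angstroms.
#' @return A `protein_structure` tibble with the contacting residues of `a`.
#' @export
interface_residues <- function(a, b, cutoff) {
  if (!is.numeric(cutoff) || length(cutoff) != 1 || cutoff <= 0) {
    abort("cutoff must be a single positive number.")
  }
  ha <- heavy_atoms(a)
  hb <- heavy_atoms(b)
  if (nrow(ha) == 0 || nrow(hb) == 0) abort("Both structures must be non-empty.")
  d2 <- outer(ha$x, hb$x, "-")^2 + outer(ha$y, hb$y, "-")^2 + outer(ha$z, hb$z, "-")^2
  hit <- apply(d2 <= cutoff^2, 1, any)
  keys <- distinct(ha[hit, c("chain", "resno")])
  out <- semi_join(as_tibble(a), keys, by = c("chain", "resno"))
  new_structure(out, attr(a, "structure_id") %||% "structure")
}

#' Build a pocket sphere covering selected residues
#'
#' The sphere center is the centroid of the heavy atoms of the selected
#' residues; the radius is the maximum center-to-atom distance plus
#' `padding`. This mirrors placing an active-site sphere over key residues.
#'
#' @param structure A `protein_structure` tibble.
#' @param selection A data frame (or tibble) with columns `chain` and `resno`
#'   naming the residues to cover.
#' @param padding Extra radius in Angstroms (default 3).
#' @return A [pocket_sphere()].
#' @export
sphere_from_residues <- function(structure, selection, padding = 3) {
  stopifnot(is.data.frame(selection), all(c("chain", "resno") %in% names(selection)))
  sel <- distinct(as_tibble(selection)[, c("chain", "resno")])
  hv <- heavy_atoms(structure)
  found <- semi_join(sel, hv, by = c("chain", "resno"))
  if (nrow(found) < nrow(sel)) {
    missing <- anti_join(sel, hv, by = c("chain", "resno"))
    abort(sprintf(
      "Residue(s) not found in structure: %s",
      paste(paste0(missing$chain, ":", missing$resno), collapse = ", ")
    ))
  }
  at <- semi_join(hv, sel, by = c("chain", "resno"))
  center <- c(mean(at$x), mean(at$y), mean(at$z))
  radius <- max(dist_to_point(at, center))
  pocket_sphere(center, radius + padding)
}

#' Pocket residue report
#'
#' Residue-level summary of a pocket selection: one row per residue with its
#' minimum heavy-atom distance to the sphere center, suitable for writing as
#' TSV.
#'
#' @param structure A `protein_structure` tibble.
#' @param sphere A [pocket_sphere()].
#' @return A tibble with columns `chain`, `resno`, `resname`, `min_dist`.
#' @export
pocket_report <- function(structure, sphere) {
  hv <- heavy_atoms(select_pocket(structure, sphere))
  hv$d <- dist_to_point(hv, sphere$center)
  hv |>
    group_by(.data$chain, .data$resno, .data$resname) |>
    summarise(min_dist = min(.data$d), .groups = "drop") |>
    arrange(.data$chain, .data$resno)
}
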