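# Hashed linear-path fingerprints for structural diversity analysis.
# Paths of 1..max_len heavy atoms are encoded as element/bond-order strings
# (canonicalized against reading direction) and hashed into a fixed-length
# bit vector with an explicit polynomial string hash, so bit assignment is
# reproducible across platforms.

hash_string <- function(s, nbits) {
  codes <- utf8ToInt(s)
  h <- 0
  for (c in codes) h <- (h * 131 + c) %% nbits
  as.integer(h) + 1L
}

#' Path fingerprint of a ligand
#'
#' Enumerates all simple paths of 1 to `max_len` heavy atoms, encodes each as
#' an element + bond-order string (taking the lexicographically smaller of
#' the two reading directions), and hashes every distinct string to one bit.
#'
#' @param ligand A `ligand` object.
#' @param max_len Maximum path length in atoms (default 5).
#' @param nbits Bit-vector length (default 1024).
#' @return A `fingerprint`: list with sorted set-bit positions `bits` and
#'   `nbits`.
#' @export
path_fingerprint <- function(ligand, max_len = 5, nbits = 1024) {
  key <- elem_key(ligand$atoms$element)
  is_h <- key %in% c("H", "D")
  adj <- vector("list", nrow(ligand$atoms))
  bord <- list()
  for (r in seq_len(nrow(ligand$bonds))) {
    i <- ligand$bonds$i[r]; j <- ligand$bonds$j[r]
    if (is_h[i] || is_h[j]) next
    adj[[i]] <- c(adj[[i]], j)
    adj[[j]] <- c(adj[[j]], i)
    bord[[paste(min(i, j), max(i, j))]] <- ligand$bonds$order[r]
  }
  strings <- new.env(hash = TRUE)
  path_str <- function(path) {
    toks <- key[path[1]]
    for (t in seq_along(path)[-1]) {
      a <- path[t - 1]; b <- path[t]
      toks <- c(toks, bord[[paste(min(a, b), max(a, b))]], key[b])
    }
    fwd <- paste(toks, collapse = "")
    rev_ <- paste(rev(toks), collapse = "")
    if (fwd <= rev_) fwd else rev_
  }
  dfs <- function(path) {
    assign(path_str(path), TRUE, envir = strings)
    if (length(path) >= max_len) return(invisible())
    for (w in adj[[path[length(path)]]]) {
      if (!(w %in% path)) dfs(c(path, w))
    }
  }
  for (s in which(!is_h)) dfs(s)
  bits <- sort(unique(map_int(ls(strings), hash_string, nbits = nbits)))
  structure(list(bits = bits, nbits = as.integer(nbits)), class = "fingerprint")
}

#' @export
print.fingerprint <- function(x, ...) {
  cat(sprintf("<fingerprint> %d/%d bits set\n", length(x$bits), x$nbits))
  invisible(x)
}

#' Tanimoto similarity of two fingerprints
#'
#' `|a AND b| / |a OR b|`, defined as 1 when both fingerprints are empty.
#'
#' @param a,b `fingerprint` objects with equal `nbits`.
#' @return Similarity in `[0, 1]`.
#' @export
tanimoto <- function(a, b) {
  stopifnot(inherits(a, "fingerprint"), inherits(b, "fingerprint"))
  if (a$nbits != b$nbits) abort("Fingerprints have different nbits.")
  un <- length(union(a$bits, b$bits))
  if (un == 0) return(1.0)
  length(intersect(a$bits, b$bits)) / un
}
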