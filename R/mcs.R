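# Maximum common substructure (connected, induced, heavy atoms only)
# and the pose-similarity metrics built on it.  Because all poses share
# the receptor frame, RMSD over the common graph is computed in place,
# with no superposition.

# Heavy-atom graph with the labels used for atom/bond compatibility.
mol_graph <- function(mol) {
  h <- heavy_idx(mol)
  rinfo <- ring_info(mol)
  arom <- aromatic_flags(mol, rinfo)
  A <- bond_matrix(mol)[h, h, drop = FALSE]
  # aromatic-ring bonds are labelled 4 regardless of Kekule orders
  ar_rings <- aromatic_rings(mol)
  if (length(ar_rings)) {
    pos <- match(seq_len(nrow(mol$atoms)), h)
    for (ring in ar_rings) {
      k <- length(ring)
      for (t in seq_len(k)) {
        a <- pos[ring[t]]; b <- pos[ring[if (t == k) 1L else t + 1L]]
        if (!is.na(a) && !is.na(b) && A[a, b] > 0) A[a, b] <- A[b, a] <- 4L
      }
    }
  }
  list(idx = h, element = mol$atoms$element[h], aromatic = arom[h],
       ring_size = rinfo$ring_size[h], A = A,
       adj = lapply(seq_along(h), function(i) which(A[i, ] > 0)))
}

# Pairwise atom compatibility: same element and aromaticity; unless
# ring_relaxed, the smallest-ring-size labels must also agree (0 for
# acyclic atoms), so ring atoms only match ring atoms of the same size.
.atom_compat <- function(g1, g2, ring_relaxed) {
  n1 <- length(g1$idx); n2 <- length(g2$idx)
  C <- outer(g1$element, g2$element, "==") &
    outer(g1$aromatic, g2$aromatic, "==")
  if (!ring_relaxed)
    C <- C & outer(g1$ring_size, g2$ring_size, "==")
  C
}

#' Find the maximum common graph between two molecules
#'
#' Searches for the largest connected common induced subgraph over heavy
#' atoms.  Atoms are compatible when element and aromaticity agree (and,
#' by default, the size of the smallest ring containing them); bonds
#' must carry the same order, with aromatic matching aromatic.  Among
#' all maximum-size mappings the one with the smallest in-place RMSD is
#' returned, so the metric is deterministic for poses in a shared frame.
#'
#' @param ref,probe [molecule()] objects with at least one heavy atom.
#' @param ring_relaxed When `TRUE`, atoms in rings of different sizes
#'   (or in no ring) are still compatible.
#' @param connected Require the common subgraph to be connected
#'   (default `TRUE`; the pose metrics are defined on common fragments).
#' @param max_seconds Search budget; on expiry the best mapping found
#'   under the deterministic ordering is returned with a warning.
#' @param max_mappings Maximum number of tied maximum mappings retained
#'   for the RMSD tie-break.
#' @return Object of class `mcs_mapping`: fields `ref_id`, `probe_id`,
#'   `pairs` (two-column matrix of atom indices, ref then probe),
#'   `size`, `ring_relaxed`.
#' @export
find_common_graph <- function(ref, probe, ring_relaxed = FALSE,
                              connected = TRUE,
                              max_seconds = 30, max_mappings = 64L) {
  stopifnot(inherits(ref, "molecule"), inherits(probe, "molecule"))
  if (heavy_atom_count(ref) < 1L || heavy_atom_count(probe) < 1L)
    stop("both molecules need at least one heavy atom")
  g1 <- mol_graph(ref); g2 <- mol_graph(probe)
  C <- .atom_compat(g1, g2, ring_relaxed)
  if (!any(C)) stop("no common atom between '", ref$id, "' and '",
                    probe$id, "'")
  n1 <- length(g1$idx); n2 <- length(g2$idx)
  st <- new.env(parent = emptyenv())
  st$best <- 0L; st$maps <- list(); st$deadline <- proc.time()[3] + max_seconds
  st$timed_out <- FALSE

  record <- function(map) {
    sz <- sum(!is.na(map))
    if (sz > st$best) { st$best <- sz; st$maps <- list(map) }
    else if (sz == st$best && length(st$maps) < max_mappings)
      st$maps <- c(st$maps, list(map))
  }

  # count ref atoms reachable from the mapped set through atoms that are
  # neither excluded nor mapped (upper bound on further growth)
  reach_count <- function(map, excluded) {
    seen <- !is.na(map)
    if (!connected) return(sum(!seen & !excluded))
    queue <- which(seen)
    cnt <- 0L
    visited <- seen | excluded
    while (length(queue)) {
      v <- queue[length(queue)]; queue <- queue[-length(queue)]
      for (w in g1$adj[[v]]) {
        if (!visited[w]) {
          visited[w] <- TRUE
          cnt <- cnt + 1L
          queue <- c(queue, w)
        }
      }
    }
    cnt
  }

  extend <- function(map, used2, excluded, start) {
    if (proc.time()[3] > st$deadline) { st$timed_out <- TRUE; return() }
    sz <- sum(!is.na(map))
    repeat {
      # smallest eligible frontier atom
      u <- 0L
      for (cand in seq_len(n1)) {
        if (cand < start || excluded[cand] || !is.na(map[cand])) next
        if (!connected || any(!is.na(map[g1$adj[[cand]]]))) { u <- cand; break }
      }
      if (u == 0L) { record(map); return() }
      bound <- sz + min(reach_count(map, excluded), n2 - sz)
      if (bound < st$best || (bound == st$best && length(st$maps) >= max_mappings))
        return()
      mapped1 <- which(!is.na(map))
      for (v in seq_len(n2)) {
        if (used2[v] || !C[u, v]) next
        ok <- TRUE
        for (x in mapped1) {
          b1 <- g1$A[u, x]; b2 <- g2$A[v, map[x]]
          if (b1 != b2) { ok <- FALSE; break }
        }
        if (ok) {
          map[u] <- v; used2[v] <- TRUE
          extend(map, used2, excluded, start)
          map[u] <- NA_integer_; used2[v] <- FALSE
          if (st$timed_out) return()
        }
      }
      # branch where u is excluded from this subtree
      excluded[u] <- TRUE
    }
  }

  for (i in seq_len(n1)) {
    if (st$timed_out) break
    # mappings whose smallest ref atom is i: atoms < i are excluded
    excluded <- rep(FALSE, n1)
    if (i > 1L) excluded[seq_len(i - 1L)] <- TRUE
    if (n1 - (i - 1L) < st$best) break   # cannot beat best any more
    for (j in seq_len(n2)) {
      if (!C[i, j]) next
      map <- rep(NA_integer_, n1); map[i] <- j
      used2 <- rep(FALSE, n2); used2[j] <- TRUE
      extend(map, used2, excluded, i)
      if (st$timed_out) break
    }
  }
  if (st$timed_out)
    warning("common-graph search hit the time budget; returning the best ",
            "mapping found")
  if (st$best == 0L) stop("no common atom between '", ref$id, "' and '",
                          probe$id, "'")
  # tie-break by smallest in-place RMSD, deterministically
  xyz1 <- coords(ref); xyz2 <- coords(probe)
  score <- vapply(st$maps, function(map) {
    m1 <- which(!is.na(map))
    d <- xyz1[g1$idx[m1], , drop = FALSE] -
      xyz2[g2$idx[map[m1]], , drop = FALSE]
    sqrt(mean(rowSums(d^2)))
  }, numeric(1))
  map <- st$maps[[which.min(score)]]
  m1 <- which(!is.na(map))
  pairs <- cbind(ref = g1$idx[m1], probe = g2$idx[map[m1]])
  structure(list(ref_id = ref$id, probe_id = probe$id, pairs = pairs,
                 size = nrow(pairs), ring_relaxed = ring_relaxed),
            class = "mcs_mapping")
}

#' @export
print.mcs_mapping <- function(x, ...) {
  cat("<mcs_mapping>", x$ref_id, "vs", x$probe_id, "- size", x$size,
      if (x$ring_relaxed) "(ring-relaxed)" else "", "\n")
  invisible(x)
}
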