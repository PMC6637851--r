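#' Construct a molecule
#'
#' A `molecule` is the package's ligand container: a 3D pose with elements,
#' Cartesian coordinates (Angstrom), formal charges, optional partial charges
#' (e) and a bond list.  Coordinates are taken as-is; all poses in a series
#' are assumed to share one receptor frame, so no alignment is ever applied.
#'
#' @param id Character identifier.
#' @param atoms `data.frame` with columns `element`, `x`, `y`, `z`,
#'   and optionally `formal_charge` (integer, default 0) and
#'   `partial_charge` (numeric, default `NA`).
#' @param bonds `data.frame` with columns `i`, `j` (1-based atom indices)
#'   and `order` (1, 2, 3 or 4 for aromatic).
#' @return An object of class `molecule`.
#' @examples
#' m <- molecule("methane-frag",
#'   atoms = data.frame(element = "C", x = 0, y = 0, z = 0),
#'   bonds = data.frame(i = integer(), j = integer(), order = integer()))
#' heavy_atom_count(m)
#' @export
molecule <- function(id, atoms, bonds = NULL) {
  stopifnot(is.character(id), length(id) == 1L)
  atoms <- as.data.frame(atoms)
  need <- c("element", "x", "y", "z")
  if (!all(need %in% names(atoms)))
    stop("atoms must have columns element, x, y, z")
  if (is.null(atoms$formal_charge)) atoms$formal_charge <- 0L
  if (is.null(atoms$partial_charge)) atoms$partial_charge <- NA_real_
  atoms$element <- as.character(atoms$element)
  if (!all(is.finite(as.matrix(atoms[, c("x", "y", "z")]))))
    stop("molecule '", id, "': non-finite coordinates")
  if (is.null(bonds))
    bonds <- data.frame(i = integer(), j = integer(), order = integer())
  bonds <- as.data.frame(bonds)
  if (nrow(bonds) && !all(c("i", "j", "order") %in% names(bonds)))
    stop("bonds must have columns i, j, order")
  if (nrow(bonds)) {
    bad <- bonds$i < 1 | bonds$j < 1 | bonds$i > nrow(atoms) |
      bonds$j > nrow(atoms) | bonds$i == bonds$j
    if (any(bad)) stop("molecule '", id, "': bond indices out of range")
  }
  structure(list(id = id, atoms = atoms, bonds = bonds), class = "molecule")
}

#' Number of non-hydrogen atoms
#' @param mol A [molecule()].
#' @return Integer count of heavy (non-H) atoms.
#' @export
heavy_atom_count <- function(mol) {
  stopifnot(inherits(mol, "molecule"))
  sum(mol$atoms$element != "H")
}

#' @export
print.molecule <- function(x, ...) {
  cat("<molecule>", x$id, "\n")
  cat("  atoms:", nrow(x$atoms), "(", heavy_atom_count(x), "heavy )",
      " bonds:", nrow(x$bonds), "\n")
  chg <- sum(x$atoms$formal_charge)
  if (chg != 0) cat("  net formal charge:", chg, "\n")
  invisible(x)
}

# Coordinates as an n x 3 matrix.
coords <- function(mol) as.matrix(mol$atoms[, c("x", "y", "z")])

# Indices of heavy atoms.
heavy_idx <- function(mol) which(mol$atoms$element != "H")

# Adjacency over all atoms: matrix of bond orders, 0 = no bond.
bond_matrix <- function(mol) {
  n <- nrow(mol$atoms)
  A <- matrix(0L, n, n)
  if (nrow(mol$bonds)) {
    for (k in seq_len(nrow(mol$bonds))) {
      i <- mol$bonds$i[k]; j <- mol$bonds$j[k]
      A[i, j] <- A[j, i] <- as.integer(mol$bonds$order[k])
    }
  }
  A
}

# Smallest ring size through each atom (0 when acyclic) plus the ring
# atom sets found, restricted to the heavy-atom graph.  For each edge
# (a, b) the shortest a..b path avoiding that edge closes the smallest
# cycle containing the edge; per-atom minima over those cycles give the
# smallest-ring-size labels used for MCS atom compatibility.
ring_info <- function(mol) {
  h <- heavy_idx(mol)
  n <- length(h)
  pos <- match(seq_len(nrow(mol$atoms)), h)   # atom -> heavy index
  A <- bond_matrix(mol)[h, h, drop = FALSE]
  adj <- lapply(seq_len(n), function(i) which(A[i, ] > 0))
  ring_size <- integer(n)
  rings <- list()
  edges <- which(upper.tri(A) & A > 0, arr.ind = TRUE)
  if (nrow(edges)) {
    for (k in seq_len(nrow(edges))) {
      a <- edges[k, 1]; b <- edges[k, 2]
      # BFS from a to b without edge (a,b)
      prev <- rep(NA_integer_, n); prev[a] <- 0L
      queue <- a; found <- FALSE
      while (length(queue) && !found) {
        v <- queue[1]; queue <- queue[-1]
        for (w in adj[[v]]) {
          if (v == a && w == b) next
          if (is.na(prev[w])) {
            prev[w] <- v
            if (w == b) { found <- TRUE; break }
            queue <- c(queue, w)
          }
        }
      }
      if (found) {
        path <- b
        while (path[1] != a) path <- c(prev[path[1]], path)
        cyc <- sort(path)
        sz <- length(path)
        for (v in path) ring_size[v] <- if (ring_size[v] == 0L) sz else min(ring_size[v], sz)
        key <- paste(cyc, collapse = ",")
        if (!key %in% names(rings)) rings[[key]] <- path
      }
    }
  }
  # map back to full atom indexing
  full_ring_size <- integer(nrow(mol$atoms))
  full_ring_size[h] <- ring_size
  full_rings <- lapply(rings, function(p) h[p])
  list(ring_size = full_ring_size, rings = full_rings)
}

# Aromatic flag per atom.  A ring counts as aromatic when (a) every ring
# bond is SDF order 4, or (b) it is a six-membered C/N ring whose bond
# orders alternate single/double (Kekule benzene/pyridine).  This covers
# the chemistry the package generates and reads; it is not a general
# Hueckel perception.
aromatic_flags <- function(mol, rinfo = NULL) {
  if (is.null(rinfo)) rinfo <- ring_info(mol)
  n <- nrow(mol$atoms)
  arom <- rep(FALSE, n)
  A <- bond_matrix(mol)
  for (ring in rinfo$rings) {
    k <- length(ring)
    ord <- vapply(seq_len(k), function(t) {
      a <- ring[t]; b <- ring[if (t == k) 1L else t + 1L]
      A[a, b]
    }, integer(1))
    el <- mol$atoms$element[ring]
    is_ar <- all(ord == 4L) ||
      (k == 6L && all(el %in% c("C", "N")) &&
         sum(ord == 2L) == 3L && sum(ord == 1L) == 3L &&
         all(abs(diff(ord)) == 1L))
    if (is_ar) arom[ring] <- TRUE
  }
  arom
}

# Ring atom index sets that are aromatic (used for ring-centroid geometry).
aromatic_rings <- function(mol) {
  rinfo <- ring_info(mol)
  A <- bond_matrix(mol)
  keep <- list()
  for (ring in rinfo$rings) {
    k <- length(ring)
    ord <- vapply(seq_len(k), function(t) {
      a <- ring[t]; b <- ring[if (t == k) 1L else t + 1L]
      A[a, b]
    }, integer(1))
    el <- mol$atoms$element[ring]
    is_ar <- all(ord == 4L) ||
      (k == 6L && all(el %in% c("C", "N")) &&
         sum(ord == 2L) == 3L && sum(ord == 1L) == 3L)
    if (is_ar) keep[[length(keep) + 1L]] <- ring
  }
  keep
}

# Translate/rotate a molecule rigidly (used by equivariance tests and
# the synthetic generator).  R is a 3x3 rotation, t a length-3 shift.
transform_molecule <- function(mol, R = diag(3), t = c(0, 0, 0)) {
  xyz <- coords(mol) %*% t(R)
  xyz <- sweep(xyz, 2, t, "+")
  mol$atoms$x <- xyz[, 1]; mol$atoms$y <- xyz[, 2]; mol$atoms$z <- xyz[, 3]
  mol
}
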