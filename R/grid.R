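# Rectangular field grid shared by all compounds of a series, plus the
# OpenDX volumetric export used for coefficient contour maps.

#' Build a field grid around a set of molecules
#'
#' Axis-aligned box covering all atoms of all molecules plus `padding`
#' on each side, sampled every `spacing` Angstrom; node count per axis
#' is `floor(range / spacing) + 1`.
#'
#' @param molecules List of [molecule()] objects sharing one frame.
#' @param spacing Grid step in Angstrom (default 1.0).
#' @param padding Margin added to the bounding box (default 5.0).
#' @return Object of class `field_grid` with fields `origin`, `spacing`,
#'   `dims` (nodes per axis) and `n_nodes`.
#' @export
build_grid <- function(molecules, spacing = 1.0, padding = 5.0) {
  if (inherits(molecules, "molecule")) molecules <- list(molecules)
  if (length(molecules) == 0L) stop("no molecules supplied")
  stopifnot(spacing > 0, padding >= 0)
  xyz <- do.call(rbind, lapply(molecules, coords))
  lo <- apply(xyz, 2, min) - padding
  hi <- apply(xyz, 2, max) + padding
  dims <- pmax(floor((hi - lo) / spacing) + 1L, 1L)
  structure(list(origin = lo, spacing = spacing, dims = as.integer(dims),
                 n_nodes = as.integer(prod(dims))),
            class = "field_grid")
}

#' Cartesian coordinates of all grid nodes
#'
#' Nodes are ordered with the x index varying fastest, then y, then z
#' (column-major over the axes).
#' @param grid A [build_grid()] object.
#' @return `n_nodes x 3` matrix in Angstrom.
#' @export
grid_coords <- function(grid) {
  stopifnot(inherits(grid, "field_grid"))
  ax <- lapply(1:3, function(k)
    grid$origin[k] + grid$spacing * (seq_len(grid$dims[k]) - 1L))
  g <- expand.grid(x = ax[[1]], y = ax[[2]], z = ax[[3]],
                   KEEP.OUT.ATTRS = FALSE)
  as.matrix(g)
}

#' @export
print.field_grid <- function(x, ...) {
  cat("<field_grid>", paste(x$dims, collapse = " x "), "nodes, spacing",
      x$spacing, "A, origin", paste(round(x$origin, 2), collapse = ", "),
      "\n")
  invisible(x)
}

#' Write a per-node scalar map in OpenDX format
#'
#' Writes a regular-grid volumetric map (one value per grid node) as an
#' OpenDX text file readable by common molecular viewers.
#'
#' @param values Numeric vector, one value per node in [grid_coords()]
#'   order.
#' @param grid The [build_grid()] object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_dx <- function(values, grid, path) {
  stopifnot(inherits(grid, "field_grid"))
  if (length(values) != grid$n_nodes)
    stop("expected ", grid$n_nodes, " values, got ", length(values))
  d <- grid$dims
  # OpenDX iterates z fastest; our node order has x fastest
  dx_vals <- as.vector(aperm(array(values, dim = d), c(3, 2, 1)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("object 1 class gridpositions counts %d %d %d", d[1], d[2], d[3]),
    sprintf("origin %.4f %.4f %.4f", grid$origin[1], grid$origin[2],
            grid$origin[3]),
    sprintf("delta %.4f 0 0", grid$spacing),
    sprintf("delta 0 %.4f 0", grid$spacing),
    sprintf("delta 0 0 %.4f", grid$spacing),
    sprintf("object 2 class gridconnections counts %d %d %d",
            d[1], d[2], d[3]),
    sprintf("object 3 class array type double rank 0 items %d data follows",
            grid$n_nodes)), con)
  # three values per line
  idx <- seq(1, length(dx_vals), by = 3)
  lines <- vapply(idx, function(i) {
    paste(formatC(dx_vals[i:min(i + 2, length(dx_vals))],
                  format = "e", digits = 6), collapse = " ")
  }, "")
  writeLines(lines, con)
  writeLines(c('attribute "dep" string "positions"',
               'object "regular positions regular connections" class field',
               'component "positions" value 1',
               'component "connections" value 2',
               'component "data" value 3'), con)
  invisible(path)
}
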