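# Molecular interaction fields: steric (Lennard-Jones 6-12) and
# electrostatic (Coulomb, distance-dependent dielectric) probe energies
# at every grid node, assembled into the compounds x variables matrix
# that feeds the PLS model.

# van der Waals parameters per element: Rmin (A, at the pair minimum
# when combined) and epsilon (kcal/mol).  A compact documented table in
# the MMFF spirit; combination rules below.  The probe is an sp3 carbon.
.vdw_table <- data.frame(
  element = c("H", "C", "N", "O", "F", "P", "S", "Cl", "Br", "I"),
  rmin = c(1.20, 1.96, 1.79, 1.71, 1.65, 2.15, 2.00, 1.97, 2.22, 2.36),
  eps = c(0.022, 0.107, 0.110, 0.122, 0.081, 0.305, 0.274, 0.276,
          0.389, 0.550))

.probe_vdw <- list(rmin = 1.96, eps = 0.107)  # sp3 carbon probe
.coulomb_k <- 332.0637                        # kcal*A/(mol*e^2)

.vdw_params <- function(elements) {
  i <- match(elements, .vdw_table$element)
  if (anyNA(i))
    stop("no van der Waals parameters for element(s): ",
         paste(unique(elements[is.na(i)]), collapse = ", "))
  list(rmin = .vdw_table$rmin[i], eps = .vdw_table$eps[i])
}

#' Steric probe energy at grid nodes
#'
#' Lennard-Jones 6-12 interaction between an uncharged sp3-carbon probe
#' and all atoms of the molecule, summed per node:
#' `E = sum_i eps_i * ((Rmin_i / r_i)^12 - 2 (Rmin_i / r_i)^6)` with
#' Lorentz-Berthelot-style combination `Rmin_i = rmin(atom) + rmin(probe)`
#' and `eps_i = sqrt(eps(atom) * eps(probe))`.  At the pair minimum
#' distance the pair energy is exactly `-eps_i`.  Values are returned
#' uncapped; capping belongs to [pretreat()].
#'
#' @param nodes `n x 3` coordinate matrix (or a [build_grid()] object).
#' @param mol A [molecule()].
#' @return Energy in kcal/mol per node.
#' @export
steric_energy <- function(nodes, mol) {
  if (inherits(nodes, "field_grid")) nodes <- grid_coords(nodes)
  nodes <- rbind(nodes)
  p <- .vdw_params(mol$atoms$element)
  rmin <- p$rmin + .probe_vdw$rmin
  eps <- sqrt(p$eps * .probe_vdw$eps)
  r <- .cross_dist(nodes, coords(mol))
  r <- pmax(r, 1e-6)
  s6 <- sweep(1 / r, 2, rmin, "*")^6   # (rmin/r)^6 per node x atom
  e <- sweep(s6^2 - 2 * s6, 2, eps, "*")
  rowSums(e)
}

#' Electrostatic probe energy at grid nodes
#'
#' Coulomb interaction of a +1 charged probe with the molecule's partial
#' charges under a distance-dependent dielectric `eps(r) = r`:
#' `E = sum_i k * q_i / r_i^2` with `k = 332.0637` kcal A / (mol e^2).
#' Nodes essentially coincident with an atom (r < 1e-6 A) are evaluated
#' at that floor distance and will be capped downstream.
#'
#' @inheritParams steric_energy
#' @param dielectric Either `"r"` (distance-dependent, default) or a
#'   positive constant relative permittivity.
#' @return Energy in kcal/mol per node.
#' @export
electrostatic_energy <- function(nodes, mol, dielectric = "r") {
  if (inherits(nodes, "field_grid")) nodes <- grid_coords(nodes)
  nodes <- rbind(nodes)
  q <- mol$atoms$partial_charge
  if (any(!is.finite(q)))
    stop("molecule '", mol$id, "' has no partial charges; ",
         "run assign_partial_charges()")
  r <- .cross_dist(nodes, coords(mol))
  if (any(r < 1e-6))
    warning("grid node coincident with an atom; energy evaluated at the ",
            "1e-6 A floor and capped downstream")
  r <- pmax(r, 1e-6)
  denom <- if (identical(dielectric, "r")) r^2 else {
    stopifnot(is.numeric(dielectric), dielectric > 0)
    dielectric * r
  }
  rowSums(sweep(1 / denom, 2, .coulomb_k * q, "*"))
}

#' Compute the field data matrix for a compound series
#'
#' Evaluates the requested probe fields for every compound on a shared
#' grid and stacks them into a compounds x variables matrix; each
#' variable is one (field, grid node) pair.
#'
#' @param molecules Named list of [molecule()] objects in one frame.
#' @param grid Optional [build_grid()]; built from the series when
#'   omitted.
#' @param fields Character subset of `c("steric", "electrostatic")`.
#' @param spacing,padding Grid parameters when `grid` is omitted.
#' @param dielectric Passed to [electrostatic_energy()].
#' @return Object of class `field_matrix`: list with `X` (raw energy
#'   matrix), `block` (field label per column), `node` (grid node index
#'   per column), `grid`, `alive` (logical per column), `buw_w`
#'   (block weights, `NULL` until [buw_scale()]), `region` (`NA` until
#'   [srd_group()]), and `treatment` bookkeeping.
#' @export
compute_fields <- function(molecules, grid = NULL,
                           fields = c("steric", "electrostatic"),
                           spacing = 1.0, padding = 5.0,
                           dielectric = "r") {
  if (inherits(molecules, "molecule")) molecules <- list(molecules)
  if (length(molecules) == 0L) stop("no molecules supplied")
  fields <- match.arg(fields, c("steric", "electrostatic"),
                      several.ok = TRUE)
  if (is.null(grid)) grid <- build_grid(molecules, spacing, padding)
  nodes <- grid_coords(grid)
  ids <- vapply(seq_along(molecules), function(i) {
    id <- molecules[[i]]$id
    if (is.null(id) || !nzchar(id)) paste0("cmpd_", i) else id
  }, "")
  blocks <- list()
  for (f in fields) {
    M <- t(vapply(molecules, function(mol) {
      if (f == "steric") steric_energy(nodes, mol)
      else electrostatic_energy(nodes, mol, dielectric)
    }, numeric(nrow(nodes))))
    rownames(M) <- ids
    blocks[[f]] <- M
  }
  X <- do.call(cbind, blocks)
  block <- rep(fields, each = grid$n_nodes)
  node <- rep(seq_len(grid$n_nodes), times = length(fields))
  colnames(X) <- paste0(substr(block, 1, 1), node)
  structure(list(X = X, block = block, node = node, grid = grid,
                 alive = rep(TRUE, ncol(X)), buw_w = NULL,
                 region = rep(NA_integer_, ncol(X)),
                 treatment = list(pretreated = FALSE, buw = FALSE)),
            class = "field_matrix")
}

#' @export
print.field_matrix <- function(x, ...) {
  cat("<field_matrix>", nrow(x$X), "compounds x", ncol(x$X), "variables (",
      paste(unique(x$block), collapse = " + "), ")\n")
  cat("  alive:", sum(x$alive),
      if (x$treatment$pretreated) "(pretreated)" else "(raw)",
      if (x$treatment$buw) "BUW-scaled" else "", "\n")
  invisible(x)
}
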