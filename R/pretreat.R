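# Field-matrix pretreatment, block-unscaled weighting and smart region
# definition.

#' Pretreat a field matrix
#'
#' Applies the standard variable pretreatment: (i) energies above `cap`
#' are set to `cap` (electrostatic energies are also floored at `-cap`);
#' (ii) values with magnitude below `zero_threshold` are set to zero;
#' (iii) variables taking at most `nlevel_max` distinct values across
#' compounds (n-level variables), or with zero variance, are marked dead
#' and excluded from modelling.
#'
#' @param fm A [compute_fields()] matrix.
#' @param cap Energy cap in kcal/mol (default 30).
#' @param zero_threshold Magnitude below which values are zeroed
#'   (default 0.05 kcal/mol).
#' @param nlevel_max Maximum distinct-value count of a dead variable
#'   (default 4).
#' @return The pretreated `field_matrix`.
#' @export
pretreat <- function(fm, cap = 30, zero_threshold = 0.05, nlevel_max = 4L) {
  stopifnot(inherits(fm, "field_matrix"))
  if (cap <= zero_threshold) stop("cap must exceed zero_threshold")
  X <- fm$X
  X[X > cap] <- cap
  neg <- fm$block[col(X)] == "electrostatic" & X < -cap
  X[neg] <- -cap
  X[abs(X) < zero_threshold] <- 0
  nlev <- apply(X, 2, function(v) length(unique(v)))
  vvar <- apply(X, 2, stats::var)
  fm$X <- X
  fm$alive <- fm$alive & nlev > nlevel_max & vvar > 0
  fm$treatment$pretreated <- TRUE
  fm$treatment$cap <- cap
  fm$treatment$zero_threshold <- zero_threshold
  fm$treatment$nlevel_max <- nlevel_max
  fm
}

#' Block Unscaled Weighting
#'
#' Multiplies every field block by `1 / sqrt(total column variance of
#' the block)` (alive variables only), so each block contributes unit
#' total variance while the relative scale of variables within a block
#' is preserved.
#'
#' @param fm A pretreated `field_matrix`.
#' @return The scaled `field_matrix` with `buw_w` set.
#' @export
buw_scale <- function(fm) {
  stopifnot(inherits(fm, "field_matrix"))
  if (!any(fm$alive)) stop("no alive variables")
  w <- numeric(0)
  for (b in unique(fm$block)) {
    sel <- fm$block == b & fm$alive
    if (!any(sel)) next
    tv <- sum(apply(fm$X[, sel, drop = FALSE], 2, stats::var))
    if (tv <= 0) stop("block '", b, "' has zero total variance")
    wb <- 1 / sqrt(tv)
    fm$X[, fm$block == b] <- fm$X[, fm$block == b, drop = FALSE] * wb
    w[b] <- wb
  }
  fm$buw_w <- if (is.null(fm$buw_w)) w else fm$buw_w * w
  fm$treatment$buw <- TRUE
  fm
}

#' Smart Region Definition grouping
#'
#' Groups alive grid variables into spatially contiguous regions:
#' (1) per field block, the `n_seeds` alive variables with the largest
#' preliminary weights become seeds; (2) every alive variable within
#' `critical_distance` of at least one seed of its block joins its
#' nearest seed (Voronoi assignment, ties to the lowest seed index);
#' (3) spatially adjacent regions whose compound-profile correlation is
#' at least `collinearity_cutoff` are merged; (4) variables assigned to
#' no region are dropped from modelling (marked dead).
#'
#' @param fm A pretreated, BUW-scaled `field_matrix`.
#' @param weights Preliminary per-variable importance, e.g.
#'   `abs(coef())` of a pilot PLS fit; length `ncol(fm$X)`.
#' @param n_seeds Seeds per block; default 10% of the block's alive
#'   variables, capped at 200.
#' @param critical_distance Seed attraction radius in Angstrom
#'   (default 2.0).
#' @param collinearity_cutoff Correlation at or above which adjacent
#'   regions merge (default 0.8).
#' @return The `field_matrix` with `region` filled in and orphan
#'   variables dead.
#' @export
srd_group <- function(fm, weights, n_seeds = NULL,
                      critical_distance = 2.0,
                      collinearity_cutoff = 0.8) {
  stopifnot(inherits(fm, "field_matrix"))
  if (length(weights) != ncol(fm$X))
    stop("weights must have one entry per variable")
  nodes <- grid_coords(fm$grid)
  region <- rep(NA_integer_, ncol(fm$X))
  next_id <- 0L
  seed_of_region <- integer(0)
  for (b in unique(fm$block)) {
    sel <- which(fm$block == b & fm$alive)
    if (!length(sel)) next
    ns <- if (is.null(n_seeds)) min(max(1L, floor(0.1 * length(sel))), 200L)
      else n_seeds
    if (ns < 1L || ns > length(sel))
      stop("n_seeds must be between 1 and the alive variable count (",
           length(sel), ") of block '", b, "'")
    ord <- sel[order(-abs(weights[sel]), sel)]   # ties: lowest index
    seeds <- ord[seq_len(ns)]
    sxyz <- nodes[fm$node[seeds], , drop = FALSE]
    vxyz <- nodes[fm$node[sel], , drop = FALSE]
    D <- .cross_dist(vxyz, sxyz)
    nearest <- apply(D, 1, which.min)
    within <- apply(D, 1, min) <= critical_distance
    region[sel[within]] <- next_id + nearest[within]
    seed_of_region <- c(seed_of_region, seeds)
    next_id <- next_id + ns
  }
  # merge spatially adjacent, collinear regions (within a block)
  ids <- sort(unique(region[!is.na(region)]))
  if (length(ids) > 1L) {
    profile <- vapply(ids, function(r) {
      rowMeans(fm$X[, which(region == r), drop = FALSE])
    }, numeric(nrow(fm$X)))
    # union-find
    parent <- seq_along(ids)
    find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
    for (a in seq_along(ids)) {
      for (bb in seq_along(ids)) {
        if (bb <= a) next
        va <- which(region == ids[a]); vb <- which(region == ids[bb])
        if (fm$block[va[1]] != fm$block[vb[1]]) next
        dmin <- min(.cross_dist(nodes[fm$node[va], , drop = FALSE],
                                nodes[fm$node[vb], , drop = FALSE]))
        if (dmin > fm$grid$spacing * 1.5) next   # not adjacent
        pa <- profile[, a]; pb <- profile[, bb]
        if (stats::sd(pa) == 0 || stats::sd(pb) == 0) next
        if (stats::cor(pa, pb) >= collinearity_cutoff) {
          ra <- find(a); rb <- find(bb)
          if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
        }
      }
    }
    root <- vapply(seq_along(ids), find, integer(1))
    region[!is.na(region)] <-
      root[match(region[!is.na(region)], ids)]
  }
  fm$region <- region
  fm$alive <- fm$alive & !is.na(region)
  fm$treatment$srd <- list(critical_distance = critical_distance,
                           collinearity_cutoff = collinearity_cutoff)
  fm
}

# Restrict a field matrix to a subset of compounds (rows).
subset_rows <- function(fm, rows) {
  fm$X <- fm$X[rows, , drop = FALSE]
  fm
}
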