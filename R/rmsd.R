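# In-place RMSD over a common-graph mapping and the %RefMatch/%MolMatch
# coverage percentages.

#' In-place RMSD over a common-graph mapping
#'
#' Root-mean-square deviation over the mapped atom pairs, computed
#' directly in the shared receptor frame: no fitting or superposition is
#' applied, since docked poses are already in one coordinate system.
#'
#' @param mapping An `mcs_mapping` from [find_common_graph()].
#' @param ref,probe The molecules the mapping refers to.
#' @return RMSD in Angstrom.
#' @export
rmsd_in_place <- function(mapping, ref, probe) {
  stopifnot(inherits(mapping, "mcs_mapping"))
  if (mapping$size < 1L) stop("empty mapping")
  p <- mapping$pairs
  if (any(p[, 1] > nrow(ref$atoms)) || any(p[, 2] > nrow(probe$atoms)))
    stop("mapping references atoms outside the molecules")
  d <- coords(ref)[p[, 1], , drop = FALSE] -
    coords(probe)[p[, 2], , drop = FALSE]
  sqrt(mean(rowSums(d^2)))
}

#' Common-graph coverage percentages
#'
#' `%RefMatch` is the common-graph size as a percentage of the
#' reference's heavy atoms; `%MolMatch` the same relative to the probe's
#' heavy atoms.  High values of both mean the probe is nearly the whole
#' reference and vice versa.
#'
#' @inheritParams rmsd_in_place
#' @return Named vector `c(ref_match = , mol_match = )` in percent.
#' @export
match_percents <- function(mapping, ref, probe) {
  stopifnot(inherits(mapping, "mcs_mapping"))
  if (mapping$size < 1L) stop("empty mapping")
  hr <- heavy_atom_count(ref); hp <- heavy_atom_count(probe)
  if (hr == 0L || hp == 0L) stop("molecule without heavy atoms")
  c(ref_match = 100 * mapping$size / hr,
    mol_match = 100 * mapping$size / hp)
}

#' Common-graph RMSD table against a reference pose
#'
#' For each probe pose, finds the maximum common graph with the
#' reference, computes the in-place RMSD and the coverage percentages,
#' and returns a report table (RMSD to 2 decimals, percentages rounded
#' to integers).  Per-pair failures are recorded in the `note` column
#' rather than aborting the table.
#'
#' @param ref Reference [molecule()].
#' @param probes List of probe molecules.
#' @param ring_relaxed Passed to [find_common_graph()].
#' @param ... Further arguments to [find_common_graph()].
#' @return `data.frame` with columns `id`, `rmsd_A`, `ref_match_pct`,
#'   `mol_match_pct`, `note`.
#' @export
rmsd_table <- function(ref, probes, ring_relaxed = FALSE, ...) {
  if (inherits(probes, "molecule")) probes <- list(probes)
  if (length(probes) == 0L)
    return(data.frame(id = character(), rmsd_A = numeric(),
                      ref_match_pct = numeric(), mol_match_pct = numeric(),
                      note = character()))
  rows <- lapply(probes, function(probe) {
    res <- tryCatch({
      m <- find_common_graph(ref, probe, ring_relaxed = ring_relaxed, ...)
      pct <- match_percents(m, ref, probe)
      data.frame(id = probe$id,
                 rmsd_A = round(rmsd_in_place(m, ref, probe), 2),
                 ref_match_pct = round(pct[["ref_match"]]),
                 mol_match_pct = round(pct[["mol_match"]]),
                 note = "")
    }, error = function(e) {
      data.frame(id = probe$id, rmsd_A = NA_real_,
                 ref_match_pct = NA_real_, mol_match_pct = NA_real_,
                 note = if (grepl("no common atom", conditionMessage(e)))
                   "no common graph" else conditionMessage(e))
    })
    res
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  if (is.null(out))
    out <- data.frame(id = character(), rmsd_A = numeric(),
                      ref_match_pct = numeric(), mol_match_pct = numeric(),
                      note = character())
  out
}
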