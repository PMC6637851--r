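# SDF (V2000) reading and writing, via ChemmineR, mapped onto the
# package's molecule class.  Formal charges are taken from the atom-block
# charge column and from M  CHG property lines (which override); partial
# charges come from a named SDF data field when present, otherwise from
# the bond-charge-increment scheme in assign_partial_charges().

.mdl_charge_decode <- function(code) {
  # V2000 atom-block charge codes: 1..7 = +3,+2,+1,radical,-1,-2,-3
  map <- c(0L, 3L, 2L, 1L, 0L, -1L, -2L, -3L)
  out <- map[pmin(pmax(as.integer(code), 0L), 7L) + 1L]
  out[is.na(out)] <- 0L
  out
}

.mdl_charge_encode <- function(q) {
  enc <- integer(length(q))
  enc[q == 3L] <- 1L; enc[q == 2L] <- 2L; enc[q == 1L] <- 3L
  enc[q == -1L] <- 5L; enc[q == -2L] <- 6L; enc[q == -3L] <- 7L
  enc
}

#' Read docked ligand poses from an SDF file
#'
#' Reads a multi-record V2000 SDF into a list of [molecule()] objects.
#' Records flagged as 2D (dimension code in the program line) are
#' rejected, since the pipeline interprets coordinates as docked 3D poses.
#'
#' @param path SDF file path.
#' @param charge_property Name of an SDF data field holding
#'   whitespace-separated per-atom partial charges; used when present.
#' @param assign_charges When no charge property is present, assign
#'   bond-charge-increment partial charges (default `TRUE`).
#' @return List of `molecule` objects, named by record title.
#' @export
read_sdf <- function(path, charge_property = "PARTIAL_CHARGES",
                     assign_charges = TRUE) {
  if (!file.exists(path)) stop("SDF file not found: ", path)
  sdfstr <- ChemmineR::read.SDFstr(path)
  reclines <- as(sdfstr, "list")
  sdfset <- suppressWarnings(as(sdfstr, "SDFset"))
  ok <- ChemmineR::validSDF(sdfset)
  if (!all(ok))
    stop("unparsable SDF record(s) at index: ",
         paste(which(!ok), collapse = ", "))
  out <- vector("list", length(sdfset))
  for (r in seq_along(sdfset)) {
    sdf <- sdfset[[r]]
    hd <- ChemmineR::header(sdf)
    ab <- ChemmineR::atomblock(sdf)
    bb <- ChemmineR::bondblock(sdf)
    if (grepl("2D", hd[["Source"]], fixed = TRUE))
      stop("SDF record ", r, " (", hd[["Molecule_Name"]],
           ") is flagged 2D; docked 3D poses are required")
    el <- vapply(strsplit(rownames(ab), "_", fixed = TRUE), `[`, "", 1L)
    fc <- .mdl_charge_decode(ab[, "C5"])
    # M  CHG lines override the atom-block codes
    mchg <- grep("^M  CHG", reclines[[r]], value = TRUE)
    if (length(mchg)) {
      fc[] <- 0L
      for (ln in mchg) {
        v <- as.integer(strsplit(trimws(sub("^M  CHG", "", ln)), "\\s+")[[1]])
        nent <- v[1]
        for (e in seq_len(nent)) {
          fc[v[2 * e]] <- v[2 * e + 1]
        }
      }
    }
    atoms <- data.frame(element = el,
                        x = ab[, "C1"], y = ab[, "C2"], z = ab[, "C3"],
                        formal_charge = fc,
                        partial_charge = NA_real_)
    bonds <- if (nrow(bb)) {
      data.frame(i = as.integer(bb[, "C1"]), j = as.integer(bb[, "C2"]),
                 order = as.integer(bb[, "C3"]))
    } else NULL
    id <- hd[["Molecule_Name"]]
    if (!nzchar(id)) id <- paste0("record_", r)
    mol <- molecule(id, atoms, bonds)
    db <- ChemmineR::datablock(sdf)
    if (length(db) && charge_property %in% names(db)) {
      q <- as.numeric(strsplit(trimws(db[[charge_property]]), "\\s+")[[1]])
      if (length(q) != nrow(atoms))
        stop("SDF record ", r, ": ", charge_property,
             " has ", length(q), " values for ", nrow(atoms), " atoms")
      mol$atoms$partial_charge <- q
    } else if (assign_charges) {
      mol <- assign_partial_charges(mol)
    }
    out[[r]] <- mol
  }
  names(out) <- vapply(out, function(m) m$id, "")
  out
}

#' Write molecules to an SDF file
#'
#' Writes a list of [molecule()] objects as V2000 records.  Formal
#' charges go into the atom-block charge column; partial charges are
#' stored in a data field so that [read_sdf()] round-trips them.
#'
#' @param mols List of `molecule` objects.
#' @param path Output file path.
#' @param charge_property Data field name used for partial charges.
#' @return `path`, invisibly.
#' @export
write_sdf <- function(mols, path, charge_property = "PARTIAL_CHARGES") {
  if (inherits(mols, "molecule")) mols <- list(mols)
  sdfs <- lapply(mols, function(mol) {
    n <- nrow(mol$atoms); nb <- nrow(mol$bonds)
    ab <- cbind(round(coords(mol), 4), matrix(0L, n, 12))
    colnames(ab) <- c("C1", "C2", "C3", paste0("C", 5:16))
    ab[, "C5"] <- .mdl_charge_encode(as.integer(mol$atoms$formal_charge))
    rownames(ab) <- paste(mol$atoms$element, seq_len(n), sep = "_")
    bb <- matrix(0L, nb, 4, dimnames = list(NULL, c("C1", "C2", "C3", "C4")))
    if (nb) {
      bb[, 1] <- as.integer(mol$bonds$i)
      bb[, 2] <- as.integer(mol$bonds$j)
      bb[, 3] <- as.integer(mol$bonds$order)
    }
    db <- character(0)
    if (all(is.finite(mol$atoms$partial_charge))) {
      db <- stats::setNames(
        paste(formatC(mol$atoms$partial_charge, digits = 6, format = "f"),
              collapse = " "),
        charge_property)
    }
    counts <- sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", n, nb)
    methods::new(methods::getClass("SDF", where = asNamespace("ChemmineR")),
                 header = c(Molecule_Name = mol$id, Source = "  fieldsar",
                            Comment = "", Counts_Line = counts),
                 atomblock = ab, bondblock = bb, datablock = db)
  })
  sdfset <- methods::new(
    methods::getClass("SDFset", where = asNamespace("ChemmineR")),
    SDF = unname(sdfs), ID = vapply(mols, function(m) m$id, ""))
  ChemmineR::write.SDF(sdfset, file = path)
  invisible(path)
}
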