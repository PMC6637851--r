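# Receptor structures.  Parsing is delegated to bio3d; the package keeps
# a flat atom table with a backbone flag, which is all the interaction
# fingerprint machinery needs.

.backbone_names <- c("N", "CA", "C", "O", "OXT")

#' Construct a protein structure from an atom table
#'
#' @param atoms `data.frame` with columns `chain`, `resno`, `insert`,
#'   `resid`, `atom_name`, `element`, `x`, `y`, `z`.
#' @return Object of class `protein_structure`.
#' @export
protein_structure <- function(atoms) {
  atoms <- as.data.frame(atoms)
  need <- c("chain", "resno", "insert", "resid", "atom_name", "element",
            "x", "y", "z")
  if (!all(need %in% names(atoms)))
    stop("atoms must have columns: ", paste(need, collapse = ", "))
  if (nrow(atoms) == 0L) stop("empty structure: no ATOM records")
  atoms$backbone <- atoms$atom_name %in% .backbone_names
  atoms$res_key <- paste(atoms$chain, atoms$resno, atoms$insert, sep = "|")
  rn <- unique(atoms[, c("res_key", "resid")])
  if (anyDuplicated(rn$res_key))
    stop("residue identifier maps to more than one residue name")
  structure(list(atoms = atoms), class = "protein_structure")
}

#' Load a receptor structure from a PDB file
#'
#' Reads ATOM/HETATM records via bio3d.  When alternate locations are
#' present, the highest-occupancy conformer of each atom is kept.  A
#' structure containing only CA atoms loads with a warning (side-chain
#' dependent interaction bits are undefined downstream).
#'
#' @param path PDB file path.
#' @param keep_hetatm Keep HETATM records (default `FALSE`).
#' @return A [protein_structure()].
#' @export
read_protein <- function(path, keep_hetatm = FALSE) {
  if (!file.exists(path)) stop("PDB file not found: ", path)
  pdb <- bio3d::read.pdb(path, rm.alt = FALSE, verbose = FALSE)
  at <- pdb$atom
  if (!keep_hetatm) at <- at[at$type == "ATOM", , drop = FALSE]
  if (nrow(at) == 0L) stop("empty structure: no ATOM records in ", path)
  at$insert[is.na(at$insert)] <- ""
  at$alt[is.na(at$alt)] <- ""
  at$o[is.na(at$o)] <- 1
  # alternate locations: keep highest occupancy per atom slot
  key <- paste(at$chain, at$resno, at$insert, at$elety, sep = "|")
  if (anyDuplicated(key)) {
    ord <- order(key, -at$o)
    at <- at[ord, , drop = FALSE]
    at <- at[!duplicated(paste(at$chain, at$resno, at$insert, at$elety,
                               sep = "|")), , drop = FALSE]
    at <- at[order(as.integer(rownames(at))), , drop = FALSE]
  }
  elem <- at$elesy
  if (is.null(elem) || all(is.na(elem)) || all(!nzchar(trimws(elem)))) {
    elem <- substr(trimws(at$elety), 1, 1)
  } else {
    elem <- trimws(elem)
    miss <- is.na(elem) | !nzchar(elem)
    elem[miss] <- substr(trimws(at$elety[miss]), 1, 1)
  }
  atoms <- data.frame(chain = at$chain, resno = at$resno, insert = at$insert,
                      resid = at$resid, atom_name = trimws(at$elety),
                      element = elem, x = at$x, y = at$y, z = at$z)
  ps <- protein_structure(atoms)
  if (all(ps$atoms$atom_name == "CA"))
    warning("structure contains only CA atoms; side-chain-dependent ",
            "interaction bits will be undefined")
  ps
}

#' Write a protein structure to a PDB file
#' @param protein A [protein_structure()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_protein <- function(protein, path) {
  stopifnot(inherits(protein, "protein_structure"))
  a <- protein$atoms
  bio3d::write.pdb(file = path,
                   xyz = as.vector(t(as.matrix(a[, c("x", "y", "z")]))),
                   resno = a$resno, resid = a$resid, chain = a$chain,
                   elety = a$atom_name, insert = ifelse(nzchar(a$insert),
                                                        a$insert, ""),
                   o = rep(1, nrow(a)), b = rep(0, nrow(a)),
                   elesy = a$element)
  invisible(path)
}

#' @export
print.protein_structure <- function(x, ...) {
  a <- x$atoms
  cat("<protein_structure>", length(unique(a$res_key)), "residues,",
      nrow(a), "atoms\n")
  invisible(x)
}

# Split the atom table by residue, preserving order of first appearance.
residue_list <- function(protein) {
  a <- protein$atoms
  split(a, factor(a$res_key, levels = unique(a$res_key)))
}

# "E172"-style residue label used in fingerprint reports.
.aa3to1 <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
             GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
             LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
             SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V")

residue_label <- function(resid, resno) {
  one <- .aa3to1[resid]
  one[is.na(one)] <- "X"
  paste0(one, resno)
}
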