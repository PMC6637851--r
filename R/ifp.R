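# Protein-ligand interaction fingerprints and essential-interaction pose
# filtering.  Bits per residue: C contact, B backbone contact, S
# side-chain contact, P polar, H hydrophobic, A hydrogen bond with the
# residue as acceptor, D with the residue as donor, Ar aromatic
# (stacking or pi-cation), Ch electrostatic between charged groups.

# Side-chain chemotype tables by residue name / atom name.
.res_acceptors <- list(
  ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"), SER = "OG", THR = "OG1",
  TYR = "OH", ASN = "OD1", GLN = "OE1", HIS = c("ND1", "NE2"))
.res_donors <- list(
  SER = "OG", THR = "OG1", TYR = "OH", ASN = "ND2", GLN = "NE2",
  HIS = c("ND1", "NE2"), LYS = "NZ", ARG = c("NE", "NH1", "NH2"),
  TRP = "NE1")
.res_neg <- list(ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"))
.res_pos <- list(LYS = "NZ", ARG = c("NE", "NH1", "NH2"))
.res_rings <- list(
  PHE = list(c("CG", "CD1", "CD2", "CE1", "CE2", "CZ")),
  TYR = list(c("CG", "CD1", "CD2", "CE1", "CE2", "CZ")),
  HIS = list(c("CG", "ND1", "CD2", "CE1", "NE2")),
  TRP = list(c("CG", "CD1", "NE1", "CE2", "CD2"),
             c("CD2", "CE2", "CZ2", "CH2", "CZ3", "CE3")))

#' Interaction-fingerprint cutoff configuration
#'
#' All cutoffs in Angstrom; angle in degrees.  Defaults follow common
#' structural-bioinformatics conventions and every value can be
#' overridden.
#'
#' @param contact Heavy-atom contact cutoff (bit C; default 4.5).
#' @param polar N/O polar cutoff (bit P; default 4.0).
#' @param hbond Donor-acceptor heavy-atom cutoff (bits A/D; default 3.5).
#' @param hbond_angle Minimum donor angle in degrees when an explicit H
#'   is available (default 120).
#' @param aromatic Ring-centroid/ring-centroid cutoff (bit Ar; default 5.0).
#' @param pication Ring-centroid/cation cutoff (bit Ar; default 4.5).
#' @param charged Opposite-charge cutoff (bit Ch; default 4.5).
#' @param salt_bridge Cation/carboxylate-O cutoff for
#'   [detect_salt_bridge()] (default 4.5).
#' @param protonate_amines Treat neutral amine nitrogens as cationic
#'   (physiological protonation; default `FALSE`).
#' @return Named list of parameters.
#' @export
ifp_config <- function(contact = 4.5, polar = 4.0, hbond = 3.5,
                       hbond_angle = 120, aromatic = 5.0, pication = 4.5,
                       charged = 4.5, salt_bridge = 4.5,
                       protonate_amines = FALSE) {
  if (any(c(contact, polar, hbond, aromatic, pication, charged,
            salt_bridge) <= 0))
    stop("cutoffs must be positive")
  list(contact = contact, polar = polar, hbond = hbond,
       hbond_angle = hbond_angle, aromatic = aromatic, pication = pication,
       charged = charged, salt_bridge = salt_bridge,
       protonate_amines = protonate_amines)
}

#' A docked protein-ligand complex
#'
#' @param protein A [protein_structure()].
#' @param ligand A [molecule()] in the protein's frame.
#' @param score Docking score in kcal/mol (lower is better).
#' @return Object of class `complex_pose`.
#' @export
complex_pose <- function(protein, ligand, score = NA_real_) {
  stopifnot(inherits(protein, "protein_structure"),
            inherits(ligand, "molecule"))
  if (!is.na(score) && !is.finite(score)) stop("score must be finite")
  structure(list(protein = protein, ligand = ligand, score = score),
            class = "complex_pose")
}

# Cationic ligand atoms: formal charge > 0, optionally auto-protonated
# neutral amine N (N with only single bonds and < 4 heavy neighbours).
ligand_cations <- function(ligand, protonate_amines = FALSE) {
  pos <- which(ligand$atoms$formal_charge > 0)
  if (protonate_amines) {
    A <- bond_matrix(ligand)
    for (i in which(ligand$atoms$element == "N" &
                    ligand$atoms$formal_charge == 0)) {
      ords <- A[i, A[i, ] > 0]
      heavy_nb <- sum(A[i, ] > 0 & ligand$atoms$element != "H")
      if (all(ords == 1L) && heavy_nb < 4L) pos <- c(pos, i)
    }
  }
  sort(unique(pos))
}

#' Detect a ligand-carboxylate salt bridge
#'
#' `TRUE` when any cationic ligand nitrogen lies within `cutoff` of any
#' side-chain carboxylate oxygen of the named residue.  This is the
#' essential interaction a valid pose of an aminergic ligand must keep
#' with the anionic anchor residue of the site.
#'
#' @param complex A [complex_pose()].
#' @param resno Residue sequence number of the anionic residue.
#' @param chain Optional chain identifier.
#' @param cutoff Distance cutoff in Angstrom (default 4.5).
#' @param config An [ifp_config()] (for `protonate_amines`).
#' @return Logical.
#' @export
detect_salt_bridge <- function(complex, resno, chain = NULL, cutoff = 4.5,
                               config = ifp_config()) {
  stopifnot(inherits(complex, "complex_pose"))
  a <- complex$protein$atoms
  sel <- a$resno == resno
  if (!is.null(chain)) sel <- sel & a$chain == chain
  if (!any(sel)) stop("residue ", resno, " not found in structure")
  res <- a[sel, , drop = FALSE]
  carbox <- res[res$resid %in% names(.res_neg) &
                  res$atom_name %in% unlist(.res_neg), , drop = FALSE]
  if (nrow(carbox) == 0L)
    stop("residue ", resno, " has no side-chain carboxylate oxygens")
  cat_idx <- ligand_cations(complex$ligand, config$protonate_amines)
  cat_idx <- cat_idx[complex$ligand$atoms$element[cat_idx] == "N"]
  if (length(cat_idx) == 0L) {
    warning("ligand '", complex$ligand$id, "' has no cationic nitrogen")
    return(FALSE)
  }
  lig <- coords(complex$ligand)[cat_idx, , drop = FALSE]
  pro <- as.matrix(carbox[, c("x", "y", "z")])
  min(.cross_dist(lig, pro)) <= cutoff
}

# all pairwise distances between rows of two coordinate matrices
.cross_dist <- function(a, b) {
  a2 <- rowSums(a^2); b2 <- rowSums(b^2)
  d2 <- outer(a2, b2, "+") - 2 * tcrossprod(a, b)
  sqrt(pmax(d2, 0))
}

#' Select the best compliant pose
#'
#' Returns the lowest-score pose among those satisfying all essential
#' interaction predicates; when none complies, the overall lowest-score
#' pose is returned with attribute `compliant = FALSE` so non-compliant
#' compounds are retained and flagged rather than dropped.
#'
#' @param poses Non-empty list of [complex_pose()] objects.
#' @param essential List of predicate functions `function(pose) logical`.
#' @return A `complex_pose` with a logical attribute `compliant`.
#' @export
select_pose <- function(poses, essential = list()) {
  if (inherits(poses, "complex_pose")) poses <- list(poses)
  if (length(poses) == 0L) stop("no poses supplied")
  scores <- vapply(poses, function(p) p$score, numeric(1))
  ok <- vapply(poses, function(p) {
    all(vapply(essential, function(f) isTRUE(f(p)), logical(1)))
  }, logical(1))
  pool <- if (any(ok)) which(ok) else seq_along(poses)
  # ties on score resolved by input order for determinism under
  # permutation the pool minimum is unique almost surely; exact ties
  # pick the smallest score then first occurrence
  best <- pool[which.min(scores[pool])]
  out <- poses[[best]]
  attr(out, "compliant") <- any(ok)
  out
}

# centroids of aromatic rings, n x 3 (possibly 0-row)
.ring_centroids <- function(xyz, rings) {
  if (!length(rings)) return(matrix(numeric(0), 0, 3))
  do.call(rbind, lapply(rings, function(r) colMeans(xyz[r, , drop = FALSE])))
}

#' Compute the per-residue interaction fingerprint of one complex
#'
#' Evaluates the geometric definitions of all nine bits for every
#' residue with at least one set bit (the interacting set).  Implied
#' bits are closed explicitly: A or D set P; any chemotyped bit sets C.
#'
#' @param complex A [complex_pose()].
#' @param config An [ifp_config()].
#' @return `data.frame` with columns `residue` (label such as `E172`),
#'   `resno`, `chain`, and logical columns
#'   `C`, `B`, `S`, `P`, `H`, `A`, `D`, `Ar`, `Ch`.
#' @export
compute_ifp <- function(complex, config = ifp_config()) {
  stopifnot(inherits(complex, "complex_pose"))
  lig <- complex$ligand
  lh <- heavy_idx(lig)
  lxyz <- coords(lig)
  lel <- lig$atoms$element
  A_lig <- bond_matrix(lig)
  lig_rings <- aromatic_rings(lig)
  lig_ring_cent <- .ring_centroids(lxyz, lig_rings)
  cations <- ligand_cations(lig, config$protonate_amines)
  anions <- which(lig$atoms$formal_charge < 0)
  lig_polar <- lh[lel[lh] %in% c("N", "O")]
  # ligand donors: N/O bearing an explicit H or a positive formal charge
  lig_donor <- lig_polar[vapply(lig_polar, function(i) {
    any(A_lig[i, ] > 0 & lel == "H") || lig$atoms$formal_charge[i] > 0
  }, logical(1))]
  # ligand acceptors: N/O, excluding positively charged centres
  lig_acc <- lig_polar[lig$atoms$formal_charge[lig_polar] <= 0]

  bits <- c("C", "B", "S", "P", "H", "A", "D", "Ar", "Ch")
  rows <- list()
  for (res in residue_list(complex$protein)) {
    rxyz <- as.matrix(res[, c("x", "y", "z")])
    rel <- res$element
    rname <- res$resid[1]
    heavy <- rel != "H"
    D <- .cross_dist(rxyz, lxyz)          # residue atoms x ligand atoms
    b <- stats::setNames(rep(FALSE, length(bits)), bits)
    contact_at <- heavy & apply(D[, lh, drop = FALSE] <= config$contact, 1, any)
    b["C"] <- any(contact_at)
    b["B"] <- any(contact_at & res$backbone)
    b["S"] <- any(contact_at & !res$backbone)
    hyd_res <- which(rel %in% c("C", "S"))
    hyd_lig <- which(lel %in% c("C", "S"))
    if (length(hyd_res) && length(hyd_lig))
      b["H"] <- any(D[hyd_res, hyd_lig, drop = FALSE] <= config$contact)
    pol_res <- which(rel %in% c("N", "O"))
    pol_lig <- unique(c(lig_polar, cations, anions))
    if (length(pol_res) && length(pol_lig))
      b["P"] <- any(D[pol_res, pol_lig, drop = FALSE] <= config$polar)
    # A: residue acceptor vs ligand donor (donor angle via explicit H)
    acc_names <- c(.res_acceptors[[rname]], "O",
                   if ("OXT" %in% res$atom_name) "OXT")
    acc_idx <- which(res$atom_name %in% acc_names)
    if (length(acc_idx) && length(lig_donor)) {
      for (d_at in lig_donor) {
        for (a_at in acc_idx) {
          if (D[a_at, d_at] > config$hbond) next
          hs <- which(A_lig[d_at, ] > 0 & lel == "H")
          if (length(hs)) {
            # D-H...A angle at the hydrogen; a hydrogen pointing at the
            # acceptor gives an angle near 180 degrees
            ang <- vapply(hs, function(h) {
              v1 <- lxyz[d_at, ] - lxyz[h, ]
              v2 <- rxyz[a_at, ] - lxyz[h, ]
              acos(pmin(pmax(sum(v1 * v2) /
                (sqrt(sum(v1^2)) * sqrt(sum(v2^2))), -1), 1)) * 180 / pi
            }, numeric(1))
            if (any(ang >= config$hbond_angle)) b["A"] <- TRUE
          } else {
            b["A"] <- TRUE   # no explicit H: distance criterion only
          }
        }
        if (b[["A"]]) break
      }
    }
    # D: residue donor vs ligand acceptor (protein H rarely present:
    # distance criterion)
    don_names <- c(.res_donors[[rname]],
                   if (any(res$atom_name == "N")) "N")
    don_idx <- which(res$atom_name %in% don_names)
    if (length(don_idx) && length(lig_acc))
      b["D"] <- any(D[don_idx, lig_acc, drop = FALSE] <= config$hbond)
    # Ar: ring stacking or pi-cation
    rrings <- .res_rings[[rname]]
    if (!is.null(rrings)) {
      ok_rings <- vapply(rrings, function(rr) all(rr %in% res$atom_name),
                         logical(1))
      rcent <- .ring_centroids(rxyz, lapply(rrings[ok_rings], function(rr)
        match(rr, res$atom_name)))
      if (nrow(rcent)) {
        if (nrow(lig_ring_cent) &&
            min(.cross_dist(rcent, lig_ring_cent)) <= config$aromatic)
          b["Ar"] <- TRUE
        if (length(cations) &&
            min(.cross_dist(rcent, lxyz[cations, , drop = FALSE])) <=
            config$pication)
          b["Ar"] <- TRUE
      }
    }
    # Ch: oppositely charged groups
    neg_res <- which(res$atom_name %in% .res_neg[[rname]])
    pos_res <- which(res$atom_name %in% .res_pos[[rname]])
    ch <- FALSE
    if (length(neg_res) && length(cations))
      ch <- ch || min(D[neg_res, cations]) <= config$charged
    if (length(pos_res) && length(anions))
      ch <- ch || min(D[pos_res, anions]) <= config$charged
    b["Ch"] <- ch
    # implication closure
    if (b[["A"]] || b[["D"]]) b["P"] <- TRUE
    if (any(b[c("B", "S", "P", "H", "A", "D", "Ar", "Ch")])) b["C"] <- TRUE
    if (any(b)) {
      rows[[length(rows) + 1L]] <- data.frame(
        residue = residue_label(rname, res$resno[1]),
        resno = res$resno[1], chain = res$chain[1],
        as.list(b))
    }
  }
  if (!length(rows))
    return(data.frame(residue = character(), resno = integer(),
                      chain = character(),
                      C = logical(), B = logical(), S = logical(),
                      P = logical(), H = logical(), A = logical(),
                      D = logical(), Ar = logical(), Ch = logical()))
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Occurrence profile over a set of complexes
#'
#' Percentage of complexes in which each bit is set, per residue,
#' computed over the same complex set for all residues.  Residues whose
#' bits are never set are omitted.
#'
#' @param ifps List of fingerprints from [compute_ifp()], one per
#'   complex.
#' @return `data.frame` with `residue` and one percentage column per bit.
#' @export
occurrence_profile <- function(ifps) {
  if (inherits(ifps, "data.frame")) ifps <- list(ifps)
  if (length(ifps) == 0L) stop("no fingerprints supplied")
  n <- length(ifps)
  bits <- c("C", "B", "S", "P", "H", "A", "D", "Ar", "Ch")
  resids <- unique(unlist(lapply(ifps, function(f) f$residue)))
  out <- data.frame(residue = resids)
  for (bt in bits) {
    out[[bt]] <- vapply(resids, function(r) {
      100 * sum(vapply(ifps, function(f) {
        i <- match(r, f$residue)
        !is.na(i) && isTRUE(f[[bt]][i])
      }, logical(1))) / n
    }, numeric(1))
  }
  out[rowSums(out[bits]) > 0, , drop = FALSE]
}
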