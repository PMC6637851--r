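# Synthetic congeneric series with planted field effects.
#
# The generator emulates the data the pipeline expects from a docking
# study of an arylalkylamine series: a rigid shared scaffold (phenyl
# ring, branched alkyl chain, protonated amine) "posed" in one frame,
# substituents of graded bulk at a para site (H to n-butyl), a meta
# substituent drawn from {H, OH, OMe, F, NH2}, and activities built
# from the planted rule
# activity = base + w_steric * (heavy atoms in the steric effect region)
#          + w_elec * (negative partial charge at the meta heteroatom)
#          + N(0, noise_sd).
# Substituent geometry is template-based (idealised bond lengths), not
# minimised: fields need a plausible, reproducible 3D occupancy only.

.scaffold_atoms <- function() {
  th <- (0:5) * pi / 3
  ring <- data.frame(element = "C", x = 1.396 * cos(th),
                     y = 1.396 * sin(th), z = 0,
                     formal_charge = 0L, partial_charge = NA_real_)
  chain <- data.frame(
    element = c("C", "C", "C", "C", "N", "C", "C", "H"),
    x = c(2.90, 3.40, 3.70, 5.20, 5.90, 7.40, 5.50, 5.35),
    y = c(0.00, 1.35, -1.20, -1.20, 0.05, 0.05, 1.20, -0.45),
    z = c(0.00, 0.50, 0.00, 0.30, 0.60, 0.60, 1.50, 1.45),
    formal_charge = c(0L, 0L, 0L, 0L, 1L, 0L, 0L, 0L),
    partial_charge = NA_real_)
  rbind(ring, chain)
}

.scaffold_bonds <- function() {
  ring <- data.frame(i = 1:6, j = c(2:6, 1), order = c(2, 1, 2, 1, 2, 1))
  # ring C1 - C7(H)(C8 methyl) - C9 - C10 - N11(+) - C12, C13 methyls,
  # H14 on the charged nitrogen
  chain <- data.frame(i = c(1, 7, 7, 9, 10, 11, 11, 11),
                      j = c(7, 8, 9, 10, 11, 12, 13, 14),
                      order = 1)
  rbind(ring, chain)
}

# para substituent: alkyl chain of n carbons growing along -x
.para_substituent <- function(n) {
  if (n == 0L) return(NULL)
  data.frame(element = "C",
             x = -2.80 - 1.30 * (seq_len(n) - 1L),
             y = 0.45 * rep_len(c(1, -1), n) * (seq_len(n) > 1),
             z = 0.25 * rep_len(c(0, 1), n),
             formal_charge = 0L, partial_charge = NA_real_)
}

# meta substituent templates (attached at ring atom 3, growing along
# the 120-degree ring direction); option 0 is unsubstituted
.meta_substituent <- function(option) {
  dir <- c(cos(2 * pi / 3), sin(2 * pi / 3), 0)
  at <- function(el, d, z = 0) data.frame(
    element = el, x = (1.396 + d) * dir[1], y = (1.396 + d) * dir[2],
    z = z, formal_charge = 0L, partial_charge = NA_real_)
  switch(as.character(option),
    "0" = NULL,
    "1" = list(atoms = rbind(at("O", 1.36), at("H", 2.05, 0.30)),
               bonds = cbind(prev = c(0L, 1L), ord = 1L)),        # OH
    "2" = list(atoms = rbind(at("O", 1.36), at("C", 2.70, 0.40)),
               bonds = cbind(prev = c(0L, 1L), ord = 1L)),        # OMe
    "3" = list(atoms = at("F", 1.35),
               bonds = cbind(prev = 0L, ord = 1L)),               # F
    "4" = list(atoms = rbind(at("N", 1.40), at("H", 2.00, 0.45),
                             at("H", 2.00, -0.45)),
               bonds = cbind(prev = c(0L, 1L, 1L), ord = 1L)))    # NH2
}

#' Specification of a synthetic congeneric series
#'
#' @param n_compounds Series size (>= 5; default 40).
#' @param noise_sd Gaussian noise SD on the pKi scale (default 0.2).
#' @param steric_weight Activity gain per heavy atom occupying the
#'   steric effect region (default 0.4).
#' @param elec_weight Activity gain per elementary charge of negative
#'   partial charge on the meta heteroatom (default 4; the meta groups
#'   carry 0 to about -0.17 e, so the planted electrostatic spread is
#'   about 0.7 pKi units).
#' @param base_pki Baseline activity (default 6).
#' @param seed Integer seed fixing all randomness (default 1).
#' @return Object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_compounds = 40L, noise_sd = 0.2,
                           steric_weight = 0.4, elec_weight = 4,
                           base_pki = 6, seed = 1L) {
  if (n_compounds < 5L) stop("n_compounds must be at least 5")
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  stopifnot(is.finite(steric_weight), is.finite(elec_weight))
  structure(list(n_compounds = as.integer(n_compounds),
                 noise_sd = noise_sd,
                 steric_weight = steric_weight, elec_weight = elec_weight,
                 base_pki = base_pki, seed = as.integer(seed),
                 steric_region = list(center = c(-4.2, 0, 0),
                                      radius = 2.2),
                 elec_region = list(center = c(-1.4, 2.4, 0),
                                    radius = 2.0)),
            class = "synthetic_spec")
}

#' Generate a synthetic congeneric series with known activities
#'
#' Builds `n_compounds` analogs on the fixed scaffold frame: a para
#' alkyl substituent of 0-4 carbons (the steric series) and a meta
#' substituent from {H, OH, OMe, F, NH2} (the polar series), assigns
#' bond-charge-increment partial charges, and computes activities from
#' the planted effect map plus Gaussian noise.  The same seed yields identical molecules and
#' activities.  Compounds whose substituent atoms would clash with the
#' scaffold (non-bonded heavy-atom pair < 1.0 A) are rejected with a
#' reason.
#'
#' @param spec A [synthetic_spec()].
#' @return List with `molecules` (list of [molecule()]), `activities`
#'   (an [activity_table()]), `truth` (planted effects and per-compound
#'   steric occupancy / polar indicator) and `rejected`.
#' @export
generate_series <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  n <- spec$n_compounds
  draws <- with_seed(spec$seed, {
    list(steric = sample(0:4, n, replace = TRUE),
         meta = sample(0:4, n, replace = TRUE),
         noise = stats::rnorm(n, 0, spec$noise_sd))
  })
  base_a <- .scaffold_atoms(); base_b <- .scaffold_bonds()
  mols <- vector("list", n)
  occ <- integer(n)
  polarity <- numeric(n)
  rejected <- character(0)
  for (i in seq_len(n)) {
    atoms <- base_a; bonds <- base_b
    sub <- .para_substituent(draws$steric[i])
    if (!is.null(sub)) {
      first <- nrow(atoms) + 1L
      atoms <- rbind(atoms, sub)
      prev <- c(4L, first + seq_len(nrow(sub) - 1L) - 1L)
      bonds <- rbind(bonds, data.frame(i = prev,
                                       j = first + seq_len(nrow(sub)) - 1L,
                                       order = 1))
    }
    meta_idx <- NA_integer_
    msub <- .meta_substituent(draws$meta[i])
    if (!is.null(msub)) {
      first <- nrow(atoms) + 1L
      meta_idx <- first
      atoms <- rbind(atoms, msub$atoms)
      prev <- ifelse(msub$bonds[, "prev"] == 0L, 3L,
                     first + msub$bonds[, "prev"] - 1L)
      bonds <- rbind(bonds, data.frame(
        i = prev, j = first + seq_len(nrow(msub$atoms)) - 1L,
        order = msub$bonds[, "ord"]))
    }
    mol <- molecule(sprintf("syn_%03d", i), atoms, bonds)
    # clash screen on non-bonded heavy atoms
    h <- heavy_idx(mol)
    D <- .cross_dist(coords(mol)[h, , drop = FALSE],
                     coords(mol)[h, , drop = FALSE])
    B <- bond_matrix(mol)[h, h] > 0
    diag(D) <- Inf; D[B] <- Inf
    if (min(D) < 1.0) {
      rejected <- c(rejected, sprintf(
        "%s: substituent clash (%.2f A non-bonded contact)", mol$id, min(D)))
      mols[i] <- list(NULL)
      next
    }
    mol <- assign_partial_charges(mol)
    mols[[i]] <- mol
    # steric occupancy of the planted region
    d <- .cross_dist(coords(mol)[h, , drop = FALSE],
                     rbind(spec$steric_region$center))
    occ[i] <- sum(d <= spec$steric_region$radius)
    # negative charge planted at the meta heteroatom
    if (!is.na(meta_idx))
      polarity[i] <- max(0, -mol$atoms$partial_charge[meta_idx])
  }
  keep <- !vapply(mols, is.null, logical(1))
  mols <- mols[keep]
  activity <- spec$base_pki + spec$steric_weight * occ[keep] +
    spec$elec_weight * polarity[keep] + draws$noise[keep]
  tab <- activity_table(id = vapply(mols, function(m) m$id, ""),
                        pki = activity)
  list(molecules = stats::setNames(mols, tab$id),
       activities = tab,
       truth = list(steric_region = spec$steric_region,
                    elec_region = spec$elec_region,
                    steric_weight = spec$steric_weight,
                    elec_weight = spec$elec_weight,
                    steric_occupancy = occ[keep],
                    meta_option = draws$meta[keep],
                    meta_polarity = polarity[keep],
                    noise_sd = spec$noise_sd),
       rejected = rejected)
}

# hand-placed residue templates for the toy pocket (coordinates chosen
# relative to the scaffold frame of .scaffold_atoms())
.pocket_residue <- function(resid, resno, atoms) {
  data.frame(chain = "A", resno = resno, insert = "", resid = resid,
             atom_name = atoms$name, element = substr(atoms$name, 1, 1),
             x = atoms$x, y = atoms$y, z = atoms$z)
}

#' Generate a toy binding pocket for a synthetic series
#'
#' Places a glutamate whose side-chain carboxylate faces the series'
#' protonated amine (3-4 A away, the anionic anchor every pose must
#' reach), a phenylalanine ring stacked over the scaffold phenyl, and
#' hydrophobic leucines lining the para substituent site.  The result
#' is a valid structure for the fingerprint and pose-filter machinery.
#'
#' @param include_glu,include_phe,include_leu Toggle individual
#'   residues (defaults all `TRUE`).
#' @return A [protein_structure()].
#' @export
generate_pocket <- function(include_glu = TRUE, include_phe = TRUE,
                            include_leu = TRUE) {
  res <- list()
  if (include_glu) {
    # carboxylate oxygens ~3.2 A above the amine nitrogen (5.9, 0.05, 0.6)
    res$glu <- .pocket_residue("GLU", 172L, data.frame(
      name = c("N", "CA", "C", "O", "CB", "CG", "CD", "OE1", "OE2"),
      x = c(7.6, 7.0, 7.8, 8.9, 6.3, 6.3, 5.9, 5.9, 5.7),
      y = c(1.8, 0.9, -0.1, -0.3, 0.3, 0.2, 0.1, -1.0, 1.1),
      z = c(7.4, 6.6, 6.0, 6.3, 5.5, 4.0, 3.6, 3.4, 3.5)))
  }
  if (include_phe) {
    # ring centroid ~3.6 A above the scaffold phenyl centroid (origin)
    th <- (0:5) * pi / 3
    ring <- data.frame(
      name = c("CG", "CD1", "CE1", "CZ", "CE2", "CD2"),
      x = 1.39 * cos(th), y = 1.39 * sin(th), z = 3.6)
    res$phe <- .pocket_residue("PHE", 107L, rbind(
      data.frame(name = c("N", "CA", "C", "O", "CB"),
                 x = c(0.6, 0.2, 1.2, 2.2, -0.4),
                 y = c(3.2, 2.4, 1.8, 2.1, 1.3),
                 z = c(7.8, 6.8, 5.9, 6.0, 5.9)),
      ring))
  }
  if (include_leu) {
    res$leu1 <- .pocket_residue("LEU", 95L, data.frame(
      name = c("N", "CA", "C", "O", "CB", "CG", "CD1", "CD2"),
      x = c(-6.6, -6.0, -6.8, -7.9, -5.2, -4.6, -4.2, -5.2),
      y = c(2.8, 1.9, 1.0, 1.2, 1.1, 0.4, -0.9, 1.0),
      z = c(6.9, 6.1, 5.4, 5.6, 5.0, 3.8, 3.9, 2.6)))
    res$leu2 <- .pocket_residue("LEU", 105L, data.frame(
      name = c("N", "CA", "C", "O", "CB", "CG", "CD1", "CD2"),
      x = c(-2.8, -2.4, -3.2, -4.3, -1.6, -1.9, -2.4, -0.7),
      y = c(-3.4, -2.6, -1.9, -2.1, -1.7, -1.2, -0.1, -2.2),
      z = c(-6.9, -6.0, -5.2, -5.4, -5.0, -3.6, -3.4, -2.8)))
  }
  if (!length(res)) stop("pocket needs at least one residue")
  protein_structure(do.call(rbind, c(res, list(make.row.names = FALSE))))
}

#' Run the full field-QSAR recovery experiment on synthetic data
#'
#' Generates a series, splits it (stratified), computes steric and
#' electrostatic fields, pretreats, applies BUW (and optionally SRD),
#' fits the requested model, and reports whether the planted effect is
#' recovered: leave-one-out `Q2`, external `Rtest2`, and whether the
#' largest-|coefficient| steric grid node lies in (or within one grid
#' step of) the planted steric region with a positive sign.
#'
#' @param spec A [synthetic_spec()].
#' @param ncomp Components for the fitted model (default 3).
#' @param fields Field blocks for the final model (default both).
#' @param test_fraction External test fraction (default 0.2).
#' @param srd Apply Smart Region Definition (default `FALSE`).
#' @param spacing,padding Grid parameters.
#' @return List with `q2`, `s_loo`, `r2`, `rtest2`, `s_test`,
#'   `top_node_in_region`, `top_sign_positive`, `model`, `series`.
#' @export
recovery_experiment <- function(spec, ncomp = 3L,
                                fields = c("steric", "electrostatic"),
                                test_fraction = 0.2, srd = FALSE,
                                spacing = 1.0, padding = 5.0) {
  stopifnot(inherits(spec, "synthetic_spec"))
  ser <- generate_series(spec)
  tab <- ser$activities
  n_test <- max(2L, round(test_fraction * nrow(tab)))
  tab <- split_dataset(tab, n_test, seed = spec$seed + 1L)
  fm <- compute_fields(ser$molecules, spacing = spacing, padding = padding)
  tr <- which(tab$split == "train"); te <- which(tab$split == "test")
  model <- comfa_pls(fm, tab$pKi[tr], ncomp = ncomp, fields = fields,
                     rows = tr, srd = srd)
  cv <- loo_q2(model)
  pred_te <- predict(model, fm, rows = te)
  ext <- external_stats(tab$pKi[te], pred_te)
  # planted-region recovery on the steric coefficient map
  maps <- export_contours(model, tempfile("contours"))
  st <- maps[["steric"]]$values
  top <- which.max(abs(st))
  node_xyz <- grid_coords(fm$grid)[top, ]
  d <- sqrt(sum((node_xyz - spec$steric_region$center)^2))
  list(q2 = cv$q2, s_loo = cv$s_loo, r2 = model$r2,
       rtest2 = ext[["rtest2"]], s_test = ext[["s_test"]],
       top_node_in_region =
         d <= spec$steric_region$radius + spacing,
       top_sign_positive = st[top] > 0,
       model = model, series = ser, split = tab)
}
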