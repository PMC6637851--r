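# helpers: a minimal glutamate whose carboxylate sits at a controlled
# distance from the origin, and cationic/neutral probe ligands
glu_at <- function(d, resno = 172L) {
  protein_structure(data.frame(
    chain = "A", resno = resno, insert = "", resid = "GLU",
    atom_name = c("N", "CA", "C", "O", "CB", "CG", "CD", "OE1", "OE2"),
    element = c("N", "C", "C", "O", "C", "C", "C", "O", "O"),
    x = c(3, 3, 4, 5, 2, 1, 0.5, 0, 0.8),
    y = c(5, 4, 3.5, 3.8, 3.2, 3.0, 2.0, 0, 0) + c(rep(0, 7), 0, 1),
    z = c(rep(6, 7), d, d)))
}

cation_at_origin <- function(charged = TRUE) {
  m <- molecule("amine",
                data.frame(element = c("N", "C", "H"),
                           x = c(0, 1.5, -0.3), y = c(0, 0, 0.2),
                           z = c(0, 0, 0.9),   # N-H points toward +z
                           formal_charge = c(if (charged) 1L else 0L, 0L, 0L)),
                data.frame(i = c(1, 1), j = c(2, 3), order = 1))
  assign_partial_charges(m, overwrite = TRUE)
}

test_that("salt-bridge detection follows the distance rule", {
  lig <- cation_at_origin()
  expect_true(detect_salt_bridge(complex_pose(glu_at(3.0), lig), 172))
  expect_false(detect_salt_bridge(complex_pose(glu_at(6.0), lig), 172))
  expect_error(detect_salt_bridge(complex_pose(glu_at(3), lig), 999),
               "not found")
  expect_warning(
    ok <- detect_salt_bridge(complex_pose(glu_at(3), cation_at_origin(FALSE)),
                             172),
    "cationic")
  expect_false(ok)
  # monotone in cutoff: true at c implies true at any larger cutoff
  cplx <- complex_pose(glu_at(4.4), lig)
  expect_true(detect_salt_bridge(cplx, 172, cutoff = 4.5))
  expect_true(detect_salt_bridge(cplx, 172, cutoff = 6.0))
  expect_false(detect_salt_bridge(cplx, 172, cutoff = 4.0))
})

test_that("pose selection prefers compliant poses, then score", {
  lig_far <- cation_at_origin()
  prot_near <- glu_at(3.0)
  prot_far <- glu_at(8.0)
  bridge <- function(p) detect_salt_bridge(p, 172)
  p1 <- complex_pose(prot_far, lig_far, score = -9.0)   # better score, no bridge
  p2 <- complex_pose(prot_near, lig_far, score = -8.5)  # bridge
  sel <- select_pose(list(p1, p2), list(bridge))
  expect_equal(sel$score, -8.5)
  expect_true(attr(sel, "compliant"))
  # order invariance
  sel2 <- select_pose(list(p2, p1), list(bridge))
  expect_equal(sel2$score, sel$score)
  # all compliant -> global best
  p3 <- complex_pose(glu_at(2.8), lig_far, score = -9.5)
  expect_equal(select_pose(list(p2, p3), list(bridge))$score, -9.5)
  # none compliant -> best score, flagged
  sel3 <- select_pose(list(p1), list(bridge))
  expect_false(attr(sel3, "compliant"))
  expect_equal(sel3$score, -9.0)
  expect_error(select_pose(list()), "no poses")
})

test_that("fingerprint bits fire on constructed geometries", {
  # carboxylate O ~3 A from an ammonium N with the H pointing at it
  lig <- cation_at_origin()
  f <- compute_ifp(complex_pose(glu_at(3.0), lig))
  e172 <- f[f$residue == "E172", ]
  expect_equal(nrow(e172), 1)
  expect_true(all(unlist(e172[c("C", "S", "P", "Ch", "A")])))
  # far ligand: no bits at all
  lig_far <- cation_at_origin()
  lig_far$atoms$x <- lig_far$atoms$x + 50
  expect_equal(nrow(compute_ifp(complex_pose(glu_at(3), lig_far))), 0)
  # stacked phenylalanine ring fires the aromatic bit
  pocket <- generate_pocket(include_glu = FALSE, include_leu = FALSE)
  bz <- assign_partial_charges(make_benzene())
  f2 <- compute_ifp(complex_pose(pocket, bz))
  expect_true(f2$Ar[f2$residue == "F107"])
})

test_that("bit implications hold on fuzzed geometries", {
  pocket <- generate_pocket()
  set.seed(31)
  for (k in 1:20) {
    lig <- rand_mol(6, seed = 400 + k)
    lig$atoms$x <- lig$atoms$x * 1.5
    lig$atoms$formal_charge[1] <- sample(c(-1L, 0L, 1L), 1)
    lig <- assign_partial_charges(lig, overwrite = TRUE)
    f <- compute_ifp(complex_pose(pocket, lig))
    if (!nrow(f)) next
    for (r in seq_len(nrow(f))) {
      any_chem <- any(unlist(f[r, c("P", "H", "A", "D", "Ar", "Ch")]))
      expect_true(!any_chem || f$C[r])
      expect_true(!(f$B[r] || f$S[r]) || f$C[r])
      expect_true(!(f$A[r] || f$D[r]) || f$P[r])
    }
  }
})

test_that("occurrence profiles are percentages over the complex set", {
  lig <- cation_at_origin()
  near <- compute_ifp(complex_pose(glu_at(3.0), lig))
  far <- compute_ifp(complex_pose(glu_at(6.0), lig))
  prof <- occurrence_profile(c(replicate(8, near, simplify = FALSE),
                               replicate(2, far, simplify = FALSE)))
  expect_equal(prof$Ch[prof$residue == "E172"], 80)
  prof1 <- occurrence_profile(list(near))
  expect_equal(prof1$Ch[prof1$residue == "E172"], 100)
  expect_error(occurrence_profile(list()), "no fingerprints")
})

test_that("a pocket facing every cation keeps full charged occurrence", {
  # every synthetic ligand holds its charged N at the same frame position
  ser <- generate_series(synthetic_spec(n_compounds = 8, seed = 5))
  pocket <- generate_pocket()
  ifps <- lapply(ser$molecules, function(m)
    compute_ifp(complex_pose(pocket, m)))
  prof <- occurrence_profile(ifps)
  expect_equal(prof$Ch[prof$residue == "E172"], 100)
  expect_equal(prof$Ar[prof$residue == "F107"], 100)
  # salt bridge true for every compound by construction
  ok <- vapply(ser$molecules, function(m)
    detect_salt_bridge(complex_pose(pocket, m), 172), logical(1))
  expect_true(all(ok))
  # no glutamate, no charged interactions anywhere
  pocket2 <- generate_pocket(include_glu = FALSE)
  prof2 <- occurrence_profile(lapply(ser$molecules, function(m)
    compute_ifp(complex_pose(pocket2, m))))
  expect_true(all(prof2$Ch == 0))
})
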