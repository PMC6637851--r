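test_that("grid construction follows the box arithmetic", {
  one <- molecule("pt", data.frame(element = "C", x = 0, y = 0, z = 0))
  g <- build_grid(one, spacing = 1, padding = 5)
  expect_equal(g$dims, c(11L, 11L, 11L))
  g2 <- build_grid(one, spacing = 2, padding = 5)
  expect_equal(g2$dims, c(6L, 6L, 6L))
  g0 <- build_grid(one, spacing = 1, padding = 0)
  expect_equal(g0$dims, c(1L, 1L, 1L))
  expect_error(build_grid(list()), "no molecules")
  # every atom lies inside the box
  mols <- lapply(1:3, function(i) rand_mol(6, seed = i))
  g3 <- build_grid(mols, spacing = 1, padding = 2)
  xyz <- do.call(rbind, lapply(mols, fieldsar:::coords))
  hi <- g3$origin + (g3$dims - 1) * g3$spacing
  expect_true(all(t(xyz) >= g3$origin - 1e-9))
  expect_true(all(t(xyz) <= hi + 1e-9))
})

test_that("steric energies decay and reach minus epsilon at the minimum", {
  methane <- molecule("methane", data.frame(element = "C", x = 0, y = 0,
                                            z = 0))
  far <- steric_energy(matrix(c(20, 0, 0), 1), methane)
  expect_lt(abs(far), 0.01)
  # closed-form pair minimum: r = Rmin(C) + Rmin(probe), E = -eps
  rmin <- 2 * 1.96; eps <- 0.107
  at_min <- steric_energy(matrix(c(rmin, 0, 0), 1), methane)
  expect_equal(at_min, -eps, tolerance = 1e-12)
  # node at an atom centre is huge and positive (capped downstream)
  expect_gt(steric_energy(matrix(0, 1, 3), methane), 30)
  expect_error(steric_energy(matrix(0, 1, 3),
                             molecule("x", data.frame(element = "Xe",
                                                      x = 0, y = 0, z = 0))),
               "Xe")
})

test_that("electrostatic energies follow Coulomb with dielectric r", {
  m <- molecule("q", data.frame(element = "C", x = 0, y = 0, z = 0))
  m$atoms$partial_charge <- 0.5
  e <- electrostatic_energy(matrix(c(4, 0, 0), 1), m)
  expect_equal(e, 332.0637 * 0.5 / 16, tolerance = 1e-12)
  # neutral molecule gives zero everywhere
  m0 <- m; m0$atoms$partial_charge <- 0
  expect_equal(electrostatic_energy(matrix(c(4, 0, 0), 1), m0), 0)
  # odd in the charge
  mneg <- m; mneg$atoms$partial_charge <- -0.5
  expect_equal(electrostatic_energy(matrix(c(4, 0, 0), 1), mneg), -e)
  # constant dielectric option
  e2 <- electrostatic_energy(matrix(c(4, 0, 0), 1), m, dielectric = 4)
  expect_equal(e2, 332.0637 * 0.5 / 16, tolerance = 1e-12)
  expect_warning(electrostatic_energy(matrix(0, 1, 3), m), "coincident")
})

test_that("field matrices are equivariant under rigid motion", {
  mols <- lapply(1:4, function(i) {
    m <- generate_series(synthetic_spec(n_compounds = 5, seed = i))$molecules[[1]]
    m$id <- paste0("m", i)
    m
  })
  g <- build_grid(mols, spacing = 2, padding = 3)
  fm <- compute_fields(mols, grid = g)
  th <- 0.35
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  t <- c(3, -2, 1)
  mols2 <- lapply(mols, transform_molecule, R = R, t = t)
  g2 <- g
  # transform the grid nodes by evaluating at transformed node coords:
  # equivalently compare energies node-by-node
  nodes <- grid_coords(g)
  nodes2 <- sweep(nodes %*% t(R), 2, t, "+")
  for (k in c(1, 3)) {
    e1 <- steric_energy(nodes, mols[[k]])
    e2 <- steric_energy(nodes2, mols2[[k]])
    expect_equal(e1, e2, tolerance = 1e-6)
    q1 <- electrostatic_energy(nodes, mols[[k]])
    q2 <- electrostatic_energy(nodes2, mols2[[k]])
    expect_equal(q1, q2, tolerance = 1e-6)
  }
})

test_that("pretreatment caps, zeroes and kills n-level variables", {
  # synthetic 6x5 matrix exercising every rule
  X <- rbind(c(50, 0.04, 1, 0.2, 5),
             c(40, -0.04, 2, 0.2, 5),
             c(35, 0.01, 3, 0.2, 5),
             c(31, 0.02, 4, 0.2, 5),
             c(90, -0.01, 5, 0.2, 5),
             c(70, 0.03, 6, 0.2, 5))
  fm <- structure(list(X = X, block = rep("steric", 5), node = 1:5,
                       grid = build_grid(molecule("a", data.frame(
                         element = "C", x = 0, y = 0, z = 0))),
                       alive = rep(TRUE, 5), buw_w = NULL,
                       region = rep(NA_integer_, 5),
                       treatment = list(pretreated = FALSE, buw = FALSE)),
                  class = "field_matrix")
  out <- pretreat(fm)
  expect_true(all(out$X[, 1] == 30))       # capped
  expect_true(all(out$X[, 2] == 0))        # zeroed
  expect_false(out$alive[1])               # 1 level after capping
  expect_false(out$alive[2])               # constant zero
  expect_true(out$alive[3])                # 6 distinct values
  expect_false(out$alive[4])               # constant
  expect_false(out$alive[5])               # constant
  expect_error(pretreat(fm, cap = 0.01), "exceed")
  # electrostatic block is floored at -cap as well
  fme <- fm; fme$block <- rep("electrostatic", 5)
  fme$X[, 1] <- c(-90, -50, 31, 40, 2, 1)
  oute <- pretreat(fme)
  expect_equal(sort(unique(oute$X[, 1])), c(-30, 1, 2, 30))
  # fuzzed invariants: nothing above cap, no nonzero below threshold
  set.seed(9)
  for (k in 1:10) {
    Xf <- matrix(rnorm(60, sd = 20), 10)
    fmf <- fm; fmf$X <- Xf; fmf$block <- rep("steric", 6)
    fmf$node <- 1:6; fmf$alive <- rep(TRUE, 6)
    of <- pretreat(fmf)
    expect_true(all(of$X <= 30))
    expect_true(all(of$X[of$X != 0] >= 0.05 | of$X[of$X != 0] <= -0.05))
  }
})

test_that("block unscaled weighting gives unit block variance", {
  set.seed(4)
  n <- 12
  Xs <- matrix(rnorm(n * 8, sd = 3), n)
  Xe <- matrix(rnorm(n * 6, sd = 0.3), n)
  fm <- structure(list(X = cbind(Xs, Xe),
                       block = rep(c("steric", "electrostatic"), c(8, 6)),
                       node = c(1:8, 1:6),
                       grid = build_grid(molecule("a", data.frame(
                         element = "C", x = 0, y = 0, z = 0))),
                       alive = rep(TRUE, 14), buw_w = NULL,
                       region = rep(NA_integer_, 14),
                       treatment = list(pretreated = TRUE, buw = FALSE,
                                        cap = 30, zero_threshold = 0.05)),
                  class = "field_matrix")
  out <- buw_scale(fm)
  for (b in c("steric", "electrostatic")) {
    tv <- sum(apply(out$X[, out$block == b], 2, var))
    expect_equal(tv, 1, tolerance = 1e-9)
  }
  # intra-block ratios preserved
  r0 <- fm$X[, 2] / fm$X[, 5]
  expect_equal(out$X[, 2] / out$X[, 5], r0, tolerance = 1e-9)
  # idempotent once variances are recomputed
  out2 <- buw_scale(out)
  expect_equal(out2$X, out$X, tolerance = 1e-9)
  # explicit weights: blocks with total variances 4 and 9 get 1/2, 1/3
  fm2 <- fm
  fm2$X <- cbind(sqrt(4 / var(Xs[, 1])) * Xs[, 1, drop = FALSE],
                 sqrt(9 / var(Xe[, 1])) * Xe[, 1, drop = FALSE])
  fm2$block <- c("steric", "electrostatic"); fm2$node <- c(1L, 1L)
  fm2$alive <- rep(TRUE, 2); fm2$region <- rep(NA_integer_, 2)
  out3 <- buw_scale(fm2)
  expect_equal(unname(out3$buw_w), c(1 / 2, 1 / 3), tolerance = 1e-9)
})

test_that("smart region definition groups variables around seeds", {
  # two separated clusters of informative nodes on a 1-A line grid
  mols <- lapply(1:6, function(i) molecule(paste0("m", i), data.frame(
    element = "C", x = i / 2, y = 0, z = 0)))
  g <- build_grid(mols, spacing = 1, padding = 3)
  set.seed(21)
  nvar <- g$n_nodes
  X <- matrix(rnorm(6 * nvar), 6)
  fm <- structure(list(X = X, block = rep("steric", nvar), node = 1:nvar,
                       grid = g, alive = rep(TRUE, nvar), buw_w = NULL,
                       region = rep(NA_integer_, nvar),
                       treatment = list(pretreated = TRUE, buw = TRUE,
                                        cap = 30, zero_threshold = 0.05)),
                  class = "field_matrix")
  w <- numeric(nvar); w[c(5, nvar - 5)] <- c(10, 8)
  out <- srd_group(fm, w, n_seeds = 2, critical_distance = 2)
  regs <- unique(out$region[!is.na(out$region)])
  expect_equal(length(regs), 2)
  # orphans are dead
  expect_true(all(!out$alive[is.na(out$region)]))
  # members lie within the critical distance of their seed
  nodes <- grid_coords(g)
  for (r in regs) {
    seeds <- which(w > 0)
    dmin <- apply(fieldsar:::.cross_dist(
      nodes[out$node[out$region %in% r & !is.na(out$region)], ,
            drop = FALSE],
      nodes[out$node[seeds], , drop = FALSE]), 1, min)
    expect_true(all(dmin <= 2 + 1e-9))
  }
  # critical distance 0 leaves only the seeds
  out0 <- srd_group(fm, w, n_seeds = 2, critical_distance = 0)
  expect_equal(sum(!is.na(out0$region)), 2)
  # identical profiles in adjacent regions merge
  fm2 <- fm
  fm2$X[, 6] <- fm2$X[, 5]   # nodes 5 and 6 are 1 A apart, same profile
  w2 <- numeric(nvar); w2[c(5, 6)] <- c(10, 9)
  out2 <- srd_group(fm2, w2, n_seeds = 2, critical_distance = 0.5,
                    collinearity_cutoff = 0.99)
  expect_equal(length(unique(stats::na.omit(out2$region))), 1)
  expect_error(srd_group(fm, w, n_seeds = 0), "n_seeds")
})
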