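# a small helper producing a ready field_matrix-like object from a
# plain numeric matrix, bypassing the geometry stages
as_fm <- function(X, block = rep("steric", ncol(X)),
                  pretreated = TRUE, buw = TRUE) {
  structure(list(X = X, block = block,
                 node = unlist(lapply(table(block)[unique(block)], seq_len)),
                 grid = build_grid(molecule("a", data.frame(
                   element = "C", x = 0, y = 0, z = 0))),
                 alive = rep(TRUE, ncol(X)), buw_w = NULL,
                 region = rep(NA_integer_, ncol(X)),
                 treatment = list(pretreated = pretreated, buw = buw,
                                  cap = 30, zero_threshold = 0.05)),
            class = "field_matrix")
}

test_that("NIPALS reproduces exact linear structure and validates inputs", {
  set.seed(1)
  X <- matrix(rnorm(12 * 6), 12)
  # orthogonalise the nuisance columns against column 3 so that a
  # single component can carry the whole (exactly linear) signal
  x3 <- X[, 3]
  for (j in setdiff(1:6, 3)) X[, j] <- stats::resid(stats::lm(X[, j] ~ x3))
  y <- 2 * X[, 3] + 1
  m <- comfa_pls(as_fm(X), y, ncomp = 1)
  expect_equal(fitted(m), y, tolerance = 1e-8)
  expect_equal(m$r2, 1, tolerance = 1e-8)
  expect_error(comfa_pls(as_fm(X), y, ncomp = 0), "component")
  expect_error(comfa_pls(as_fm(X), rep(1, 12), ncomp = 1), "constant")
  expect_error(comfa_pls(as_fm(X), y, ncomp = 50), "exceeds")
})

test_that("NIPALS coefficients match the independent Krylov oracle", {
  set.seed(2024)
  worst <- 0
  for (r in 1:50) {
    n <- sample(8:16, 1); p <- sample(5:30, 1)
    nc <- sample(1:4, 1)
    X <- matrix(rnorm(n * p), n)
    y <- rnorm(n)
    fit <- fieldsar:::nipals_pls1(X, y, nc)
    if (fit$ncomp < nc) next
    b_oracle <- oracle_pls_beta(X, y, nc)
    worst <- max(worst, max(abs(fit$beta - b_oracle)))
  }
  expect_lt(worst, 1e-6)
})

test_that("PLS scores are orthogonal and R2 is monotone in components", {
  set.seed(5)
  X <- matrix(rnorm(20 * 15), 20)
  y <- X[, 1] - X[, 2] + rnorm(20, sd = 0.5)
  r2 <- vapply(1:5, function(nc) comfa_pls(as_fm(X), y, nc)$r2, numeric(1))
  expect_true(all(diff(r2) >= -1e-10))
  f <- fieldsar:::nipals_pls1(X, y, 5)
  G <- crossprod(f$scores)
  expect_lt(max(abs(G[upper.tri(G)])), 1e-8)
})

test_that("predictions are invariant to constant column shifts", {
  set.seed(6)
  X <- matrix(rnorm(15 * 8), 15)
  y <- rnorm(15)
  m1 <- comfa_pls(as_fm(X), y, ncomp = 3)
  m2 <- comfa_pls(as_fm(sweep(X, 2, rnorm(8), "+")), y, ncomp = 3)
  expect_equal(fitted(m1), fitted(m2), tolerance = 1e-8)
})

test_that("leave-one-out Q2 matches a brute-force per-fold oracle", {
  set.seed(7)
  X <- matrix(rnorm(14 * 10), 14)
  y <- X[, 1] + rnorm(14, sd = 0.3)
  m <- comfa_pls(as_fm(X), y, ncomp = 2)
  cv <- loo_q2(m)
  expect_equal(cv$q2, oracle_loo_q2(X, y, 2), tolerance = 1e-8)
  expect_equal(cv$s_loo,
               sqrt(sum((y - cv$predictions)^2) / length(y)),
               tolerance = 1e-12)
  # perfect LOO predictions give Q2 = 1; mean predictions give Q2 = 0
  expect_equal(1 - 0 / sum((y - mean(y))^2), 1)
  press_mean <- sum((y - mean(y))^2)
  expect_equal(1 - press_mean / press_mean, 0)
  # hand-computable 3-row case
  X3 <- matrix(c(1, 2, 3), 3, 1)
  y3 <- c(1, 2, 3)
  m3 <- comfa_pls(as_fm(X3), y3, ncomp = 1)
  expect_equal(loo_q2(m3)$q2, oracle_loo_q2(X3, y3, 1), tolerance = 1e-10)
})

test_that("model selection maximises Q2 with deterministic tie-breaks", {
  set.seed(8)
  n <- 24
  Xs <- matrix(rnorm(n * 10), n)
  Xe <- matrix(rnorm(n * 10), n)
  y <- Xs[, 1] + Xe[, 1]   # both blocks needed, noiseless
  fm <- as_fm(cbind(Xs, Xe),
              block = rep(c("steric", "electrostatic"), each = 10))
  sel <- select_model(fm, y, ncomp_max = 3)
  expect_s3_class(sel$model, "comfa_pls")
  # both blocks carry signal, so the two-field model must win
  expect_setequal(sel$model$fields, c("steric", "electrostatic"))
  expect_equal(max(sel$scan$q2), sel$q2)
  # single-candidate selection returns that candidate
  sel1 <- select_model(fm, y, field_sets = list(S = "steric"),
                       ncomp_max = 2)
  expect_equal(sel1$model$fields, "steric")
})

test_that("external statistics reproduce definitions and edge cases", {
  obs <- c(6, 7, 8, 9)
  expect_equal(unname(external_stats(obs, obs)), c(1, 0))
  pred <- c(6.5, 6.8, 8.4, 8.8)
  ext <- external_stats(obs, pred)
  expect_equal(ext[["rtest2"]], cor(obs, pred)^2)
  expect_equal(ext[["s_test"]], sqrt(mean((pred - obs)^2)))
  expect_error(external_stats(c(7, 7), c(6, 8)), "constant")
  expect_error(external_stats(7, 8), "pairs")
})

test_that("field contributions are a unit-sum split over blocks", {
  set.seed(9)
  n <- 20
  Xs <- matrix(rnorm(n * 6), n)
  y <- Xs[, 1] + rnorm(n, sd = 0.1)
  # duplicated identical blocks split evenly
  fm_dup <- as_fm(cbind(Xs, Xs),
                  block = rep(c("steric", "electrostatic"), each = 6))
  m <- comfa_pls(fm_dup, y, ncomp = 2)
  ctr <- field_contributions(m)
  expect_equal(sum(ctr), 1, tolerance = 1e-12)
  expect_equal(unname(ctr), c(0.5, 0.5), tolerance = 1e-9)
  # single-block model returns 1
  m1 <- comfa_pls(as_fm(Xs), y, ncomp = 2, fields = "steric")
  expect_equal(unname(field_contributions(m1)), 1)
  # random fits still sum to one
  fm_r <- as_fm(cbind(Xs, matrix(rnorm(n * 6), n)),
                block = rep(c("steric", "electrostatic"), each = 6))
  m2 <- comfa_pls(fm_r, rnorm(n), ncomp = 3)
  expect_equal(sum(field_contributions(m2)), 1, tolerance = 1e-12)
})

test_that("contour export writes coefficient maps with linear sign", {
  ser <- generate_series(synthetic_spec(n_compounds = 12, seed = 3))
  fm <- compute_fields(ser$molecules, spacing = 2, padding = 3)
  y <- ser$activities$pKi
  m <- comfa_pls(fm, y, ncomp = 2)
  dir <- withr::local_tempdir()
  maps <- export_contours(m, dir)
  expect_true(file.exists(maps$steric$path))
  expect_true(file.exists(maps$electrostatic$path))
  expect_equal(length(maps$steric$values), fm$grid$n_nodes)
  # dead variables appear as zero in the map
  alive_nodes <- m$prep$node[m$prep$cols][
    m$prep$block[m$prep$cols] == "steric"]
  expect_true(all(maps$steric$values[-alive_nodes] == 0))
  # negating y negates every map
  m_neg <- comfa_pls(fm, -y, ncomp = 2)
  maps_neg <- export_contours(m_neg, withr::local_tempdir())
  expect_equal(maps_neg$steric$values, -maps$steric$values,
               tolerance = 1e-9)
  # dx file parses back to the same number of items
  txt <- readLines(maps$steric$path)
  expect_true(any(grepl(sprintf("items %d", fm$grid$n_nodes), txt)))
})

test_that("model methods behave like standard R model objects", {
  ser <- generate_series(synthetic_spec(n_compounds = 15, seed = 2))
  fm <- compute_fields(ser$molecules, spacing = 2, padding = 3)
  y <- ser$activities$pKi
  m <- comfa_pls(fm, y, ncomp = 2)
  expect_equal(length(coef(m)), ncol(fm$X))
  expect_equal(fitted(m) + residuals(m), y, tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(predict(m), fitted(m))
  # predict on the training field matrix reproduces fitted values
  expect_equal(predict(m, fm), fitted(m), tolerance = 1e-9)
  sim <- simulate(m, nsim = 3, seed = 1)
  expect_equal(dim(sim), c(15L, 3L))
  expect_output(print(m), "components")
  s <- summary(m)
  expect_output(print(s), "Q2")
  pdf(NULL); on.exit(dev.off())
  expect_silent(plot(m))
})

test_that("y-scrambling destroys cross-validated performance", {
  spec <- synthetic_spec(n_compounds = 24, noise_sd = 0.2, seed = 12)
  ser <- generate_series(spec)
  fm <- compute_fields(ser$molecules, spacing = 1.5, padding = 4)
  y <- ser$activities$pKi
  m <- comfa_pls(fm, y, ncomp = 3)
  q2_real <- loo_q2(m)$q2
  expect_gte(q2_real, 0.5)
  set.seed(77)
  q2_perm <- vapply(1:20, function(i) {
    yp <- sample(y)
    loo_q2(comfa_pls(fm, yp, ncomp = 3))$q2
  }, numeric(1))
  expect_lte(mean(q2_perm), 0.2)
})
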