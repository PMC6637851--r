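# Molecule builders used across the suite.  All coordinates are
# deterministic; graph-level tests only need valid finite geometry.

# aromatic six-ring (Kekule orders) centred at `center`, radius 1.396
make_benzene <- function(id = "benzene", center = c(0, 0, 0)) {
  th <- (0:5) * pi / 3
  molecule(id,
           data.frame(element = "C",
                      x = center[1] + 1.396 * cos(th),
                      y = center[2] + 1.396 * sin(th),
                      z = center[3]),
           data.frame(i = 1:6, j = c(2:6, 1), order = c(2, 1, 2, 1, 2, 1)))
}

make_toluene <- function(id = "toluene") {
  b <- make_benzene(id)
  atoms <- rbind(b$atoms,
                 data.frame(element = "C", x = 2.9, y = 0, z = 0,
                            formal_charge = 0L, partial_charge = NA_real_))
  molecule(id, atoms, rbind(b$bonds, data.frame(i = 1, j = 7, order = 1)))
}

# saturated six-ring of carbons (order-1 bonds)
make_cyclohexane <- function(id = "cyclohexane", r = 1.5) {
  th <- (0:5) * pi / 3
  molecule(id,
           data.frame(element = "C", x = r * cos(th), y = r * sin(th),
                      z = 0),
           data.frame(i = 1:6, j = c(2:6, 1), order = 1))
}

make_chain <- function(id, elements, x0 = 0) {
  n <- length(elements)
  molecule(id,
           data.frame(element = elements, x = x0 + 1.5 * (seq_len(n) - 1),
                      y = 0, z = 0),
           if (n > 1) data.frame(i = 1:(n - 1), j = 2:n, order = 1)
           else NULL)
}

# Arylalkylamine reference compound used in the pose-metric tests: a
# biphenyl head, a 3-substituted butyl linker and a piperidine.  22
# heavy atoms; the phenyl-only analog of the same skeleton has 16.
make_biphenyl_amine <- function(id = "ref", biphenyl = TRUE) {
  th <- (0:5) * pi / 3
  ringA <- data.frame(element = "C", x = 1.396 * cos(th),
                      y = 1.396 * sin(th), z = 0)
  atoms <- ringA
  bonds <- data.frame(i = 1:6, j = c(2:6, 1), order = c(2, 1, 2, 1, 2, 1))
  if (biphenyl) {
    ringB <- data.frame(element = "C", x = -2.8 + 1.396 * cos(th),
                        y = 1.396 * sin(th), z = 0.8)
    atoms <- rbind(atoms, ringB)
    bonds <- rbind(bonds,
                   data.frame(i = 7:12, j = c(8:12, 7),
                              order = c(2, 1, 2, 1, 2, 1)),
                   data.frame(i = 4, j = 7, order = 1))
  }
  base <- nrow(atoms)
  chain <- data.frame(element = c("C", "C", "C", "C"),
                      x = c(2.9, 3.3, 3.7, 5.2),
                      y = c(0, 1.4, -1.2, -1.3),
                      z = c(0, 0.4, 0.1, 0.4))
  pip <- data.frame(element = c("N", "C", "C", "C", "C", "C"),
                    x = 5.9 + c(0, 1.2, 2.5, 2.6, 1.4, 0.1),
                    y = c(0, 0.8, 0.1, -1.2, -2.0, -1.4),
                    z = 0.6 + c(0, 0.4, 0.5, 0.1, -0.3, -0.4))
  atoms <- rbind(atoms, chain, pip)
  c1 <- base + 1L  # CH bonded to ring atom 1
  bonds <- rbind(bonds,
                 data.frame(i = c(1, c1, c1, c1 + 2, c1 + 3),
                            j = c(c1, c1 + 1, c1 + 2, c1 + 3, c1 + 4),
                            order = 1),
                 data.frame(i = base + 4 + 1:6,
                            j = base + 4 + c(2:6, 1), order = 1))
  molecule(id, atoms, bonds)
}

# random connected molecule: a labelled tree plus (optionally) one
# ring-closing order-1 edge; no aromatic systems by construction
rand_mol <- function(n, seed, ring = FALSE) {
  set.seed(seed)
  el <- sample(c("C", "C", "C", "N", "O"), n, replace = TRUE)
  bonds <- NULL
  if (n > 1) {
    parent <- vapply(2:n, function(i) sample.int(i - 1L, 1L), integer(1))
    ord <- sample(c(1L, 1L, 1L, 2L), n - 1L, replace = TRUE)
    bonds <- data.frame(i = parent, j = 2:n, order = ord)
    if (ring && n >= 5) {
      # close one extra cycle between two non-adjacent vertices
      cand <- which(outer(1:n, 1:n, function(a, b) a < b - 1))
      pick <- sample(seq_len(n - 2L), 1L)
      a <- pick; b <- pick + 2L
      if (!any(bonds$i == a & bonds$j == b))
        bonds <- rbind(bonds, data.frame(i = a, j = b, order = 1L))
    }
  }
  molecule(paste0("rand", seed),
           data.frame(element = el,
                      x = stats::runif(n, -5, 5),
                      y = stats::runif(n, -5, 5),
                      z = stats::runif(n, -5, 5)),
           bonds)
}
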