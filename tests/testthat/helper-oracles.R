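# Independent oracles the implementation is checked against.

# PLS1 regression vector via the Krylov-subspace closed form: the
# k-component PLS1 solution is the least-squares solution restricted to
# span{s, As, ..., A^(k-1)s} with A = Xc'Xc, s = Xc'y.  This shares no
# code path with the NIPALS implementation.
oracle_pls_beta <- function(X, y, nc) {
  Xc <- scale(X, scale = FALSE)
  yc <- y - mean(y)
  s <- crossprod(Xc, yc)
  A <- crossprod(Xc)
  K <- matrix(0, ncol(X), nc)
  v <- s
  for (k in seq_len(nc)) { K[, k] <- v; v <- A %*% v }
  Q <- qr.Q(qr(K))
  drop(Q %*% solve(crossprod(Q, A %*% Q), crossprod(Q, s)))
}

# brute-force maximum connected common induced subgraph size, matching
# on element and exact bond order: enumerate connected vertex subsets
# of the first graph (largest first) and try to embed each into the
# second graph by naive backtracking
oracle_mcs_size <- function(mol1, mol2) {
  g <- function(mol) {
    h <- which(mol$atoms$element != "H")
    A <- matrix(0L, nrow(mol$atoms), nrow(mol$atoms))
    if (nrow(mol$bonds))
      for (k in seq_len(nrow(mol$bonds))) {
        A[mol$bonds$i[k], mol$bonds$j[k]] <-
          A[mol$bonds$j[k], mol$bonds$i[k]] <- as.integer(mol$bonds$order[k])
      }
    list(el = mol$atoms$element[h], A = A[h, h, drop = FALSE])
  }
  g1 <- g(mol1); g2 <- g(mol2)
  n1 <- length(g1$el)
  stopifnot(n1 <= 14)       # bitmask enumeration
  connected <- function(S) {
    if (length(S) == 1L) return(TRUE)
    seen <- S[1]; frontier <- S[1]
    while (length(frontier)) {
      nxt <- setdiff(S[colSums(g1$A[frontier, S, drop = FALSE] > 0) > 0],
                     seen)
      seen <- c(seen, nxt); frontier <- nxt
    }
    length(seen) == length(S)
  }
  embeds <- function(S) {
    k <- length(S)
    # order S so every vertex after the first touches an earlier one
    ordS <- S[1]; rest <- S[-1]
    while (length(rest)) {
      nx <- rest[which(colSums(g1$A[ordS, rest, drop = FALSE] > 0) > 0)[1]]
      ordS <- c(ordS, nx); rest <- setdiff(rest, nx)
    }
    used <- rep(FALSE, length(g2$el))
    assign <- integer(k)
    bt <- function(i) {
      if (i > k) return(TRUE)
      for (v in which(!used & g2$el == g1$el[ordS[i]])) {
        ok <- TRUE
        for (j in seq_len(i - 1)) {
          if (g1$A[ordS[i], ordS[j]] != g2$A[v, assign[j]]) {
            ok <- FALSE; break
          }
        }
        if (ok) {
          assign[i] <<- v; used[v] <<- TRUE
          if (bt(i + 1L)) return(TRUE)
          used[v] <<- FALSE
        }
      }
      FALSE
    }
    bt(1L)
  }
  subsets <- lapply(seq_len(2^n1 - 1L), function(m) which(bitwAnd(
    m, 2^(seq_len(n1) - 1L)) > 0))
  sizes <- lengths(subsets)
  for (k in sort(unique(sizes), decreasing = TRUE)) {
    for (S in subsets[sizes == k]) {
      if (connected(S) && embeds(S)) return(k)
    }
  }
  0L
}

# brute-force leave-one-out Q2 using the Krylov oracle per fold
oracle_loo_q2 <- function(X, y, nc) {
  n <- length(y)
  pred <- vapply(seq_len(n), function(i) {
    b <- oracle_pls_beta(X[-i, , drop = FALSE], y[-i], nc)
    xm <- colMeans(X[-i, , drop = FALSE])
    drop((X[i, ] - xm) %*% b) + mean(y[-i])
  }, numeric(1))
  1 - sum((y - pred)^2) / sum((y - mean(y))^2)
}
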