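# Independent oracles and small shared fixtures for the test suite.

# Horn's quaternion method for optimal superposition RMSD: an independent
# route to the least-squares rigid-fit RMSD (no SVD, no shared code with
# kabsch_superpose).
quaternion_rmsd <- function(P, Q) {
  P <- as.matrix(P); Q <- as.matrix(Q)
  Pc <- sweep(P, 2, colMeans(P)); Qc <- sweep(Q, 2, colMeans(Q))
  M <- crossprod(Pc, Qc)
  Sxx <- M[1,1]; Sxy <- M[1,2]; Sxz <- M[1,3]
  Syx <- M[2,1]; Syy <- M[2,2]; Syz <- M[2,3]
  Szx <- M[3,1]; Szy <- M[3,2]; Szz <- M[3,3]
  K <- matrix(c(
    Sxx+Syy+Szz, Syz-Szy,     Szx-Sxz,     Sxy-Syx,
    Syz-Szy,     Sxx-Syy-Szz, Sxy+Syx,     Szx+Sxz,
    Szx-Sxz,     Sxy+Syx,     -Sxx+Syy-Szz, Syz+Szy,
    Sxy-Syx,     Szx+Sxz,     Syz+Szy,     -Sxx-Syy+Szz), 4, 4, byrow = TRUE)
  lam <- max(eigen(K, symmetric = TRUE, only.values = TRUE)$values)
  msd <- (sum(Pc^2) + sum(Qc^2) - 2 * lam) / nrow(P)
  sqrt(max(msd, 0))
}

# Brute-force pair scans over the package's own pseudo-atom positions:
# independent R re-implementations of the pairwise energy rules.
bf_excluded_volume <- function(conf, model) {
  ca <- lift_to_cartesian(conf)
  pa <- rebuild_pseudoatoms(conf)
  n <- nrow(ca)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (j - i < 2) next
    if (sqrt(sum((ca[i,] - ca[j,])^2)) < model$hardcore_ca) return(Inf)
    if (sqrt(sum((pa$cb[i,] - pa$cb[j,])^2)) < model$hardcore_cb) return(Inf)
  }
  0
}

bf_contact_energy <- function(conf, model) {
  pa <- rebuild_pseudoatoms(conf)
  cls <- latticeloop:::.contact_class[strsplit(conf$sequence, "")[[1]]]
  n <- nrow(pa$sc); e <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (j - i < 3) next
    r <- sqrt(sum((pa$sc[i,] - pa$sc[j,])^2))
    if (r < model$r_rep) e <- e + model$eps_rep
    else if (r >= model$r_min && r <= model$r_max)
      e <- e - model$eps[cls[i], cls[j]]
  }
  e
}

bf_restraint_energy <- function(coords, rset) {
  e <- 0
  for (r in seq_len(nrow(rset))) {
    d <- sqrt(sum((coords[rset$i[r], ] - coords[rset$j[r], ])^2))
    ex <- abs(d - rset$d0[r]) - rset$tol[r]
    if (ex > 0) e <- e + rset$weight[r] * ex^2
  }
  e
}

# the 24 proper rotations of the cube (integer matrices, det +1)
cube_rotations <- function() {
  perms <- list(c(1,2,3), c(1,3,2), c(2,1,3), c(2,3,1), c(3,1,2), c(3,2,1))
  out <- list()
  for (p in perms) for (sx in c(-1,1)) for (sy in c(-1,1)) for (sz in c(-1,1)) {
    R <- matrix(0, 3, 3)
    s <- c(sx, sy, sz)
    for (k in 1:3) R[k, p[k]] <- s[k]
    if (abs(det(R) - 1) < 1e-9) out[[length(out) + 1L]] <- R
  }
  out
}

# standard small fixture shared across tests
hlh_case <- local({
  memo <- NULL
  function() {
    if (is.null(memo)) {
      fx <- make_fixture(fixture_spec("helix-loop-helix", n_res = 15,
                                      loop_length = 4, seed = 1))
      memo <<- list(fx = fx, case = excise_loop(fx$structure, fx$loopspec))
    }
    memo
  }
})

# a short valid lattice conformation (projected helix), memoized
helix_conf <- local({
  memo <- NULL
  function(n = 12) {
    key <- as.character(n)
    if (is.null(memo[[key]])) {
      vs <- build_vector_set()
      p <- project_chain(make_helix(n), vs)
      if (is.null(memo)) memo <<- list()
      memo[[key]] <<- p$conf
    }
    memo[[key]]
  }
})

# random valid lattice conformation via short random growth (no clashes)
random_conf <- function(n, seed, spacing = 0.61) {
  vs <- build_vector_set(spacing)
  V <- vs$vectors
  set.seed(seed)
  ca <- matrix(0L, n, 3)
  min_sq <- (3.3 / spacing)^2
  for (i in 2:n) {
    repeat {
      cand <- ca[i - 1, ] + V[sample.int(nrow(V), 1), ]
      prev <- ca[seq_len(max(i - 2, 0)), , drop = FALSE]
      if (nrow(prev) == 0 ||
          min(colSums((t(prev) - cand)^2)) >= min_sq) break
    }
    ca[i, ] <- cand
  }
  seqs <- paste(sample(c("A","L","G","S","K","E","V","F"), n, replace = TRUE),
                collapse = "")
  lattice_conf(seqs, ca, spacing)
}
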