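vs <- build_vector_set()

# small synthetic snapshot families: two well-separated loop conformers
two_families <- function(n_per = 4, jitter = 0.05, seed = 2) {
  base <- lift_to_cartesian(helix_conf(12))
  fam2 <- base
  fam2[5:8, ] <- fam2[5:8, ] + matrix(c(6, 6, 0), 4, 3, byrow = TRUE)
  set.seed(seed)
  out <- list()
  for (i in seq_len(n_per)) out[[i]] <- base + matrix(rnorm(36, 0, jitter), 12)
  for (i in seq_len(n_per)) out[[n_per + i]] <- fam2 + matrix(rnorm(36, 0, jitter), 12)
  out
}

test_that("pairwise RMSD matrix is symmetric, zero-diagonal, rotation-blind", {
  snaps <- two_families(3)
  M <- pairwise_rmsd_matrix(snaps)
  expect_equal(M, t(M))
  expect_true(all(diag(M) == 0))
  # identical snapshots -> all zeros
  M0 <- pairwise_rmsd_matrix(list(snaps[[1]], snaps[[1]], snaps[[1]]))
  expect_equal(max(M0), 0, tolerance = 1e-9)
  # rigid rotation of one copy superposes away
  R <- cube_rotations()[[7]]
  M1 <- pairwise_rmsd_matrix(list(snaps[[1]], snaps[[1]] %*% t(R) + 3))
  expect_equal(M1[1, 2], 0, tolerance = 1e-9)
})

test_that("pairwise RMSD entries match independent recomputation", {
  snaps <- two_families(3)[c(1, 2, 4, 5, 6)]
  M <- pairwise_rmsd_matrix(snaps)
  for (a in 1:4) for (b in (a + 1):5)
    expect_equal(M[a, b], quaternion_rmsd(snaps[[a]], snaps[[b]]),
                 tolerance = 1e-9)
})

test_that("global medoid equals the exhaustive row-sum scan", {
  snaps <- two_families(4)
  M <- pairwise_rmsd_matrix(snaps)
  expect_equal(global_medoid(M), which.min(rowSums(M)))
  expect_equal(global_medoid(snaps), which.min(rowSums(M)))
  expect_equal(global_medoid(M[1, 1, drop = FALSE]), 1L)
  # three collinear conformations: the middle one wins
  a <- snaps[[1]]; b <- a; b[5, 1] <- b[5, 1] + 2; c <- a; c[5, 1] <- c[5, 1] + 4
  expect_equal(global_medoid(list(a, b, c)), 2L)
})

test_that("k-means separates well-separated conformer families", {
  snaps <- two_families(4)
  cl <- kmeans_cluster(snaps, k = 2, seed = 1)
  expect_length(cl$labels, 8)
  expect_equal(length(unique(cl$labels[1:4])), 1)
  expect_equal(length(unique(cl$labels[5:8])), 1)
  expect_false(cl$labels[1] == cl$labels[5])
  # medoid of each cluster belongs to the cluster
  for (g in 1:2)
    expect_true(cl$labels[cl$medoid_per_cluster[g]] == g)
  expect_error(kmeans_cluster(snaps, k = 9), "exceeds")
})

test_that("k = 1 collapses to the global medoid and objective is converged", {
  snaps <- two_families(3)
  cl <- kmeans_cluster(snaps, k = 1, seed = 1)
  expect_true(all(cl$labels == 1))
  expect_equal(cl$medoid_per_cluster, cl$global_medoid)
  cl2 <- kmeans_cluster(snaps, k = 2, seed = 1)
  expect_lte(cl2$objective, cl$objective + 1e-9)
})

test_that("top-model selection is the medoid of the collated snapshots", {
  case <- hlh_case()$case
  em <- default_energy_model()
  rs <- scaffold_restraints(case, seed = 1)
  tiny <- remc_schedule("quick", n_replicas = 2, n_macrocycles = 5,
                        steps_per_cycle = 10, seed = 3)
  trs <- run_repeats(case, em, rs, tiny, n_repeats = 2)
  top <- select_top_model(trs, k = 3, seed = 1)
  # equals the global medoid of the concatenation in loop-RMSD space
  col <- latticeloop:::collate_snapshots(trs)
  loop <- case$loop_idx
  sc <- setdiff(seq_len(34), loop)
  M <- pairwise_rmsd_matrix(col$coords, superpose_idx = sc, rmsd_idx = loop)
  expect_equal(top$index, which.min(rowSums(M)))
  # permuting trajectory order leaves the selected conformation unchanged
  top_rev <- select_top_model(rev(trs), k = 3, seed = 1)
  expect_equal(top_rev$coords, col$coords[[top$index]][, ],
               tolerance = 1e-12, ignore_attr = TRUE)
  # single-snapshot trajectory selects that snapshot
  t1 <- trs[[1]]; t1$snapshots <- t1$snapshots[1]
  t1$energies <- t1$energies[1]; t1$cycles <- t1$cycles[1]
  top1 <- select_top_model(t1)
  expect_equal(top1$index, 1L)
})

test_that("medoid selection is stable under snapshot duplication", {
  snaps <- two_families(3)
  gm <- global_medoid(snaps)
  gm2 <- global_medoid(c(snaps, snaps))
  expect_equal(snaps[[((gm2 - 1) %% 6) + 1]], snaps[[gm]])
})

test_that("best-observed model scans exhaustively and bounds the top model", {
  case <- hlh_case()$case
  em <- default_energy_model()
  nat <- native_ca(case)
  rs <- consensus_restraints(list(nat, nat), loop = case$loop_idx, seed = 1)
  tiny <- remc_schedule("quick", n_replicas = 2, n_macrocycles = 5,
                        steps_per_cycle = 10, seed = 3)
  tr <- run_remc(case, em, rs, tiny)
  best <- select_best_model(tr, case)
  crmsds <- vapply(seq_along(tr$snapshots), function(s)
    loop_crmsd(snapshot_coords(tr, s), nat, loop_idx = case$loop_idx), 0)
  expect_equal(best$crmsd, min(crmsds), tolerance = 1e-12)
  expect_equal(best$index, which.min(crmsds))
  top <- select_top_model(tr)
  top_crmsd <- loop_crmsd(top$coords, nat, loop_idx = case$loop_idx)
  expect_lte(best$crmsd, top_crmsd + 1e-12)
})
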