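# Blind model selection: collate trajectory snapshots, cluster by K-means in
# superposed-coordinate space, and report the trajectory medoid as the top
# model. The "best observed" selector (needs the native loop) exists only
# for benchmarking.

# collate snapshots of one or more trajectories into Angstrom coordinates
collate_snapshots <- function(trajectories) {
  if (inherits(trajectories, "remc_trajectory"))
    trajectories <- list(trajectories)
  if (length(trajectories) == 0 ||
      all(vapply(trajectories, function(t) length(t$snapshots), 0L) == 0))
    stop("no snapshots to collate")
  coords <- list(); run_id <- integer(0); cycle <- integer(0); energy <- numeric(0)
  for (t in seq_along(trajectories)) {
    tr <- trajectories[[t]]
    for (s in seq_along(tr$snapshots)) {
      coords[[length(coords) + 1L]] <- snapshot_coords(tr, s)
      run_id <- c(run_id, tr$run_id %||% t)
      cycle <- c(cycle, tr$cycles[s])
      energy <- c(energy, tr$energies[s])
    }
  }
  list(coords = coords, run_id = run_id, cycle = cycle, energy = energy,
       loop_idx = trajectories[[1]]$loop_idx,
       sequence = trajectories[[1]]$sequence,
       spacing = trajectories[[1]]$spacing,
       snapshots = unlist(lapply(trajectories, function(t) t$snapshots),
                          recursive = FALSE),
       origin = trajectories[[1]]$origin)
}

#' Pairwise superposed-RMSD matrix of snapshots
#'
#' Entry (a, b) is the Calpha RMSD between snapshots a and b computed over
#' `rmsd_idx` after least-squares superposition on `superpose_idx`.
#'
#' @param coords list of equal-size n x 3 coordinate matrices
#' @param superpose_idx residue indices used for the superposition
#'   (default: all)
#' @param rmsd_idx residue indices over which the RMSD is taken
#'   (default: all)
#' @return symmetric matrix (Angstrom) with zero diagonal
#' @export
pairwise_rmsd_matrix <- function(coords, superpose_idx = NULL, rmsd_idx = NULL) {
  n <- length(coords)
  nres <- nrow(coords[[1]])
  if (is.null(superpose_idx)) superpose_idx <- seq_len(nres)
  if (is.null(rmsd_idx)) rmsd_idx <- seq_len(nres)
  M <- matrix(0, n, n)
  for (a in seq_len(n)) {
    for (b in seq_len(n)) {
      if (b <= a) next
      fit <- kabsch_superpose(coords[[a]][superpose_idx, , drop = FALSE],
                              coords[[b]][superpose_idx, , drop = FALSE])
      moved <- sweep(coords[[a]], 2, fit$center_p) %*% fit$rotation
      moved <- sweep(moved, 2, fit$center_q, "+")
      M[a, b] <- M[b, a] <-
        sqrt(mean(rowSums((moved[rmsd_idx, , drop = FALSE] -
                           coords[[b]][rmsd_idx, , drop = FALSE])^2)))
    }
  }
  M
}

#' Index of the global medoid
#'
#' The snapshot minimizing the summed pairwise distance to all others
#' (row-sum of the pairwise RMSD matrix); ties resolve to the lowest index.
#'
#' @param x either a list of coordinate matrices or a precomputed symmetric
#'   distance matrix
#' @param ... passed to [pairwise_rmsd_matrix()] when `x` is a list
#' @return integer index
#' @export
global_medoid <- function(x, ...) {
  M <- if (is.matrix(x)) x else pairwise_rmsd_matrix(x, ...)
  which.min(rowSums(M))
}

#' K-means clustering of snapshots
#'
#' Snapshots are superposed onto the global medoid (on `superpose_idx`),
#' the coordinates over `cluster_idx` are flattened into feature vectors,
#' and `stats::kmeans` is run with a seeded deterministic start. Medoids
#' per cluster minimize the summed pairwise RMSD within the cluster.
#'
#' @param coords list of n x 3 coordinate matrices
#' @param k number of clusters (1 <= k <= number of snapshots)
#' @param seed RNG seed for the K-means start
#' @param superpose_idx indices used for superposition (default all)
#' @param cluster_idx indices whose coordinates are clustered (default all)
#' @return a `cluster_result`: list with `labels`, `medoid_per_cluster`,
#'   `global_medoid`, `sizes`, `objective`
#' @export
kmeans_cluster <- function(coords, k, seed = 1, superpose_idx = NULL,
                           cluster_idx = NULL) {
  n <- length(coords)
  if (k > n) stop(sprintf("k = %d exceeds the number of snapshots (%d)", k, n))
  nres <- nrow(coords[[1]])
  if (is.null(superpose_idx)) superpose_idx <- seq_len(nres)
  if (is.null(cluster_idx)) cluster_idx <- seq_len(nres)
  M <- pairwise_rmsd_matrix(coords, superpose_idx, cluster_idx)
  gm <- which.min(rowSums(M))
  ref <- coords[[gm]]
  feats <- t(vapply(coords, function(x) {
    fit <- kabsch_superpose(x[superpose_idx, , drop = FALSE],
                            ref[superpose_idx, , drop = FALSE])
    moved <- sweep(sweep(x, 2, fit$center_p) %*% fit$rotation, 2,
                   fit$center_q, "+")
    as.vector(moved[cluster_idx, , drop = FALSE])
  }, numeric(3 * length(cluster_idx))))
  # cannot place more centers than distinct snapshots (low-T trajectories
  # often repeat conformations)
  k_eff <- min(k, nrow(unique(feats)))
  if (k_eff <= 1 || n == 1) {
    labels <- rep(1L, n)
    objective <- sum(sweep(feats, 2, colMeans(feats))^2)
  } else if (k_eff >= n) {
    # one snapshot per cluster (stats::kmeans needs k < n)
    labels <- seq_len(n)
    objective <- 0
  } else {
    km <- with_seed(seed, kmeans(feats, centers = k_eff, nstart = 5,
                                 iter.max = 50))
    labels <- km$cluster
    objective <- km$tot.withinss
  }
  medoids <- vapply(seq_len(max(labels)), function(cl) {
    idx <- which(labels == cl)
    idx[which.min(rowSums(M[idx, idx, drop = FALSE]))]
  }, 0L)
  structure(list(labels = labels, medoid_per_cluster = medoids,
                 global_medoid = gm, sizes = tabulate(labels),
                 objective = objective),
            class = "cluster_result")
}

# snapshot index -> lattice_conf
.snapshot_conf <- function(col, i) {
  lattice_conf(col$sequence, col$snapshots[[i]], col$spacing, col$origin)
}

#' Select the top-ranked (blind) model: the trajectory medoid
#'
#' Collates the snapshots of all repeats, computes the global medoid in
#' loop-RMSD space after scaffold superposition (or whole-chain space with
#' `cluster_on = "full"`), and returns it as the top model. Cluster medoids
#' are reported for diagnostics; native coordinates are never consulted.
#'
#' @param trajectories an `remc_trajectory` or list of them (repeats)
#' @param cluster_on "loop" (default) or "full": coordinates used for the
#'   medoid/clustering metric
#' @param k number of K-means clusters for the diagnostic clustering
#' @param seed K-means seed
#' @return list with `conf` (the selected `lattice_conf`), `coords`
#'   (Angstrom CA matrix), `index` (into the collated snapshot list),
#'   `run_id`, `clusters` (a `cluster_result`)
#' @export
select_top_model <- function(trajectories, cluster_on = c("loop", "full"),
                             k = 5, seed = 1) {
  cluster_on <- match.arg(cluster_on)
  col <- collate_snapshots(trajectories)
  n <- length(col$coords)
  nres <- nrow(col$coords[[1]])
  loop <- col$loop_idx
  if (cluster_on == "loop" && !is.null(loop) && length(loop) < nres) {
    sup <- setdiff(seq_len(nres), loop); cl_idx <- loop
  } else {
    sup <- seq_len(nres); cl_idx <- seq_len(nres)
  }
  cl <- kmeans_cluster(col$coords, k = min(k, n), seed = seed,
                       superpose_idx = sup, cluster_idx = cl_idx)
  idx <- cl$global_medoid
  list(conf = .snapshot_conf(col, idx), coords = col$coords[[idx]],
       index = idx, run_id = col$run_id[idx], clusters = cl)
}

#' Select the best observed model (benchmark oracle; needs the native loop)
#'
#' Scans every snapshot for the minimum loop cRMSD against the native loop
#' (scaffold superposition, deviation over loop Calpha only).
#'
#' @param trajectories an `remc_trajectory` or list of them
#' @param case the `excised_case` holding the native loop coordinates
#' @return list with `conf`, `coords`, `index`, `crmsd` (Angstrom)
#' @export
select_best_model <- function(trajectories, case) {
  col <- collate_snapshots(trajectories)
  nat <- native_ca(case)
  crmsd <- vapply(col$coords, function(x)
    loop_crmsd(x, nat, loop_idx = case$loop_idx), numeric(1))
  idx <- which.min(crmsd)
  list(conf = .snapshot_conf(col, idx), coords = col$coords[[idx]],
       index = idx, crmsd = crmsd[idx], all_crmsd = crmsd)
}
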