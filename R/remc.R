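# Replica-exchange Monte Carlo over the lattice model: local move set,
# Metropolis acceptance, jointly annealed constant-spacing temperature
# ladder, snapshots recorded from the lowest-temperature replica.

#' Default move set
#'
#' Proposal weights for the five move kinds: single-Calpha displacement,
#' rigid shifts of 2-, 3- and 4-residue fragments, and small rigid
#' displacements of larger (4-22 residue) fragments re-projected onto the
#' lattice. Weights must be positive and are normalized to sum to one.
#'
#' @param single_ca,fragment_2,fragment_3,fragment_4,large_shift proposal
#'   weights
#' @param large_shift_sigma Gaussian sigma (Angstrom) of the large-fragment
#'   displacement
#' @return a `move_set`
#' @export
default_move_set <- function(single_ca = 0.40, fragment_2 = 0.20,
                             fragment_3 = 0.15, fragment_4 = 0.15,
                             large_shift = 0.10, large_shift_sigma = 0.8) {
  w <- c(single_ca = single_ca, fragment_2 = fragment_2,
         fragment_3 = fragment_3, fragment_4 = fragment_4,
         large_shift = large_shift)
  stopifnot(all(w > 0))
  structure(list(weights = w / sum(w), large_shift_sigma = large_shift_sigma),
            class = "move_set")
}

#' Annealed replica-exchange schedule
#'
#' Replica temperatures start equally spaced on `[t_low, t_high]` (reduced
#' units) and the whole ladder is scaled by `anneal_factor` after every
#' macro-cycle, preserving the constant spacing between replicas. One
#' snapshot per macro-cycle is recorded from the lowest-temperature replica.
#'
#' @param preset "paper" (20 replicas, 100 macro-cycles of 100 sweeps,
#'   anneal factor 0.98) or "quick" (5 replicas, 20 macro-cycles, anneal
#'   factor 0.90 so the ladder cools to a comparable final temperature) for
#'   test-scale runs
#' @param n_replicas,t_high,t_low,anneal_factor,n_macrocycles,steps_per_cycle,swap_interval,seed
#'   overrides of the preset values; `steps_per_cycle` counts sweeps (one
#'   sweep = n attempted moves), `swap_interval` is in sweeps
#' @return a `remc_schedule`
#' @export
remc_schedule <- function(preset = c("paper", "quick"), n_replicas = NULL,
                          t_high = 2.5, t_low = 1.0, anneal_factor = NULL,
                          n_macrocycles = NULL, steps_per_cycle = 100,
                          swap_interval = 5, seed = 1) {
  preset <- match.arg(preset)
  if (is.null(n_replicas)) n_replicas <- if (preset == "paper") 20L else 5L
  if (is.null(n_macrocycles)) n_macrocycles <- if (preset == "paper") 100L else 20L
  if (is.null(anneal_factor)) anneal_factor <- if (preset == "paper") 0.98 else 0.90
  stopifnot(n_replicas >= 1, t_low > 0, t_high >= t_low,
            anneal_factor > 0, anneal_factor <= 1)
  structure(list(n_replicas = as.integer(n_replicas), t_high = t_high,
                 t_low = t_low, anneal_factor = anneal_factor,
                 n_macrocycles = as.integer(n_macrocycles),
                 steps_per_cycle = as.integer(steps_per_cycle),
                 swap_interval = as.integer(swap_interval),
                 seed = as.integer(seed), preset = preset),
            class = "remc_schedule")
}

.ladder <- function(schedule) {
  if (schedule$n_replicas == 1) schedule$t_low
  else seq(schedule$t_low, schedule$t_high, length.out = schedule$n_replicas)
}

#' Metropolis acceptance rule
#'
#' @param dE energy difference (proposed minus current), reduced units
#' @param temperature reduced temperature (> 0; the limit T -> 0 rejects
#'   every uphill move)
#' @param u uniform(0,1) draw (default: one draw from R's RNG)
#' @return logical: accept?
#' @export
metropolis_accept <- function(dE, temperature, u = runif(length(dE))) {
  ifelse(dE <= 0, TRUE, u < exp(-dE / temperature))
}

#' Replica-swap acceptance rule
#'
#' Standard detailed-balance criterion for exchanging conformations between
#' adjacent temperatures: accept with probability
#' `min(1, exp((1/T_i - 1/T_j) * (E_i - E_j)))`.
#'
#' @param E_i,E_j replica energies
#' @param T_i,T_j replica temperatures
#' @param u uniform(0,1) draw
#' @return logical: swap?
#' @export
replica_swap <- function(E_i, E_j, T_i, T_j, u = runif(length(E_i))) {
  delta <- (1 / T_i - 1 / T_j) * (E_i - E_j)
  ifelse(delta >= 0, TRUE, u < exp(delta))
}

# hard-core clash test on lattice positions (squared lattice distance)
.clash_free <- function(pos, others, min_sq) {
  if (nrow(others) == 0) return(rep(TRUE, nrow(pos)))
  apply(pos, 1, function(p)
    min(colSums((t(others) - p)^2)) >= min_sq)
}

#' Insert a random loop conformation into a projected scaffold
#'
#' The scaffold is projected onto the lattice (both segments share one
#' fitted rigid offset); the loop is then grown residue by residue with
#' random admissible bond vectors, rejecting hard-core clashes, biased
#' toward closing onto the downstream anchor. Growth is retried with
#' progressively weaker bias; if the closure bond is impossible at every
#' relaxation level an error is raised.
#'
#' @param case an `excised_case`
#' @param vset a `vector_set`
#' @param seed RNG seed for the random growth
#' @param max_retries growth attempts per relaxation level
#' @param hardcore_ca hard-core Calpha diameter (Angstrom) for clash tests
#' @return a `lattice_conf` of the full chain (attribute `scaffold_rmsd`
#'   holds the scaffold projection RMSD in Angstrom)
#' @export
random_loop_insert <- function(case, vset = build_vector_set(), seed = 1,
                               max_retries = 200, hardcore_ca = 3.3) {
  nat <- native_ca(case)
  n <- nrow(nat)
  loop <- case$loop_idx
  sc_idx <- setdiff(seq_len(n), loop)
  segs <- split(sc_idx, cumsum(c(1, diff(sc_idx) != 1)))
  # joint rigid-offset fit over all scaffold segments
  offs <- .projection_offsets(vset$spacing)
  best <- NULL
  for (r in seq_len(nrow(offs))) {
    off <- offs[r, ]
    tot <- 0; pos <- vector("list", length(segs)); ok <- TRUE
    for (s in seq_along(segs)) {
      idx <- segs[[s]]
      if (length(idx) == 1) {
        # lone scaffold residue: nearest vertex
        t1 <- (nat[idx, ] + off) / vset$spacing
        p <- matrix(as.integer(round(t1)), 1)
        tot <- tot + sum((p - t1)^2)
        pos[[s]] <- p
        next
      }
      pr <- .project_segment(nat[idx, , drop = FALSE], vset, off)
      if (!pr$ok) { ok <- FALSE; break }
      tot <- tot + pr$sumsq
      pos[[s]] <- pr$pos
    }
    if (ok && (is.null(best) || tot < best$tot))
      best <- list(tot = tot, pos = pos, off = off)
  }
  if (is.null(best)) stop("scaffold projection failed")
  ca <- matrix(NA_integer_, n, 3)
  for (s in seq_along(segs)) ca[segs[[s]], ] <- best$pos[[s]]
  origin <- -best$off
  lifted_sc <- sweep(ca[sc_idx, , drop = FALSE] * vset$spacing, 2, origin, "+")
  scaffold_rmsd <- sqrt(mean(rowSums((lifted_sc - nat[sc_idx, , drop = FALSE])^2)))

  V <- vset$vectors
  min_sq <- (hardcore_ca / vset$spacing)^2
  max_bond <- sqrt(max(rowSums(V^2)))
  A <- if (min(loop) > 1) ca[min(loop) - 1, ] else NULL
  B <- if (max(loop) < n) ca[max(loop) + 1, ] else NULL
  m <- length(loop)
  others_all <- ca[sc_idx, , drop = FALSE]

  # drop rows identical to any of the bonded partners (bonds are exempt from
  # the hard-core test; the shortest admissible bond is below hardcore_ca)
  .drop_bonded <- function(others, partners) {
    if (length(partners) == 0 || nrow(others) == 0) return(others)
    ex <- logical(nrow(others))
    for (p in partners)
      ex <- ex | (others[, 1] == p[1] & others[, 2] == p[2] & others[, 3] == p[3])
    others[!ex, , drop = FALSE]
  }

  grow <- function(sigma_lu) {
    placed <- matrix(NA_integer_, m, 3)
    if (is.null(A)) {
      # N-terminal loop: grow backwards from B, unconstrained closure
      cur <- B
      for (k in m:1) {
        cand <- sweep(V, 2, cur, "+")
        others <- .drop_bonded(rbind(others_all,
                                     placed[seq_len(m) > k, , drop = FALSE]),
                               list(cur))
        okc <- .clash_free(cand, others, min_sq)
        feas <- which(okc)
        if (length(feas) == 0) return(NULL)
        placed[k, ] <- cand[feas[sample.int(length(feas), 1)], ]
        cur <- placed[k, ]
      }
      return(placed)
    }
    cur <- A
    for (k in seq_len(m)) {
      cand <- sweep(V, 2, cur, "+")
      rem_after <- m + 1 - k          # bonds from this residue to B
      neighbors_ok <- rep(TRUE, nrow(cand))
      partners <- list(cur)
      if (!is.null(B)) {
        gap <- sqrt(rowSums(sweep(cand, 2, B)^2))
        neighbors_ok <- gap <= rem_after * max_bond + 1e-9
        if (rem_after == 1) {
          gv <- matrix(rep(B, each = nrow(cand)), ncol = 3) - cand
          neighbors_ok <- neighbors_ok & (vector_id(vset, gv) > 0)
          partners <- c(partners, list(B))
        }
      }
      prev_placed <- placed[seq_len(m) < k, , drop = FALSE]
      others <- .drop_bonded(rbind(others_all, prev_placed), partners)
      clash_ok <- .clash_free(cand, others, min_sq)
      feas <- which(neighbors_ok & clash_ok)
      if (length(feas) == 0) return(NULL)
      if (!is.null(B) && is.finite(sigma_lu)) {
        ideal <- cur + (B - cur) / rem_after
        w <- exp(-rowSums(sweep(cand[feas, , drop = FALSE], 2, ideal)^2) /
                 (2 * sigma_lu^2))
        if (sum(w) <= 0) w <- rep(1, length(feas))
        pick <- feas[sample.int(length(feas), 1, prob = w / sum(w))]
      } else {
        pick <- feas[sample.int(length(feas), 1)]
      }
      placed[k, ] <- cand[pick, ]
      cur <- placed[k, ]
    }
    placed
  }

  # a grown loop must also respect the Cbeta hard core once pseudo-atoms
  # are rebuilt; violations count as failed attempts
  cb_ok <- function(placed, hardcore_cb = 2.5) {
    ca_full <- ca
    ca_full[loop, ] <- placed
    conf <- lattice_conf(case$sequence, ca_full, vset$spacing, origin)
    cb <- rebuild_pseudoatoms(conf)$cb
    D <- as.matrix(dist(cb))
    D[abs(row(D) - col(D)) <= 1] <- Inf
    min(D[loop, ]) >= hardcore_cb
  }

  sigmas <- c(1.5, 3, Inf) / vset$spacing
  placed <- with_seed(seed, {
    res <- NULL
    for (sig in sigmas) {
      for (try in seq_len(max_retries)) {
        res <- grow(sig)
        if (!is.null(res) && !cb_ok(res)) res <- NULL
        if (!is.null(res)) break
      }
      if (!is.null(res)) break
    }
    res
  })
  if (is.null(placed))
    stop(sprintf("loop closure impossible after %d retries at every relaxation level",
                 max_retries))
  ca[loop, ] <- placed
  conf <- lattice_conf(case$sequence, ca, vset$spacing, origin)
  attr(conf, "scaffold_rmsd") <- scaffold_rmsd
  conf
}

#' One Metropolis Monte Carlo step
#'
#' Proposes one move from the move set and applies the Metropolis rule at
#' the given temperature. Proposals violating the lattice chain invariant
#' or the hard core are auto-rejected.
#'
#' @param conf a `lattice_conf`
#' @param model an `energy_model`
#' @param restraints a `restraint_set` or NULL
#' @param temperature reduced temperature
#' @param move_set a `move_set`
#' @param vset a `vector_set`
#' @param seed RNG seed
#' @param n_steps number of consecutive steps to take
#' @return list with `conf` (possibly updated), `accepted` (was the last
#'   step accepted), `n_accepted`, `energy`
#' @export
metropolis_step <- function(conf, model = default_energy_model(),
                            restraints = NULL, temperature = 1,
                            move_set = default_move_set(),
                            vset = build_vector_set(conf$spacing),
                            seed = 1, n_steps = 1) {
  cls <- .seq_classes(conf$sequence)
  r <- cpp_mc_steps(conf$ca, conf$spacing, unclass(model),
                    cls$cclass, cls$hec, cls$dsc,
                    .restraint_matrix(restraints), vset$vectors,
                    temperature, as.integer(n_steps),
                    move_set$weights, move_set$large_shift_sigma, 8L,
                    as.double(seed))
  out <- conf
  out$ca <- r$ca
  list(conf = out, accepted = r$last_accepted, n_accepted = r$n_accepted,
       energy = r$energy)
}

#' Run one annealed replica-exchange simulation
#'
#' All replicas start from the same random-loop conformation. Each
#' macro-cycle runs `steps_per_cycle` sweeps per replica with swap attempts
#' between adjacent replicas every `swap_interval` sweeps (even/odd pair
#' ordering alternates); afterwards all temperatures are scaled by the
#' anneal factor and one snapshot is appended from the lowest-temperature
#' replica. Fully reproducible from the schedule seed.
#'
#' @param case an `excised_case`
#' @param model an `energy_model`
#' @param restraints a `restraint_set` or NULL
#' @param schedule an `remc_schedule`
#' @param move_set a `move_set`
#' @param vset a `vector_set`
#' @return an `remc_trajectory`: list with `snapshots` (list of integer
#'   lattice CA matrices), `energies`, `cycles`, `sequence`, `spacing`,
#'   `origin`, `loop_idx`, `seed`, plus acceptance diagnostics
#' @export
run_remc <- function(case, model = default_energy_model(), restraints = NULL,
                     schedule = remc_schedule("quick"),
                     move_set = default_move_set(),
                     vset = build_vector_set()) {
  conf0 <- random_loop_insert(case, vset, seed = schedule$seed)
  cls <- .seq_classes(conf0$sequence)
  r <- cpp_run_remc(conf0$ca, conf0$spacing, unclass(model),
                    cls$cclass, cls$hec, cls$dsc,
                    .restraint_matrix(restraints), vset$vectors,
                    .ladder(schedule), schedule$anneal_factor,
                    schedule$n_macrocycles, schedule$steps_per_cycle,
                    schedule$swap_interval, move_set$weights,
                    move_set$large_shift_sigma, 8L,
                    as.double(schedule$seed))
  structure(list(snapshots = r$snapshots, energies = as.numeric(r$energies),
                 cycles = as.integer(r$cycles), sequence = conf0$sequence,
                 spacing = conf0$spacing, origin = conf0$origin,
                 loop_idx = case$loop_idx, seed = schedule$seed,
                 acc_rate = r$acc_rate, swap_rate = r$swap_rate,
                 final_temps = r$final_temps),
            class = "remc_trajectory")
}

#' @export
print.remc_trajectory <- function(x, ...) {
  cat(sprintf("<remc_trajectory: %d snapshots, %d residues, seed %d, acc %.2f>\n",
              length(x$snapshots), nchar(x$sequence), x$seed, x$acc_rate))
  invisible(x)
}

#' Repeat the REMC simulation with independent random streams
#'
#' @inheritParams run_remc
#' @param n_repeats number of independent runs (default 3); repeat seeds
#'   are spread multiplicatively from the master seed so different master
#'   seeds never share a repeat stream
#' @return list of `remc_trajectory`, each tagged with `run_id`
#' @export
run_repeats <- function(case, model = default_energy_model(),
                        restraints = NULL, schedule = remc_schedule("quick"),
                        n_repeats = 3, move_set = default_move_set(),
                        vset = build_vector_set()) {
  stopifnot(n_repeats >= 1)
  lapply(seq_len(n_repeats), function(k) {
    sch <- schedule
    sch$seed <- as.integer((as.numeric(schedule$seed) * 1009 + (k - 1)) %%
                           .Machine$integer.max)
    tr <- run_remc(case, model, restraints, sch, move_set, vset)
    tr$run_id <- k
    tr
  })
}

#' Snapshot CA coordinates in Angstrom
#' @param traj an `remc_trajectory`
#' @param i snapshot index
#' @return n x 3 numeric matrix
#' @export
snapshot_coords <- function(traj, i) {
  sweep(traj$snapshots[[i]] * traj$spacing, 2, traj$origin, "+")
}

#' Write a trajectory as a multi-MODEL CA-trace PDB plus an energy log
#' @param traj an `remc_trajectory`
#' @param pdb_path,log_path output paths (NULL = skip)
#' @export
write_trajectory <- function(traj, pdb_path = NULL, log_path = NULL) {
  seq3 <- .aa1to3[strsplit(traj$sequence, "")[[1]]]
  if (!is.null(pdb_path)) {
    con <- file(pdb_path, "w")
    on.exit(close(con))
    for (s in seq_along(traj$snapshots)) {
      writeLines(sprintf("MODEL     %4d", s), con)
      xyz <- snapshot_coords(traj, s)
      for (i in seq_len(nrow(xyz)))
        writeLines(sprintf("ATOM  %5d  CA  %3s A%4d    %8.3f%8.3f%8.3f  1.00  0.00",
                           i, seq3[i], i, xyz[i,1], xyz[i,2], xyz[i,3]), con)
      writeLines("ENDMDL", con)
    }
    writeLines("END", con)
  }
  if (!is.null(log_path))
    write.table(data.frame(cycle = traj$cycles, energy = traj$energies),
                log_path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(traj)
}
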