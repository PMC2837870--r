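case <- hlh_case()$case
vs <- build_vector_set()
em <- default_energy_model()

# deliberately small schedule: correctness checks, not production sampling
tiny <- remc_schedule("quick", n_replicas = 2, n_macrocycles = 4,
                      steps_per_cycle = 10, seed = 11)

test_that("random loop insertion yields a valid closed conformation", {
  conf <- random_loop_insert(case, vs, seed = 1)
  expect_true(isTRUE(validate_conf(conf, vs)))
  expect_equal(nrow(conf$ca), 34)
  expect_lt(attr(conf, "scaffold_rmsd"), 0.5)
  # anchors: bonds into and out of the loop are admissible (covered by
  # validate_conf) and the scaffold matches its projection regardless of seed
  conf2 <- random_loop_insert(case, vs, seed = 2)
  sc <- setdiff(seq_len(34), case$loop_idx)
  expect_identical(conf$ca[sc, ], conf2$ca[sc, ])
  # different seeds produce different loops, same seed reproduces
  expect_false(identical(conf$ca, conf2$ca))
  expect_identical(conf$ca, random_loop_insert(case, vs, seed = 1)$ca)
})

test_that("metropolis rule: downhill always, uphill by Boltzmann factor, frozen at T->0", {
  expect_true(all(metropolis_accept(c(-3, -0.1, 0), 1, u = c(0.99, 0.99, 0.99))))
  expect_false(metropolis_accept(1, 1e-12, u = 1e-300 + 0.5))
  expect_true(metropolis_accept(1, 1, u = 0.3))     # < exp(-1)
  expect_false(metropolis_accept(1, 1, u = 0.4))    # > exp(-1)
})

test_that("metropolis_step proposes valid conformations and can accept", {
  conf <- random_loop_insert(case, vs, seed = 4)
  st <- metropolis_step(conf, em, NULL, temperature = 2, vset = vs,
                        seed = 5, n_steps = 50)
  expect_true(isTRUE(validate_conf(st$conf, vs)))
  expect_gt(st$n_accepted, 0)
  expect_true(is.finite(st$energy))
})

test_that("replica swap accepts its deterministic limits", {
  expect_true(replica_swap(5, 5, 1.0, 1.5, u = 0.999999))   # equal energies
  expect_true(replica_swap(9, 2, 1.0, 1.5, u = 0.999999))   # low E at higher T
  # downhill-in-ladder case follows the analytic exponent exp(delta)
  p <- exp((1 / 1.0 - 1 / 1.5) * (2 - 9))
  expect_true(replica_swap(2, 9, 1.0, 1.5, u = p * 0.99))
  expect_false(replica_swap(2, 9, 1.0, 1.5, u = p * 1.01))
})

test_that("swap frequency on sampled harmonic-well energies matches the rule's mean", {
  # E ~ (T/2) chi^2_1 for a 1-D harmonic well; empirical acceptance of
  # replica_swap must match the analytic mean of min(1, exp(delta))
  set.seed(42)
  T1 <- 1.0; T2 <- 2.0; n <- 20000
  E1 <- T1 / 2 * rchisq(n, df = 1)
  E2 <- T2 / 2 * rchisq(n, df = 1)
  delta <- (1 / T1 - 1 / T2) * (E1 - E2)
  analytic <- mean(pmin(1, exp(delta)))
  empirical <- mean(replica_swap(E1, E2, T1, T2, u = runif(n)))
  expect_lt(abs(empirical - analytic), 0.01)
})

test_that("run_remc is bit-reproducible and degenerates to annealed MC at 1 replica", {
  rs <- scaffold_restraints(case, seed = 1)
  t1 <- run_remc(case, em, rs, tiny)
  t2 <- run_remc(case, em, rs, tiny)
  expect_identical(t1$snapshots, t2$snapshots)
  expect_identical(t1$energies, t2$energies)
  one <- remc_schedule("quick", n_replicas = 1, n_macrocycles = 3,
                       steps_per_cycle = 10, seed = 2)
  tr1 <- run_remc(case, em, rs, one)
  expect_equal(length(tr1$snapshots), 3)
  expect_true(all(is.finite(tr1$energies)))
})

test_that("every stored snapshot satisfies the chain and excluded-volume invariants", {
  rs <- scaffold_restraints(case, seed = 1)
  tr <- run_remc(case, em, rs, tiny)
  for (s in seq_along(tr$snapshots)) {
    conf <- lattice_conf(tr$sequence, tr$snapshots[[s]], tr$spacing, tr$origin)
    expect_true(isTRUE(validate_conf(conf, vs)))
    expect_true(is.finite(tr$energies[s]))
  }
})

test_that("annealing drives snapshot energies downward on the fixture", {
  rs <- scaffold_restraints(case, seed = 1)
  sch <- remc_schedule("quick", n_replicas = 3, n_macrocycles = 12,
                       steps_per_cycle = 30, seed = 5)
  tr <- run_remc(case, em, rs, sch)
  rho <- suppressWarnings(cor(seq_along(tr$energies), tr$energies,
                              method = "spearman"))
  expect_lt(rho, 0)
})

test_that("restraint satisfaction does not degrade along the trajectory", {
  rs <- scaffold_restraints(case, seed = 1)
  sch <- remc_schedule("quick", n_replicas = 3, n_macrocycles = 12,
                       steps_per_cycle = 30, seed = 6)
  tr <- run_remc(case, em, rs, sch)
  frac <- vapply(seq_along(tr$snapshots), function(s) {
    xyz <- snapshot_coords(tr, s)
    d <- sqrt(rowSums((xyz[rs$i, ] - xyz[rs$j, ])^2))
    mean(abs(d - rs$d0) <= rs$tol)
  }, 0)
  rho <- suppressWarnings(cor(seq_along(frac), frac, method = "spearman"))
  expect_gte(rho, 0)
})

test_that("repeats use distinct streams and preserve ordering tags", {
  rs <- scaffold_restraints(case, seed = 1)
  trs <- run_repeats(case, em, rs, tiny, n_repeats = 3)
  expect_length(trs, 3)
  expect_equal(vapply(trs, function(t) t$run_id, 0L), 1:3)
  expect_equal(length(unique(vapply(trs, function(t) t$seed, 0L))), 3)
  expect_false(identical(trs[[1]]$snapshots, trs[[2]]$snapshots))
  one <- run_repeats(case, em, rs, tiny, n_repeats = 1)
  expect_length(one, 1)
})

test_that("a three-state toy chain driven by the metropolis rule reaches Boltzmann", {
  # states with energies 0, 1, 2; symmetric proposals between all pairs
  E <- c(0, 1, 2); Temp <- 1
  set.seed(9)
  n <- 1e5
  state <- 1L
  counts <- c(0L, 0L, 0L)
  us <- runif(n); props <- sample.int(2L, n, replace = TRUE)
  for (t in seq_len(n)) {
    cand <- ((state - 1L + props[t]) %% 3L) + 1L
    if (metropolis_accept(E[cand] - E[state], Temp, u = us[t])) state <- cand
    counts[state] <- counts[state] + 1L
  }
  p_emp <- counts / n
  p_bol <- exp(-E / Temp) / sum(exp(-E / Temp))
  se <- sqrt(p_bol * (1 - p_bol) / n) * 3     # ~3 sigma, ignoring autocorrelation
  expect_true(all(abs(p_emp - p_bol) < pmax(se * 10, 0.01)))
})
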