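test_that("kabsch superposition recovers exact fits", {
  set.seed(1)
  P <- matrix(rnorm(18), 6)
  fit <- kabsch_superpose(P, P)
  expect_equal(fit$rmsd, 0, tolerance = 1e-12)
  expect_equal(fit$rotation, diag(3), tolerance = 1e-9)
  th <- 0.7
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  Q <- P %*% t(R) + matrix(c(1, 2, 3), 6, 3, byrow = TRUE)
  expect_equal(kabsch_superpose(P, Q)$rmsd, 0, tolerance = 1e-12)
  expect_error(kabsch_superpose(P, P[-1, ]), "size")
})

test_that("kabsch rmsd agrees with the quaternion method on random point sets", {
  set.seed(7)
  for (i in 1:100) {
    P <- matrix(rnorm(18), 6)
    Q <- matrix(rnorm(18), 6)
    expect_equal(kabsch_superpose(P, Q)$rmsd, quaternion_rmsd(P, Q),
                 tolerance = 1e-9)
  }
})

test_that("kabsch excludes reflections", {
  set.seed(3)
  P <- matrix(rnorm(15), 5)
  Q <- P
  Q[, 1] <- -Q[, 1]                 # mirror image
  fit <- kabsch_superpose(P, Q)
  expect_equal(det(fit$rotation), 1, tolerance = 1e-9)
  expect_gt(fit$rmsd, 1e-3)         # cannot be matched by a proper rotation
})

test_that("loop cRMSD is zero at identity and exact for a rigid loop shift", {
  fx <- hlh_case()$fx
  nat <- ca_coords(fx$structure)
  expect_equal(loop_crmsd(nat, nat, fx$loopspec), 0, tolerance = 1e-12)
  shifted <- nat
  idx <- 16:19
  shifted[idx, ] <- shifted[idx, ] + matrix(c(1, 0, 0), 4, 3, byrow = TRUE)
  expect_equal(loop_crmsd(shifted, nat, fx$loopspec), 1.0, tolerance = 1e-9)
  # invariance under a rigid motion applied jointly to the model
  R <- cube_rotations()[[9]]
  moved <- shifted %*% t(R) + matrix(c(4, -2, 8), nrow(nat), 3, byrow = TRUE)
  rownames(moved) <- rownames(nat)
  expect_equal(loop_crmsd(moved, nat, fx$loopspec), 1.0, tolerance = 1e-9)
})

test_that("loop cRMSD equals the explicit superpose-then-measure composition", {
  fx <- hlh_case()$fx
  nat <- ca_coords(fx$structure)
  set.seed(5)
  model <- nat + matrix(rnorm(length(nat), sd = 0.4), nrow(nat))
  rownames(model) <- rownames(nat)
  idx <- 16:19
  sc <- setdiff(seq_len(nrow(nat)), idx)
  fit <- kabsch_superpose(model[sc, ], nat[sc, ])
  moved <- sweep(sweep(model, 2, fit$center_p) %*% fit$rotation, 2,
                 fit$center_q, "+")
  byhand <- sqrt(mean(rowSums((moved[idx, ] - nat[idx, ])^2)))
  expect_equal(loop_crmsd(model, nat, fx$loopspec), byhand, tolerance = 1e-12)
})

test_that("bin statistics reproduce hand-computed means and conserve counts", {
  recs <- data.frame(
    case_id = paste0("c", 1:6),
    method = c("cabs", "cabs", "cabs", "cabs", "hybrid", "hybrid"),
    length = c(5, 5, 10, 20, 5, 20),
    top_crmsd = c(1.0, 2.0, 4.0, 8.0, 1.0, 7.0),
    best_crmsd = c(0.5, 1.5, 2.0, 5.0, 0.8, 6.0))
  b <- bin_statistics(recs)
  expect_equal(sum(b$n), nrow(recs))
  expect_equal(b$mean_top[b$bin == "4-6" & b$method == "cabs"], 1.5)
  expect_equal(b$mean_best[b$bin == "4-6" & b$method == "cabs"], 1.0)
  expect_equal(b$mean_top[b$bin == "7-12" & b$method == "cabs"], 4.0)
  expect_equal(b$mean_top[b$bin == "16-25" & b$method == "hybrid"], 7.0)
  # single record: its bin mean is the value itself
  one <- recs[1, ]
  expect_equal(bin_statistics(one)$mean_top, 1.0)
  # identical records: mean equals the common value
  same <- recs[c(1, 1, 1), ]
  expect_equal(bin_statistics(same)$mean_top, 1.0)
})

test_that("lengths outside every bin are dropped with a warning", {
  recs <- data.frame(case_id = c("a", "b"), method = "m",
                     length = c(5, 14), top_crmsd = c(1, 2),
                     best_crmsd = c(1, 2))
  expect_warning(b <- bin_statistics(recs), "outside")
  expect_equal(sum(b$n), 1)
})

test_that("paired t-test matches the textbook formula", {
  a <- c(2.1, 3.4, 1.9, 4.2, 2.8, 3.3, 2.2, 3.9)
  b <- c(1.8, 3.9, 2.0, 3.6, 2.2, 3.1, 2.5, 3.0)
  r <- paired_t_test(a, b)
  d <- a - b
  t_byhand <- mean(d) / (sd(d) / sqrt(length(d)))
  p_byhand <- 2 * pt(-abs(t_byhand), df = length(d) - 1)
  expect_equal(r$t, t_byhand, tolerance = 1e-12)
  expect_equal(r$p, p_byhand, tolerance = 1e-12)
  expect_equal(r$df, 7)
})

test_that("paired t-test handles identical and degenerate inputs", {
  a <- c(1, 2, 3, 4)
  r <- paired_t_test(a, a)
  expect_equal(r$t, 0)
  expect_equal(r$p, 1)
  expect_error(paired_t_test(a + 1, a), "zero variance")
  expect_error(paired_t_test(1, 2))
})
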