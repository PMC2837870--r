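vs <- build_vector_set()

test_that("vector-set enumeration matches forced counts and symmetry", {
  expect_equal(nrow(vs$vectors), 800)
  expect_equal(nrow(build_vector_set(window = c(1, 1))$vectors), 6)
  expect_equal(nrow(build_vector_set(window = c(2, 2))$vectors), 12)
  expect_error(build_vector_set(window = c(5, 4)))
  # bond lengths lie in a band around 3.78 A
  lens <- sqrt(rowSums(vs$vectors^2)) * vs$spacing
  expect_true(all(lens >= 3.28 & lens <= 4.28))
  # closed under the full cube point group (permutations and sign flips)
  key <- function(m) sort(paste(m[, 1], m[, 2], m[, 3]))
  k0 <- key(vs$vectors)
  for (R in cube_rotations()[c(1, 5, 9, 17)])
    expect_identical(key(vs$vectors %*% t(R)), k0)
  expect_identical(key(-vs$vectors), k0)
})

test_that("vector ids form a bijection", {
  ids <- vector_id(vs, vs$vectors)
  expect_identical(ids, seq_len(800))
  expect_equal(vector_id(vs, c(100, 0, 0)), 0L)
})

test_that("a trace already on admissible lattice vertices projects exactly", {
  conf <- helix_conf(10)
  lifted <- lift_to_cartesian(conf)
  p2 <- project_chain(lifted, vs)
  expect_equal(p2$rmsd, 0, tolerance = 1e-9)
  expect_equal(lift_to_cartesian(p2$conf), lifted, tolerance = 1e-9)
})

test_that("ideal helix projects with admissible bonds and rmsd below 0.5 A", {
  h <- make_helix(20)
  p <- project_chain(h, vs)
  expect_true(isTRUE(validate_conf(p$conf, vs)))
  expect_lt(p$rmsd, 0.5)
  # reported rmsd equals the lift-vs-input deviation by definition
  lifted <- lift_to_cartesian(p$conf)
  expect_equal(sqrt(mean(rowSums((lifted - h)^2))), p$rmsd, tolerance = 1e-12)
})

test_that("projection error never exceeds nearest-vertex rounding plus one unit", {
  for (tr in synthetic_trace_suite(6, seed = 11)) {
    p <- project_chain(tr, vs)
    err <- abs(lift_to_cartesian(p$conf) - tr)
    expect_true(all(err <= 1.5 * vs$spacing + 1e-9))
  }
})

test_that("projection is idempotent", {
  tr <- synthetic_trace_suite(3, seed = 5)[[3]]
  p1 <- project_chain(tr, vs)
  p2 <- project_chain(lift_to_cartesian(p1$conf), vs)
  expect_equal(p2$rmsd, 0, tolerance = 1e-9)
  expect_equal(lift_to_cartesian(p2$conf), lift_to_cartesian(p1$conf),
               tolerance = 1e-9)
})

test_that("chain breaks are rejected with the offending position", {
  h <- make_helix(10)
  h[6, ] <- h[6, ] + 10
  expect_error(project_chain(h, vs), "position")
})

test_that("lift is multiplication by spacing plus origin", {
  conf <- lattice_conf("AA", rbind(c(0, 0, 0), c(7, 0, 0)), spacing = 0.61)
  expect_equal(lift_to_cartesian(conf),
               rbind(c(0, 0, 0), c(4.27, 0, 0)))
  conf1 <- lattice_conf("A", matrix(0L, 1, 3), spacing = 0.61)
  expect_equal(lift_to_cartesian(conf1), matrix(0, 1, 3))
})

test_that("pseudo-atoms: glycine side chain sits on CA, midpoints exact", {
  conf <- lattice_conf("GAG", rbind(c(0, 0, 0), c(7, 0, 0), c(7, 6, 3)),
                       spacing = 0.61)
  pa <- rebuild_pseudoatoms(conf)
  ca <- lift_to_cartesian(conf)
  expect_equal(pa$sc[1, ], unname(ca[1, ]))
  expect_equal(pa$sc[3, ], unname(ca[3, ]))
  expect_equal(pa$mid[1, ], c(2.135, 0, 0))
  expect_equal(pa$mid, (ca[-3, ] + ca[-1, ]) / 2, ignore_attr = TRUE)
  # Cbeta at the canonical distance from CA
  expect_equal(sqrt(sum((pa$cb[2, ] - ca[2, ])^2)), 1.53, tolerance = 1e-9)
})

test_that("geometry-table lookups are deterministic and error on bad keys", {
  gt <- build_geometry_table(vs)
  g1 <- lookup_geometry(gt, 10, 20, "L")
  g2 <- lookup_geometry(gt, 10, 20, "L")
  expect_identical(g1, g2)
  expect_equal(sqrt(sum(g1$cb^2)), 1.53, tolerance = 1e-9)
  expect_error(lookup_geometry(gt, 0, 20, "L"), "bond-id pair")
  expect_error(lookup_geometry(gt, 10, 9999, "L"), "bond-id pair")
  expect_error(lookup_geometry(gt, 10, 20, "Z"), "residue type")
  # same id pair twice in one chain gives identical offsets: direct check
  # that the serialized table is a pure function of (id1, id2, restype)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_geometry_table(gt, f, pairs = rbind(c(10, 20), c(10, 20)),
                       restypes = c("A", "G"))
  tab <- read.table(f, header = TRUE, sep = "\t")
  expect_equal(tab[1:2, -(1:3)], tab[3:4, -(1:3)], ignore_attr = TRUE)
  expect_equal(unname(unlist(tab[tab$restype == "G", c("sc_dx","sc_dy","sc_dz")][1, ])),
               c(0, 0, 0))
})
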