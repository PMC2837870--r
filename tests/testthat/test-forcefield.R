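em <- default_energy_model()
vs <- build_vector_set()

test_that("a two-residue chain has only short-range terms (here zero windows)", {
  conf <- lattice_conf("AA", rbind(c(0, 0, 0), c(7, 0, 0)))
  comp <- energy_components(conf, em)
  expect_equal(unname(comp["excluded_volume"]), 0)
  expect_equal(unname(comp["contact"]), 0)
  expect_equal(unname(comp["hbond"]), 0)
  expect_equal(unname(comp["total"]),
               unname(comp["short_generic"] + comp["short_seq"]))
})

test_that("coincident non-bonded CAs trigger the +Inf hard-core sentinel", {
  conf <- lattice_conf("AAA", rbind(c(0, 0, 0), c(7, 0, 0), c(0, 0, 0)))
  expect_identical(excluded_volume(conf, em), Inf)
  expect_identical(energy_total(conf, em), Inf)
})

test_that("energy_total equals the weighted sum of its terms", {
  for (seed in 1:5) {
    conf <- random_conf(20, seed)
    comp <- energy_components(conf, em)
    if (!is.finite(comp["total"])) next
    w <- em$weights
    expect_equal(unname(comp["total"]),
                 unname(w["contact"] * comp["contact"] +
                        w["hbond"] * comp["hbond"] +
                        w["short"] * (comp["short_generic"] + comp["short_seq"])),
                 tolerance = 1e-9)
  }
})

test_that("excluded volume matches a brute-force pair scan", {
  for (seed in 1:6) {
    conf <- random_conf(30, seed)
    expect_identical(excluded_volume(conf, em), bf_excluded_volume(conf, em))
  }
  # extended chain, all pairs far apart
  ext <- lattice_conf(strrep("A", 10),
                      cbind(7L * (0:9), 0L, 0L))
  expect_identical(excluded_volume(ext, em), 0)
})

test_that("side-chain contacts match brute-force enumeration", {
  found_nonzero <- FALSE
  for (seed in 1:8) {
    conf <- random_conf(25, seed)
    if (!is.finite(energy_total(conf, em))) next
    e <- pair_contact_energy(conf, em)
    expect_equal(e, bf_contact_energy(conf, em), tolerance = 1e-9)
    if (e != 0) found_nonzero <- TRUE
  }
  expect_true(found_nonzero)
})

test_that("two hydrophobic side chains inside the well score -eps once", {
  # straight sparse chain, then bring two L side chains into range:
  # residues far apart in sequence, CA ~5 A apart
  ca <- rbind(c(0,0,0), c(7,0,0), c(14,0,0), c(14,7,0), c(14,14,0),
              c(7,14,0), c(0,14,0))
  conf <- lattice_conf("LGGGGGL", ca)
  e <- pair_contact_energy(conf, em)
  expect_equal(e, bf_contact_energy(conf, em), tolerance = 1e-9)
  # all pairs beyond r_max -> 0
  far <- lattice_conf(strrep("L", 5), cbind(7L * (0:4), 0L, 0L))
  expect_equal(pair_contact_energy(far, em), 0)
})

test_that("deepening eps strictly lowers the contact energy when contacts exist", {
  conf <- helix_conf(14)
  conf$sequence <- strrep("L", 14)
  e1 <- pair_contact_energy(conf, em)
  em2 <- em
  em2$eps <- em$eps * 2
  e2 <- pair_contact_energy(conf, em2)
  expect_lt(e1, 0)
  expect_lt(e2, e1)
})

test_that("registered parallel strands give 4 H-bonds and 3 cooperative bonuses", {
  # two parallel extended 4-residue strands 4.88 A apart (registered pairs
  # (i, i+8)); the intervening residues continue along x far away so their
  # geometry contributes no bonds and leaves the strand tangents clean
  ca <- rbind(cbind(10L * (0:3), 0L, 0L),          # strand 1
              cbind(40L + 10L * (0:3), 0L, 0L),    # spacer, far downstream
              cbind(10L * (0:3), 8L, 0L))          # strand 2, parallel
  conf <- lattice_conf(strrep("A", 12), ca, spacing = 0.61)
  xyz <- lift_to_cartesian(conf)
  d <- sqrt(rowSums((xyz[1:4, ] - xyz[9:12, ])^2))
  expect_true(all(d > em$hb_lo & d < em$hb_hi))
  e <- hbond_energy(conf, em)
  expect_equal(e, -(4 * em$e_hb + 3 * em$e_coop), tolerance = 1e-9)
})

test_that("a fully extended isolated chain has zero H-bond energy", {
  ext <- lattice_conf(strrep("A", 12), cbind(7L * (0:11), 0L, 0L))
  expect_equal(hbond_energy(ext, em), 0)
})

test_that("every term is invariant under lattice-preserving rigid motions", {
  conf <- random_conf(18, seed = 3)
  ref <- energy_components(conf, em)
  for (R in cube_rotations()[c(2, 7, 13)]) {
    moved <- conf
    moved$ca <- conf$ca %*% t(R) + matrix(c(5L, -3L, 11L), nrow(conf$ca), 3,
                                          byrow = TRUE)
    storage.mode(moved$ca) <- "integer"
    expect_equal(energy_components(moved, em), ref, tolerance = 1e-9)
  }
})

test_that("ideal helix windows sit in the generic table's minimum band", {
  conf <- helix_conf(12)
  # every r13 window of the projected helix must score the table minimum
  ca <- lift_to_cartesian(conf)
  r13 <- sqrt(rowSums((ca[1:10, ] - ca[3:12, ])^2))
  bins <- pmin(pmax(floor((r13 - em$r13_lo) / em$r13_step) + 1, 1),
               length(em$r13_gen))
  expect_true(all(em$r13_gen[bins] == min(em$r13_gen)))
})

test_that("a left-handed helix scores strictly worse than right-handed", {
  h <- make_helix(14)
  left <- h
  left[, 1] <- -left[, 1]           # mirror: reverses chirality
  pr <- project_chain(h, vs)
  pl <- project_chain(left, vs)
  er <- short_range_energy(pr$conf, em)
  el <- short_range_energy(pl$conf, em)
  expect_lt(er, el)
})

test_that("a compact fixture scores below its fully extended conformer", {
  fx <- hlh_case()$fx
  p <- project_chain(fx$coords, vs, sequence = structure_sequence(fx$structure))
  compact <- energy_total(p$conf, em)
  n <- nrow(fx$coords)
  ext <- lattice_conf(structure_sequence(fx$structure),
                      cbind(7L * (0:(n - 1)), 0L, 0L))
  expect_lt(compact, energy_total(ext, em))
})

test_that("energy model round-trips through its config-file format", {
  f <- withr::local_tempfile(fileext = ".cfg")
  write_energy_model(em, f)
  em2 <- read_energy_model(f)
  expect_equal(em2$eps, em$eps, tolerance = 1e-6)
  expect_equal(em2$r14_gen, em$r14_gen, tolerance = 1e-6)
  expect_equal(em2$hardcore_ca, em$hardcore_ca)
  conf <- helix_conf(10)
  expect_equal(energy_total(conf, em2), energy_total(conf, em), tolerance = 1e-6)
})
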