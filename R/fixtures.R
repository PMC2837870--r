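# Deterministic generator of small idealized protein structures (CA traces)
# with known loop coordinates, so every pipeline stage is testable without
# structure downloads. Sequences are poly-alanine with leucine placed on
# inward-facing positions so that every energy term is exercised.

#' Ideal alpha-helix Calpha trace
#'
#' Rise 1.5 Angstrom per residue, radius 2.3 Angstrom, 100 degrees per
#' residue; consecutive Calpha distances come out near 3.8 Angstrom.
#'
#' @param n number of residues (>= 4)
#' @return n x 3 coordinate matrix (helix axis = z)
#' @export
make_helix <- function(n) {
  if (n < 4) stop("make_helix needs n >= 4")
  i <- seq_len(n) - 1
  th <- i * 100 * pi / 180
  cbind(2.3 * cos(th), 2.3 * sin(th), 1.5 * i)
}

#' Ideal pleated-strand Calpha trace
#'
#' Extended zigzag: 3.3 Angstrom advance per residue with alternating
#' 0.95 Angstrom lateral pleat (consecutive distance ~3.81 Angstrom).
#'
#' @param n number of residues (>= 2)
#' @return n x 3 coordinate matrix (strand direction = x)
#' @export
make_strand <- function(n) {
  if (n < 2) stop("make_strand needs n >= 2")
  i <- seq_len(n) - 1
  cbind(3.3 * i, 1.9 * (i %% 2) - 0.95, 0)
}

# circular-arc connector: m interior points on the circle through A and B
# whose arc length is (m+1) * 3.8 A, so segment chords come out near 3.8 A
# by construction; the arc bulges into the half-space of `updir`
.arc_connector <- function(A, B, m, updir, jitter = NULL) {
  cvec <- B - A
  cl <- sqrt(sum(cvec^2))
  L <- (m + 1) * 3.8
  t <- seq_len(m) / (m + 1)
  if (L <= cl * 1.02) {
    # gap nearly spans the contour length: straight interpolation
    pts <- t(vapply(t, function(tt) A + tt * cvec, numeric(3)))
  } else {
    # solve sin(x)/x = chord/arc for the half-angle x, R = L / (2x)
    f <- function(x) sin(x) / x - cl / L
    x <- stats::uniroot(f, c(1e-9, pi - 1e-9))$root
    R <- L / (2 * x)
    e1 <- cvec / cl
    u <- updir - sum(updir * e1) * e1
    u <- u / sqrt(sum(u^2))
    O <- (A + B) / 2 - (R * cos(x)) * u      # circle center below the chord
    vA <- A - O
    w1 <- vA / sqrt(sum(vA^2))
    vB <- B - O
    w2 <- vB - sum(vB * w1) * w1
    s2 <- R * sin(2 * x)           # signed: B sits at angle +2x from A
    if (abs(s2) < 1e-8) w2 <- u else w2 <- w2 / s2
    ang <- t * 2 * x
    pts <- t(vapply(ang, function(a)
      O + R * (cos(a) * w1 + sin(a) * w2), numeric(3)))
  }
  if (!is.null(jitter)) pts <- pts + jitter
  pts
}

# relax connector spacing toward the 3.6-4.0 A band with endpoints fixed
.relax_spacing <- function(pts, A, B, n_iter = 200) {
  full <- rbind(A, pts, B)
  n <- nrow(full)
  for (it in seq_len(n_iter)) {
    d <- sqrt(rowSums(diff(full)^2))
    if (all(d > 3.55 & d < 4.05)) break
    for (b in seq_len(n - 1)) {
      if (d[b] <= 3.55 || d[b] >= 4.05) {
        mid <- (full[b, ] + full[b + 1, ]) / 2
        dir <- (full[b + 1, ] - full[b, ]) / d[b]
        tgt <- 3.8
        if (b > 1) full[b, ] <- mid - dir * tgt / 2
        if (b + 1 < n) full[b + 1, ] <- mid + dir * tgt / 2
      }
    }
    full[1, ] <- A; full[n, ] <- B
  }
  full[2:(n - 1), , drop = FALSE]
}

# sequence assignment: LEU on positions whose side-chain frame points toward
# the bundle interior (negative x for the first helix etc.), ALA elsewhere,
# GLY/SER in loops
.assign_sequence <- function(n_total, elements) {
  seq1 <- rep("A", n_total)
  for (el in elements) {
    if (el$kind == "loop") {
      seq1[el$idx] <- rep(c("G", "S"), length.out = length(el$idx))
    } else {
      # every 3rd-4th position hydrophobic, crude amphipathic pattern
      pos <- el$idx[seq_along(el$idx) %% 7 %in% c(0, 3, 4)]
      seq1[pos] <- "L"
    }
  }
  paste(seq1, collapse = "")
}

#' Fixture specification
#'
#' @param topology "helix-loop-helix", "beta-hairpin" or "three-helix"
#' @param n_res residues per secondary-structure element (scalar or vector)
#' @param loop_length residues in the designated loop
#' @param seed deterministic generation seed
#' @return a `fixture_spec`
#' @export
fixture_spec <- function(topology = c("helix-loop-helix", "beta-hairpin",
                                      "three-helix"),
                         n_res = 15, loop_length = 4, seed = 1) {
  topology <- match.arg(topology)
  stopifnot(loop_length >= 1, loop_length <= 30)
  structure(list(topology = topology, n_res = n_res,
                 loop_length = loop_length, seed = as.integer(seed)),
            class = "fixture_spec")
}

#' Generate a synthetic protein structure with a designated loop
#'
#' Assembles idealized helices/strands joined by smooth coil connectors with
#' protein-like geometry (consecutive CA distances near 3.8 Angstrom, no CA
#' pair below 3.5 Angstrom), deterministic in the seed. The designated loop
#' is the connector between the first two elements.
#'
#' @param spec a `fixture_spec`
#' @return list with `structure` (an `llstructure`), `loopspec` (a
#'   `loopspec` for the designated loop) and `coords` (CA matrix)
#' @export
make_fixture <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  n_el <- switch(spec$topology, "helix-loop-helix" = 2, "beta-hairpin" = 2,
                 "three-helix" = 3)
  n_res <- rep(spec$n_res, length.out = n_el)
  m <- spec$loop_length
  total_check <- sum(n_res) + m * (n_el - 1)
  if (total_check > 120) stop("fixture too large (> 120 residues)")

  build <- function(jit_scale) with_seed(spec$seed, {
    if (spec$topology == "beta-hairpin") {
      s1 <- make_strand(n_res[1])
      # antiparallel partner 5.0 A away in y, running back along -x, with
      # the pleat phased so every registered cross-strand pair sits at 5 A
      n2 <- n_res[2]
      i2 <- seq_len(n2)
      s2 <- cbind(3.3 * (n2 - i2),
                  1.9 * ((n2 - i2) %% 2) - 0.95 + 5.0,
                  0)
      A <- s1[n_res[1], ]; B <- s2[1, ]
      up <- c(0.3, 0.2, 1); up <- up / sqrt(sum(up^2))
      jit <- matrix(runif(3 * m, -jit_scale, jit_scale), m, 3)
      conn <- .relax_spacing(.arc_connector(A, B, m, up, jit), A, B)
      coords <- rbind(s1, conn, s2)
      elements <- list(list(kind = "strand", idx = seq_len(n_res[1])),
                       list(kind = "loop", idx = n_res[1] + seq_len(m)),
                       list(kind = "strand", idx = n_res[1] + m + seq_len(n_res[2])))
    } else {
      nh <- n_el
      helices <- list()
      sep <- 9.5                      # packing distance between helix axes
      for (h in seq_len(nh)) {
        hx <- make_helix(n_res[h])
        if (h %% 2 == 0) hx <- cbind(hx[, 1], hx[, 2], max(hx[, 3]) - hx[, 3])
        hx[, 1] <- hx[, 1] + (h - 1) * sep
        helices[[h]] <- hx
      }
      coords <- helices[[1]]
      elements <- list(list(kind = "helix", idx = seq_len(n_res[1])))
      for (h in 2:nh) {
        A <- coords[nrow(coords), ]
        B <- helices[[h]][1, ]
        up <- if (h %% 2 == 0) c(0.2, 0.4, 1) else c(0.2, 0.4, -1)
        up <- up / sqrt(sum(up^2))
        mh <- if (h == 2) m else max(3, m)
        jit <- matrix(runif(3 * mh, -jit_scale, jit_scale), mh, 3)
        conn <- .relax_spacing(.arc_connector(A, B, mh, up, jit), A, B)
        elements[[length(elements) + 1L]] <-
          list(kind = "loop", idx = nrow(coords) + seq_len(mh))
        coords <- rbind(coords, conn)
        elements[[length(elements) + 1L]] <-
          list(kind = "helix", idx = nrow(coords) + seq_len(n_res[h]))
        coords <- rbind(coords, helices[[h]])
      }
    }
    list(coords = coords, elements = elements)
  })

  got <- NULL
  for (jit_scale in c(0.15, 0.1, 0.05, 0)) {
    cand <- build(jit_scale)
    d2 <- as.matrix(dist(cand$coords))
    diag(d2) <- Inf
    d2[abs(row(d2) - col(d2)) == 1] <- Inf
    bonds <- sqrt(rowSums(diff(cand$coords)^2))
    if (min(d2) >= 3.5 && all(bonds > 3.4 & bonds < 4.2)) { got <- cand; break }
  }
  if (is.null(got)) stop("fixture assembly clash after retries")

  n <- nrow(got$coords)
  seq1 <- .assign_sequence(n, got$elements)
  seq3 <- .aa1to3[strsplit(seq1, "")[[1]]]
  atoms <- data.frame(elety = "CA", resid = seq3, chain = "A",
                      resno = seq_len(n), insert = "",
                      x = got$coords[, 1], y = got$coords[, 2],
                      z = got$coords[, 3], o = 1, stringsAsFactors = FALSE)
  st <- new_structure(sprintf("fix_%s_%d", gsub("-", "", spec$topology),
                              spec$seed), atoms)
  loop_idx <- got$elements[[2]]$idx
  list(structure = st,
       loopspec = loop_spec(st$id, min(loop_idx), max(loop_idx)),
       coords = got$coords)
}

#' A suite of synthetic protein-like Calpha traces
#'
#' Deterministic collection of idealized helices, strands and assembled
#' fixtures (20-80 residues) used to measure lattice projection accuracy.
#'
#' @param n number of traces
#' @param seed base seed
#' @return list of coordinate matrices
#' @export
synthetic_trace_suite <- function(n = 50, seed = 1) {
  out <- vector("list", n)
  for (i in seq_len(n)) {
    kind <- (i - 1) %% 3
    size <- 20 + ((i * 7) %% 61)
    out[[i]] <- with_seed(seed + i, {
      base <- if (kind == 0) make_helix(size)
              else if (kind == 1) make_strand(max(size %/% 2, 10))
              else make_fixture(fixture_spec("helix-loop-helix",
                                             n_res = max(8, size %/% 3),
                                             loop_length = 4, seed = seed + i))$coords
      # random rigid orientation so lattice axes are not privileged
      th <- runif(3, 0, 2 * pi)
      Rx <- rbind(c(1,0,0), c(0,cos(th[1]),-sin(th[1])), c(0,sin(th[1]),cos(th[1])))
      Ry <- rbind(c(cos(th[2]),0,sin(th[2])), c(0,1,0), c(-sin(th[2]),0,cos(th[2])))
      Rz <- rbind(c(cos(th[3]),-sin(th[3]),0), c(sin(th[3]),cos(th[3]),0), c(0,0,1))
      base %*% (Rx %*% Ry %*% Rz) + matrix(runif(3, -2, 2), nrow(base), 3,
                                           byrow = TRUE)
    })
  }
  out
}
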