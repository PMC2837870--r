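#' Build the lattice virtual-bond vector set
#'
#' The Calpha trace lives on a fine cubic lattice; a virtual Calpha-Calpha
#' bond is any integer vector whose squared length (in lattice units) lies
#' in a window chosen so that, at the default 0.61 Angstrom spacing, bond
#' lengths fluctuate around the canonical 3.78 Angstrom. The default window
#' `[29, 49]` enumerates exactly 800 vectors (3.28-4.27 Angstrom).
#'
#' Vectors are ordered deterministically (lexicographic by x, then y, then
#' z), defining the id index 1..|vectors|.
#'
#' @param spacing lattice spacing in Angstrom per lattice unit
#' @param window integer length-2 vector `(smin, smax)`: inclusive bounds on
#'   the squared length in lattice units
#' @return a `vector_set`: list with `spacing`, `window`, `vectors` (integer
#'   m x 3 matrix, row i = vector id i)
#' @export
build_vector_set <- function(spacing = 0.61, window = c(29L, 49L)) {
  smin <- as.integer(window[1]); smax <- as.integer(window[2])
  if (is.na(smin) || is.na(smax) || smin <= 0L || smax < smin)
    stop("window must be positive integers with smin <= smax")
  m <- as.integer(floor(sqrt(smax)))
  g <- as.matrix(expand.grid(x = -m:m, y = -m:m, z = -m:m))
  n2 <- rowSums(g^2)
  keep <- n2 >= smin & n2 <= smax
  if (!any(keep)) stop("empty vector-set window")
  v <- g[keep, , drop = FALSE]
  v <- v[order(v[, 1], v[, 2], v[, 3]), , drop = FALSE]
  dimnames(v) <- NULL
  storage.mode(v) <- "integer"
  structure(list(spacing = spacing, window = c(smin, smax), vectors = v),
            class = "vector_set")
}

#' @export
print.vector_set <- function(x, ...) {
  cat(sprintf("<vector_set: %d vectors, |v|^2 in [%d,%d], spacing %.2f A (%.2f-%.2f A)>\n",
              nrow(x$vectors), x$window[1], x$window[2], x$spacing,
              sqrt(x$window[1]) * x$spacing, sqrt(x$window[2]) * x$spacing))
  invisible(x)
}

#' Id of a lattice vector within a vector set (0 if not admissible)
#' @param vset a `vector_set`
#' @param v integer 3-vector or n x 3 matrix
#' @return integer id(s) in 1..|vectors|, or 0
#' @export
vector_id <- function(vset, v) {
  v <- matrix(as.integer(v), ncol = 3)
  key <- paste(v[, 1], v[, 2], v[, 3])
  tab <- paste(vset$vectors[, 1], vset$vectors[, 2], vset$vectors[, 3])
  id <- match(key, tab)
  id[is.na(id)] <- 0L
  id
}

#' Construct a lattice conformation
#'
#' @param sequence 1-letter amino-acid string of length n
#' @param ca integer n x 3 matrix of Calpha lattice positions
#' @param spacing Angstrom per lattice unit
#' @param origin rigid offset in Angstrom added when lifting to Cartesian
#' @return a `lattice_conf`
#' @export
lattice_conf <- function(sequence, ca, spacing = 0.61, origin = c(0, 0, 0)) {
  ca <- matrix(as.integer(round(ca)), ncol = 3)
  stopifnot(nchar(sequence) == nrow(ca))
  structure(list(sequence = sequence, ca = ca, spacing = spacing,
                 origin = as.numeric(origin)), class = "lattice_conf")
}

#' @export
print.lattice_conf <- function(x, ...) {
  cat(sprintf("<lattice_conf: %d residues, spacing %.2f A>\n",
              nrow(x$ca), x$spacing))
  invisible(x)
}

#' Validate the chain invariant of a lattice conformation
#'
#' Every consecutive Calpha-Calpha bond must be an admissible vector and no
#' two non-bonded Calpha may come closer than the hard-core distance.
#'
#' @param conf a `lattice_conf`
#' @param vset the `vector_set`
#' @param hardcore_ca hard-core Calpha diameter in Angstrom
#' @return TRUE, or a character description of the first violation
#' @export
validate_conf <- function(conf, vset, hardcore_ca = 3.3) {
  ca <- conf$ca
  n <- nrow(ca)
  if (n >= 2) {
    ids <- vector_id(vset, diff(ca))
    if (any(ids == 0L))
      return(sprintf("bond %d not in vector set", which(ids == 0L)[1]))
  }
  if (n >= 3) {
    d2 <- as.matrix(dist(ca * conf$spacing))^2
    d2[abs(row(d2) - col(d2)) <= 1] <- Inf
    if (any(d2 < hardcore_ca^2)) {
      w <- which(d2 < hardcore_ca^2, arr.ind = TRUE)[1, ]
      return(sprintf("hard-core clash between residues %d and %d", w[1], w[2]))
    }
  }
  TRUE
}

# internal: greedy projection of one segment at a given offset (Angstrom)
.project_segment <- function(coords, vset, offset, prev_anchor = NULL,
                             next_anchor = NULL, topk = 8L) {
  tgt <- sweep(coords, 2, -offset) / vset$spacing  # (x + offset)/spacing
  cpp_project_segment(tgt, vset$vectors,
                      if (is.null(prev_anchor)) integer(0) else as.integer(prev_anchor),
                      if (is.null(next_anchor)) integer(0) else as.integer(next_anchor),
                      as.integer(topk))
}

# sub-lattice rigid offsets searched during projection (Angstrom)
.projection_offsets <- function(spacing, grid = 5L) {
  s <- (seq_len(grid) - 1) / grid * spacing
  as.matrix(expand.grid(x = s, y = s, z = s))
}

#' Project a Calpha trace onto the lattice
#'
#' Fits a rigid sub-lattice shift of the input (grid search over 5^3
#' offsets), anchors the first residue at its nearest vertex and assigns
#' each subsequent virtual bond greedily to the admissible vector minimizing
#' the cumulative squared error, with a one-bond lookahead.
#'
#' @param coords numeric n x 3 Calpha coordinates in Angstrom (n >= 3;
#'   consecutive distances must be within 2.5-4.8 Angstrom)
#' @param vset a `vector_set`
#' @param sequence optional 1-letter sequence (default poly-A)
#' @param grid sub-lattice grid per axis for the rigid-offset search
#' @param topk lookahead beam width
#' @return list with `conf` (a `lattice_conf` whose `origin` holds the
#'   fitted shift) and `rmsd` (Angstrom, input vs lifted lattice trace)
#' @export
project_chain <- function(coords, vset, sequence = NULL, grid = 5L, topk = 8L) {
  coords <- as.matrix(coords)
  n <- nrow(coords)
  if (n < 3) stop("project_chain needs at least 3 residues")
  d <- sqrt(rowSums(diff(coords)^2))
  if (any(d < 2.5 | d > 4.8))
    stop(sprintf("chain break: consecutive CA distance %.2f A at position %d",
                 d[which(d < 2.5 | d > 4.8)[1]], which(d < 2.5 | d > 4.8)[1]))
  offs <- .projection_offsets(vset$spacing, grid)
  best <- NULL
  for (r in seq_len(nrow(offs))) {
    off <- offs[r, ]
    pr <- .project_segment(coords, vset, off, topk = topk)
    if (!pr$ok) next
    if (is.null(best) || pr$sumsq < best$sumsq)
      best <- list(sumsq = pr$sumsq, pos = pr$pos, off = off)
  }
  if (is.null(best)) stop("projection failed for every rigid offset")
  # origin maps lattice back to input frame: x = ca*spacing + origin
  origin <- -best$off
  if (is.null(sequence)) sequence <- paste(rep("A", n), collapse = "")
  conf <- lattice_conf(sequence, best$pos, vset$spacing, origin)
  lifted <- lift_to_cartesian(conf)
  rmsd <- sqrt(mean(rowSums((lifted - coords)^2)))
  list(conf = conf, rmsd = rmsd)
}

#' Lift a lattice conformation to Cartesian Calpha coordinates
#'
#' @param conf a `lattice_conf`
#' @return numeric n x 3 matrix in Angstrom: `ca * spacing + origin`
#' @export
lift_to_cartesian <- function(conf) {
  sweep(conf$ca * conf$spacing, 2, conf$origin, "+")
}

# ---------------------------------------------------------------------------
# Geometry table: local-frame offsets of Cbeta and the side-chain center for
# the central residue of every 3-Calpha fragment, keyed by the ids of the two
# flanking virtual bonds and the residue type. Our table is idealized and
# closed-form (see the methods vignette): entries are generated on demand and
# cached; write_geometry_table() serializes any subset to the 6-column text
# format (id1, id2, restype, dx, dy, dz per pseudo-atom).
# ---------------------------------------------------------------------------

# canonical Calpha -> side-chain-center distances (Angstrom), idealized
.sc_distance <- c(A=1.53, R=4.1, N=2.5, D=2.5, C=2.1, Q=3.1, E=3.1, G=0,
                  H=3.1, I=2.3, L=2.6, K=3.5, M=2.9, F=3.4, P=1.9, S=1.9,
                  T=1.9, W=3.9, Y=3.8, V=2.0)

#' Build the pseudo-atom geometry table
#'
#' @param vset a `vector_set`
#' @param cb_length Calpha-Cbeta distance in Angstrom
#' @return a `geometry_table` (lazy: entries computed on demand and cached)
#' @export
build_geometry_table <- function(vset, cb_length = 1.53) {
  structure(list(vset = vset, cb_length = cb_length,
                 sc_distance = .sc_distance,
                 cache = new.env(parent = emptyenv())),
            class = "geometry_table")
}

# unit direction of the pseudo-atom frame given two bond vectors (Angstrom)
.frame_direction <- function(b1, b2) {
  u1 <- b1 / sqrt(sum(b1^2)); u2 <- b2 / sqrt(sum(b2^2))
  nn <- u1 - u2
  pp <- c(u1[2]*u2[3] - u1[3]*u2[2], u1[3]*u2[1] - u1[1]*u2[3],
          u1[1]*u2[2] - u1[2]*u2[1])
  ln <- sqrt(sum(nn^2)); lp <- sqrt(sum(pp^2))
  if (ln < 1e-9 && lp < 1e-9) {
    d <- c(-u1[2], u1[1], 0)
    if (sqrt(sum(d^2)) < 1e-9) d <- c(0, -u1[3], u1[2])
    return(d / sqrt(sum(d^2)))
  }
  d <- 0.9 * (if (ln > 1e-9) nn / ln else c(0, 0, 0)) +
       0.44 * (if (lp > 1e-9) pp / lp else c(0, 0, 0))
  d / sqrt(sum(d^2))
}

#' Look up geometry-table offsets for a bond-id pair and residue type
#'
#' @param table a `geometry_table`
#' @param id1,id2 ids of the incoming and outgoing virtual bonds
#' @param restype 1-letter residue code
#' @return list with `cb` and `sc` offsets (Angstrom, relative to Calpha)
#' @export
lookup_geometry <- function(table, id1, id2, restype) {
  nv <- nrow(table$vset$vectors)
  if (id1 < 1 || id1 > nv || id2 < 1 || id2 > nv)
    stop(sprintf("no geometry-table entry for bond-id pair (%d, %d)", id1, id2))
  if (!restype %in% names(table$sc_distance))
    stop(sprintf("unknown residue type '%s'", restype))
  key <- paste0(id1, "_", id2)
  dir <- table$cache[[key]]
  if (is.null(dir)) {
    b1 <- table$vset$vectors[id1, ] * table$vset$spacing
    b2 <- table$vset$vectors[id2, ] * table$vset$spacing
    dir <- .frame_direction(b1, b2)
    assign(key, dir, envir = table$cache)
  }
  list(cb = table$cb_length * dir,
       sc = unname(table$sc_distance[restype]) * dir)
}

#' Serialize geometry-table entries to a plain-text table
#'
#' @param table a `geometry_table`
#' @param path output path
#' @param pairs integer 2-column matrix of bond-id pairs to emit
#' @param restypes residue types to emit (default all 20)
#' @export
write_geometry_table <- function(table, path, pairs,
                                 restypes = names(table$sc_distance)) {
  pairs <- matrix(as.integer(pairs), ncol = 2)
  rows <- list()
  for (r in seq_len(nrow(pairs)))
    for (rt in restypes) {
      g <- lookup_geometry(table, pairs[r, 1], pairs[r, 2], rt)
      rows[[length(rows) + 1L]] <- data.frame(
        id1 = pairs[r, 1], id2 = pairs[r, 2], restype = rt,
        cb_dx = g$cb[1], cb_dy = g$cb[2], cb_dz = g$cb[3],
        sc_dx = g$sc[1], sc_dy = g$sc[2], sc_dz = g$sc[3])
    }
  write.table(do.call(rbind, rows), path, sep = "\t", row.names = FALSE,
              quote = FALSE)
  invisible(path)
}

#' Rebuild the off-lattice pseudo-atoms of a conformation
#'
#' Bond midpoints are exact; Cbeta and side-chain centers come from the
#' geometry-table rule keyed by the two flanking virtual bonds and the
#' residue type (glycine side-chain center coincides with Calpha). Chain
#' termini copy the nearest interior residue's local frame.
#'
#' @param conf a `lattice_conf`
#' @param table a `geometry_table` (defaults to the idealized table)
#' @return list with `cb`, `sc` (n x 3) and `mid` ((n-1) x 3), Angstrom,
#'   in the lifted (origin-shifted) frame
#' @export
rebuild_pseudoatoms <- function(conf, table = NULL) {
  if (is.null(table)) table <- build_geometry_table(build_vector_set(conf$spacing))
  seq1 <- strsplit(conf$sequence, "")[[1]]
  dsc <- unname(table$sc_distance[seq1])
  if (anyNA(dsc)) stop("sequence contains unknown residue types")
  p <- cpp_pseudoatoms(conf$ca, conf$spacing, dsc)
  shift <- function(m) if (nrow(m)) sweep(m, 2, conf$origin, "+") else m
  list(cb = shift(p$cb), sc = shift(p$sc), mid = shift(p$mid))
}
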