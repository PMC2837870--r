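# Flat-bottom Calpha-Calpha distance restraints: zero penalty inside
# |d - d0| <= tol, harmonic in the excess outside. Residue indices i, j are
# 1-based positions along the modeled chain.

.new_restraint_set <- function(df, provenance) {
  if (nrow(df)) df <- df[order(df$i, df$j), , drop = FALSE]
  rownames(df) <- NULL
  stopifnot(!anyDuplicated(paste(df$i, df$j)))
  attr(df, "provenance") <- provenance
  class(df) <- c("restraint_set", class(df))
  df
}

#' @export
print.restraint_set <- function(x, ...) {
  cat(sprintf("<restraint_set: %d restraints, provenance %s>\n",
              nrow(x), attr(x, "provenance")))
  invisible(x)
}

# run a thunk with a private RNG stream, restoring global state afterwards
with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  force(expr)
}

# admissible index pairs: sequence separation >= min_sep
.candidate_pairs <- function(idx, min_sep) {
  if (length(idx) < 2) return(matrix(integer(0), ncol = 2))
  cmb <- t(combn(sort(idx), 2))
  cmb[cmb[, 2] - cmb[, 1] >= min_sep, , drop = FALSE]
}

#' Distance restraints read from the fixed scaffold
#'
#' Candidate pairs are non-loop residue pairs with sequence separation at
#' least `min_sep` and observed CA distance at most `cutoff`; the target
#' distance is the observed one. When candidates exceed `max_count` a
#' uniform random subsample (driven by `seed`) is kept. Scaffold restraints
#' are strong (10x the loop-restraint weight) so that the scaffold stays put
#' during sampling while still being formally mobile.
#'
#' @param case an `excised_case`
#' @param max_count maximum number of restraints
#' @param cutoff CA-CA distance cutoff in Angstrom
#' @param min_sep minimum sequence separation
#' @param tol flat-bottom half-width in Angstrom
#' @param weight restraint weight
#' @param seed subsampling seed
#' @return a `restraint_set` (data.frame i, j, d0, tol, weight)
#' @export
scaffold_restraints <- function(case, max_count = 500, cutoff = 12,
                                min_sep = 5, tol = 0.5, weight = 50,
                                seed = 1) {
  nat <- native_ca(case)
  sc_idx <- setdiff(seq_len(nrow(nat)), case$loop_idx)
  if (length(sc_idx) < 2) stop("scaffold has fewer than 2 coordinated residues")
  pairs <- .candidate_pairs(sc_idx, min_sep)
  if (nrow(pairs) > 0) {
    d <- sqrt(rowSums((nat[pairs[, 1], , drop = FALSE] -
                       nat[pairs[, 2], , drop = FALSE])^2))
    keep <- d <= cutoff
    pairs <- pairs[keep, , drop = FALSE]
    d <- d[keep]
  } else d <- numeric(0)
  if (nrow(pairs) > max_count) {
    sel <- with_seed(seed, sample.int(nrow(pairs), max_count))
    sel <- sort(sel)
    pairs <- pairs[sel, , drop = FALSE]
    d <- d[sel]
  }
  .new_restraint_set(
    data.frame(i = pairs[, 1], j = pairs[, 2], d0 = unname(d),
               tol = rep(tol, nrow(pairs)), weight = rep(weight, nrow(pairs))),
    "scaffold")
}

#' Consensus restraints from multiple template models (hybrid mode)
#'
#' Templates must share sequence length with the target chain. For each
#' admissible pair the target distance is the mean over templates and the
#' tolerance is `max(tol_min, sd)`; pairs whose spread exceeds the
#' divergence cap are dropped. Loop-region pairs are included: pairs
#' touching the loop get `weight_loop`, scaffold-scaffold pairs the strong
#' `weight_scaffold`.
#'
#' @param templates list of >= 2 `llstructure` objects (or n x 3 CA
#'   matrices) of the full target chain
#' @param max_count maximum number of restraints
#' @param cutoff mean-distance cutoff in Angstrom
#' @param min_sep minimum sequence separation for scaffold-scaffold pairs
#' @param min_sep_loop minimum sequence separation for pairs touching the
#'   loop (the templates' loop fragments carry the local signal, so
#'   near-anchor and loop-internal pairs are kept down to this separation)
#' @param tol_min minimum flat-bottom half-width in Angstrom
#' @param divergence_cap drop pairs with sd above this (Angstrom)
#' @param loop integer indices of the loop region, or NULL
#' @param weight_scaffold,weight_loop weights for scaffold-only and
#'   loop-touching pairs
#' @param seed subsampling seed
#' @return a `restraint_set`
#' @export
consensus_restraints <- function(templates, max_count = 500, cutoff = 12,
                                 min_sep = 5, min_sep_loop = 3,
                                 tol_min = 0.5,
                                 divergence_cap = 3, loop = NULL,
                                 weight_scaffold = 50, weight_loop = 5,
                                 seed = 1) {
  if (length(templates) < 2) stop("consensus needs at least 2 templates")
  mats <- lapply(templates, function(t)
    if (inherits(t, "llstructure")) ca_coords(t) else as.matrix(t))
  n <- nrow(mats[[1]])
  if (any(vapply(mats, nrow, 0L) != n))
    stop("templates have unequal length")
  pairs <- .candidate_pairs(seq_len(n),
                            if (is.null(loop)) min_sep else min(min_sep, min_sep_loop))
  if (!is.null(loop)) {
    touches <- pairs[, 1] %in% loop | pairs[, 2] %in% loop
    sep <- pairs[, 2] - pairs[, 1]
    pairs <- pairs[(touches & sep >= min_sep_loop) |
                   (!touches & sep >= min_sep), , drop = FALSE]
  }
  dmat <- vapply(mats, function(m)
    sqrt(rowSums((m[pairs[, 1], , drop = FALSE] -
                  m[pairs[, 2], , drop = FALSE])^2)), numeric(nrow(pairs)))
  d0 <- rowMeans(dmat)
  sdev <- apply(dmat, 1, sd)
  keep <- d0 <= cutoff & sdev <= divergence_cap
  pairs <- pairs[keep, , drop = FALSE]
  d0 <- d0[keep]; sdev <- sdev[keep]
  if (nrow(pairs) > max_count) {
    sel <- sort(with_seed(seed, sample.int(nrow(pairs), max_count)))
    pairs <- pairs[sel, , drop = FALSE]
    d0 <- d0[sel]; sdev <- sdev[sel]
  }
  touches_loop <- if (is.null(loop)) rep(FALSE, nrow(pairs)) else
    (pairs[, 1] %in% loop | pairs[, 2] %in% loop)
  .new_restraint_set(
    data.frame(i = pairs[, 1], j = pairs[, 2], d0 = unname(d0),
               tol = unname(pmax(tol_min, sdev)),
               weight = ifelse(touches_loop, weight_loop, weight_scaffold)),
    sprintf("consensus(%d templates)", length(templates)))
}

#' Flat-bottom restraint energy
#'
#' Per restraint: 0 when `|d - d0| <= tol`, else
#' `weight * (|d - d0| - tol)^2`; summed.
#'
#' @param conf a `lattice_conf`, or a numeric n x 3 CA coordinate matrix in
#'   Angstrom
#' @param restraints a `restraint_set`
#' @return numeric scalar (>= 0)
#' @export
restraint_energy <- function(conf, restraints) {
  coords <- if (inherits(conf, "lattice_conf")) lift_to_cartesian(conf) else as.matrix(conf)
  if (is.null(restraints) || nrow(restraints) == 0) return(0)
  d <- sqrt(rowSums((coords[restraints$i, , drop = FALSE] -
                     coords[restraints$j, , drop = FALSE])^2))
  ex <- pmax(0, abs(d - restraints$d0) - restraints$tol)
  sum(restraints$weight * ex^2)
}

#' Read / write restraints in the 5-column text format (i, j, d0, tol, weight)
#' @param restraints a `restraint_set`
#' @param path file path
#' @export
write_restraints <- function(restraints, path) {
  write.table(as.data.frame(restraints)[, c("i","j","d0","tol","weight")],
              path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_restraints
#' @export
read_restraints <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t")
  stopifnot(all(c("i","j","d0","tol","weight") %in% names(df)))
  .new_restraint_set(df, sprintf("file(%s)", basename(path)))
}
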