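# Benchmark evaluation: scaffold superposition, loop-only Calpha cRMSD,
# length-binned summary statistics, and the two-sample paired t-test.

#' Least-squares rigid superposition (Kabsch)
#'
#' Finds the proper rotation (reflections excluded by determinant
#' correction) and translation minimizing the RMSD mapping P onto Q.
#'
#' @param P,Q numeric n x 3 point sets (n >= 3, not all collinear)
#' @return list with `rotation` (3 x 3, applied to centered P), `center_p`,
#'   `center_q`, `translation`, `rmsd` (Angstrom). The fitted mapping is
#'   `sweep(P, 2, center_p) %*% rotation + center_q` (row-wise).
#' @export
kabsch_superpose <- function(P, Q) {
  P <- as.matrix(P); Q <- as.matrix(Q)
  if (!all(dim(P) == dim(Q))) stop("point sets differ in size")
  cp <- colMeans(P); cq <- colMeans(Q)
  Pc <- sweep(P, 2, cp); Qc <- sweep(Q, 2, cq)
  H <- crossprod(Pc, Qc)
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  D <- diag(c(1, 1, d))
  R <- s$u %*% D %*% t(s$v)
  moved <- Pc %*% R
  rmsd <- sqrt(mean(rowSums((moved - Qc)^2)))
  list(rotation = R, center_p = cp, center_q = cq,
       translation = cq - as.vector(cp %*% R), rmsd = rmsd)
}

#' Loop-only Calpha cRMSD after scaffold superposition
#'
#' Model and native are superposed on the non-loop (scaffold) Calpha and
#' the deviation is computed over the loop Calpha only.
#'
#' @param model full-chain model: an `llstructure`, `lattice_conf`, or
#'   n x 3 CA matrix sharing residue order with the native
#' @param native the native full chain (same forms accepted)
#' @param loopspec a `loopspec` (author numbering, requires structures) —
#'   or give `loop_idx` directly
#' @param loop_idx integer positions of the loop within the chain
#' @return cRMSD in Angstrom
#' @export
loop_crmsd <- function(model, native, loopspec = NULL, loop_idx = NULL) {
  get_ca <- function(x) {
    if (inherits(x, "llstructure")) ca_coords(x)
    else if (inherits(x, "lattice_conf")) lift_to_cartesian(x)
    else as.matrix(x)
  }
  mc <- get_ca(model); nc <- get_ca(native)
  if (nrow(mc) != nrow(nc))
    stop("model and native have different residue counts")
  if (is.null(loop_idx)) {
    if (is.null(loopspec)) stop("need loopspec or loop_idx")
    rn <- rownames(nc)
    if (is.null(rn)) stop("native has no residue numbering; pass loop_idx")
    loop_idx <- match(as.character(seq(loopspec$start, loopspec$end)), rn)
    if (anyNA(loop_idx)) stop("loop residues missing from the native input")
  }
  sc <- setdiff(seq_len(nrow(nc)), loop_idx)
  fit <- kabsch_superpose(mc[sc, , drop = FALSE], nc[sc, , drop = FALSE])
  moved <- sweep(sweep(mc, 2, fit$center_p) %*% fit$rotation, 2,
                 fit$center_q, "+")
  sqrt(mean(rowSums((moved[loop_idx, , drop = FALSE] -
                     nc[loop_idx, , drop = FALSE])^2)))
}

.length_bins <- list("4-6" = 4:6, "7-12" = 7:12, "16-25" = 16:25)

#' Length-binned benchmark statistics
#'
#' Aggregates evaluation records into the three loop-length bins (4-6,
#' 7-12, 16-25): mean top-model and mean best-model cRMSD per method per
#' bin. Lengths falling in no bin (13-15) are dropped with a warning.
#'
#' @param records data.frame with columns `case_id`, `method`, `length`,
#'   `top_crmsd`, `best_crmsd`
#' @return data.frame with columns `bin`, `method`, `n`, `mean_top`,
#'   `mean_best`
#' @export
bin_statistics <- function(records) {
  stopifnot(nrow(records) > 0,
            all(c("method", "length", "top_crmsd", "best_crmsd") %in% names(records)))
  binof <- rep(NA_character_, nrow(records))
  for (b in names(.length_bins))
    binof[records$length %in% .length_bins[[b]]] <- b
  if (anyNA(binof)) {
    warning(sprintf("%d record(s) with loop length outside all bins dropped",
                    sum(is.na(binof))))
    records <- records[!is.na(binof), , drop = FALSE]
    binof <- binof[!is.na(binof)]
  }
  out <- list()
  for (b in names(.length_bins)) for (m in unique(records$method)) {
    sel <- binof == b & records$method == m
    if (!any(sel)) next
    out[[length(out) + 1L]] <- data.frame(
      bin = b, method = m, n = sum(sel),
      mean_top = mean(records$top_crmsd[sel]),
      mean_best = mean(records$best_crmsd[sel]))
  }
  do.call(rbind, out)
}

#' Two-sample paired t-test
#'
#' Classic paired t on the differences (df = n - 1), as used to compare two
#' methods' cRMSD over the same benchmark cases.
#'
#' @param a,b equal-length paired numeric samples (n >= 2)
#' @return list with `t`, `p` (two-sided), `df`, `mean_diff`
#' @export
paired_t_test <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) >= 2)
  d <- a - b
  if (sd(d) == 0) {
    if (all(d == 0)) return(list(t = 0, p = 1, df = length(a) - 1, mean_diff = 0))
    stop("zero variance of paired differences: t statistic undefined")
  }
  tt <- t.test(a, b, paired = TRUE)
  list(t = unname(tt$statistic), p = tt$p.value,
       df = unname(tt$parameter), mean_diff = unname(tt$estimate))
}
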