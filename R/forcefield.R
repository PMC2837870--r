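# Reduced-model energy. All parameters are documented surrogate values: the
# term structure (hard core, square-well side-chain contacts, cooperative
# H-bonds, generic + sequence-dependent short-range bias, restraints) is the
# contract; the numbers are editable package defaults.

# residue classes for the contact well depths:
# 1 hydrophobic, 2 polar, 3 basic, 4 acidic
.contact_class <- c(A=1, V=1, L=1, I=1, M=1, F=1, W=1, C=1,
                    G=2, S=2, T=2, N=2, Q=2, Y=2, P=2, H=2,
                    K=3, R=3, D=4, E=4)

# secondary-structure propensity class (Chou-Fasman-style):
# 0 helix former (H), 1 strand former (E), 2 coil/neutral (C)
.hec_class <- c(A=0, E=0, L=0, M=0, Q=0, K=0, H=0,
                V=1, I=1, Y=1, C=1, W=1, F=1, T=1,
                G=2, P=2, S=2, N=2, D=2, R=2)

.band <- function(centers, lo, hi, value) ifelse(centers >= lo & centers <= hi, value, 0)

#' Default reduced-model energy parameters
#'
#' Returns the surrogate parameter set: hard-core diameters, square-well
#' side-chain contact parameters per residue-class pair, the cooperative
#' main-chain hydrogen-bond model, binned short-range bias tables on the
#' r13 and (chirality-signed) r14 Calpha descriptors, and per-term weights.
#' Energies are in reduced units (k_B = 1).
#'
#' @param weights named numeric: multipliers for `contact`, `hbond`,
#'   `short`, `restraint`
#' @return an `energy_model`
#' @export
default_energy_model <- function(weights = c(contact = 1, hbond = 1,
                                             short = 1, restraint = 1)) {
  eps <- matrix(0.1, 4, 4)
  eps[1, 1] <- 0.5                       # hydrophobic-hydrophobic
  eps[1, 2] <- eps[2, 1] <- 0.15
  eps[3, 4] <- eps[4, 3] <- 0.4          # salt bridge
  eps[3, 3] <- eps[4, 4] <- 0.0          # like-charge: no attraction
  # r13 bins: 3.0-7.8 A, 0.3 A steps
  r13_lo <- 3.0; r13_step <- 0.3; n13 <- 16L
  c13 <- r13_lo + (seq_len(n13) - 0.5) * r13_step
  r13_gen <- .band(c13, 4.9, 6.0, -0.5) + .band(c13, 6.1, 7.3, -0.5)
  r13_class <- rbind(H = .band(c13, 4.9, 6.0, -0.5),
                     E = .band(c13, 6.1, 7.3, -0.5),
                     C = rep(0, n13))
  # signed r14 bins: -10.8..10.8 A, 0.6 A steps; the sign encodes backbone
  # chirality (positive = right-handed twist)
  r14_lo <- -10.8; r14_step <- 0.6; n14 <- 36L
  c14 <- r14_lo + (seq_len(n14) - 0.5) * r14_step
  r14_gen <- .band(c14, 4.4, 5.9, -0.5) + .band(c14, 8.8, 10.3, -0.5) +
             .band(c14, -5.9, -4.4, 0.3)   # left-handed helix penalized
  r14_class <- rbind(H = .band(c14, 4.4, 5.9, -0.5),
                     E = .band(c14, 8.8, 10.3, -0.5),
                     C = rep(0, n14))
  w <- c(contact = 1, hbond = 1, short = 1, restraint = 1)
  w[names(weights)] <- weights
  structure(list(
    hardcore_ca = 3.3, hardcore_cb = 2.5,
    r_rep = 3.0, r_min = 4.0, r_max = 6.5, eps_rep = 2.0, eps = eps,
    hb_lo = 4.6, hb_hi = 5.4, hb_colin = 0.5, e_hb = 1.0, e_coop = 0.5,
    r13_lo = r13_lo, r13_step = r13_step, r13_gen = r13_gen, r13_class = r13_class,
    r14_lo = r14_lo, r14_step = r14_step, r14_gen = r14_gen, r14_class = r14_class,
    weights = w), class = "energy_model")
}

#' Read / write an energy model as a key = value config file
#' @param model an `energy_model`
#' @param path file path
#' @export
write_energy_model <- function(model, path) {
  flat <- unclass(model)
  lines <- vapply(names(flat), function(nm) {
    v <- flat[[nm]]
    paste0(nm, " = ", paste(format(as.vector(v), digits = 10), collapse = " "))
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_energy_model
#' @export
read_energy_model <- function(path) {
  base <- default_energy_model()
  lines <- readLines(path)
  for (ln in lines[nzchar(trimws(lines))]) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    nm <- trimws(kv[1])
    vals <- as.numeric(strsplit(trimws(kv[2]), "\\s+")[[1]])
    if (!nm %in% names(base)) stop(sprintf("unknown energy-model key '%s'", nm))
    tmpl <- base[[nm]]
    if (is.matrix(tmpl)) {
      m <- matrix(vals, nrow(tmpl), ncol(tmpl))
      dimnames(m) <- dimnames(tmpl)
      base[[nm]] <- m
    } else {
      v <- vals
      names(v) <- names(tmpl)
      base[[nm]] <- v
    }
  }
  base
}

# per-residue class vectors for the C++ core (0-based)
.seq_classes <- function(sequence) {
  s <- strsplit(sequence, "")[[1]]
  cc <- .contact_class[s]; hh <- .hec_class[s]; ds <- .sc_distance[s]
  if (anyNA(cc)) stop(sprintf("unknown residue type(s): %s",
                              paste(unique(s[is.na(cc)]), collapse = ",")))
  list(cclass = as.integer(cc - 1L), hec = as.integer(hh), dsc = unname(ds))
}

.empty_restraints <- function() matrix(numeric(0), ncol = 5)

.restraint_matrix <- function(restraints) {
  if (is.null(restraints) || (is.data.frame(restraints) && nrow(restraints) == 0))
    return(.empty_restraints())
  as.matrix(restraints[, c("i", "j", "d0", "tol", "weight")])
}

.energy_terms <- function(conf, model, restraints = NULL) {
  cls <- .seq_classes(conf$sequence)
  cpp_energy(conf$ca, conf$spacing, unclass(model),
             cls$cclass, cls$hec, cls$dsc, .restraint_matrix(restraints))
}

#' Total reduced-model energy
#'
#' Weighted sum of excluded volume (0 or +Inf), side-chain contacts,
#' cooperative hydrogen bonds, generic and sequence-dependent short-range
#' bias, and restraint energy. Returns `+Inf` when the hard core is
#' violated.
#'
#' @param conf a `lattice_conf`
#' @param model an `energy_model`
#' @param restraints a `restraint_set` or NULL
#' @return numeric scalar in reduced units
#' @export
energy_total <- function(conf, model = default_energy_model(), restraints = NULL) {
  unname(.energy_terms(conf, model, restraints)["total"])
}

#' Energy components
#' @inheritParams energy_total
#' @return named numeric vector of unweighted terms plus the weighted total
#' @export
energy_components <- function(conf, model = default_energy_model(), restraints = NULL) {
  .energy_terms(conf, model, restraints)
}

#' Hard-core excluded volume term
#' @inheritParams energy_total
#' @return 0, or `+Inf` if any non-bonded Calpha-Calpha pair is closer than
#'   `hardcore_ca` or any Cbeta-Cbeta pair closer than `hardcore_cb`
#' @export
excluded_volume <- function(conf, model = default_energy_model()) {
  unname(.energy_terms(conf, model)["excluded_volume"])
}

#' Square-well side-chain contact term
#' @inheritParams energy_total
#' @return summed well energies over side-chain-center pairs with sequence
#'   separation >= 3 (unweighted)
#' @export
pair_contact_energy <- function(conf, model = default_energy_model()) {
  unname(.energy_terms(conf, model)["contact"])
}

#' Cooperative main-chain hydrogen-bond term
#' @inheritParams energy_total
#' @return `-e_hb` per geometric H-bond plus `-e_coop` per pair of bonds
#'   adjacent in both partners (unweighted)
#' @export
hbond_energy <- function(conf, model = default_energy_model()) {
  unname(.energy_terms(conf, model)["hbond"])
}

#' Short-range bias (generic + sequence-dependent)
#' @inheritParams energy_total
#' @return sum of the generic and sequence-dependent binned-table terms over
#'   all 3- and 4-residue windows (unweighted)
#' @export
short_range_energy <- function(conf, model = default_energy_model()) {
  t <- .energy_terms(conf, model)
  unname(t["short_generic"] + t["short_seq"])
}
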