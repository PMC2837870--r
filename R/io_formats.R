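#' @useDynLib latticeloop, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

# Standard residues accepted for modeling; MSE is read and treated as MET.
.standard_aa3 <- c("ALA","ARG","ASN","ASP","CYS","GLN","GLU","GLY","HIS","ILE",
                   "LEU","LYS","MET","PHE","PRO","SER","THR","TRP","TYR","VAL")
.aa3to1 <- c(ALA="A",ARG="R",ASN="N",ASP="D",CYS="C",GLN="Q",GLU="E",GLY="G",
             HIS="H",ILE="I",LEU="L",LYS="K",MET="M",PHE="F",PRO="P",SER="S",
             THR="T",TRP="W",TYR="Y",VAL="V")
.aa1to3 <- setNames(names(.aa3to1), unname(.aa3to1))

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Construct a structure object
#'
#' A structure is an ordered table of atoms grouped into residues, in the
#' order they appeared in the source file. Coordinates are in Angstrom.
#'
#' @param id structure identifier (e.g. a PDB code)
#' @param atoms data.frame with columns `elety` (atom name), `resid`
#'   (3-letter residue name), `chain`, `resno` (author numbering, integer),
#'   `insert` (insertion code, "" if none), `x`, `y`, `z`, `o` (occupancy)
#' @return an object of class `llstructure`
#' @export
new_structure <- function(id, atoms) {
  stopifnot(is.data.frame(atoms),
            all(c("elety","resid","chain","resno","insert","x","y","z") %in% names(atoms)))
  if (is.null(atoms$o)) atoms$o <- 1
  atoms$insert[is.na(atoms$insert)] <- ""
  structure(list(id = id, atoms = atoms), class = "llstructure")
}

#' @export
print.llstructure <- function(x, ...) {
  res <- residue_table(x)
  cat(sprintf("<llstructure %s: %d atoms, %d residues, chain(s) %s>\n",
              x$id, nrow(x$atoms), nrow(res),
              paste(unique(res$chain), collapse = ",")))
  invisible(x)
}

# one row per residue, file order
residue_table <- function(struct) {
  a <- struct$atoms
  key <- paste(a$chain, a$resno, a$insert, sep = "|")
  first <- !duplicated(key)
  data.frame(chain = a$chain[first], resno = a$resno[first],
             insert = a$insert[first], resid = a$resid[first],
             key = key[first], stringsAsFactors = FALSE)
}

# pick the modeled chain: explicit > single chain > "A"
select_chain <- function(struct, chain = NULL) {
  chains <- unique(struct$atoms$chain)
  if (!is.null(chain) && nzchar(chain)) {
    if (!chain %in% chains)
      stop(sprintf("chain '%s' not present in structure %s", chain, struct$id))
    return(chain)
  }
  if (length(chains) == 1L) return(chains)
  if ("A" %in% chains) return("A")
  stop(sprintf("structure %s has multiple chains (%s) and no chain was specified",
               struct$id, paste(chains, collapse = ",")))
}

#' Calpha coordinates of one chain
#'
#' @param struct an `llstructure`
#' @param chain chain id; defaults to the single chain (or chain A)
#' @return numeric matrix (n x 3) with rownames `resno|insert`; residues
#'   lacking coordinates are omitted
#' @export
ca_coords <- function(struct, chain = NULL) {
  ch <- select_chain(struct, chain)
  a <- struct$atoms[struct$atoms$chain == ch & struct$atoms$elety == "CA", , drop = FALSE]
  m <- as.matrix(a[, c("x","y","z")])
  rownames(m) <- paste0(a$resno, ifelse(nzchar(a$insert), a$insert, ""))
  m
}

#' One-letter sequence of one chain
#' @inheritParams ca_coords
#' @export
structure_sequence <- function(struct, chain = NULL) {
  ch <- select_chain(struct, chain)
  res <- residue_table(struct)
  res <- res[res$chain == ch, , drop = FALSE]
  paste(.aa3to1[res$resid], collapse = "")
}

#' Read a PDB file
#'
#' Parses ATOM records of the first MODEL. HETATM records are ignored except
#' selenomethionine (MSE), which is read as MET. Alternate locations are
#' resolved per atom by highest occupancy, ties broken by file order.
#' Non-standard residues other than MSE are rejected. Every residue must
#' carry a CA atom.
#'
#' @param path path to a PDB file
#' @param id optional structure id (default: file base name)
#' @return an `llstructure`
#' @export
read_pdb <- function(path, id = NULL) {
  if (!file.exists(path)) stop(sprintf("PDB file not found: %s", path))
  pdb <- bio3d::read.pdb(path, multi = FALSE, rm.alt = FALSE, verbose = FALSE)
  a <- pdb$atom
  keep <- a$type == "ATOM" | (a$type == "HETATM" & a$resid == "MSE")
  a <- a[keep, , drop = FALSE]
  if (nrow(a) == 0L) stop(sprintf("no ATOM records in %s", path))
  a$resid[a$resid == "MSE"] <- "MET"
  a$elety[a$elety == "SE"] <- "SD"
  bad <- setdiff(unique(a$resid), .standard_aa3)
  if (length(bad) > 0)
    stop(sprintf("non-standard residue(s) in %s: %s", path, paste(bad, collapse = ", ")))
  a$insert[is.na(a$insert)] <- ""
  a$chain[is.na(a$chain)] <- "A"
  if (is.null(a$o)) a$o <- 1
  a$o[is.na(a$o)] <- 1
  # altloc resolution: highest occupancy then first occurrence, per atom slot
  akey <- paste(a$chain, a$resno, a$insert, a$elety, sep = "|")
  ord <- order(match(akey, unique(akey)), -a$o, seq_len(nrow(a)))
  a <- a[ord, , drop = FALSE]
  a <- a[!duplicated(paste(a$chain, a$resno, a$insert, a$elety, sep = "|")), , drop = FALSE]
  # restore file order of residues
  a <- a[order(match(paste(a$chain, a$resno, a$insert, sep = "|"),
                     unique(paste(a$chain, a$resno, a$insert, sep = "|")))), , drop = FALSE]
  st <- new_structure(id %||% sub("\\.(pdb|ent)$", "", basename(path)),
                      a[, c("elety","resid","chain","resno","insert","x","y","z","o")])
  res <- residue_table(st)
  has_ca <- res$key %in% paste(a$chain, a$resno, a$insert, sep = "|")[a$elety == "CA"]
  if (any(!has_ca)) {
    r <- res[!has_ca, ][1, ]
    stop(sprintf("residue %s%s%s (%s) has no CA atom",
                 r$chain, r$resno, r$insert, r$resid))
  }
  st
}

#' Write a structure as a PDB file
#'
#' Emits standard fixed-width ATOM records (8.3 coordinate fields), a TER
#' record after each chain, and END.
#'
#' @param struct an `llstructure`
#' @param path output path
#' @return invisibly, the path
#' @export
write_pdb <- function(struct, path) {
  con <- file(path, "w")
  on.exit(close(con))
  a <- struct$atoms
  n <- nrow(a)
  serial <- 0L
  if (n > 0) {
    for (ch in unique(a$chain)) {
      rows <- which(a$chain == ch)
      for (r in rows) {
        serial <- serial + 1L
        elety <- a$elety[r]
        # atom-name column convention: 1-3 char names start in column 14
        name <- if (nchar(elety) >= 4) substr(elety, 1, 4) else sprintf(" %-3s", elety)
        writeLines(sprintf("ATOM  %5d %4s %3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f",
                           serial, name, a$resid[r], ch, a$resno[r],
                           ifelse(nzchar(a$insert[r]), a$insert[r], " "),
                           a$x[r], a$y[r], a$z[r], a$o[r], 0), con)
      }
      serial <- serial + 1L
      last <- rows[length(rows)]
      writeLines(sprintf("TER   %5d      %3s %1s%4d",
                         serial, a$resid[last], ch, a$resno[last]), con)
    }
  }
  writeLines("END", con)
  invisible(path)
}

#' Parse a loop benchmark table
#'
#' The dialect is one row per loop length: `length<TAB>code start-end, code
#' start-end, ...`. Each `code start-end` token becomes one loop
#' specification; the declared row length must equal `end - start + 1`.
#'
#' @param text the table as a character scalar (or vector of lines); or use
#'   `path`
#' @param path path to a file containing the table
#' @return a data.frame of class `loopspec_table` with columns `pdb_code`,
#'   `start`, `end`, `length`, `chain` (empty = unspecified)
#' @export
parse_benchmark_table <- function(text = NULL, path = NULL) {
  if (is.null(text)) {
    stopifnot(!is.null(path))
    text <- readLines(path)
  }
  lines <- unlist(strsplit(paste(text, collapse = "\n"), "\n"))
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  out <- list()
  for (ln in lines) {
    parts <- strsplit(ln, "\t")[[1]]
    if (length(parts) < 2) next
    len <- suppressWarnings(as.integer(parts[1]))
    if (is.na(len)) next  # header row
    tokens <- trimws(strsplit(paste(parts[-1], collapse = " "), ",")[[1]])
    tokens <- tokens[nzchar(tokens)]
    for (tok in tokens) {
      m <- regmatches(tok, regexec("^(\\S{4})\\s+(\\d+)-(\\d+)$", tok))[[1]]
      if (length(m) != 4)
        stop(sprintf("cannot parse loop token '%s'", tok))
      start <- as.integer(m[3]); end <- as.integer(m[4])
      if (end - start + 1L != len)
        stop(sprintf("token '%s' has length %d but row declares %d",
                     tok, end - start + 1L, len))
      out[[length(out) + 1L]] <- data.frame(
        pdb_code = m[2], start = start, end = end, length = len,
        chain = "", stringsAsFactors = FALSE)
    }
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(pdb_code = character(), start = integer(), end = integer(),
               length = integer(), chain = character(), stringsAsFactors = FALSE)
  class(res) <- c("loopspec_table", class(res))
  res
}

#' Create a loop specification
#'
#' @param pdb_code structure identifier
#' @param start,end author residue numbers, 1-based inclusive range
#' @param chain chain id ("" = the single/first chain)
#' @return a `loopspec`
#' @export
loop_spec <- function(pdb_code, start, end, chain = "") {
  stopifnot(end >= start)
  structure(list(pdb_code = pdb_code, start = as.integer(start),
                 end = as.integer(end), chain = chain,
                 length = as.integer(end - start + 1L)),
            class = "loopspec")
}

#' Excise a loop from a structure
#'
#' Removes the coordinates of the loop residues while retaining their
#' identities, producing the modeling problem: a scaffold plus the native
#' loop CA coordinates kept aside for evaluation.
#'
#' @param struct an `llstructure`
#' @param spec a `loopspec` (author numbering, inclusive)
#' @return an `excised_case`: list with `scaffold` (structure without loop
#'   atoms), `native_loop` (data.frame resno/x/y/z of loop CA), `sequence`
#'   (full-chain 1-letter string), `loop_idx` (positions of the loop within
#'   the chain), `chain`, `struct_id`, `spec`
#' @export
excise_loop <- function(struct, spec) {
  ch <- select_chain(struct, if (nzchar(spec$chain)) spec$chain else NULL)
  a <- struct$atoms
  in_chain <- a$chain == ch
  res <- residue_table(struct)
  res <- res[res$chain == ch, , drop = FALSE]
  want <- seq(spec$start, spec$end)
  present <- want %in% res$resno[res$insert == ""]
  if (!all(present))
    stop(sprintf("loop range %d-%d not fully resolved in %s chain %s (missing %s)",
                 spec$start, spec$end, struct$id, ch,
                 paste(want[!present], collapse = ",")))
  loop_idx <- match(want, res$resno)
  if (any(diff(loop_idx) != 1L))
    stop(sprintf("loop range %d-%d is not contiguous in %s chain %s",
                 spec$start, spec$end, struct$id, ch))
  is_loop_atom <- in_chain & a$resno %in% want & a$insert == ""
  ca_loop <- a[is_loop_atom & a$elety == "CA", , drop = FALSE]
  ca_loop <- ca_loop[order(ca_loop$resno), , drop = FALSE]
  scaffold <- new_structure(struct$id, a[!is_loop_atom, , drop = FALSE])
  structure(list(
    scaffold = scaffold,
    native_loop = data.frame(resno = ca_loop$resno, x = ca_loop$x,
                             y = ca_loop$y, z = ca_loop$z),
    sequence = paste(.aa3to1[res$resid], collapse = ""),
    resno = res$resno,
    loop_idx = loop_idx,
    chain = ch,
    struct_id = struct$id,
    spec = spec), class = "excised_case")
}

#' @export
print.excised_case <- function(x, ...) {
  cat(sprintf("<excised_case %s: chain %s, %d residues, loop %d-%d (length %d)>\n",
              x$struct_id, x$chain, nchar(x$sequence),
              x$spec$start, x$spec$end, length(x$loop_idx)))
  invisible(x)
}

#' Re-insert the native loop into an excised case
#'
#' Inverse of [excise_loop()] (CA trace): returns a structure whose chain
#' holds scaffold plus native loop CA coordinates in residue order.
#'
#' @param case an `excised_case`
#' @return an `llstructure`
#' @export
reinsert_loop <- function(case) {
  sc <- case$scaffold$atoms
  nl <- case$native_loop
  seq3 <- .aa1to3[strsplit(case$sequence, "")[[1]]]
  loop_atoms <- data.frame(
    elety = "CA", resid = seq3[case$loop_idx], chain = case$chain,
    resno = nl$resno, insert = "", x = nl$x, y = nl$y, z = nl$z, o = 1,
    stringsAsFactors = FALSE)
  all_atoms <- rbind(sc[, names(loop_atoms)], loop_atoms)
  all_atoms <- all_atoms[order(match(all_atoms$chain, unique(sc$chain)),
                               all_atoms$resno), , drop = FALSE]
  new_structure(case$struct_id, all_atoms)
}

#' Full-chain native CA coordinates of an excised case (benchmark oracle)
#' @param case an `excised_case`
#' @return n x 3 matrix in chain order (scaffold + native loop)
#' @export
native_ca <- function(case) {
  ca_sc <- ca_coords(case$scaffold, case$chain)
  n <- nchar(case$sequence)
  m <- matrix(NA_real_, n, 3)
  sc_idx <- setdiff(seq_len(n), case$loop_idx)
  m[sc_idx, ] <- ca_sc
  m[case$loop_idx, ] <- as.matrix(case$native_loop[, c("x","y","z")])
  rownames(m) <- case$resno
  m
}
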