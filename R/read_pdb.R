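#' Read a PDB file into a flat atom table
#'
#' Thin wrapper around [bio3d::read.pdb()] that flattens the result into a
#' single atom data.frame and applies deterministic alternate-location
#' handling: within each (chain, resno, insert, atom name) group the altloc
#' with the highest occupancy is kept, ties broken alphabetically, so blank
#' or 'A' conformers win in the common case. Only the first model of
#' multi-model files is used. B-factors are preserved for later correlation
#' against elastic-network predictions.
#'
#' @param path path to a PDB file containing at least one ATOM/HETATM record.
#' @return object of class `pdb_structure`: a list with `atoms` (data.frame
#'   with columns record, serial, name, altloc, resname, chain, resno,
#'   insert, x, y, z, occupancy, b, element) and `source`.
#' @export
read_pdb <- function(path) {
  if (!file.exists(path)) stop(sprintf("cannot read '%s': no such file", path))
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, multi = FALSE, rm.alt = FALSE,
                                     verbose = FALSE)),
    error = function(e) stop(sprintf("failed to parse '%s': %s",
                                     path, conditionMessage(e)), call. = FALSE))
  a <- pdb$atom
  if (is.null(a) || nrow(a) == 0L)
    stop(sprintf("'%s' contains no ATOM/HETATM records", path))
  atoms <- data.frame(
    record = a$type,
    serial = a$eleno,
    name = a$elety,
    altloc = ifelse(is.na(a$alt), "", a$alt),
    resname = a$resid,
    chain = ifelse(is.na(a$chain), "", a$chain),
    resno = a$resno,
    insert = ifelse(is.na(a$insert), "", a$insert),
    x = a$x, y = a$y, z = a$z,
    occupancy = ifelse(is.na(a$o), 1, a$o),
    b = ifelse(is.na(a$b), 0, a$b),
    element = element_from_record(a),
    stringsAsFactors = FALSE)
  atoms <- select_altloc(atoms)
  structure(list(atoms = atoms, source = path), class = "pdb_structure")
}

element_from_record <- function(a) {
  el <- if (!is.null(a$elesy)) toupper(trimws(a$elesy)) else rep("", nrow(a))
  blank <- is.na(el) | el == ""
  if (any(blank)) {
    # fall back on the atom name: strip digits/primes, first letter
    nm <- gsub("[0-9' ]", "", a$elety[blank])
    el[blank] <- toupper(substr(nm, 1, 1))
  }
  el
}

# keep, per atom site, the altloc with highest occupancy (alphabetical ties)
select_altloc <- function(atoms) {
  key <- paste(atoms$record, atoms$chain, atoms$resno, atoms$insert, atoms$name)
  keep <- unlist(lapply(split(seq_len(nrow(atoms)), key), function(idx) {
    if (length(idx) == 1L) return(idx)
    sub <- atoms[idx, ]
    ord <- order(-sub$occupancy, sub$altloc)
    idx[ord[1]]
  }), use.names = FALSE)
  out <- atoms[sort(keep), ]
  rownames(out) <- NULL
  out
}

#' @export
print.pdb_structure <- function(x, ...) {
  cat(sprintf("pdb_structure: %d atoms (%d ATOM, %d HETATM), chains: %s\n",
              nrow(x$atoms), sum(x$atoms$record == "ATOM"),
              sum(x$atoms$record == "HETATM"),
              paste(unique(x$atoms$chain), collapse = ", ")))
  invisible(x)
}

#' Write a structure or bead set as a PDB file
#'
#' Uses [bio3d::write.pdb()]. `node_set` beads are written as C-alpha ATOM
#' records (protein) and HETATM records (ligand), which lets every fixture
#' round-trip through [read_pdb()].
#'
#' @param x a `pdb_structure` or `node_set`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(x, path) UseMethod("write_pdb")

#' @export
write_pdb.pdb_structure <- function(x, path) {
  a <- x$atoms
  bio3d::write.pdb(file = path,
                   type = a$record,
                   xyz = as.numeric(t(as.matrix(a[, c("x", "y", "z")]))),
                   resno = a$resno, resid = a$resname, chain = a$chain,
                   elety = a$name, o = a$occupancy, b = a$b,
                   elesy = a$element)
  invisible(path)
}

#' @export
write_pdb.node_set <- function(x, path) {
  lab <- x$labels
  is_prot <- lab$kind == "protein"
  bio3d::write.pdb(file = path,
                   type = ifelse(is_prot, "ATOM", "HETATM"),
                   xyz = as.numeric(t(x$xyz)),
                   resno = lab$resno,
                   resid = ifelse(is_prot, lab$name, lab$name),
                   chain = lab$chain,
                   elety = ifelse(is_prot, "CA", "C1"),
                   o = rep(1, nrow(x$xyz)), b = rep(0, nrow(x$xyz)),
                   elesy = rep("C", nrow(x$xyz)))
  invisible(path)
}
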