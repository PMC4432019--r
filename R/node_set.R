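#' Coarse-grained bead set
#'
#' A `node_set` is the coarse-grained representation an elastic network is
#' built from: one bead per protein C-alpha (plus optional ligand beads),
#' each with a label, Cartesian coordinates in Angstrom and a mass.
#'
#' @param labels data.frame with columns `chain`, `resno`, `kind`
#'   (`"protein"` or `"ligand"`) and `name`. `(chain, resno, kind, name)`
#'   must be unique.
#' @param xyz numeric matrix, one row per bead, 3 columns (Angstrom).
#' @param masses positive numeric vector, recycled; default 1 for every bead
#'   (the cooperativity ratio is computed from frequency ratios and is
#'   insensitive to a common mass scale).
#' @param source free-text provenance.
#'
#' @return An object of class `node_set`.
#' @export
node_set <- function(labels, xyz, masses = 1, source = "") {
  xyz <- as.matrix(xyz)
  storage.mode(xyz) <- "double"
  if (ncol(xyz) != 3L) stop("xyz must have 3 columns")
  n <- nrow(xyz)
  if (n < 2L) stop("a node_set needs at least 2 beads")
  if (!all(is.finite(xyz))) stop("coordinates must be finite")
  labels <- as.data.frame(labels, stringsAsFactors = FALSE)
  need <- c("chain", "resno", "kind", "name")
  if (!all(need %in% names(labels)))
    stop("labels must have columns chain, resno, kind, name")
  if (nrow(labels) != n) stop("labels and xyz disagree in length")
  if (!all(labels$kind %in% c("protein", "ligand")))
    stop("kind must be 'protein' or 'ligand'")
  key <- paste(labels$chain, labels$resno, labels$kind, labels$name)
  if (anyDuplicated(key)) stop("duplicate (chain, resno, kind, name) label")
  masses <- rep_len(as.numeric(masses), n)
  if (any(!is.finite(masses) | masses <= 0)) stop("masses must be positive")
  structure(list(labels = labels, xyz = xyz, masses = masses,
                 source = source),
            class = "node_set")
}

#' @export
print.node_set <- function(x, ...) {
  np <- sum(x$labels$kind == "protein")
  nl <- sum(x$labels$kind == "ligand")
  cat(sprintf("node_set: %d beads (%d protein, %d ligand)", nrow(x$xyz), np, nl))
  if (nzchar(x$source)) cat("  [", x$source, "]", sep = "")
  cat("\n")
  invisible(x)
}

#' @export
length.node_set <- function(x) nrow(x$xyz)

#' Indices of protein beads in a node_set
#' @param nodes a `node_set`.
#' @return integer vector.
#' @export
protein_beads <- function(nodes) which(nodes$labels$kind == "protein")

bead_label_string <- function(nodes, i = seq_len(nrow(nodes$xyz))) {
  with(nodes$labels[i, , drop = FALSE], paste0(chain, ":", resno, ":", name))
}

#' Resolve a bead reference to indices
#'
#' Beads may be referenced by integer index, by `"chain:resno"` string, or by
#' bare residue number (matched in every chain, the convention for modelling
#' a point mutation present in all protomers of a homomer).
#'
#' @param nodes a `node_set`.
#' @param bead integer index vector, `"chain:resno"` string, or residue number
#'   given as a character (e.g. `"132"`) to match all chains.
#' @return integer vector of bead indices.
#' @export
resolve_bead <- function(nodes, bead) {
  lab <- nodes$labels
  if (is.numeric(bead)) {
    idx <- as.integer(bead)
    if (any(idx < 1L | idx > nrow(lab))) stop("bead index out of range")
    return(idx)
  }
  if (is.character(bead)) {
    out <- integer(0)
    for (b in bead) {
      if (grepl(":", b, fixed = TRUE)) {
        parts <- strsplit(b, ":", fixed = TRUE)[[1]]
        hit <- which(lab$chain == parts[1] & lab$resno == as.integer(parts[2]) &
                       lab$kind == "protein")
      } else {
        hit <- which(lab$resno == as.integer(b) & lab$kind == "protein")
      }
      if (!length(hit)) stop(sprintf("no bead matching '%s'", b))
      out <- c(out, hit)
    }
    return(unique(out))
  }
  stop("bead must be numeric or character")
}
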